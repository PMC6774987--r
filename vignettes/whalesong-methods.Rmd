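---
title: "Quantifying humpback song similarity and assigning singers to populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying humpback song similarity and assigning singers to populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Male humpback whales sing long, hierarchically structured displays: discrete
sounds ("units") form stereotyped "phrases", repeated phrases form numbered
"themes", and a set order of themes forms a song; songs sharing theme content
belong to a "song type". Within a wintering population most singers converge
on one song type per season, while whole song types are transmitted between
populations, generally west to east across the South Pacific. A migratory
stopover where several populations' routes overlap is a natural place for
that transmission to happen. This package implements the sequence-analysis
side of that question: given transcribed songs from several wintering
grounds and from a stopover, how similar are they, and which population did
each stopover singer most plausibly come from?

# The similarity model

All comparisons are edit distances over label sequences. For sequences $a$
and $b$, the weighted Levenshtein distance $d_w(a, b)$ is the minimum total
cost of insertions, deletions (each costing 1) and substitutions (costing
$c(x, y) \in [0, 1]$) converting $a$ into $b$, computed by full
dynamic programming. The Levenshtein similarity index normalises by the
longer sequence:

$$\mathrm{LSI}(a, b) \;=\; 1 - \frac{d_w(a, b)}{\max(|a|, |b|)} \in [0, 1].$$

The denominator is the longer string's length: with indel cost 1 this is the
standard normalisation that guarantees the unit interval, since
$d_w \le \max(|a|,|b|)$ whenever substitution costs do not exceed the indel
cost. "Normalising to account for length" admits other readings; this one is
the conventional choice and the only structural constraint we rely on
(`lsi = 1` exactly when `weighted_ld = 0`).

Similarity is assessed at two levels:

* **fine scale** — per theme, the sequences of units making up each singer's
  phrase strings, compared with the *weighted* LSI so that swapping a unit
  for an acoustically similar one (a common population-level idiosyncrasy)
  costs little;
* **broad scale** — per singer, the sequence of themes making up the song,
  compared *unweighted* (themes are categorical; there is no natural theme
  substitution cost).

A singer's representative "median" string at either level is the **medoid**:
the attested rendition minimising the summed edit distance to the singer's
other renditions, with ties broken by order of occurrence. A medoid (rather
than, say, a majority-vote consensus) keeps the representative an actual
production of the singer and is well defined under any cost matrix.

## Substitution costs from acoustic features

Each unit type carries 11 measurements (duration; minimum, maximum, peak,
start and end frequency; bandwidth; start/end and min/max frequency ratios;
inflection count; pulse rate, 0 for non-pulsed units). The cost between two
unit types is computed from per-type centroids — the feature-wise *median*
over measured exemplars, robust to rare unit types measured once or twice —
min–max normalised to $[0,1]$ across types, as the mean absolute normalised
difference over the 11 features. This yields costs in $[0,1]$, zero iff the
centroids coincide, symmetric, and invariant to affine rescaling of any
feature (so units of measurement are irrelevant). Features constant across
all types carry no information and are dropped from the mean with a warning.
The underlying field analyses derived costs "as part of CART" without
printing a formula; because of that ambiguity the cost matrix can also be
read from a CSV (`read_cost_matrix()`), so an externally derived matrix can
be substituted without touching the rest of the pipeline. At build time the
matrix is checked for the triangle inequality and flagged accordingly
(when it holds, the weighted edit distance is a true metric).

A classification-tree check (`classification_consistency()`, built on
`rpart` under stratified k-fold cross-validation) reports how well the 11
features predict the human-assigned unit labels — a consistency check on the
transcription, not part of the similarity computation.

# Clustering and bootstrap support

LSI matrices are converted to distances $d = 1 - \mathrm{LSI}$ and clustered
with average linkage (UPGMA, via `stats::hclust`), giving an ultrametric
merge tree. Node reliability uses the multiscale bootstrap: at scale ratios
$r \in \{0.5, 0.6, \ldots, 1.4\}$, $\lceil r\,m\rceil$ of the $m$ feature
rows of the item-profile matrix are resampled with replacement $B = 1000$
times, items are reclustered, and each original node's recovery frequency
$\mathrm{BP}_r$ is recorded. Per node, $\Phi^{-1}(1-\mathrm{BP}_r)$ is
regressed on $(\sqrt{r}, 1/\sqrt{r})$ by weighted least squares with
binomial weights, giving signed distance $v$ and curvature $c$; the
approximately unbiased support is $\mathrm{AU} = 1 - \Phi(v - c)$, with a
delta-method standard error from the fit covariance. Numerical guards:
frequencies of 0 or 1 are clipped to $1/(2B)$ and $1 - 1/(2B)$ before the
probit transform; nodes recovered in *every* replicate at every scale (or in
none) leave the regression unidentified and are assigned AU 1 (resp. 0, with
a flag) directly. Raw BP is reported at the scale closest to 1.

**What is resampled.** For a similarity matrix computed directly from edit
distances there is no underlying observation-by-feature data matrix, so the
resampling unit is genuinely open. By default each item's profile is its
vector of distances to all items (so $m$ equals the number of items); when
the matrix does derive from per-item feature vectors, an explicit profile
matrix can be passed (`multiscale_bootstrap(..., profiles = X)`) and its
rows are resampled instead, which is the classical setting in which the AU
extrapolation is asymptotically calibrated. With the short default profiles
the AU values are the more approximate — one reason published AU/BP values
are only expected to reproduce approximately.

Thresholds follow the field convention: AU > 0.95 defines a *stable*
cluster; BP > 0.70 is reported but never gates anything. `stable_clusters()`
returns the *maximal* ("highest level") supported nodes, mirroring how boxes
are drawn on published dendrograms; the root is excluded. The cophenetic
correlation coefficient (CCC) between input and tree-implied distances is
reported per tree, with > 0.8 read as a faithful dendrogram; it equals 1
exactly on ultrametric input.

# Origin assignment

Three independent lines of evidence per eligible stopover singer:

1. **Percent matched** — $100 \times$ (phrase types shared with a ground's
   pooled inventory) / (phrase types in the singer's recording). The ground
   with the strictly highest percentage is called; any tie for the maximum
   leaves the singer unassigned.
2. **Fine-scale LSI** — per theme, the singer's phrase string is followed
   outward through the supported (AU > 0.95) nodes of that theme's tree to
   the *innermost* one containing wintering-ground strings: exactly one
   ground there gives a call, several grounds give none. Per-theme calls
   must agree; conflicting themes leave the singer unassigned.
3. **Broad-scale LSI** — the same innermost-supported-cluster rule on the
   song-level tree.

The innermost-cluster reading deserves a note. The published rule links a
singer when it is "grouped in a stable cluster with a phrase string from
only one wintering ground". If only the *maximal* supported boxes were
eligible, broad-scale assignment would be structurally impossible whenever a
whole song-type block is itself strongly supported (the box then spans every
ground singing that type) — yet broad-scale assignments are reported in the
field. Walking outward from the singer to the first supported node that
contains ground members implements the rule as used while staying
conservative: an uninformative all-stopover subcluster is skipped, and the
first informative node decides, one ground or nothing.

Eligibility is conservative: singers recorded with a single theme carry no
sequence information and are excluded (`single_phrase_type`), as are singers
whose repertoire is self-contradictory — a phrase type found at exactly one
ground together with phrase types absent from that ground
(`exclusive_phrase_conflict`). Every exclusion is logged with its reason
rather than forcing any particular headline count, since published totals
leave a two-singer gap between the stated exclusions and the number
analysed.

**Consensus** is strict by default: all three methods must produce a call
and name the same ground. Strictness is the only reading that reproduces the
published count of three-way agreements; a lenient mode (at least two calls,
none disagreeing) is available but off by default. By construction a
non-missing consensus implies all three per-method calls equal it.

# The synthetic song-culture generator

`generate_corpus()` builds a study with known ground truth so every stage is
testable without recordings. Its moving parts, and what they emulate:

* Unit types are drawn in **acoustic-neighbour pairs** (a perturbed copy at
  moderate feature distance), because both population-private phrase
  variants and transcription noise substitute a unit for a similar-sounding
  one; neighbour substitution costs sit below the inventory's median cost.
* Each population sings one song type; per theme it carries, with
  probability `variant_rate` (0.9 at field scale — population-specific
  phrase combinations were the norm in the field data), a **private phrase
  variant**: one unit swapped for its neighbour, earning a new phrase-type
  letter. With probability `theme_variant_rate` (0.5) a population also
  omits one theme of its type, the broad-scale analogue of fine-scale
  population signal.
* Transcription noise is independent per unit: substitution to the unit's
  neighbour (`sub`), insertion of a random unit (`ins`), deletion (`del`) —
  the simplest model under which the edit distance is the natural recovery
  statistic. Defaults 0.02/0.01/0.01.
* Stopover singers draw a true origin from mixture weights (zero weight
  models a population whose whales do not pass the stopover); a fraction
  `incomplete_rate` of stopover recordings (0.2 at field scale, matching the
  field study's 8 of 39 single-theme singers) captures only one theme and is
  later excluded by the eligibility filter.

`field_scale_preset()` fixes the design at the field study's shape: six
grounds with 11, 11, 8, 7, 8, 7 singers, 39 stopover singers, song type 3
confined to EA, type 2 in the west, type 1a central, and stopover weights 0
for EA and FP.

What the generator does **not** emulate: song evolution within a season,
theme revisits and truncated phrase renditions, transcriber-specific label
drift, hybrid singers, and realistic sharing of phrase variants between
adjacent populations. Passing recovery tests therefore show the pipeline
recovers structure *of the kind the analysis assumes*, at realistic sizes
and noise — not that real corpora are this clean. In particular the
synthetic broad scale carries more population signal than the field data
(where only three broad-scale links were found), so synthetic consensus
rates are higher than field ones.

# Numerical and testing choices

* Dynamic programming uses the full $(|a|+1)\times(|b|+1)$ table in C++ —
  strings are tens of units, no banding needed. Equality with a memoised
  recursive oracle is asserted over random inventories and cost matrices.
* UPGMA is cross-checked against a naive $O(n^3)$ average-linkage oracle on
  random matrices (cophenetic equality within $10^{-9}$).
* Degenerate inputs: two empty sequences have no LSI (error); corpora with a
  single eligible singer refuse song-level analysis; themes sung by fewer
  than two singers are skipped in the fine-scale loop; similarity matrices
  whose distances are all zero return CCC 1 when the tree reproduces them
  exactly and NA otherwise.
* Bootstrap-heavy checks in the test suite run at $B$ between 100 and 200
  with 4–12 items; the calibration and field-scale recovery checks run at
  the full $B = 1000$. The field-scale end-to-end run (52 + 39 singers,
  eleven themes plus the song level, $10^4$ replicates each) completes in
  about three and a half minutes on one core.
* All randomness — generation, fold assignment, resampling — funnels through
  explicit integer seeds; identical inputs and seeds reproduce artefacts
  byte-for-byte.

# Limitations

* The substitution-cost formula is a reasoned reconstruction (the source
  analyses did not print one); conclusions sensitive to the exact costs
  should be re-run with an externally supplied matrix.
* AU support from distance-profile resampling is approximate in small
  matrices (the extrapolation is asymptotic in the number of profile rows);
  published AU/BP values are expected to reproduce only approximately.
* Singer identity follows the transcription convention that silence or
  singer overlap starts a new suffixed "singer"; the package never merges
  suffixed singers, so singer counts are conventions, not animal counts.
* Audio, spectrograms and unit segmentation are out of scope: the pipeline
  starts at transcriptions.
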