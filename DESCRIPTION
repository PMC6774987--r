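Package: whalesong
Title: Song Similarity and Origin Assignment for Humpback Whale Song Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying similarity among humpback whale song
    transcriptions and assigning migratory-stopover singers to likely
    wintering-ground populations. Implements the weighted Levenshtein
    distance and its length-normalised similarity index (LSI) over unit and
    theme sequences, acoustic-feature-based substitution costs, medoid
    (median) representative strings, average-linkage (UPGMA) clustering with
    multiscale-bootstrap approximately unbiased (AU) node support,
    stable-cluster extraction, cophenetic validation, a percent-matched
    phrase-repertoire statistic, and a rule-based consensus assignment of
    stopover singers to populations. Includes a synthetic song-culture
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
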