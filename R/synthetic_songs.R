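#' Configuration for the synthetic song-culture generator
#'
#' Describes a set of wintering-ground populations, each singing one song
#' type with population-specific phrase (and possibly theme-sequence)
#' variants, plus a mixed-origin migratory-stopover sample, with independent
#' per-unit transcription noise and full ground truth.
#'
#' @param populations location codes of the wintering-ground populations
#'   (subset of EA, NC, TO, NI, CI, FP).
#' @param song_type_assignments named character vector mapping each
#'   population to a song-type name of `themes_per_type`.
#' @param singers_per_population integer, scalar or named per population.
#' @param n_stopover number of stopover (KI) singers.
#' @param stopover_mixture named non-negative sampling weights per
#'   population; weight 0 models a population absent from the stopover.
#' @param n_unit_types size of the unit inventory (even; units are generated
#'   in acoustic-neighbour pairs used for variant substitution).
#' @param exemplars_per_unit measured exemplars per unit type.
#' @param units_per_phrase length-2 range of units per phrase.
#' @param phrase_repeats length-2 range of phrase repeats per theme block.
#' @param variant_rate probability a population carries a private variant of
#'   a given theme's phrase (one unit swapped for its acoustic neighbour).
#' @param theme_variant_rate probability a population's rendition of its song
#'   type omits one (population-specific) theme, creating broad-scale
#'   population signal in the theme sequence.
#' @param noise named per-unit transcription noise rates `sub` (substitute
#'   with the unit's acoustic neighbour), `ins` (insert a random unit after),
#'   `del` (delete).
#' @param incomplete_rate probability a stopover singer's recording captures
#'   only a single theme (such singers are later excluded as carrying no
#'   sequence information).
#' @param themes_per_type named list of integer theme vectors per song type;
#'   defaults to [song_type_definitions()].
#' @param seed mandatory integer seed; generation is fully deterministic
#'   given the config.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(populations = c("NC", "TO"),
                             song_type_assignments = c(NC = "2", TO = "2"),
                             singers_per_population = 5,
                             n_stopover = 10,
                             stopover_mixture = c(NC = 1, TO = 1),
                             n_unit_types = 16,
                             exemplars_per_unit = 6,
                             units_per_phrase = c(4, 8),
                             phrase_repeats = c(2, 4),
                             variant_rate = 0.9,
                             theme_variant_rate = 0.5,
                             noise = c(sub = 0.02, ins = 0.01, del = 0.01),
                             incomplete_rate = 0,
                             themes_per_type = song_type_definitions(),
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  populations <- as.character(populations)
  if (length(setdiff(populations, setdiff(LOCATION_CODES, "KI"))))
    stop("populations must be wintering-ground codes (not KI)")
  if (!all(populations %in% names(song_type_assignments)))
    stop("song_type_assignments must cover every population")
  if (!all(song_type_assignments[populations] %in% names(themes_per_type)))
    stop("unknown song type in song_type_assignments")
  if (length(singers_per_population) == 1L)
    singers_per_population <- setNames(rep(as.integer(singers_per_population),
                                           length(populations)), populations)
  if (!all(populations %in% names(singers_per_population)))
    stop("singers_per_population must cover every population")
  if (!all(populations %in% names(stopover_mixture)))
    stop("stopover_mixture must cover every population")
  stopover_mixture <- stopover_mixture[populations]
  if (any(stopover_mixture < 0) || sum(stopover_mixture) == 0)
    stop("stopover weights must be non-negative and not all zero")
  probs <- c(variant_rate, theme_variant_rate, incomplete_rate, noise)
  if (any(probs < 0 | probs > 1)) stop("rates must lie in [0, 1]")
  if (!all(c("sub", "ins", "del") %in% names(noise)))
    stop("noise must name sub, ins and del rates")
  if (n_unit_types %% 2L || n_unit_types < 2L)
    stop("n_unit_types must be even and >= 2")
  structure(list(populations = populations,
                 song_type_assignments = song_type_assignments[populations],
                 singers_per_population = singers_per_population[populations],
                 n_stopover = as.integer(n_stopover),
                 stopover_mixture = stopover_mixture,
                 n_unit_types = as.integer(n_unit_types),
                 exemplars_per_unit = as.integer(exemplars_per_unit),
                 units_per_phrase = as.integer(units_per_phrase),
                 phrase_repeats = as.integer(phrase_repeats),
                 variant_rate = variant_rate,
                 theme_variant_rate = theme_variant_rate,
                 noise = noise,
                 incomplete_rate = incomplete_rate,
                 themes_per_type = themes_per_type,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Field-scale synthetic design
#'
#' A configuration mirroring the shape of the field study: six wintering
#' grounds with 11, 11, 8, 7, 8 and 7 singers (EA, NC, TO, NI, CI, FP; 52 in
#' total), 39 stopover singers, song type 3 confined to eastern Australia,
#' type 2 dominant in the west (NC, TO, NI) and type 1a in the central
#' Pacific (CI, FP), and stopover mixture weights of zero for EA and FP
#' (populations whose whales do not pass the stopover). About a fifth of
#' stopover recordings capture only one theme, matching the study's
#' single-theme exclusions.
#'
#' @param seed mandatory integer seed.
#' @param noise per-unit transcription noise rates (see [synthetic_config()]).
#' @return A `synthetic_config`.
#' @export
field_scale_preset <- function(seed,
                               noise = c(sub = 0.02, ins = 0.01, del = 0.01)) {
  synthetic_config(
    populations = c("EA", "NC", "TO", "NI", "CI", "FP"),
    song_type_assignments = c(EA = "3", NC = "2", TO = "2", NI = "2",
                              CI = "1a", FP = "1a"),
    singers_per_population = c(EA = 11, NC = 11, TO = 8, NI = 7, CI = 8, FP = 7),
    n_stopover = 39,
    stopover_mixture = c(EA = 0, NC = 0.35, TO = 0.30, NI = 0.20,
                         CI = 0.15, FP = 0),
    n_unit_types = 24,
    variant_rate = 0.9,
    theme_variant_rate = 0.5,
    noise = noise,
    incomplete_rate = 0.2,
    seed = seed)
}

#' Generate a synthetic unit inventory with measurements
#'
#' Draws unit-type feature centroids from plausible humpback-unit ranges
#' (durations 0.1-3 s, frequencies 30-5000 Hz) and scatters exemplars around
#' them. Units are generated in acoustic-neighbour pairs — each even-indexed
#' unit is a perturbed copy of the preceding one — so substituting a unit for
#' its neighbour is cheap under the derived cost matrix; those pairs are what
#' population-private phrase variants and substitution noise swap.
#'
#' @param config a [synthetic_config()].
#' @return A `unit_feature_table` with attribute `neighbours` (data.frame
#'   `a`, `b` of paired unit labels) and attribute `labels` (inventory).
#' @export
generate_unit_inventory <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_unit_types
  labels <- sprintf("u%02d", seq_len(n))
  cent <- matrix(NA_real_, n, length(UNIT_FEATURES),
                 dimnames = list(labels, UNIT_FEATURES))
  draw_centroid <- function() {
    dur <- runif(1, 0.1, 3)
    fmin <- exp(runif(1, log(30), log(2500)))
    fmax <- min(fmin * exp(runif(1, log(1.3), log(3))), 5000)
    c(duration_s = dur, min_freq_hz = fmin, max_freq_hz = fmax,
      bandwidth_hz = fmax - fmin, peak_freq_hz = runif(1, fmin, fmax),
      start_freq_hz = runif(1, fmin, fmax), end_freq_hz = runif(1, fmin, fmax),
      freq_trend_ratio = NA, freq_range_ratio = NA,
      n_inflections = rpois(1, 1.5),
      pulse_rate_hz = if (runif(1) < 0.3) runif(1, 5, 50) else 0)
  }
  perturb_neighbour <- function(x) {
    # moderate shift: acoustically similar but measurably different
    scale <- exp(runif(4, log(0.85), log(1.18)))
    fmin <- max(x["min_freq_hz"] * scale[1], 30)
    fmax <- min(max(x["max_freq_hz"] * scale[2], fmin * 1.05), 5000)
    c(duration_s = unname(max(x["duration_s"] * scale[3], 0.05)),
      min_freq_hz = unname(fmin), max_freq_hz = unname(fmax),
      bandwidth_hz = unname(fmax - fmin),
      peak_freq_hz = unname(min(max(x["peak_freq_hz"] * scale[4], fmin), fmax)),
      start_freq_hz = unname(min(max(x["start_freq_hz"], fmin), fmax)),
      end_freq_hz = unname(min(max(x["end_freq_hz"], fmin), fmax)),
      freq_trend_ratio = NA, freq_range_ratio = NA,
      n_inflections = unname(max(x["n_inflections"] + sample(c(-1, 0, 1), 1), 0)),
      pulse_rate_hz = unname(x["pulse_rate_hz"]))
  }
  for (i in seq(1, n, by = 2)) {
    cent[i, ] <- draw_centroid()
    cent[i + 1, ] <- perturb_neighbour(cent[i, ])
  }
  rows <- vector("list", n * config$exemplars_per_unit)
  k <- 0L
  for (i in seq_len(n)) {
    for (e in seq_len(config$exemplars_per_unit)) {
      fmin <- max(cent[i, "min_freq_hz"] * exp(stats::rnorm(1, 0, 0.03)), 20)
      fmax <- max(cent[i, "max_freq_hz"] * exp(stats::rnorm(1, 0, 0.03)),
                  fmin * 1.02)
      peak <- min(max(cent[i, "peak_freq_hz"], fmin), fmax)
      sf <- min(max(cent[i, "start_freq_hz"] * exp(stats::rnorm(1, 0, 0.03)),
                    fmin), fmax)
      ef <- min(max(cent[i, "end_freq_hz"] * exp(stats::rnorm(1, 0, 0.03)),
                    fmin), fmax)
      k <- k + 1L
      rows[[k]] <- data.frame(
        unit_label = labels[i],
        duration_s = max(cent[i, "duration_s"] * exp(stats::rnorm(1, 0, 0.05)),
                         0.02),
        min_freq_hz = fmin, max_freq_hz = fmax, bandwidth_hz = fmax - fmin,
        peak_freq_hz = peak, start_freq_hz = sf, end_freq_hz = ef,
        freq_trend_ratio = sf / ef, freq_range_ratio = fmin / fmax,
        n_inflections = cent[i, "n_inflections"],
        pulse_rate_hz = cent[i, "pulse_rate_hz"])
    }
  }
  out <- unit_feature_table(do.call(rbind, rows))
  attr(out, "neighbours") <- data.frame(
    a = labels[seq(1, n, by = 2)], b = labels[seq(2, n, by = 2)],
    stringsAsFactors = FALSE)
  out
}

# neighbour lookup: partner unit of each label
neighbour_map <- function(neighbours) {
  setNames(c(neighbours$b, neighbours$a), c(neighbours$a, neighbours$b))
}

apply_unit_noise <- function(units, noise, partner, inventory) {
  out <- character(0)
  for (u in units) {
    r <- runif(3)
    if (r[1] < noise[["del"]]) {
      # deleted
    } else if (r[2] < noise[["sub"]]) {
      out <- c(out, unname(partner[u]))
    } else {
      out <- c(out, u)
    }
    if (r[3] < noise[["ins"]]) out <- c(out, sample(inventory, 1))
  }
  if (length(out) == 0L) out <- units[1]  # transcription never fully empty
  out
}

#' Generate a synthetic study: wintering grounds, stopover, ground truth
#'
#' Builds base phrase strings per theme, assigns population-private phrase
#' variants (one unit swapped for its acoustic neighbour, yielding a new
#' phrase-type letter) and population-specific theme-sequence variants, then
#' sings every singer: each theme of the population's song type is repeated
#' a few times with independent per-unit transcription noise. Stopover (KI)
#' singers draw their population of origin from the mixture weights; a
#' fraction of their recordings is truncated to a single theme.
#'
#' @param config a [synthetic_config()].
#' @return list with `grounds` and `stopover` ([song_corpus] objects, both
#'   carrying `origin_truth`), `truth` (data.frame `singer_id`, `population`,
#'   `song_type`), `clean` (named list of each singer's noise-free phrase
#'   strings), `inventory` (the `unit_feature_table`) and `repertoire` (per
#'   population, the clean phrase string and phrase-type code per theme).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  inventory <- generate_unit_inventory(config)  # seeds the RNG stream
  labels <- sort(unique(inventory$unit_label))
  neigh <- attr(inventory, "neighbours")
  partner <- neighbour_map(neigh)
  base_units <- neigh$a

  defs <- config$themes_per_type
  used_types <- unique(config$song_type_assignments)
  themes <- sort(unique(unlist(defs[used_types])))

  base_phrase <- list()
  for (th in themes) {
    len <- sample(seq(config$units_per_phrase[1], config$units_per_phrase[2]), 1)
    base_phrase[[as.character(th)]] <- sample(base_units, len, replace = TRUE)
  }

  # population repertoires: phrase string + phrase-type letter per theme,
  # and the population's (possibly shortened) theme sequence
  letters_used <- lapply(themes, function(th) "A")
  names(letters_used) <- as.character(themes)
  variant_strings <- lapply(themes, function(th)
    list(A = base_phrase[[as.character(th)]]))
  names(variant_strings) <- as.character(themes)
  repertoire <- list()
  for (pop in config$populations) {
    type <- config$song_type_assignments[[pop]]
    pop_themes <- defs[[type]]
    if (length(pop_themes) > 2 && runif(1) < config$theme_variant_rate)
      pop_themes <- pop_themes[-sample(length(pop_themes), 1)]
    rep_pop <- list()
    for (th in pop_themes) {
      key <- as.character(th)
      if (runif(1) < config$variant_rate) {
        # private variant: swap one unit for its neighbour; retry the
        # position until the string is new for this theme
        for (attempt in seq_len(10)) {
          pos <- sample(length(base_phrase[[key]]), 1)
          cand <- base_phrase[[key]]
          cand[pos] <- unname(partner[cand[pos]])
          if (!any(vapply(variant_strings[[key]], identical, logical(1), cand)))
            break
        }
        if (any(vapply(variant_strings[[key]], identical, logical(1), cand))) {
          # fell back on an existing variant: reuse its letter
          letter <- names(variant_strings[[key]])[vapply(
            variant_strings[[key]], identical, logical(1), cand)][1]
        } else {
          letter <- LETTERS[length(letters_used[[key]]) + 1L]
          letters_used[[key]] <- c(letters_used[[key]], letter)
          variant_strings[[key]][[letter]] <- cand
        }
        rep_pop[[key]] <- list(units = variant_strings[[key]][[letter]],
                               phrase_type = paste0(th, letter))
      } else {
        rep_pop[[key]] <- list(units = base_phrase[[key]],
                               phrase_type = paste0(th, "A"))
      }
    }
    repertoire[[pop]] <- list(song_type = type, themes = pop_themes,
                              phrases = rep_pop)
  }

  sing <- function(singer_id, location, recording, pop, only_first_theme) {
    rep_pop <- repertoire[[pop]]
    pop_themes <- rep_pop$themes
    if (only_first_theme) pop_themes <- pop_themes[1]
    rows <- list(); clean <- list(); idx <- 0L
    for (th in pop_themes) {
      key <- as.character(th)
      n_rep <- sample(seq(config$phrase_repeats[1], config$phrase_repeats[2]), 1)
      for (r in seq_len(n_rep)) {
        noisy <- apply_unit_noise(rep_pop$phrases[[key]]$units, config$noise,
                                  partner, labels)
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          singer_id = singer_id, location = location, recording = recording,
          phrase_index = idx,
          phrase_type = rep_pop$phrases[[key]]$phrase_type, theme = th,
          units = paste(noisy, collapse = " "), stringsAsFactors = FALSE)
      }
      clean[[key]] <- rep_pop$phrases[[key]]$units
    }
    list(rows = do.call(rbind, rows), clean = clean)
  }

  ground_rows <- list(); truth <- list(); clean_all <- list()
  for (pop in config$populations) {
    for (i in seq_len(config$singers_per_population[[pop]])) {
      sid <- sprintf("%s%02dS1", pop, i)
      s <- sing(sid, pop, i, pop, only_first_theme = FALSE)
      ground_rows[[sid]] <- s$rows
      clean_all[[sid]] <- s$clean
      truth[[sid]] <- data.frame(singer_id = sid, population = pop,
                                 song_type = repertoire[[pop]]$song_type,
                                 stringsAsFactors = FALSE)
    }
  }
  w <- config$stopover_mixture
  stop_rows <- list()
  for (i in seq_len(config$n_stopover)) {
    pop <- sample(names(w), 1, prob = w)
    sid <- sprintf("KI%02dS1", i)
    s <- sing(sid, "KI", i, pop,
              only_first_theme = runif(1) < config$incomplete_rate)
    stop_rows[[sid]] <- s$rows
    clean_all[[sid]] <- s$clean
    truth[[sid]] <- data.frame(singer_id = sid, population = pop,
                               song_type = repertoire[[pop]]$song_type,
                               stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  truth_map <- setNames(truth$population, truth$singer_id)
  ground_ids <- names(ground_rows); stop_ids <- names(stop_rows)
  list(grounds = song_corpus(do.call(rbind, ground_rows),
                             origin_truth = truth_map[ground_ids]),
       stopover = song_corpus(do.call(rbind, stop_rows),
                              origin_truth = truth_map[stop_ids]),
       truth = truth, clean = clean_all, inventory = inventory,
       repertoire = repertoire)
}

#' Write the ground-truth table
#'
#' CSV with columns `singer_id`, `population`, `song_type`.
#'
#' @param truth the `truth` element of [generate_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
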