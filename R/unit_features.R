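# The 11 acoustic measurements taken per unit: duration, minimum/maximum/
# peak frequency, bandwidth, start/end frequency, frequency trend ratio
# (start/end), frequency range ratio (min/max), inflection count and pulse
# repetition rate (0 for non-pulsed units).
UNIT_FEATURES <- c("duration_s", "min_freq_hz", "max_freq_hz", "bandwidth_hz",
                   "peak_freq_hz", "start_freq_hz", "end_freq_hz",
                   "freq_trend_ratio", "freq_range_ratio", "n_inflections",
                   "pulse_rate_hz")

#' Construct a unit feature table
#'
#' Holds per-exemplar acoustic measurements of song units: eleven frequency
#' and duration features per measured unit, keyed by the unit-type label.
#' Multiple exemplars per unit type are allowed (and needed for the
#' classification consistency check).
#'
#' @param rows data.frame with a `unit_label` column plus the 11 feature
#'   columns `duration_s`, `min_freq_hz`, `max_freq_hz`, `bandwidth_hz`,
#'   `peak_freq_hz`, `start_freq_hz`, `end_freq_hz`, `freq_trend_ratio`,
#'   `freq_range_ratio`, `n_inflections`, `pulse_rate_hz`.
#' @param bandwidth_tol tolerance (Hz) for the `bandwidth = max - min` check.
#' @return Object of class `unit_feature_table` (a validated data.frame).
#' @details Invariants enforced per row: all frequencies and the duration
#'   positive; `min_freq_hz <= peak_freq_hz <= max_freq_hz`; bandwidth equal
#'   to the frequency range within `bandwidth_tol`. Pulse rate is 0 for
#'   non-pulsed units so every unit has a complete feature vector.
#' @export
unit_feature_table <- function(rows, bandwidth_tol = 1) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("unit_label", UNIT_FEATURES)
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols))
    stop("measurement table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  rows <- rows[need]
  rows$unit_label <- canonical_units(rows$unit_label)
  for (f in UNIT_FEATURES) {
    v <- suppressWarnings(as.numeric(rows[[f]]))
    if (nrow(rows) && anyNA(v))
      stop("non-numeric value in feature '", f, "' (row ",
           which(is.na(v))[1], ")")
    rows[[f]] <- v
  }
  bad_row <- function(cond, what) {
    if (any(cond)) stop(what, " (row ", which(cond)[1], ")", call. = FALSE)
  }
  bad_row(!nzchar(rows$unit_label), "empty unit label")
  bad_row(rows$duration_s <= 0, "duration must be positive")
  freq <- c("min_freq_hz", "max_freq_hz", "peak_freq_hz",
            "start_freq_hz", "end_freq_hz")
  for (f in freq) bad_row(rows[[f]] <= 0, paste(f, "must be positive"))
  bad_row(rows$min_freq_hz > rows$peak_freq_hz |
            rows$peak_freq_hz > rows$max_freq_hz,
          "need min_freq <= peak_freq <= max_freq")
  bad_row(rows$n_inflections < 0 | rows$pulse_rate_hz < 0,
          "counts and rates must be non-negative")
  bw_gap <- abs(rows$bandwidth_hz - (rows$max_freq_hz - rows$min_freq_hz))
  if (any(bw_gap > bandwidth_tol))
    warning("bandwidth differs from max - min by more than ", bandwidth_tol,
            " Hz in ", sum(bw_gap > bandwidth_tol), " row(s)")
  structure(rows, class = c("unit_feature_table", "data.frame"))
}

#' Read a unit measurement CSV
#'
#' Expects the 12-column format `unit_label` plus the 11 feature columns of
#' [unit_feature_table()].
#'
#' @param path path to the CSV.
#' @inheritParams unit_feature_table
#' @return A `unit_feature_table`.
#' @export
read_measurements <- function(path, bandwidth_tol = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  unit_feature_table(read.csv(path, stringsAsFactors = FALSE),
                     bandwidth_tol = bandwidth_tol)
}

#' Write a unit measurement CSV
#'
#' @param table a `unit_feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(inherits(table, "unit_feature_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-label feature centroids
#'
#' Median of each feature over a label's exemplars. The median keeps the
#' centroid meaningful for rare units measured only once or twice.
#'
#' @param table a `unit_feature_table`.
#' @return matrix (labels x 11 features).
#' @export
unit_centroids <- function(table) {
  stopifnot(inherits(table, "unit_feature_table"))
  labels <- sort(unique(table$unit_label))
  cent <- matrix(NA_real_, length(labels), length(UNIT_FEATURES),
                 dimnames = list(labels, UNIT_FEATURES))
  for (lab in labels) {
    sub <- table[table$unit_label == lab, UNIT_FEATURES, drop = FALSE]
    cent[lab, ] <- vapply(sub, median, numeric(1))
  }
  cent
}

#' Check transcription naming consistency with a classification tree
#'
#' Fits a classification tree (CART) predicting the human-assigned unit label
#' from the 11 acoustic features, under k-fold cross-validation, and reports
#' the fraction of exemplars whose predicted label agrees with the human
#' label. High agreement indicates the qualitative unit naming is acoustically
#' consistent.
#'
#' @param table a `unit_feature_table` with at least 2 labels having >= 2
#'   exemplars each; single-exemplar labels are excluded with a warning.
#' @param seed integer seed controlling fold assignment (results are
#'   deterministic given the seed).
#' @param k number of cross-validation folds (capped at the smallest class
#'   size).
#' @return list with `agreement` (fraction in \[0, 1\]), `n` (exemplars used)
#'   and `confusion` (table of human vs predicted labels).
#' @export
classification_consistency <- function(table, seed, k = 5) {
  stopifnot(inherits(table, "unit_feature_table"))
  counts <- base::table(table$unit_label)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    warning("excluding single-exemplar label(s): ",
            paste(singletons, collapse = ", "))
    table <- table[!table$unit_label %in% singletons, , drop = FALSE]
  }
  labs <- unique(table$unit_label)
  if (length(labs) < 2)
    stop("need >= 2 unit labels with >= 2 exemplars each")
  dat <- as.data.frame(table)[c("unit_label", UNIT_FEATURES)]
  dat$unit_label <- factor(dat$unit_label)
  k <- max(2L, min(k, min(base::table(dat$unit_label))))
  set.seed(as.integer(seed))
  # stratified folds so every training split sees every label
  fold <- integer(nrow(dat))
  for (lab in levels(dat$unit_label)) {
    idx <- which(dat$unit_label == lab)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  pred <- factor(rep(NA_character_, nrow(dat)), levels = levels(dat$unit_label))
  for (f in seq_len(k)) {
    fit <- rpart::rpart(unit_label ~ ., data = dat[fold != f, , drop = FALSE],
                        method = "class",
                        control = rpart::rpart.control(minsplit = 4, cp = 0.001,
                                                       xval = 0))
    pred[fold == f] <- predict(fit, dat[fold == f, , drop = FALSE],
                               type = "class")
  }
  list(agreement = mean(pred == dat$unit_label),
       n = nrow(dat),
       confusion = base::table(human = dat$unit_label, predicted = pred))
}

#' Substitution-cost matrix from acoustic features
#'
#' Derives the unit-substitution costs used by the weighted edit distance
#' from acoustic feature similarity: per-label centroids (feature medians
#' over exemplars) are min-max normalised to \[0, 1\] across labels, and the
#' cost between two unit types is the mean absolute normalised difference
#' over the 11 features. Acoustically similar units thus substitute cheaply
#' (near 0) while dissimilar units approach the indel cost of 1.
#'
#' @param table a `unit_feature_table` covering every label in `labels`.
#' @param labels unit inventory to build the matrix over; defaults to all
#'   labels in `table`.
#' @return A `cost_matrix`: symmetric matrix with zero diagonal, entries in
#'   \[0, 1\], `indel_cost` attribute fixed at 1, and a `metric` attribute
#'   recording whether the costs satisfy the triangle inequality (when they
#'   do, the weighted edit distance is a true metric).
#' @details Features constant across all centroids carry no information and
#'   are dropped from the mean with a warning. The matrix can also be read
#'   from file ([read_cost_matrix()]) so externally derived costs can be
#'   substituted.
#' @export
substitution_costs <- function(table, labels = NULL) {
  cent <- unit_centroids(table)
  if (is.null(labels)) labels <- rownames(cent)
  missing_labels <- setdiff(labels, rownames(cent))
  if (length(missing_labels))
    stop("no measurements for unit label(s): ",
         paste(missing_labels, collapse = ", "))
  cent <- cent[labels, , drop = FALSE]
  rng <- apply(cent, 2, range)
  span <- rng[2, ] - rng[1, ]
  constant <- span == 0
  if (all(constant))
    stop("all features constant across unit types; costs undefined")
  if (any(constant))
    warning("dropping constant feature(s): ",
            paste(colnames(cent)[constant], collapse = ", "))
  norm <- sweep(sweep(cent[, !constant, drop = FALSE], 2, rng[1, !constant]),
                2, span[!constant], "/")
  n <- length(labels)
  costs <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      costs[i, j] <- mean(abs(norm[i, ] - norm[j, ]))
      costs[j, i] <- costs[i, j]
    }
  }
  cost_matrix(costs)
}

#' Construct a cost matrix
#'
#' @param costs symmetric numeric matrix with labelled rows/columns, zero
#'   diagonal, entries in \[0, 1\].
#' @param indel_cost cost of an insertion or deletion (fixed at 1 in the
#'   weighted similarity analyses).
#' @return A `cost_matrix` object.
#' @export
cost_matrix <- function(costs, indel_cost = 1) {
  costs <- as.matrix(costs)
  if (is.null(rownames(costs)) || is.null(colnames(costs)))
    stop("cost matrix must have labelled rows and columns")
  if (!isTRUE(all.equal(rownames(costs), colnames(costs))))
    stop("row and column labels must match")
  if (!isSymmetric(unname(costs), tol = 1e-9)) stop("cost matrix must be symmetric")
  if (any(diag(costs) != 0)) stop("cost matrix diagonal must be 0")
  if (any(costs < 0 | costs > 1)) stop("costs must lie in [0, 1]")
  structure(costs, indel_cost = indel_cost,
            metric = is_triangle(costs),
            class = c("cost_matrix", "matrix", "array"))
}

is_triangle <- function(costs, tol = 1e-9) {
  n <- nrow(costs)
  for (k in seq_len(n))
    if (any(costs > outer(costs[, k], costs[k, ], "+") + tol)) return(FALSE)
  TRUE
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat("cost_matrix:", nrow(x), "unit types; indel cost",
      attr(x, "indel_cost"),
      if (isTRUE(attr(x, "metric"))) "(triangle inequality holds)"
      else "(triangle inequality violated)", "\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Write / read a cost matrix CSV
#'
#' Square CSV with labelled rows and columns, 6-decimal fixed point.
#'
#' @param costs a `cost_matrix`.
#' @param path file path.
#' @return `path` invisibly (write); a `cost_matrix` (read).
#' @export
write_cost_matrix <- function(costs, path) {
  stopifnot(inherits(costs, "cost_matrix"))
  out <- format(round(unclass(costs), 6), nsmall = 6, trim = TRUE)
  write.csv(as.data.frame(out), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_cost_matrix
#' @export
read_cost_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  cost_matrix(m)
}
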