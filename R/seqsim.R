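#' Weighted Levenshtein distance between label sequences
#'
#' Minimum total edit cost converting sequence `a` into sequence `b`, by
#' dynamic programming over the full (|a|+1) x (|b|+1) table. Insertions and
#' deletions always cost `indel_cost` (1 by default); substitutions cost
#' `costs[x, y]` when a cost matrix is supplied, otherwise 1 for any unequal
#' pair (the classic unweighted edit distance).
#'
#' @param a,b character vectors of labels (unit types, or theme numbers as
#'   strings). Either may be empty.
#' @param costs a [cost_matrix] covering every label of `a` and `b`, or
#'   `NULL` for the unweighted distance.
#' @return Non-negative edit cost (count of edits when unweighted).
#' @seealso [lsi()] for the length-normalised similarity form.
#' @examples
#' weighted_ld(c("a", "b", "c"), c("a", "c", "d"))  # 2 edits
#' @export
weighted_ld <- function(a, b, costs = NULL) {
  a <- as.character(a); b <- as.character(b)
  if (is.null(costs)) {
    labels <- unique(c(a, b))
    if (!length(labels)) return(0)
    cm <- 1 - diag(length(labels))
    dimnames(cm) <- list(labels, labels)
    indel <- 1
  } else {
    stopifnot(inherits(costs, "cost_matrix"))
    labels <- rownames(costs)
    unknown <- setdiff(unique(c(a, b)), labels)
    if (length(unknown))
      stop("label(s) missing from cost matrix: ",
           paste(unknown, collapse = ", "))
    cm <- unclass(costs)
    indel <- attr(costs, "indel_cost")
  }
  .weighted_ld_cpp(match(a, labels), match(b, labels), cm, indel)
}

#' Levenshtein similarity index (LSI)
#'
#' The edit distance normalised by the longer sequence length and reflected
#' into a similarity: `1 - weighted_ld(a, b) / max(|a|, |b|)`. With indel
#' cost 1 and substitution costs in \[0, 1\] the LSI always lies in \[0, 1\];
#' identical sequences score 1 and maximally different sequences 0.
#'
#' @inheritParams weighted_ld
#' @return Similarity in \[0, 1\].
#' @export
lsi <- function(a, b, costs = NULL) {
  n <- max(length(a), length(b))
  if (n == 0L) stop("LSI undefined for two empty sequences")
  1 - weighted_ld(a, b, costs) / n
}

#' Medoid ("median") representative string
#'
#' The attested sequence minimising the summed edit distance to all the
#' others — the representative rendition of a singer. Ties are broken by
#' earliest position in the input, so the result is deterministic and is
#' always one of the inputs.
#'
#' @param strings non-empty list of character vectors.
#' @inheritParams weighted_ld
#' @return One element of `strings`.
#' @export
medoid_string <- function(strings, costs = NULL) {
  if (!is.list(strings) || length(strings) == 0L)
    stop("need a non-empty list of sequences")
  if (length(strings) == 1L) return(strings[[1]])
  d <- pairwise_ld(strings, costs)
  strings[[which.min(rowSums(d))]]
}

# All pairwise weighted LDs among a list of sequences (symmetric matrix).
pairwise_ld <- function(strings, costs = NULL) {
  strings <- lapply(strings, as.character)
  if (is.null(costs)) {
    labels <- unique(unlist(strings))
    if (!length(labels)) labels <- "."
    cm <- 1 - diag(length(labels))
    dimnames(cm) <- list(labels, labels)
    indel <- 1
  } else {
    stopifnot(inherits(costs, "cost_matrix"))
    labels <- rownames(costs)
    unknown <- setdiff(unique(unlist(strings)), labels)
    if (length(unknown))
      stop("label(s) missing from cost matrix: ",
           paste(unknown, collapse = ", "))
    cm <- unclass(costs)
    indel <- attr(costs, "indel_cost")
  }
  idx <- lapply(strings, function(s) match(s, labels))
  .pairwise_ld_cpp(idx, cm, indel)
}

#' Construct a similarity matrix
#'
#' @param values symmetric numeric matrix of LSI scores in \[0, 1\] with unit
#'   diagonal and labelled rows/columns.
#' @param items optional data.frame of per-row metadata (`id`, `singer_id`,
#'   `location`, and `phrase_type` at phrase level).
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(values, items = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("similarity matrix must be labelled")
  if (!isSymmetric(unname(values), tol = 1e-9)) stop("similarity matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-9) stop("diagonal must be 1")
  if (any(values < -1e-9 | values > 1 + 1e-9)) stop("similarities must lie in [0, 1]")
  structure(values, items = items,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix:", nrow(x), "items, mean off-diagonal LSI",
      round(mean(x[lower.tri(x)]), 3), "\n")
  invisible(x)
}

#' Fine-scale phrase similarity matrix for one theme
#'
#' For every singer who sang the given theme, and every phrase type of that
#' theme the singer used, the singer's medoid unit string is computed under
#' the weighted edit distance, and the pairwise weighted LSI between medoids
#' forms the matrix. Row ids follow the `singer_phraseType` convention (e.g.
#' `"KI12S2_1A"`).
#'
#' @param corpus a [song_corpus].
#' @param theme theme number present in the corpus.
#' @param costs a [cost_matrix] covering the corpus unit inventory.
#' @return A `similarity_matrix` with an `items` attribute (`id`,
#'   `singer_id`, `location`, `phrase_type`).
#' @export
phrase_similarity_matrix <- function(corpus, theme, costs) {
  stopifnot(inherits(corpus, "song_corpus"))
  rows <- corpus$phrases[corpus$phrases$theme == theme, , drop = FALSE]
  if (nrow(rows) == 0L) stop("theme ", theme, " absent from corpus")
  key <- unique(rows[c("singer_id", "location", "phrase_type")])
  if (length(unique(key$singer_id)) < 2L)
    stop("theme ", theme, " sung by fewer than 2 singers")
  medoids <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    occ <- rows[rows$singer_id == key$singer_id[i] &
                  rows$phrase_type == key$phrase_type[i], , drop = FALSE]
    occ <- occ[order(occ$phrase_index), , drop = FALSE]
    medoids[[i]] <- medoid_string(strsplit(occ$units, " "), costs)
  }
  ids <- paste0(key$singer_id, "_", key$phrase_type)
  sim <- 1 - pairwise_ld(medoids, costs) /
    outer(lengths(medoids), lengths(medoids), pmax)
  dimnames(sim) <- list(ids, ids)
  diag(sim) <- 1
  similarity_matrix(sim, items = data.frame(
    id = ids, singer_id = key$singer_id, location = key$location,
    phrase_type = key$phrase_type, row.names = NULL))
}

#' Broad-scale song similarity matrix (theme sequences)
#'
#' One row per eligible singer; entries are the unweighted LSI between
#' singers' theme sequences (consecutive repeats collapsed). Singers recorded
#' singing only one theme carry no sequence information and are excluded.
#'
#' @param corpus a [song_corpus].
#' @return A `similarity_matrix` with an `items` attribute (`id`,
#'   `singer_id`, `location`) covering the eligible singers.
#' @export
song_similarity_matrix <- function(corpus) {
  stopifnot(inherits(corpus, "song_corpus"))
  ids <- singer_ids(corpus)
  seqs <- lapply(ids, function(s) as.character(theme_sequence_of(corpus, s)))
  eligible <- lengths(seqs) >= 2L
  if (sum(eligible) < 2L)
    stop("fewer than 2 singers with more than one theme")
  ids <- ids[eligible]; seqs <- seqs[eligible]
  sim <- 1 - pairwise_ld(seqs, costs = NULL) /
    outer(lengths(seqs), lengths(seqs), pmax)
  dimnames(sim) <- list(ids, ids)
  diag(sim) <- 1
  loc <- corpus$phrases$location[match(ids, corpus$phrases$singer_id)]
  similarity_matrix(sim, items = data.frame(
    id = ids, singer_id = ids, location = loc, row.names = NULL))
}

#' Write / read a similarity matrix CSV
#'
#' Square labelled CSV at 6-decimal fixed point. Optionally writes the
#' companion distance matrix `d = 1 - LSI`.
#'
#' @param sim a `similarity_matrix`.
#' @param path file path.
#' @param distance_path optional path for the companion distance CSV.
#' @return `path` invisibly (write); a `similarity_matrix` (read; `items`
#'   metadata is not stored in the CSV).
#' @export
write_similarity_matrix <- function(sim, path, distance_path = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  fmt <- function(m) as.data.frame(format(round(m, 6), nsmall = 6, trim = TRUE),
                                   check.names = FALSE)
  write.csv(fmt(unclass(sim)), path, quote = FALSE)
  if (!is.null(distance_path))
    write.csv(fmt(1 - unclass(sim)), distance_path, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  m <- (m + t(m)) / 2  # undo 6-decimal rounding asymmetry, if any
  diag(m) <- 1
  similarity_matrix(m)
}
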