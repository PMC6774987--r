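#' @section Song hierarchy:
#' Humpback song is hierarchical: discrete sounds ("units") form stereotyped
#' "phrases"; repeated similar phrases form numbered "themes"; a set order of
#' themes forms a "song"; songs sharing theme content form a "song type".
#' A corpus stores one row per phrase occurrence, in the order sung.
#' @name song-hierarchy
#' @keywords internal
NULL

# Recognised recording locations: the six South Pacific wintering grounds and
# the Kermadec Islands migratory stopover.
LOCATION_CODES <- c("EA", "NC", "TO", "NI", "CI", "FP", "KI")

TRANSCRIPTION_COLUMNS <- c("singer_id", "location", "recording",
                           "phrase_index", "phrase_type", "theme", "units")

#' Construct a song corpus
#'
#' A `song_corpus` holds singer-level song transcriptions: one row per phrase
#' occurrence (ordered as sung), a unit inventory, and (for synthetic corpora)
#' an optional map of true population origins.
#'
#' @param phrases data.frame with columns `singer_id`, `location`,
#'   `recording`, `phrase_index`, `phrase_type`, `theme`, `units` (a
#'   space-separated unit-label sequence, lower case).
#' @param origin_truth optional named character vector mapping `singer_id` to
#'   a true population label (synthetic data only).
#' @return An object of class `song_corpus` with elements `phrases`,
#'   `unit_inventory` and `origin_truth`.
#' @details Unit labels are free strings canonicalised to lower case;
#'   comparisons are case-sensitive after that canonicalisation. Theme numbers
#'   must equal the digits of the phrase-type code (phrase type `"3B"` is a
#'   variant of theme 3). Suffixed singer ids (e.g. `"KI01S1a"`, created when
#'   a singer fell silent for over three minutes or several singers were
#'   present) are treated as distinct singers and never merged.
#' @examples
#' cor <- song_corpus(data.frame(
#'   singer_id = "KI01S1", location = "KI", recording = 1L,
#'   phrase_index = 1L, phrase_type = "1A", theme = 1L, units = "a b c"))
#' singer_ids(cor)
#' @export
song_corpus <- function(phrases, origin_truth = NULL) {
  phrases <- as.data.frame(phrases, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRANSCRIPTION_COLUMNS, names(phrases))
  if (length(missing_cols))
    stop("transcription table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  phrases <- phrases[TRANSCRIPTION_COLUMNS]
  phrases$singer_id    <- as.character(phrases$singer_id)
  phrases$location     <- as.character(phrases$location)
  phrases$recording    <- as.integer(phrases$recording)
  phrases$phrase_index <- as.integer(phrases$phrase_index)
  phrases$phrase_type  <- toupper(as.character(phrases$phrase_type))
  phrases$theme        <- as.integer(phrases$theme)
  phrases$units        <- canonical_units(phrases$units)
  validate_phrases(phrases)
  if (!is.null(origin_truth)) {
    if (is.null(names(origin_truth)))
      stop("origin_truth must be a named character vector (singer_id -> population)")
    origin_truth <- setNames(as.character(origin_truth), names(origin_truth))
  }
  rownames(phrases) <- NULL
  inventory <- as.character(sort(unique(unlist(strsplit(phrases$units, " ")))))
  structure(list(phrases = phrases,
                 unit_inventory = inventory,
                 origin_truth = origin_truth),
            class = "song_corpus")
}

canonical_units <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

validate_phrases <- function(phrases, lines = seq_len(nrow(phrases))) {
  bad <- function(cond, what) {
    if (any(cond))
      stop(what, " (row ", paste(lines[which(cond)[1]]), ")", call. = FALSE)
  }
  if (nrow(phrases) == 0L) return(invisible(phrases))
  bad(!phrases$location %in% LOCATION_CODES,
      paste0("unknown location code; expected one of ",
             paste(LOCATION_CODES, collapse = ", ")))
  bad(!nzchar(phrases$units), "empty unit sequence")
  bad(is.na(phrases$theme) | phrases$theme < 1L, "theme must be a positive integer")
  bad(!grepl("^[0-9]+[A-Z]$", phrases$phrase_type),
      "phrase_type must be digits followed by one letter (e.g. '3B')")
  derived_theme <- as.integer(sub("[A-Z]$", "", phrases$phrase_type))
  bad(derived_theme != phrases$theme, "theme does not match phrase_type digits")
  bad(!grepl("^(EA|NC|TO|NI|CI|FP|KI)[0-9]+S[0-9]+[a-z]?$", phrases$singer_id),
      "malformed singer_id (expected e.g. 'KI01S1' or 'KI01S1a')")
  bad(substr(phrases$singer_id, 1, 2) != phrases$location,
      "singer_id prefix does not match location")
  invisible(phrases)
}

#' @export
print.song_corpus <- function(x, ...) {
  cat("song_corpus:", length(singer_ids(x)), "singers,",
      nrow(x$phrases), "phrase occurrences,",
      length(x$unit_inventory), "unit types\n")
  tab <- table(unique(x$phrases[c("singer_id", "location")])$location)
  cat("singers per location:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a song transcription file
#'
#' Reads the tab-separated transcription format: header row plus one row per
#' phrase occurrence with columns `singer_id`, `location`, `recording`,
#' `phrase_index`, `phrase_type`, `theme`, `units` (space-separated unit
#' labels). Rows must be ordered as sung; rows sharing a `singer_id` are
#' grouped into one singer in file order.
#'
#' @param path path to a transcription TSV.
#' @return A [song_corpus].
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = TRUE)
  missing_cols <- setdiff(TRANSCRIPTION_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (col in c("recording", "phrase_index", "theme")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    if (nrow(raw) && anyNA(v))
      stop("parse error in ", path, ": non-integer '", col, "' at line ",
           which(is.na(v))[1] + 1L)
    raw[[col]] <- v
  }
  song_corpus(raw)
}

#' Write a song corpus to a transcription file
#'
#' Inverse of [read_corpus()]: the output re-reads to an identical corpus
#' (lossless round trip of singers, phrase strings and theme order).
#'
#' @param corpus a [song_corpus].
#' @param path output path (tab-separated, UTF-8, header row).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "song_corpus"))
  write.table(corpus$phrases, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Singer identifiers in a corpus
#'
#' @param corpus a [song_corpus].
#' @return Character vector of unique singer ids, in order of first appearance.
#' @export
singer_ids <- function(corpus) unique(corpus$phrases$singer_id)

#' Phrases of one singer
#'
#' @param corpus a [song_corpus].
#' @param singer_id a singer identifier present in `corpus`.
#' @return The singer's phrase rows, ordered as sung.
#' @export
singer_phrases <- function(corpus, singer_id) {
  rows <- corpus$phrases[corpus$phrases$singer_id == singer_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown singer: ", singer_id)
  rows[order(rows$phrase_index), , drop = FALSE]
}

#' Phrase-type inventory of a location
#'
#' The set of distinct phrase types sung by any singer recorded at one
#' location, pooling across singers ("the wintering ground as a whole").
#'
#' @param corpus a [song_corpus].
#' @param location a location code present in the corpus.
#' @return Sorted character vector of phrase-type codes.
#' @export
phrase_inventory <- function(corpus, location) {
  if (!location %in% corpus$phrases$location)
    stop("no singers recorded at location: ", location)
  sort(unique(corpus$phrases$phrase_type[corpus$phrases$location == location]))
}

#' Theme sequence of a singer
#'
#' The ordered list of themes as sung, with consecutive repeats of the same
#' theme collapsed to a single entry (a theme is a block of repeated phrases).
#' Revisits of an earlier theme are preserved.
#'
#' @param corpus a [song_corpus].
#' @param singer_id a singer identifier present in `corpus`.
#' @return Integer vector of theme numbers.
#' @export
theme_sequence_of <- function(corpus, singer_id) {
  themes <- singer_phrases(corpus, singer_id)$theme
  themes[c(TRUE, themes[-1] != themes[-length(themes)])]
}

#' Combine song corpora
#'
#' @param ... [song_corpus] objects with pairwise-disjoint singer ids.
#' @return A single [song_corpus]; origin-truth maps are concatenated.
#' @export
merge_corpora <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "song_corpus")))
  ids <- unlist(lapply(parts, singer_ids))
  if (anyDuplicated(ids))
    stop("duplicate singer ids across corpora: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  truth <- do.call(c, lapply(parts, `[[`, "origin_truth"))
  song_corpus(do.call(rbind, lapply(parts, `[[`, "phrases")),
              origin_truth = truth)
}

#' Plain-text corpus summary
#'
#' Singer counts and phrase-type inventories per location.
#'
#' @param corpus a [song_corpus].
#' @return A character vector of report lines, invisibly; printed by default.
#' @param quiet if `TRUE`, do not print.
#' @export
corpus_summary <- function(corpus, quiet = FALSE) {
  lines <- character(0)
  for (loc in intersect(LOCATION_CODES, unique(corpus$phrases$location))) {
    n <- length(unique(corpus$phrases$singer_id[corpus$phrases$location == loc]))
    inv <- phrase_inventory(corpus, loc)
    lines <- c(lines,
               sprintf("%s: %d singer(s); phrase types: %s", loc, n,
                       paste(inv, collapse = " ")))
  }
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
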