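#' Default song-type definitions
#'
#' The theme content of each South Pacific song type in the study season:
#' type 1a (themes 7, 8, 9, 10, 11), type 1b (7, 9, 11, 12, 13, 14), type 2
#' (themes 1-6) and type 3 (themes 15-17). Themes 7, 9 and 11 are shared by
#' the two versions of type 1; themes 8 and 10 discriminate 1a, themes 12-14
#' discriminate 1b.
#'
#' @return Named list of integer theme vectors.
#' @export
song_type_definitions <- function() {
  list("1a" = c(7L, 8L, 9L, 10L, 11L),
       "1b" = c(7L, 9L, 11L, 12L, 13L, 14L),
       "2"  = 1:6,
       "3"  = 15:17)
}

#' Classify a theme sequence into a song type
#'
#' A singer whose themes all belong to one song type gets that type; themes
#' drawn from exactly two types make a hybrid (a singer caught mid-switch
#' between an old and a new song); anything else is unclassified. Because
#' types 1a and 1b share themes 7, 9 and 11, a sequence covered by both
#' resolves by its discriminating themes (8 or 10 for 1a; 12, 13 or 14 for
#' 1b); with only shared themes the call is type "1" flagged ambiguous.
#'
#' @param themes integer vector of theme numbers (order irrelevant here).
#' @param definitions named list of theme sets, as [song_type_definitions()].
#' @return list with `kind` (`"single"`, `"hybrid"` or `"unclassified"`),
#'   `types` (character vector: length 1 for single, the two component types
#'   for hybrid, ordered by number of themes covered) and `ambiguous`
#'   (`TRUE` when 1a/1b cannot be separated).
#' @examples
#' classify_song_type(1:6)            # type 2
#' classify_song_type(c(1, 2, 3, 8))  # hybrid of types 2 and 1a
#' @export
classify_song_type <- function(themes, definitions = song_type_definitions()) {
  themes <- unique(as.integer(themes))
  if (length(themes) == 0L) stop("need at least one theme")
  known <- unique(unlist(definitions))
  if (length(setdiff(themes, known)))
    stop("unknown theme id(s): ", paste(setdiff(themes, known), collapse = ", "))
  covers <- names(definitions)[vapply(definitions, function(d)
    all(themes %in% d), logical(1))]
  pick_1ab <- function(types) {
    if (!all(c("1a", "1b") %in% types)) return(list(types = types, amb = FALSE))
    others <- setdiff(types, c("1a", "1b"))
    if (any(c(8L, 10L) %in% themes))  return(list(types = c(others, "1a"), amb = FALSE))
    if (any(c(12L, 13L, 14L) %in% themes)) return(list(types = c(others, "1b"), amb = FALSE))
    list(types = c(others, "1"), amb = TRUE)
  }
  if (length(covers)) {
    res <- pick_1ab(covers)
    if (length(res$types) == 1L)
      return(list(kind = "single", types = res$types, ambiguous = res$amb))
    # several unrelated types cover (tiny theme sets); take the smallest
    sizes <- lengths(definitions[res$types])
    return(list(kind = "single", types = names(sort(sizes))[1],
                ambiguous = res$amb))
  }
  pairs <- utils::combn(names(definitions), 2, simplify = FALSE)
  ok <- Filter(function(p) all(themes %in% unlist(definitions[p])), pairs)
  if (length(ok) == 0L)
    return(list(kind = "unclassified", types = character(0), ambiguous = FALSE))
  amb <- FALSE
  if (length(ok) > 1L) {
    # distinguish e.g. {2,1a} from {2,1b} via the discriminating themes
    has_1a <- any(c(8L, 10L) %in% themes)
    has_1b <- any(c(12L, 13L, 14L) %in% themes)
    pref <- if (has_1a && !has_1b) "1a" else if (has_1b && !has_1a) "1b" else NA
    if (!is.na(pref)) {
      filtered <- Filter(function(p) pref %in% p, ok)
      if (length(filtered)) ok <- filtered
    }
    if (length(ok) > 1L) amb <- TRUE
  }
  pair <- ok[[1]]
  n_cov <- vapply(definitions[pair], function(d) sum(themes %in% d), integer(1))
  list(kind = "hybrid", types = pair[order(-n_cov, pair)], ambiguous = amb)
}

#' Percent-matched phrase types against a wintering ground
#'
#' The fraction (as a percentage) of a stopover singer's distinct phrase
#' types that are also present in a wintering ground's pooled inventory:
#' `100 * |shared| / |singer's phrase types|`.
#'
#' @param singer_phrase_types non-empty character vector of the singer's
#'   distinct phrase-type codes.
#' @param ground_inventory character vector of phrase types present at the
#'   ground (pooled over all its singers).
#' @return Percentage in \[0, 100\].
#' @examples
#' percent_matched(c("1A", "2A", "3A", "4A", "5A"),
#'                 c("1A", "2A", "3A", "4A"))  # 80
#' @export
percent_matched <- function(singer_phrase_types, ground_inventory) {
  singer_phrase_types <- unique(as.character(singer_phrase_types))
  if (length(singer_phrase_types) == 0L)
    stop("singer has no phrase types")
  100 * length(intersect(singer_phrase_types, unique(ground_inventory))) /
    length(singer_phrase_types)
}

#' Eligibility filter for stopover singers
#'
#' Mirrors the conservative exclusions applied before origin assignment:
#' (i) singers recorded singing only one theme (including single-phrase-type
#' singers) carry no sequence information and are excluded
#' (`single_phrase_type`); (ii) singers who sang a phrase type found at
#' exactly one wintering ground *and* at least one phrase type absent from
#' that same ground are contradictory and excluded
#' (`exclusive_phrase_conflict`).
#'
#' @param stopover a [song_corpus] of stopover (e.g. Kermadec) singers.
#' @param grounds a [song_corpus] of wintering-ground singers.
#' @return data.frame with `singer_id`, `n_phrase_types`, `n_themes`,
#'   `eligible`, `flags` (comma-separated exclusion flags, empty when
#'   eligible).
#' @export
filter_eligible <- function(stopover, grounds) {
  stopifnot(inherits(stopover, "song_corpus"), inherits(grounds, "song_corpus"))
  ground_locs <- unique(grounds$phrases$location)
  inv <- lapply(ground_locs, function(g) phrase_inventory(grounds, g))
  names(inv) <- ground_locs
  exclusive_to <- function(pt) {
    where <- ground_locs[vapply(inv, function(x) pt %in% x, logical(1))]
    if (length(where) == 1L) where else NA_character_
  }
  ids <- singer_ids(stopover)
  out <- data.frame(singer_id = ids,
                    n_phrase_types = rep(NA_integer_, length(ids)),
                    n_themes = rep(NA_integer_, length(ids)),
                    eligible = rep(TRUE, length(ids)),
                    flags = rep("", length(ids)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    ph <- singer_phrases(stopover, ids[i])
    pts <- unique(ph$phrase_type)
    out$n_phrase_types[i] <- length(pts)
    out$n_themes[i] <- length(unique(ph$theme))
    flags <- character(0)
    if (out$n_themes[i] < 2L) flags <- c(flags, "single_phrase_type")
    for (pt in pts) {
      g <- exclusive_to(pt)
      if (!is.na(g) && any(!pts %in% inv[[g]])) {
        flags <- c(flags, "exclusive_phrase_conflict")
        break
      }
    }
    out$eligible[i] <- length(flags) == 0L
    out$flags[i] <- paste(flags, collapse = ",")
  }
  out
}

#' Origin call from percent-matched phrases
#'
#' The ground with the strictly highest percentage of matched phrase types;
#' when two or more grounds tie for the maximum the origin is left
#' unassigned (`NA`).
#'
#' @param pct named numeric vector of percentages, one per ground.
#' @return A ground code, or `NA_character_` when tied.
#' @export
assign_by_percent <- function(pct) {
  stopifnot(length(pct) >= 1, !is.null(names(pct)))
  top <- which(pct == max(pct))
  if (length(top) == 1L) names(pct)[top] else NA_character_
}

# All supported (AU > threshold) non-root clusters of a tree, as leaf-label
# sets sorted smallest-first.
supported_clusters <- function(tree, au_threshold) {
  sets <- hclust_nodesets(tree$hclust$merge)
  n <- length(tree$hclust$labels)
  ok <- which(tree$support$au > au_threshold & lengths(sets) < n)
  ok <- ok[order(lengths(sets)[ok])]
  lapply(ok, function(i) tree$hclust$labels[sets[[i]]])
}

# Innermost-supported-cluster rule shared by both LSI assignment scales: walk
# outward from the item through the supported clusters containing it, stop at
# the first that includes any wintering-ground member, and call that ground
# if (and only if) the cluster spans exactly one ground. Clusters made only
# of stopover singers are skipped (they say nothing about origin); a
# multi-ground cluster ends the search with no call.
innermost_ground_call <- function(clusters_smallest_first, own_ids, locations,
                                  stopover_code = "KI") {
  for (cl in clusters_smallest_first) {
    if (!any(own_ids %in% cl)) next
    grounds <- unique(locations[cl])
    grounds <- grounds[!is.na(grounds) & grounds != stopover_code]
    if (length(grounds) == 0L) next
    return(if (length(grounds) == 1L) grounds else NA_character_)
  }
  NA_character_
}

#' Fine-scale (phrase-level) LSI origin call
#'
#' Per theme, a stopover singer is linked to a wintering ground when the
#' innermost supported cluster (AU above threshold) around the singer's
#' phrase string that contains wintering-ground strings contains them from
#' exactly one ground; a multi-ground cluster, or no supported cluster, gives
#' no call for that theme. The singer-level call is the unique ground among
#' the per-theme calls; conflicting grounds leave the singer unassigned.
#'
#' @param theme_results named list (by theme) of lists with elements `tree`
#'   (a `supported_dendrogram` over `singer_phraseType` ids) and `items`
#'   (the matrix's `items` metadata with `id`, `singer_id`, `location`).
#' @param singer_id the stopover singer.
#' @param au_threshold AU cutoff (default 0.95).
#' @param stopover_code location code of the stopover (default `"KI"`).
#' @return list with `origin` (ground or `NA_character_`) and `per_theme`
#'   (named character vector of theme-level calls, `NA` where no call).
#' @export
assign_by_fine_lsi <- function(theme_results, singer_id, au_threshold = 0.95,
                               stopover_code = "KI") {
  per_theme <- character(0)
  for (theme in names(theme_results)) {
    tc <- theme_results[[theme]]
    locations <- setNames(tc$items$location, tc$items$id)
    own <- tc$items$id[tc$items$singer_id == singer_id]
    if (length(own) == 0L) next
    clusters <- supported_clusters(tc$tree, au_threshold)
    calls <- unique(vapply(own, function(id)
      innermost_ground_call(clusters, id, locations, stopover_code),
      character(1)))
    calls <- calls[!is.na(calls)]
    per_theme[theme] <- if (length(calls) == 1L) calls else NA_character_
  }
  called <- unique(per_theme[!is.na(per_theme)])
  list(origin = if (length(called) == 1L) called else NA_character_,
       per_theme = per_theme)
}

#' Broad-scale (song-level) LSI origin call
#'
#' The same innermost-supported-cluster rule applied to the song-level
#' (theme sequence) dendrogram.
#'
#' @param tree a `supported_dendrogram` over singer ids.
#' @param items the song matrix's `items` metadata (`id`, `location`).
#' @param singer_id the stopover singer.
#' @param au_threshold AU cutoff (default 0.95).
#' @param stopover_code location code of the stopover (default `"KI"`).
#' @return A ground code or `NA_character_`.
#' @export
assign_by_broad_lsi <- function(tree, items, singer_id, au_threshold = 0.95,
                                stopover_code = "KI") {
  if (!singer_id %in% items$id) return(NA_character_)
  locations <- setNames(items$location, items$id)
  innermost_ground_call(supported_clusters(tree, au_threshold), singer_id,
                        locations, stopover_code)
}

#' Consensus across the three assignment methods
#'
#' Strict mode (the default) assigns only when all three methods produced a
#' call and all name the same ground — the reading under which the study's
#' three-way agreements are counted. Lenient mode assigns when at least two
#' methods produced calls and every produced call names the same ground.
#'
#' @param origin_pct,origin_fine,origin_broad ground codes or `NA`.
#' @param mode `"strict"` or `"lenient"`.
#' @return A ground code or `NA_character_`.
#' @export
consensus_origin <- function(origin_pct, origin_fine, origin_broad,
                             mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  calls <- c(origin_pct, origin_fine, origin_broad)
  present <- calls[!is.na(calls)]
  agreed <- length(unique(present)) == 1L
  if (mode == "strict") {
    if (length(present) == 3L && agreed) present[1] else NA_character_
  } else {
    if (length(present) >= 2L && agreed) present[1] else NA_character_
  }
}

#' Build the full origin-assignment table
#'
#' End-to-end orchestration: eligibility filtering, percent-matched
#' assignment against every ground, fine-scale (per-theme, weighted LSI) and
#' broad-scale (song-level, unweighted LSI) stable-cluster assignment, and
#' the consensus call — one row per eligible stopover singer.
#'
#' @param grounds a [song_corpus] of wintering-ground singers.
#' @param stopover a [song_corpus] of stopover singers.
#' @param costs a [cost_matrix] covering the pooled unit inventory.
#' @param config a [pipeline_config()].
#' @return An `assignment_table` data.frame with columns `singer_id`,
#'   `n_phrase_types`, one `pct_<ground>` column per ground, `origin_pct`,
#'   `origin_fine_lsi`, `origin_broad_lsi`, `consensus` and `flags`.
#'   Attributes: `exclusions` (the [filter_eligible()] log), `fine`
#'   (per-theme trees/clusters), `broad` (song-level tree/clusters),
#'   `ccc_song` (cophenetic correlation of the song-level tree).
#' @export
build_assignment_table <- function(grounds, stopover, costs,
                                   config = pipeline_config()) {
  stopifnot(inherits(grounds, "song_corpus"), inherits(stopover, "song_corpus"))
  elig <- filter_eligible(stopover, grounds)
  keep <- elig$singer_id[elig$eligible]
  ground_locs <- sort(unique(grounds$phrases$location))
  merged <- merge_corpora(grounds, stopover)
  inv <- lapply(ground_locs, function(g) phrase_inventory(grounds, g))
  names(inv) <- ground_locs

  # fine scale: one weighted phrase-level clustering per theme sung by any
  # eligible stopover singer together with at least one other singer
  stop_themes <- sort(unique(stopover$phrases$theme[
    stopover$phrases$singer_id %in% keep]))
  fine <- list()
  for (theme in stop_themes) {
    res <- tryCatch({
      sim <- phrase_similarity_matrix(merged, theme, costs)
      tree <- multiscale_bootstrap(sim, scales = config$scales, B = config$B,
                                   seed = config$seed + theme)
      list(sim = sim, tree = tree,
           clusters = stable_clusters(tree, config$au_threshold),
           items = attr(sim, "items"),
           ccc = if (nrow(sim) >= 3) cophenetic_correlation(tree) else NA_real_)
    }, error = function(e) NULL)
    if (!is.null(res)) fine[[as.character(theme)]] <- res
  }

  # broad scale: one unweighted song-level clustering
  broad <- tryCatch({
    sim <- song_similarity_matrix(merged)
    tree <- multiscale_bootstrap(sim, scales = config$scales, B = config$B,
                                 seed = config$seed)
    list(sim = sim, tree = tree,
         clusters = stable_clusters(tree, config$au_threshold),
         items = attr(sim, "items"),
         ccc = if (nrow(sim) >= 3) cophenetic_correlation(tree) else NA_real_)
  }, error = function(e) NULL)

  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    sid <- keep[i]
    pts <- unique(singer_phrases(stopover, sid)$phrase_type)
    pct <- vapply(ground_locs, function(g) percent_matched(pts, inv[[g]]),
                  numeric(1))
    origin_pct <- assign_by_percent(pct)
    fine_call <- assign_by_fine_lsi(fine, sid, config$au_threshold)
    origin_broad <- if (is.null(broad)) NA_character_ else
      assign_by_broad_lsi(broad$tree, broad$items, sid, config$au_threshold)
    cons <- consensus_origin(origin_pct, fine_call$origin, origin_broad,
                             mode = config$consensus_mode)
    row <- data.frame(singer_id = sid, n_phrase_types = length(pts),
                      stringsAsFactors = FALSE)
    for (g in ground_locs) row[[paste0("pct_", g)]] <- unname(pct[g])
    row$origin_pct <- origin_pct
    row$origin_fine_lsi <- fine_call$origin
    row$origin_broad_lsi <- origin_broad
    row$consensus <- cons
    row$flags <- ""
    rows[[i]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    cols <- c("singer_id", "n_phrase_types", paste0("pct_", ground_locs),
              "origin_pct", "origin_fine_lsi", "origin_broad_lsi",
              "consensus", "flags")
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  structure(out, exclusions = elig, fine = fine, broad = broad,
            ccc_song = if (is.null(broad)) NA_real_ else broad$ccc,
            class = c("assignment_table", "data.frame"))
}

#' Write an assignment table as CSV
#'
#' @param table an `assignment_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment_table <- function(table, path) {
  stopifnot(inherits(table, "assignment_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}
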