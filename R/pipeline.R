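#' Pipeline configuration
#'
#' Thresholds and bootstrap settings shared by the clustering and assignment
#' stages. Defaults follow the analysis conventions: stable clusters gate on
#' AU > 0.95 (BP > 0.70 is reported but not used as a gate), 1000 bootstrap
#' replicates at each of ten scale ratios 0.5-1.4, and strict three-way
#' consensus.
#'
#' @param au_threshold AU cutoff defining a stable cluster, in (0, 1).
#' @param bp_threshold BP reporting threshold, in (0, 1).
#' @param consensus_mode `"strict"` (all three methods call the same ground)
#'   or `"lenient"` (at least two call, none disagrees).
#' @param scales multiscale-bootstrap scale ratios.
#' @param B bootstrap replicates per scale (>= 100).
#' @param seed integer seed funnelling all bootstrap randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(au_threshold = 0.95, bp_threshold = 0.70,
                            consensus_mode = c("strict", "lenient"),
                            scales = seq(0.5, 1.4, by = 0.1),
                            B = 1000, seed = 1) {
  consensus_mode <- match.arg(consensus_mode)
  if (au_threshold <= 0 || au_threshold >= 1 ||
      bp_threshold <= 0 || bp_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  if (B < 100) stop("B must be >= 100")
  structure(list(au_threshold = au_threshold, bp_threshold = bp_threshold,
                 consensus_mode = consensus_mode, scales = scales,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full similarity-and-assignment pipeline
#'
#' Reads nothing and writes everything: derives the substitution-cost matrix
#' from the unit measurements, builds the fine-scale (per-theme, weighted)
#' and broad-scale (song-level, unweighted) LSI matrices with bootstrap
#' support, extracts stable clusters, and produces the origin-assignment
#' table. When `out_dir` is given, all artefacts are exported (cost CSV,
#' similarity/distance CSVs, annotated Newick trees, node-support CSVs,
#' assignment CSV, exclusion log and a plain-text run manifest).
#'
#' @param grounds,stopover [song_corpus] objects.
#' @param measurements a `unit_feature_table` covering the pooled unit
#'   inventory (or a ready-made [cost_matrix] to use directly).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list with `costs`, `assignment` (the `assignment_table`),
#'   `ccc_song`, `ccc_theme` (named per-theme cophenetic correlations) and
#'   `config`.
#' @export
run_pipeline <- function(grounds, stopover, measurements,
                         config = pipeline_config(), out_dir = NULL) {
  merged <- merge_corpora(grounds, stopover)
  costs <- if (inherits(measurements, "cost_matrix")) measurements
  else substitution_costs(measurements, labels = merged$unit_inventory)
  assignment <- build_assignment_table(grounds, stopover, costs, config)
  fine <- attr(assignment, "fine")
  broad <- attr(assignment, "broad")
  ccc_theme <- vapply(fine, function(x) x$ccc, numeric(1))
  result <- list(costs = costs, assignment = assignment,
                 ccc_song = attr(assignment, "ccc_song"),
                 ccc_theme = ccc_theme, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(out_dir, ...)
    write_cost_matrix(costs, p("substitution_costs.csv"))
    if (!is.null(broad)) {
      write_similarity_matrix(broad$sim, p("song_lsi.csv"),
                              distance_path = p("song_distance.csv"))
      to_newick(broad$tree, p("song_tree.nwk"))
      write_node_support(broad$tree, p("song_support.csv"))
    }
    for (theme in names(fine)) {
      write_similarity_matrix(fine[[theme]]$sim,
                              p(sprintf("theme%s_lsi.csv", theme)),
                              distance_path = p(sprintf("theme%s_distance.csv",
                                                        theme)))
      to_newick(fine[[theme]]$tree, p(sprintf("theme%s_tree.nwk", theme)))
      write_node_support(fine[[theme]]$tree,
                         p(sprintf("theme%s_support.csv", theme)))
    }
    write_assignment_table(assignment, p("assignment.csv"))
    write.csv(attr(assignment, "exclusions"), p("exclusions.csv"),
              row.names = FALSE, quote = FALSE)
    manifest <- c(
      sprintf("au_threshold: %g", config$au_threshold),
      sprintf("bp_threshold: %g", config$bp_threshold),
      sprintf("consensus_mode: %s", config$consensus_mode),
      sprintf("scales: %s", paste(config$scales, collapse = " ")),
      sprintf("B: %d", config$B),
      sprintf("seed: %d", config$seed),
      sprintf("ccc_song: %s", format(result$ccc_song)),
      sprintf("themes: %s", paste(names(fine), collapse = " ")))
    writeLines(manifest, p("run_manifest.txt"))
  }
  result
}

#' Reproduce the field analysis from transcription and measurement files
#'
#' Entry point for re-running the complete analysis on real data files in
#' the documented formats: a transcription TSV containing both the
#' wintering-ground singers and the stopover (KI) singers, and the unit
#' measurement CSV. Splits the corpus on the `KI` location code, runs
#' [run_pipeline()], and summarises the headline quantities (song-level and
#' per-theme cophenetic correlations, stopover phrase-type coverage,
#' percent-matched and consensus assignment counts).
#'
#' @param transcription_path transcription TSV (grounds + stopover).
#' @param measurements_path unit-measurement CSV.
#' @param config a [pipeline_config()].
#' @param out_dir optional artefact directory.
#' @return list with `result` (from [run_pipeline()]) and `summary` (list of
#'   headline numbers).
#' @export
reproduce_field_study <- function(transcription_path, measurements_path,
                                  config = pipeline_config(), out_dir = NULL) {
  corpus <- read_corpus(transcription_path)
  measurements <- read_measurements(measurements_path)
  is_ki <- corpus$phrases$location == "KI"
  if (!any(is_ki)) stop("no stopover (KI) singers in transcription file")
  stopover <- song_corpus(corpus$phrases[is_ki, , drop = FALSE])
  grounds <- song_corpus(corpus$phrases[!is_ki, , drop = FALSE])
  result <- run_pipeline(grounds, stopover, measurements, config, out_dir)
  a <- result$assignment
  all_pts <- unique(grounds$phrases$phrase_type)
  ki_pts <- unique(stopover$phrases$phrase_type)
  summary <- list(
    ccc_song = result$ccc_song,
    ccc_theme = result$ccc_theme,
    n_phrase_types_total = length(unique(c(all_pts, ki_pts))),
    n_phrase_types_stopover = length(ki_pts),
    n_eligible = nrow(a),
    n_assigned_pct = sum(!is.na(a$origin_pct)),
    assigned_pct_by_ground = table(a$origin_pct),
    n_consensus = sum(!is.na(a$consensus)),
    consensus_by_ground = table(a$consensus))
  list(result = result, summary = summary)
}
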