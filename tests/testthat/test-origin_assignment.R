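test_that("song types classify by theme content, with 1a/1b discrimination", {
  expect_equal(classify_song_type(1:6),
               list(kind = "single", types = "2", ambiguous = FALSE))
  expect_equal(classify_song_type(c(7, 9, 11, 12, 13, 14))$types, "1b")
  expect_equal(classify_song_type(c(7, 8, 9, 10, 11))$types, "1a")
  expect_equal(classify_song_type(15:17)$types, "3")
  # only themes shared by 1a and 1b: version ambiguous
  amb <- classify_song_type(c(7, 9, 11))
  expect_equal(amb$types, "1")
  expect_true(amb$ambiguous)
  hyb <- classify_song_type(c(1, 2, 3, 8))
  expect_equal(hyb$kind, "hybrid")
  expect_equal(hyb$types, c("2", "1a"))
  expect_equal(classify_song_type(c(1, 15))$kind, "hybrid")
  expect_error(classify_song_type(99), "unknown theme")
})

test_that("percent_matched implements the shared-phrase-type percentage", {
  five <- c("1A", "2A", "3A", "4A", "5A")
  expect_equal(percent_matched(five, c("1A", "2A", "3A", "4A")), 80)
  expect_equal(percent_matched(five, five), 100)
  expect_equal(percent_matched(five, c("9A", "9B")), 0)
  expect_error(percent_matched(character(0), five), "no phrase types")
  # pooling is set-based: repertoire size of the ground is irrelevant
  expect_equal(percent_matched(five, rep(c("1A", "2A", "3A", "4A"), 10)), 80)
})

test_that("assignment by percentage requires a unique strict maximum", {
  expect_equal(assign_by_percent(c(NC = 100, TO = 80, NI = 80, CI = 60)), "NC")
  expect_true(is.na(assign_by_percent(c(NC = 100, TO = 100, NI = 100, CI = 80))))
  expect_true(is.na(assign_by_percent(c(NC = 50, TO = 50))))
  # the returned ground always carries the unique maximum
  set.seed(60)
  for (i in 1:25) {
    pct <- setNames(sample(seq(0, 100, 10), 4, replace = TRUE),
                    c("NC", "TO", "NI", "CI"))
    got <- assign_by_percent(pct)
    if (!is.na(got)) expect_equal(sum(pct == max(pct)), 1L)
  }
})

test_that("eligibility excludes single-theme and contradictory singers", {
  grounds <- song_corpus(rbind(
    phrase_row("NC01S1", 1, "3B", "a b"),   # 3B exclusive to NC
    phrase_row("NC01S1", 2, "1A", "c d"),
    phrase_row("TO01S1", 1, "1A", "c d"),
    phrase_row("TO01S1", 2, "9X", "e f")))  # 9X absent from NC
  stopover <- song_corpus(rbind(
    phrase_row("KI01S1", 1, "1A", "c d"),   # single phrase type
    phrase_row("KI02S1", 1, "3B", "a b"),   # NC-exclusive + non-NC phrase
    phrase_row("KI02S1", 2, "9X", "e f"),
    phrase_row("KI03S1", 1, "1A", "c d"),   # broadly shared: retained
    phrase_row("KI03S1", 2, "9X", "e f")))
  elig <- filter_eligible(stopover, grounds)
  expect_equal(elig$eligible, c(FALSE, FALSE, TRUE))
  expect_match(elig$flags[1], "single_phrase_type")
  expect_match(elig$flags[2], "exclusive_phrase_conflict")
  expect_equal(elig$flags[3], "")
})

test_that("LSI calls use the innermost supported cluster with one ground", {
  # hand-built song-level tree: {KI01S1, NC01S1, NC02S1} tight, TO far
  labs <- c("KI01S1", "NC01S1", "NC02S1", "TO01S1", "TO02S1")
  d <- matrix(0.9, 5, 5, dimnames = list(labs, labs))
  d[1:3, 1:3] <- 0.05; d[4:5, 4:5] <- 0.05
  diag(d) <- 0
  tree <- upgma(d)
  items <- data.frame(id = labs, singer_id = labs,
                      location = substr(labs, 1, 2))
  tree$support$au <- 1  # every node supported
  expect_equal(assign_by_broad_lsi(tree, items, "KI01S1"), "NC")
  # no supported node -> no call
  tree$support$au <- 0
  expect_true(is.na(assign_by_broad_lsi(tree, items, "KI01S1")))
  # innermost informative cluster spans two grounds -> no call
  labs2 <- c("KI01S1", "NC01S1", "TO01S1", "CI01S1")
  d2 <- matrix(0.9, 4, 4, dimnames = list(labs2, labs2))
  d2[2, 3] <- d2[3, 2] <- 0.05            # NC-TO pair merges first
  d2[1, 2:3] <- d2[2:3, 1] <- 0.2         # KI joins the two-ground cluster
  diag(d2) <- 0
  tree2 <- upgma(d2)
  tree2$support$au <- 1
  items2 <- data.frame(id = labs2, singer_id = labs2,
                       location = substr(labs2, 1, 2))
  expect_true(is.na(assign_by_broad_lsi(tree2, items2, "KI01S1")))
})

test_that("fine-scale per-theme calls must agree across themes", {
  mk_theme <- function(ground) {
    labs <- c("KI01S1_1A", paste0(ground, "01S1_1A"), paste0(ground, "02S1_1A"))
    d <- matrix(0.05, 3, 3, dimnames = list(labs, labs)); diag(d) <- 0
    tree <- upgma(d)
    tree$support$au <- 1
    list(tree = tree,
         items = data.frame(id = labs,
                            singer_id = sub("_1A$", "", labs),
                            location = substr(labs, 1, 2)))
  }
  agree <- assign_by_fine_lsi(list("1" = mk_theme("NC"), "2" = mk_theme("NC")),
                              "KI01S1")
  expect_equal(agree$origin, "NC")
  expect_equal(unname(agree$per_theme), c("NC", "NC"))
  conflict <- assign_by_fine_lsi(list("1" = mk_theme("NC"), "2" = mk_theme("TO")),
                                 "KI01S1")
  expect_true(is.na(conflict$origin))
})

test_that("consensus is strict three-way agreement by default", {
  expect_equal(consensus_origin("NC", "NC", "NC"), "NC")
  expect_equal(consensus_origin("CI", "CI", "CI"), "CI")
  expect_true(is.na(consensus_origin("NC", "TO", NA)))
  expect_true(is.na(consensus_origin("NC", "NC", NA)))
  expect_equal(consensus_origin("NC", "NC", NA, mode = "lenient"), "NC")
  expect_true(is.na(consensus_origin("NC", NA, NA, mode = "lenient")))
  expect_true(is.na(consensus_origin("NC", "TO", "NC", mode = "lenient")))
})

test_that("the assignment table recovers planted origins on clean data", {
  g <- generate_corpus(synthetic_config(
    seed = 71, populations = c("NC", "TO", "CI"),
    song_type_assignments = c(NC = "2", TO = "2", CI = "1a"),
    singers_per_population = 3, n_stopover = 6,
    stopover_mixture = c(NC = 1, TO = 1, CI = 1),
    noise = c(sub = 0, ins = 0, del = 0), variant_rate = 1))
  costs <- suppressWarnings(substitution_costs(g$inventory))
  tab <- build_assignment_table(g$grounds, g$stopover, costs,
                                pipeline_config(B = 200, seed = 5))
  truth <- setNames(g$truth$population, g$truth$singer_id)
  for (i in seq_len(nrow(tab))) {
    sid <- tab$singer_id[i]
    for (m in c("origin_pct", "origin_fine_lsi", "origin_broad_lsi",
                "consensus")) {
      if (!is.na(tab[[m]][i])) expect_equal(tab[[m]][i], unname(truth[sid]))
    }
    # consensus defined -> all three methods called and agreed
    if (!is.na(tab$consensus[i])) {
      expect_equal(tab$origin_pct[i], tab$consensus[i])
      expect_equal(tab$origin_fine_lsi[i], tab$consensus[i])
      expect_equal(tab$origin_broad_lsi[i], tab$consensus[i])
    }
  }
  expect_gt(sum(!is.na(tab$origin_pct)), 0)
})

test_that("a one-population stopover is never assigned elsewhere", {
  g <- generate_corpus(synthetic_config(
    seed = 72, populations = c("NC", "TO"),
    song_type_assignments = c(NC = "2", TO = "2"),
    singers_per_population = 3, n_stopover = 5,
    stopover_mixture = c(NC = 1, TO = 0), variant_rate = 1))
  expect_true(all(g$stopover$origin_truth == "NC"))
  costs <- suppressWarnings(substitution_costs(g$inventory))
  tab <- build_assignment_table(g$grounds, g$stopover, costs,
                                pipeline_config(B = 150, seed = 2))
  for (m in c("origin_pct", "origin_fine_lsi", "origin_broad_lsi", "consensus"))
    expect_true(all(is.na(tab[[m]]) | tab[[m]] == "NC"))
})

test_that("an empty stopover corpus yields an empty table", {
  g <- generate_corpus(synthetic_config(seed = 73, n_stopover = 2,
                                        singers_per_population = 2))
  empty <- song_corpus(g$stopover$phrases[0, ])
  costs <- suppressWarnings(substitution_costs(g$inventory))
  tab <- build_assignment_table(g$grounds, empty, costs,
                                pipeline_config(B = 150, seed = 2))
  expect_equal(nrow(tab), 0L)
})
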