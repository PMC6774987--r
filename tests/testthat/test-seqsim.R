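test_that("weighted_ld handles identities, boundaries and weighted swaps", {
  expect_equal(weighted_ld(c("a", "b"), c("a", "b")), 0)
  expect_equal(weighted_ld("x", character(0)), 1)
  expect_equal(weighted_ld(character(0), c("x", "y", "z")), 3)
  expect_equal(weighted_ld(c("A", "B", "C"), c("A", "C", "D")), 2)

  cm <- cost_matrix(matrix(c(0, 0.5, 0.5, 0), 2, 2,
                           dimnames = list(c("X", "Y"), c("X", "Y"))))
  expect_equal(weighted_ld(c("X"), c("Y"), cm), 0.5)
  costs3 <- matrix(0.5, 3, 3, dimnames = list(c("A", "X", "Y"),
                                              c("A", "X", "Y")))
  diag(costs3) <- 0
  expect_equal(weighted_ld(c("A", "X"), c("A", "Y"), cost_matrix(costs3)), 0.5)
  expect_error(weighted_ld(c("Q"), c("X"), cm), "Q")
})

test_that("weighted_ld matches the recursive oracle on random cases", {
  set.seed(100)
  inventory <- letters[1:5]
  for (i in 1:200) {
    cm <- random_cost_matrix(inventory)
    a <- sample(inventory, sample(0:6, 1), replace = TRUE)
    b <- sample(inventory, sample(0:6, 1), replace = TRUE)
    expect_equal(weighted_ld(a, b, cm),
                 ld_oracle(a, b, function(x, y) unclass(cm)[x, y]),
                 tolerance = 1e-12)
  }
})

test_that("weighted_ld is symmetric, bounded and a metric when unweighted", {
  set.seed(101)
  inventory <- letters[1:4]
  for (i in 1:50) {
    cm <- random_cost_matrix(inventory)
    a <- sample(inventory, sample(1:6, 1), replace = TRUE)
    b <- sample(inventory, sample(1:6, 1), replace = TRUE)
    cc <- sample(inventory, sample(1:6, 1), replace = TRUE)
    expect_equal(weighted_ld(a, b, cm), weighted_ld(b, a, cm))
    expect_lte(weighted_ld(a, b, cm), length(a) + length(b))
    expect_lte(weighted_ld(a, cc),
               weighted_ld(a, b) + weighted_ld(b, cc) + 1e-12)
  }
})

test_that("lsi normalises by the longer string and stays in [0, 1]", {
  expect_equal(lsi(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(lsi(character(0), c("a", "b", "c")), 0)
  expect_equal(lsi(c("A", "B", "C"), c("A", "C", "D")), 1 - 2 / 3)
  expect_error(lsi(character(0), character(0)), "empty")
  set.seed(102)
  for (i in 1:50) {
    a <- sample(letters[1:4], sample(1:6, 1), replace = TRUE)
    b <- sample(letters[1:4], sample(0:6, 1), replace = TRUE)
    s <- lsi(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s == 1, weighted_ld(a, b) == 0)
  }
})

test_that("medoid_string returns the distance-minimising attested string", {
  s <- c("a", "b", "c"); t <- c("a", "x")
  expect_equal(medoid_string(list(s)), s)
  expect_equal(medoid_string(list(t, s, s)), s)
  # equal total distance -> first input wins
  expect_equal(medoid_string(list(t, s)), t)
  expect_error(medoid_string(list()), "non-empty")
  set.seed(103)
  for (i in 1:20) {
    strs <- replicate(sample(2:5, 1),
                      sample(letters[1:3], sample(1:5, 1), replace = TRUE),
                      simplify = FALSE)
    med <- medoid_string(strs)
    expect_true(any(vapply(strs, identical, logical(1), med)))
  }
})

test_that("phrase similarity matrices match direct lsi recomputation", {
  fix <- make_test_corpora()
  merged <- merge_corpora(fix$grounds, fix$stopover)
  labels <- merged$unit_inventory
  flat <- 0.4 * (1 - diag(length(labels)))
  dimnames(flat) <- list(labels, labels)
  cm <- cost_matrix(flat)
  sim <- phrase_similarity_matrix(merged, 1, cm)
  items <- attr(sim, "items")
  expect_equal(nrow(sim), 6L)  # six singers sang theme 1, one phrase type each
  # identical medoids -> off-diagonal 1
  expect_equal(unclass(sim)["NC01S1_1B", "NC02S1_1B"], 1)
  # every entry equals a direct pairwise lsi() of the medoid strings
  medoid_of <- function(id) {
    occ <- merged$phrases[merged$phrases$singer_id == items$singer_id[items$id == id] &
                            merged$phrases$phrase_type == items$phrase_type[items$id == id], ]
    medoid_string(strsplit(occ$units, " "), cm)
  }
  for (i in rownames(sim)) for (j in colnames(sim))
    expect_equal(unclass(sim)[i, j], lsi(medoid_of(i), medoid_of(j), cm),
                 tolerance = 1e-12)
  expect_error(phrase_similarity_matrix(merged, 99, cm), "absent")
})

test_that("within-population phrase similarity exceeds between on clean data", {
  g <- generate_corpus(synthetic_config(
    seed = 51, noise = c(sub = 0, ins = 0, del = 0), variant_rate = 1,
    n_stopover = 2, singers_per_population = 3))
  costs <- suppressWarnings(substitution_costs(g$inventory))
  sim <- phrase_similarity_matrix(g$grounds, 1, costs)
  items <- attr(sim, "items")
  same <- outer(items$location, items$location, "==")
  off <- !diag(nrow(sim))
  expect_gt(min(unclass(sim)[same & off]), max(unclass(sim)[!same]))
})

test_that("song similarity uses unweighted LSI on collapsed theme sequences", {
  corpus <- song_corpus(rbind(
    phrase_row("NC01S1", 1, "1A", "a"),
    phrase_row("NC01S1", 2, "2A", "b"),
    phrase_row("NC01S1", 3, "3A", "c"),
    phrase_row("TO01S1", 1, "1A", "a"),
    phrase_row("TO01S1", 2, "3A", "c"),
    phrase_row("KI01S1", 1, "1A", "a"),
    phrase_row("KI01S1", 2, "2A", "b"),
    phrase_row("KI01S1", 3, "3A", "c"),
    phrase_row("KI02S1", 1, "9A", "z")))   # single-theme singer
  sim <- song_similarity_matrix(corpus)
  expect_false("KI02S1" %in% rownames(sim))     # eligibility rule
  expect_equal(unclass(sim)["NC01S1", "KI01S1"], 1)
  expect_equal(unclass(sim)["NC01S1", "TO01S1"], 1 - 1 / 3)  # [1,2,3] vs [1,3]
  single <- song_corpus(rbind(phrase_row("NC01S1", 1, "1A", "a"),
                              phrase_row("TO01S1", 1, "1A", "a")))
  expect_error(song_similarity_matrix(single), "fewer than 2")
})

test_that("similarity matrices round-trip through CSV", {
  fix <- make_test_corpora()
  sim <- song_similarity_matrix(merge_corpora(fix$grounds, fix$stopover))
  path <- withr::local_tempfile(fileext = ".csv")
  dpath <- withr::local_tempfile(fileext = ".csv")
  write_similarity_matrix(sim, path, distance_path = dpath)
  back <- read_similarity_matrix(path)
  expect_equal(unclass(back), unclass(sim), tolerance = 1e-6,
               ignore_attr = TRUE)
  d <- as.matrix(read.csv(dpath, row.names = 1, check.names = FALSE))
  expect_equal(d, 1 - unclass(sim), tolerance = 1e-6, ignore_attr = TRUE)
})
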