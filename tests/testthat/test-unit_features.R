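test_that("measurement CSVs read, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- feature_table_from_centroids(
    rbind(moan = make_centroid(1.2, 100, 400)))
  write_measurements(tab, path)
  back <- read_measurements(path)
  expect_equal(sort(unique(back$unit_label)), "moan")
  expect_equal(back$bandwidth_hz, 300)

  bad <- rbind(moan = make_centroid(1.2, 100, 400))
  bad[, "min_freq_hz"] <- 500  # min above max
  expect_error(feature_table_from_centroids(bad), "min_freq")

  drift <- rbind(moan = make_centroid(1.2, 100, 400))
  drift[, "bandwidth_hz"] <- 350
  expect_warning(feature_table_from_centroids(drift), "bandwidth")

  g <- generate_corpus(synthetic_config(seed = 3, n_stopover = 2,
                                        singers_per_population = 2))
  write_measurements(g$inventory, path)
  back <- read_measurements(path)
  expect_equal(as.data.frame(back), as.data.frame(g$inventory),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("tree classification agrees with naming on separable labels", {
  set.seed(1)
  rows <- do.call(rbind, lapply(1:20, function(i) rbind(
    low = make_centroid(0.5 + runif(1, 0, 0.1), 100 + runif(1, 0, 20), 200),
    high = make_centroid(2.5 + runif(1, 0, 0.1), 3000 + runif(1, 0, 100), 4000))))
  rownames(rows) <- NULL
  tab <- unit_feature_table(cbind(
    data.frame(unit_label = rep(c("low", "high"), 20)),
    as.data.frame(rows)))
  res <- classification_consistency(tab, seed = 5)
  expect_equal(res$agreement, 1.0)
  expect_equal(res$n, 40L)
})

test_that("tree classification is near chance for indistinguishable labels", {
  set.seed(2)
  mk <- function() make_centroid(runif(1, 1, 1.2), runif(1, 500, 600), 1000)
  rows <- do.call(rbind, lapply(1:40, function(i) rbind(mk(), mk())))
  tab <- unit_feature_table(cbind(
    data.frame(unit_label = rep(c("a", "b"), 40)),
    as.data.frame(rows)))
  res <- classification_consistency(tab, seed = 7)
  expect_gt(res$agreement, 0.25)
  expect_lt(res$agreement, 0.75)
})

test_that("tree classification is deterministic given a seed and drops singletons", {
  g <- generate_corpus(synthetic_config(seed = 21, n_stopover = 2,
                                        singers_per_population = 2))
  r1 <- classification_consistency(g$inventory, seed = 9)
  r2 <- classification_consistency(g$inventory, seed = 9)
  expect_identical(r1$agreement, r2$agreement)
  expect_identical(r1$confusion, r2$confusion)

  tab <- g$inventory
  lone <- cbind(data.frame(unit_label = "lonely"),
                as.data.frame(as.list(make_centroid(1, 100, 200))))
  tab2 <- unit_feature_table(rbind(as.data.frame(tab), lone))
  expect_warning(classification_consistency(tab2, seed = 9), "lonely")
})

test_that("substitution costs hit the normalisation bounds", {
  # identical centroids -> cost 0
  same <- feature_table_from_centroids(rbind(
    a = make_centroid(1, 100, 300), b = make_centroid(1, 100, 300),
    c = make_centroid(2, 500, 900)))
  costs <- suppressWarnings(substitution_costs(same))
  expect_equal(unclass(costs)["a", "b"], 0)
  # two labels at opposite extremes of every feature -> cost 1
  two <- feature_table_from_centroids(rbind(
    lo = make_centroid(0.2, 100, 200, peak = 120, sf = 110, ef = 190,
                       infl = 0, pulse = 0),
    hi = make_centroid(2.0, 900, 4000, peak = 3000, sf = 3500, ef = 1000,
                       infl = 4, pulse = 20)))
  expect_equal(unclass(substitution_costs(two))["lo", "hi"], 1)
})

test_that("three hand-set centroids give hand-computed normalised costs", {
  cents <- rbind(a = make_centroid(1.0, 100, 300),
                 b = make_centroid(2.0, 200, 500),
                 c = make_centroid(3.0, 400, 1100))
  tab <- feature_table_from_centroids(cents)
  got <- suppressWarnings(substitution_costs(tab))
  # independent arithmetic: min-max normalise each column, mean |diff|
  keep <- apply(cents, 2, function(x) diff(range(x)) > 0)
  norm <- apply(cents[, keep, drop = FALSE], 2,
                function(x) (x - min(x)) / diff(range(x)))
  expected <- function(i, j) mean(abs(norm[i, ] - norm[j, ]))
  for (p in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_equal(unclass(got)[p[1], p[2]], expected(p[1], p[2]),
                 tolerance = 1e-12)
})

test_that("cost matrices obey the contract and are unit-scale invariant", {
  g <- generate_corpus(synthetic_config(seed = 31, n_stopover = 2,
                                        singers_per_population = 2))
  costs <- suppressWarnings(substitution_costs(g$inventory))
  m <- unclass(costs)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(diag(m), setNames(rep(0, nrow(m)), rownames(m)))
  expect_equal(m, t(m))

  # affine rescaling of any feature leaves costs unchanged
  rescaled <- as.data.frame(g$inventory)
  rescaled$duration_s <- rescaled$duration_s * 1000 + 42
  costs2 <- suppressWarnings(substitution_costs(
    structure(rescaled, class = c("unit_feature_table", "data.frame"))))
  expect_equal(unclass(costs2), m, tolerance = 1e-12)
})

test_that("constant features are dropped with a warning", {
  cents <- rbind(a = make_centroid(1, 100, 300), b = make_centroid(1, 200, 600))
  tab <- feature_table_from_centroids(cents)  # duration constant
  expect_warning(substitution_costs(tab), "duration_s")
})

test_that("cost matrices round-trip through CSV at 6 decimals", {
  g <- generate_corpus(synthetic_config(seed = 41, n_stopover = 2,
                                        singers_per_population = 2))
  costs <- suppressWarnings(substitution_costs(g$inventory))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cost_matrix(costs, path)
  back <- read_cost_matrix(path)
  expect_equal(unclass(back), unclass(costs), tolerance = 1e-6)
  expect_equal(attr(back, "indel_cost"), 1)
})
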