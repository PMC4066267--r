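test_that("interval construction trisects the 5th-95th percentile range", {
  # GA sample engineered so p5 = 14.5 and p95 = 37.5: trisection puts the
  # interior cutpoints near 22.2 and 29.8 weeks
  set.seed(41)
  ga <- c(seq(6.9, 14.49, length.out = 50),
          seq(14.5, 37.5, length.out = 900),
          seq(37.51, 41, length.out = 50))
  iv <- build_intervals(ga)
  expect_equal(iv$percentiles[["p5"]], 14.5, tolerance = 0.1)
  expect_equal(iv$percentiles[["p95"]], 37.5, tolerance = 0.1)
  expect_equal(iv$cutpoints[1], 14.5 + (37.5 - 14.5) / 3, tolerance = 0.1)
  expect_equal(iv$cutpoints[2], 14.5 + 2 * (37.5 - 14.5) / 3, tolerance = 0.1)
  # outer windows reach the observed extremes so every sample is covered
  expect_equal(iv$windows$lo[1], min(ga))
  expect_equal(iv$windows$hi[3], max(ga))
  w <- assign_interval(ga, iv)
  expect_true(all(w %in% 1:3))
  expect_equal(length(w), length(ga))
  expect_equal(sum(table(w)), length(ga))  # partition
})

test_that("interval construction handles small and degenerate inputs", {
  iv <- build_intervals(c(10, 20, 30))
  expect_equal(assign_interval(c(10, 20, 30), iv), 1:3)
  expect_error(build_intervals(rep(17, 5)), "distinct")
})

test_that("orthogonal polynomial bases are orthonormal and centred", {
  set.seed(42)
  ga <- runif(60, 7, 41)
  for (d in c(1, 3, 7)) {
    B <- orthogonal_basis(ga, d)
    expect_equal(crossprod(B), diag(d), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(unname(colSums(B)), rep(0, d), tolerance = 1e-10)  # orthogonal to 1
  }
  # degree 1 is proportional to centred ga with unit norm
  b1 <- orthogonal_basis(ga, 1)[, 1]
  expect_equal(abs(cor(b1, ga)), 1, tolerance = 1e-12)
  expect_equal(sum(b1^2), 1)
  expect_error(orthogonal_basis(ga, 8), "1 and 7")
  expect_error(orthogonal_basis(c(1, 2, 3), 3), "distinct")
})

test_that("interval contrasts recover a planted monotone trend", {
  slopes <- setNames(rep(0, 99), vagilong:::default_taxa(99))
  slopes["Gemella"] <- 0.25            # strongly increasing
  slopes["Parvimonas micra"] <- -0.25  # strongly decreasing
  cfg <- cohort_config(n_preterm = 4, ga_slopes = slopes, seed = 43)
  sim <- simulate_cohort(cfg)
  sub <- sim$counts[c("sample_id", "Gemella", "Parvimonas micra",
                      "Lactobacillus iners", "Eggerthella")]
  set.seed(44)
  res <- interval_contrasts(sub, sim$metadata,
                            control = model_control(nodes = 9, restarts = 1))
  expect_equal(res$direction[res$taxon == "Gemella"], "up")
  expect_gt(res$est_3v1[res$taxon == "Gemella"], 0)
  expect_equal(res$direction[res$taxon == "Parvimonas micra"], "down")
  # planted-flat taxa stay flat
  expect_equal(res$direction[res$taxon == "Eggerthella"], "flat")
  # contrast additivity: 3v1 = 2v1 + 3v2 for the linear parameterization
  ok <- res[res$fitted, ]
  expect_equal(ok$est_3v1, ok$est_2v1 + ok$est_3v2, tolerance = 1e-8)
})

test_that("polynomial trends select a low degree for log-linear signals", {
  slopes <- setNames(rep(0, 99), vagilong:::default_taxa(99))
  slopes["Gemella"] <- 0.25
  cfg <- cohort_config(n_preterm = 4, ga_slopes = slopes, seed = 45)
  sim <- simulate_cohort(cfg)
  sub <- sim$counts[c("sample_id", "Gemella", "Lactobacillus iners")]
  set.seed(46)
  res <- polynomial_trend(sub, sim$metadata, max_degree = 4,
                          control = model_control(nodes = 9, restarts = 0))
  gem <- res[res$taxon == "Gemella", ]
  expect_true(gem$fitted)
  expect_equal(gem$direction, "up")
  expect_gt(gem$linear_estimate, 0)
  expect_lte(gem$poly_degree, 2L)
  # per-term q exists for every fitted term
  expect_equal(length(gem$term_q[[1]]), gem$poly_degree)
})

test_that("trend analyses reject out-of-scope groups and empty windows", {
  cfg <- cohort_config(n_term = 10, n_preterm = 4, seed = 47)
  sim <- simulate_cohort(cfg)
  expect_error(interval_contrasts(sim$counts, sim$metadata, group = "nope"),
               "no samples|unknown group")
})
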