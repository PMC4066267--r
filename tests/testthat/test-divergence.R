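test_that("Kullback-Leibler divergence matches hand-evaluated cases", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  # 1 * log2(1 / 0.5) = 1 bit
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  # support violation is reported as infinity, never a capped number
  expect_identical(kl_divergence(c(0.5, 0.5), c(1, 0)), Inf)
  expect_error(kl_divergence(c(1, 0), c(0.3, 0.3, 0.4)), "dimension")
})

test_that("Jensen-Shannon divergence hits its analytic endpoints", {
  expect_equal(js_divergence(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  # hand evaluation against the midpoint a = (0.75, 0.25), base-2 logs
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5)), 0.311278, tolerance = 1e-6)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(js_distance(c(0.2, 0.8), c(0.2, 0.8)), 0)
})

test_that("JSD is symmetric, bounded and finite even where KL is infinite", {
  set.seed(11)
  for (i in 1:500) {
    p <- random_simplex(6)
    q <- random_simplex(6)
    d <- js_divergence(p, q)
    expect_identical(d, js_divergence(q, p))
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
  # disjoint-support pairs: KL infinite, JSD still finite
  p <- c(0.7, 0.3, 0, 0)
  q <- c(0, 0, 0.2, 0.8)
  expect_identical(kl_divergence(p, q), Inf)
  expect_lte(js_divergence(p, q), 1)
  expect_equal(js_divergence(p, q), 1)
})

test_that("JS distance satisfies the triangle inequality", {
  set.seed(12)
  for (i in 1:1000) {
    p <- random_simplex(5); q <- random_simplex(5); r <- random_simplex(5)
    expect_lte(js_distance(p, r),
               js_distance(p, q) + js_distance(q, r) + 1e-12)
  }
})

test_that("pairwise divergence matrices agree with element-wise evaluation", {
  set.seed(13)
  states <- rbind(random_simplex(4), random_simplex(4), random_simplex(4))
  colnames(states) <- paste0("t", 1:4)
  ra <- dplyr::bind_cols(tibble::tibble(sample_id = c("a", "b", "c")),
                         tibble::as_tibble(states))
  d <- pairwise_divergence(ra)
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(d, t(d))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(d[i, j], js_divergence(states[i, ], states[j, ]),
                 tolerance = 1e-12)
  }
  d2 <- pairwise_divergence(ra, metric = "js_distance")
  expect_equal(d2, sqrt(d))
  # identical states give a zero matrix
  ra2 <- ra[c(1, 1), ]; ra2$sample_id <- c("a", "b")
  expect_true(all(pairwise_divergence(ra2) == 0))
})

test_that("Ward clustering recovers planted composition clusters", {
  set.seed(14)
  planted <- planted_cst_states(n_per = 10)
  d <- pairwise_divergence(planted$ra)
  cl <- ward_cluster(d, k = 3)
  expect_equal(mclust::adjustedRandIndex(cl$assignments$cluster, planted$truth), 1)
  # degenerate cuts
  expect_equal(sort(unique(ward_cluster(d, k = nrow(d))$assignments$cluster)),
               seq_len(nrow(d)))
  expect_equal(unique(ward_cluster(d, k = 1)$assignments$cluster), 1L)
  bad <- d; bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(ward_cluster(bad, 3), "symmetric")
})

test_that("clusters are labelled by dominant indicator taxa", {
  set.seed(15)
  planted <- planted_cst_states(n_per = 8)
  cl <- ward_cluster(pairwise_divergence(planted$ra), k = 3)
  cl <- label_csts(cl, planted$ra)
  expect_setequal(unique(cl$assignments$cst), c("I", "III", "IV-B"))
  expect_equal(cl$assignments$cst, planted$truth)
})

test_that("CST frequencies sum to 100% per stratum and tolerate empty groups", {
  asg <- tibble::tibble(sample_id = paste0("s", 1:10), cst = rep("I", 10))
  meta <- tibble::tibble(sample_id = paste0("s", 1:10),
                         subject_id = paste0("p", 1:10),
                         group = rep("term", 10),
                         gestational_age = 1:10, total_reads = rep(100, 10))
  fr <- cst_frequencies(asg, meta)
  expect_equal(fr$pct[fr$group == "overall"], 100)
  expect_false("preterm" %in% fr$group)  # empty group: no row, no crash
  totals <- tapply(fr$pct, fr$group, sum)
  expect_true(all(abs(totals - 100) < 1e-9))
})
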