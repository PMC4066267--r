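test_that("count tables round-trip through the wide TSV format", {
  tf <- write_count_fixture(c("sample_id\tA\tB", "s1\t5\t0", "s2\t0\t7", "s3\t1\t1"))
  ct <- read_count_table(tf)
  expect_equal(dim(count_matrix(ct)), c(3L, 2L))
  expect_equal(unname(count_matrix(ct)), matrix(c(5L, 0L, 1L, 0L, 7L, 1L), 3))
  out <- tempfile(fileext = ".tsv")
  write_count_table(ct, out)
  expect_identical(read_count_table(out), ct)
})

test_that("malformed count tables are rejected with informative errors", {
  expect_error(read_count_table(write_count_fixture(c("sample_id\tA", "s1\t-3"))),
               "negative count")
  expect_error(read_count_table(write_count_fixture("sample_id\tA")), "no samples")
  expect_error(read_count_table(write_count_fixture(c("sample_id\tA\tA", "s1\t1\t2"))),
               "duplicate taxon")
  expect_error(read_count_table(write_count_fixture(c("sample_id\tA", "s1\t1", "s1\t2"))),
               "duplicate sample")
  expect_error(read_count_table(write_count_fixture(c("sample_id\tA", "s1\t1.7"))),
               "non-integer")
})

test_that("metadata is validated against the count table at load", {
  ct <- tibble::tibble(sample_id = c("s1", "s2"), A = c(3L, 0L), B = c(1L, 8L))
  meta <- tibble::tibble(sample_id = c("s1", "s2"), subject_id = c("p1", "p1"),
                         group = c("term", "term"),
                         gestational_age = c(10, 14), total_reads = c(4, 8))
  expect_s3_class(validate_metadata(meta, ct), "tbl_df")
  bad <- meta; bad$total_reads[1] <- 5
  expect_error(validate_metadata(bad, ct), "total_reads mismatch")
  bad <- meta; bad$gestational_age[2] <- 10
  expect_error(validate_metadata(bad, ct), "strictly increasing")
  bad <- meta; bad$group[1] <- "unknown"
  expect_error(validate_metadata(bad, ct), "unknown group")
})

test_that("relative abundances are row proportions and invert exactly", {
  ct <- tibble::tibble(sample_id = c("s1", "s2"), A = c(3L, 0L), B = c(1L, 8L))
  ra <- relative_abundance(ct)
  expect_equal(unlist(ra[1, c("A", "B")], use.names = FALSE), c(0.75, 0.25))
  expect_equal(unlist(ra[2, c("A", "B")], use.names = FALSE), c(0, 1))
  expect_equal(rowSums(as.matrix(ra[c("A", "B")])), c(1, 1))
  # multiplying back by the totals recovers the counts exactly
  tot <- rowSums(count_matrix(ct))
  expect_identical(round(as.matrix(ra[c("A", "B")]) * tot),
                   matrix(as.numeric(count_matrix(ct)), 2,
                          dimnames = list(NULL, c("A", "B"))))
  ct0 <- tibble::tibble(sample_id = "s1", A = 0L, B = 0L)
  expect_error(relative_abundance(ct0), "zero total")
})

test_that("prevalence filter keeps the inclusive 25% boundary and is monotone", {
  # taxon present in exactly 1 of 4 samples sits on the boundary and is kept
  ct <- tibble::tibble(sample_id = paste0("s", 1:4),
                       A = c(1L, 0L, 0L, 0L), B = c(0L, 0L, 0L, 0L),
                       C = c(2L, 3L, 1L, 5L))
  kept <- taxon_names(prevalence_filter(ct, 0.25))
  expect_setequal(kept, c("A", "C"))
  expect_identical(prevalence_filter(prevalence_filter(ct, 0.25), 0.25),
                   prevalence_filter(ct, 0.25))  # idempotent
  # raising the threshold never adds taxa
  for (thr in c(0.3, 0.5, 0.9)) {
    expect_true(all(taxon_names(prevalence_filter(ct, thr)) %in% kept))
  }
  expect_error(prevalence_filter(ct, 0), "min_prevalence")
})

test_that("a planted prevalence structure is recovered exactly", {
  # 100 taxa, 40 samples; taxa 1..21 planted at >= 25% prevalence
  set.seed(404)
  n_s <- 40
  m <- matrix(0L, n_s, 100, dimnames = list(NULL, paste0("t", 1:100)))
  for (j in 1:100) {
    n_present <- if (j <= 21) sample(10:40, 1) else sample(0:9, 1)
    m[sample(n_s, n_present), j] <- sample(1:50, n_present, replace = TRUE)
  }
  m[, 22] <- m[, 22] + 1L  # keep every sample total positive
  ct <- dplyr::bind_cols(tibble::tibble(sample_id = paste0("s", 1:n_s)),
                         tibble::as_tibble(m))
  kept <- taxon_names(prevalence_filter(ct, 0.25))
  oracle <- colnames(m)[colSums(m >= 1L) / n_s >= 0.25]  # brute-force count
  expect_identical(kept, oracle)
  expect_setequal(setdiff(kept, "t22"), paste0("t", 1:21))
})

test_that("log offsets are natural logs of read totals", {
  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         total_reads = c(1, 7548, 10))
  off <- log_offsets(meta)
  expect_equal(unname(off), c(0, log(7548), log(10)))
  # scaling law: totals 10 and 100 differ by ln(10)
  m2 <- tibble::tibble(sample_id = c("a", "b"), total_reads = c(10, 100))
  expect_equal(diff(unname(log_offsets(m2))), log(10))
  expect_error(log_offsets(tibble::tibble(sample_id = "a", total_reads = 0)),
               "positive")
})
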