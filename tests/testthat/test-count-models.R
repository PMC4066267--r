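test_that("marginal likelihood matches dense-grid integration for all families", {
  set.seed(21)
  for (rep in 1:6) {
    nsub <- 3; nv <- 3
    subj <- rep(1:nsub, each = nv)
    X <- cbind(1, rep(c(0, 1, 0), each = nv))
    off <- log(runif(nsub * nv, 1000, 9000))
    beta <- c(runif(1, -6, -4), runif(1, -1, 1))
    sb <- runif(1, 0.2, 1); k <- runif(1, 0.5, 3); pi <- runif(1, 0.1, 0.5)
    y <- rnbinom(nsub * nv, mu = exp(drop(X %*% beta) + off), size = k)
    y[rbinom(length(y), 1, pi) == 1] <- 0
    for (fam in c("plme", "nblme", "zinblme")) {
      got <- marginal_loglik(y, X, off, subj, fam, beta, sb,
                             dispersion = if (fam != "plme") k else NULL,
                             zi_prob = if (fam == "zinblme") pi else NULL)
      want <- trapezoid_marginal_loglik(y, X, off, subj, fam, beta, sb, k, pi)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("sigma_b = 0 collapses to the sum of independent log pmfs", {
  set.seed(22)
  n <- 12; subj <- rep(1:4, each = 3)
  X <- cbind(1, rnorm(n)); off <- log(runif(n, 500, 5000))
  beta <- c(-5, 0.4); k <- 1.3
  y <- rnbinom(n, mu = exp(drop(X %*% beta) + off), size = k)
  got <- marginal_loglik(y, X, off, subj, "nblme", beta, sigma_b = 0,
                         dispersion = k)
  expect_equal(got, sum(dnbinom(y, mu = exp(drop(X %*% beta) + off),
                                size = k, log = TRUE)), tolerance = 1e-10)
})

test_that("single zero observation under ZINB mixes the point mass correctly", {
  # one subject, one y = 0: marginal of log(pi + (1-pi) NB(0)) over b
  X <- matrix(1, 1, 1); off <- log(5000); beta <- -6; sb <- 0.7
  k <- 0.9; pi <- 0.3
  got <- marginal_loglik(0L, X, off, 1L, "zinblme", beta, sb,
                         dispersion = k, zi_prob = pi)
  want <- trapezoid_marginal_loglik(0L, X, off, 1L, "zinblme", beta, sb, k, pi)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("zero inflation near one cannot explain positive counts", {
  X <- cbind(rep(1, 4)); off <- rep(log(1000), 4); subj <- c(1, 1, 2, 2)
  y <- c(3L, 0L, 5L, 1L)
  ll_mid <- marginal_loglik(y, X, off, subj, "zinblme", -5, 0.5,
                            dispersion = 1, zi_prob = 0.3)
  ll_hi <- marginal_loglik(y, X, off, subj, "zinblme", -5, 0.5,
                           dispersion = 1, zi_prob = 1 - 1e-10)
  expect_lt(ll_hi, ll_mid - 50)  # log(1 - pi) drives it to -infinity
  expect_error(marginal_loglik(y, X, off, subj, "zinblme", -5, 0.5,
                               dispersion = 1, zi_prob = 1), "zi_prob")
})

test_that("maximum-likelihood fits recover NBLME parameters and match glmmTMB", {
  set.seed(23)
  dat <- simulate_nblme(60, beta = c(-5, 0.8), sigma_b = 0.5, k = 1.2)
  fit <- fit_count_model(dat$y, dat$X, dat$offset, dat$subject, "nblme",
                         model_control(nodes = 25, restarts = 1))
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[2] - 0.8), 3 * fit$se_beta[2])
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik, tolerance = 1e-8)
  expect_equal(fit$n_params, 4L)  # beta (2), sigma_b, k

  # independent cross-check: Laplace-approximate fit of the same model
  suppressMessages(library(glmmTMB))
  d <- data.frame(y = dat$y, grp = dat$X[, 2], off = dat$offset,
                  subj = factor(dat$subject))
  g <- glmmTMB(y ~ grp + offset(off) + (1 | subj), family = nbinom2, data = d)
  expect_equal(unname(fit$beta), unname(fixef(g)$cond), tolerance = 0.02)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 0.01)
  expect_equal(fit$sigma_b, sqrt(VarCorr(g)$cond$subj[1, 1]), tolerance = 0.05)
})

test_that("the maximized likelihoods nest across the family ladder", {
  set.seed(24)
  dat <- simulate_nblme(40, beta = c(-5, 0.5), sigma_b = 0.4, k = 0.8)
  y <- dat$y
  y[rbinom(length(y), 1, 0.3) == 1] <- 0L
  ctl <- model_control(nodes = 15, restarts = 1)
  fn <- fit_count_model(y, dat$X, dat$offset, dat$subject, "nblme", ctl)
  fz <- fit_count_model(y, dat$X, dat$offset, dat$subject, "zinblme", ctl)
  expect_gte(fz$loglik, fn$loglik - 1e-4)   # ZINB nests NB at pi = 0
  # and the NB fit equals the ZINB profile limit at the pi -> 0 boundary
  ll_boundary <- marginal_loglik(y, dat$X, dat$offset, dat$subject, "zinblme",
                                 fn$beta, fn$sigma_b, fn$dispersion,
                                 zi_prob = 1e-12)
  expect_equal(ll_boundary, fn$loglik, tolerance = 1e-6)
})

test_that("Poisson is penalized on overdispersed data and ZINB wins on zero-inflated data", {
  set.seed(25)
  dat <- simulate_nblme(50, beta = c(-5, 0), sigma_b = 0.3, k = 0.5)
  ctl <- model_control(nodes = 15, restarts = 1)
  fp <- fit_count_model(dat$y, dat$X, dat$offset, dat$subject, "plme", ctl)
  fn <- fit_count_model(dat$y, dat$X, dat$offset, dat$subject, "nblme", ctl)
  expect_gt(fp$aic, fn$aic + 100)
  y0 <- dat$y
  y0[rbinom(length(y0), 1, 0.35) == 1] <- 0L
  fz <- fit_count_model(y0, dat$X, dat$offset, dat$subject, "zinblme", ctl)
  fn0 <- fit_count_model(y0, dat$X, dat$offset, dat$subject, "nblme", ctl)
  expect_lt(fz$aic, fn0$aic)
  expect_lt(abs(fz$zi_prob - 0.35), 0.12)
})

test_that("the offset contract holds: scaling totals shifts only the intercept", {
  set.seed(26)
  dat <- simulate_nblme(40, beta = c(-5, 0.6), sigma_b = 0.4, k = 1.5)
  ctl <- model_control(nodes = 15, restarts = 0)
  f1 <- fit_count_model(dat$y, dat$X, dat$offset, dat$subject, "nblme", ctl)
  f2 <- fit_count_model(dat$y, dat$X, dat$offset + log(10), dat$subject,
                        "nblme", ctl)
  expect_equal(unname(f2$beta[1] - f1$beta[1]), -log(10), tolerance = 1e-3)
  expect_equal(unname(f2$beta[2]), unname(f1$beta[2]), tolerance = 1e-3)
})

test_that("Wald summaries follow the normal-theory construction", {
  fake <- structure(list(family = "nblme", converged = TRUE, boundary = FALSE,
                         beta = c(a = 0, b = 1.96), se_beta = c(a = 1, b = 1),
                         vcov_beta = diag(2), term_names = c("a", "b")),
                    class = "count_model_fit")
  w <- wald_test(fake, "a")
  expect_equal(c(w$conf.low, w$conf.high), c(-1.959964, 1.959964),
               tolerance = 1e-6)
  expect_equal(w$p.value, 1)
  w2 <- wald_test(fake, "b")
  expect_equal(w2$p.value, 0.05, tolerance = 1e-3)
  # CI symmetric about the estimate
  expect_equal(w2$conf.high - w2$estimate, w2$estimate - w2$conf.low)
  ct <- contrast_test(fake, c(1, -1))
  expect_equal(ct$estimate, -1.96)
  expect_equal(ct$std.error, sqrt(2))
  nose <- fake; nose$se_beta <- c(a = NA_real_, b = NA_real_)
  expect_error(wald_test(nose, "a"), "standard error")
})

test_that("tidy and glance expose the fit in broom form", {
  set.seed(27)
  dat <- simulate_nblme(25, beta = c(-5, 0.3), sigma_b = 0.4, k = 2)
  fit <- fit_count_model(dat$y, dat$X, dat$offset, dat$subject, "nblme",
                         model_control(nodes = 9, restarts = 0))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(nrow(td), 2L)
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  expect_equal(gl$n_params, 4L)
  expect_equal(stats::AIC(fit), fit$aic)
  # fits serialize to JSON with their convergence metadata
  tf <- tempfile(fileext = ".json")
  write_fit_json(fit, tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back$family, "nblme")
  expect_equal(back$aic, fit$aic)
  expect_equal(unlist(back$coefficients), fit$beta, tolerance = 1e-12)
})

test_that("degenerate inputs are refused or flagged, never silently wrong", {
  expect_error(fit_count_model(c(1L, 2L), cbind(1, 0:1), c(0, 0), c(1, 1),
                               "nblme"), "two subjects")
  expect_error(fit_count_model(c(1L, 2L), cbind(1, c(2, 2)), c(0, 0), c(1, 2),
                               "nblme"), "rank deficient")
  # all-zero counts under ZINB: boundary solution is flagged
  set.seed(28)
  n <- 24; subj <- rep(1:8, each = 3)
  X <- cbind(`(Intercept)` = rep(1, n)); off <- rep(log(1000), n)
  fz <- fit_count_model(rep(0L, n), X, off, subj, "zinblme",
                        model_control(nodes = 9, restarts = 0))
  expect_true(is.na(fz$aic) || fz$boundary || !fz$converged)
})
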