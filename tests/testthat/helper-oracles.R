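# Independent oracles and small fixtures used across the suite.

# Dense-grid (trapezoid) integration of the marginal likelihood over the
# subject random intercept; brute-force counterpart of the quadrature kernel.
trapezoid_marginal_loglik <- function(y, X, off, subj, family, beta, sigma_b,
                                      k = NULL, pi = NULL, n_grid = 20001L,
                                      width = 10) {
  eta0 <- drop(as.matrix(X) %*% beta) + off
  obs_ll <- function(yy, eta) {
    mu <- exp(eta)
    if (family == "plme") return(dpois(yy, mu, log = TRUE))
    if (family == "nblme") return(dnbinom(yy, mu = mu, size = k, log = TRUE))
    nb <- dnbinom(yy, mu = mu, size = k)
    log(ifelse(yy == 0, pi + (1 - pi) * nb, (1 - pi) * nb))
  }
  tot <- 0
  for (s in unique(subj)) {
    i <- which(subj == s)
    bgrid <- seq(-width * sigma_b, width * sigma_b, length.out = n_grid)
    h <- vapply(bgrid, function(b) {
      sum(obs_ll(y[i], eta0[i] + b)) + dnorm(b, 0, sigma_b, log = TRUE)
    }, numeric(1))
    m <- max(h)
    tot <- tot + m + log(sum(exp(h - m)) * (bgrid[2] - bgrid[1]))
  }
  tot
}

# Random point on the simplex (uniform Dirichlet).
random_simplex <- function(n_taxa) {
  g <- rgamma(n_taxa, 1, 1)
  g / sum(g)
}

# Independent step-up BH implementation (sorted p * m / rank, cummin).
manual_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Small longitudinal NB cohort drawn directly from the NBLME model.
simulate_nblme <- function(n_subjects, visits = 2:6, beta = c(-5, 1),
                           sigma_b = 0.5, k = 1, p_group = 0.2) {
  nv <- sample(visits, n_subjects, replace = TRUE)
  subj <- rep(seq_len(n_subjects), nv)
  n <- length(subj)
  off <- log(pmax(round(rlnorm(n, log(7548), 0.42)), 100))
  grp <- rep(rbinom(n_subjects, 1, p_group), nv)
  X <- cbind(`(Intercept)` = 1, grouppreterm = grp)
  b <- rep(rnorm(n_subjects, 0, sigma_b), nv)
  y <- rnbinom(n, mu = exp(drop(X %*% beta) + off + b), size = k)
  list(y = y, X = X, offset = off, subject = subj)
}

# Three well-separated composition clusters for CST machinery tests:
# tight Dirichlet draws around L. crispatus-, L. iners- and anaerobe-
# dominated profiles over the package's default taxon set.
planted_cst_states <- function(n_per = 12, concentration = 4000) {
  taxa <- vagilong:::default_taxa(30)
  profiles <- vagilong:::default_cst_profiles(taxa)
  draw <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
  }
  states <- t(sapply(rep(1:3, each = n_per), function(i) {
    draw(concentration * profiles[i, ])
  }))
  colnames(states) <- taxa
  list(ra = dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%02d", seq_len(3 * n_per))),
    tibble::as_tibble(states)),
    truth = rep(rownames(profiles), each = n_per))
}

# Small wide-TSV count fixture on disk.
write_count_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
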