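#' Three gestational-age windows from the 5th-95th percentile range
#'
#' Computes the 5th and 95th percentiles of the sampled gestational ages and
#' trisects the interval between them into equal-width windows; the outer
#' windows are extended to the observed minimum and maximum so every sample
#' is covered. Windows are closed on the left and open on the right, except
#' the last which is closed on both ends. Cutpoints are rounded to 0.1 week
#' for display only.
#'
#' @param ga Numeric vector of gestational ages (weeks).
#' @return Object of class `ga_intervals`: list with `cutpoints` (the two
#'   interior boundaries), `percentiles` (p5, p95), and a `windows` tibble
#'   (`window`, `lo`, `hi`).
#' @export
build_intervals <- function(ga) {
  ga <- ga[is.finite(ga)]
  if (length(unique(ga)) < 3L) abort("need at least three distinct gestational ages")
  p <- quantile(ga, c(0.05, 0.95), names = FALSE)
  if (diff(p) < 1e-8) abort("degenerate gestational-age spread")
  w <- diff(p) / 3
  cuts <- c(p[1] + w, p[1] + 2 * w)
  windows <- tibble(window = 1:3,
                    lo = c(min(ga), cuts[1], cuts[2]),
                    hi = c(cuts[1], cuts[2], max(ga)))
  structure(list(cutpoints = cuts, percentiles = c(p5 = p[1], p95 = p[2]),
                 windows = windows), class = "ga_intervals")
}

#' @export
print.ga_intervals <- function(x, ...) {
  cat(sprintf("Gestational-age windows (p5 = %.1f, p95 = %.1f):\n",
              x$percentiles[1], x$percentiles[2]))
  w <- x$windows
  for (i in 1:3) cat(sprintf("  %d: [%.1f, %.1f%s\n", i, w$lo[i], w$hi[i],
                             if (i < 3) ")" else "]"))
  invisible(x)
}

#' Assign samples to gestational-age windows
#' @param ga Gestational ages (weeks).
#' @param intervals A `ga_intervals` from [build_intervals()].
#' @return Integer vector in 1..3 (one window per sample; a partition).
#' @export
assign_interval <- function(ga, intervals) {
  stopifnot(inherits(intervals, "ga_intervals"))
  cuts <- intervals$cutpoints
  ifelse(ga < cuts[1], 1L, ifelse(ga < cuts[2], 2L, 3L))
}

#' Orthogonal polynomial basis over gestational age
#'
#' Orthonormal polynomial columns (degree 1 up) built on the centred
#' gestational ages (wraps `stats::poly`): `t(X) %*% X` is the identity and
#' every column is orthogonal to the constant. The intercept is excluded and
#' handled by the model.
#'
#' @param ga Gestational ages.
#' @param degree Polynomial degree, 1-7.
#' @return Matrix with `degree` columns named `poly1..polyN`.
#' @export
orthogonal_basis <- function(ga, degree) {
  if (degree < 1 || degree > 7) abort("degree must be between 1 and 7")
  if (length(unique(ga)) <= degree) {
    abort("degree must be smaller than the number of distinct gestational ages")
  }
  b <- unclass(poly(ga, degree = degree))
  colnames(b) <- paste0("poly", seq_len(degree))
  b[, , drop = FALSE]
}

# Descriptive mean log relative abundance per window (0.5 pseudo-count).
interval_means <- function(y, total, window) {
  lra <- log((y + 0.5) / total)
  vapply(1:3, function(k) mean(lra[window == k]), numeric(1))
}

#' Between-interval contrasts of phylotype abundance (term group)
#'
#' For each taxon, fits the PLME/NBLME/ZINBLME ladder with the
#' gestational-age window as a three-level fixed factor (plus offset and
#' subject random intercept) on the term-delivery samples, selects the
#' smallest-AIC fit, and extracts the three pairwise window contrasts
#' (2 vs 1, 3 vs 2, 3 vs 1) with Wald p-values. Each contrast's p-values are
#' adjusted across phylotypes at a 10% false discovery rate.
#'
#' @param counts Prevalence-filtered count tibble.
#' @param meta Metadata tibble.
#' @param intervals Optional `ga_intervals`; computed from the term-group
#'   gestational ages when `NULL`.
#' @param group Group whose samples are analysed; default `"term"`.
#' @param fdr FDR threshold; default 0.1.
#' @param families Ladder families.
#' @param control A [model_control()].
#' @return Tibble per taxon: interval means, contrast estimates with p and q
#'   values, `best_family`, `direction` (`up`, `down`, `flat`).
#' @export
interval_contrasts <- function(counts, meta, intervals = NULL, group = "term",
                               fdr = 0.1, families = ladder_families,
                               control = model_control()) {
  meta <- align_metadata(counts, meta)
  meta <- meta[meta$group == group, , drop = FALSE]
  if (nrow(meta) == 0L) abort("no samples in the requested group")
  if (is.null(intervals)) intervals <- build_intervals(meta$gestational_age)
  window <- assign_interval(meta$gestational_age, intervals)
  if (length(unique(window)) < 3L) abort("a gestational-age window contains no samples")
  m <- count_matrix(counts)[meta$sample_id, , drop = FALSE]
  offset <- log_offsets(meta)
  design <- cbind(`(Intercept)` = 1,
                  window2 = as.numeric(window == 2L),
                  window3 = as.numeric(window == 3L))
  contr <- list(`2v1` = c(0, 1, 0), `3v2` = c(0, -1, 1), `3v1` = c(0, 0, 1))

  rows <- purrr::map(colnames(m), function(tx) {
    y <- m[, tx]
    im <- interval_means(y, meta$total_reads, window)
    lad <- fit_model_ladder(y, design, offset, meta$subject_id,
                            families = families, control = control)
    out <- tibble(taxon = tx, best_family = lad$best_family,
                  mean1 = im[1], mean2 = im[2], mean3 = im[3],
                  est_2v1 = NA_real_, p_2v1 = NA_real_,
                  est_3v2 = NA_real_, p_3v2 = NA_real_,
                  est_3v1 = NA_real_, p_3v1 = NA_real_,
                  fitted = !is.na(lad$best_family))
    if (out$fitted) {
      for (nm in names(contr)) {
        ct <- contrast_test(lad$best_fit, contr[[nm]], label = nm)
        out[[paste0("est_", nm)]] <- ct$estimate
        out[[paste0("p_", nm)]] <- ct$p.value
      }
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  for (nm in names(contr)) {
    qcol <- paste0("q_", nm)
    res[[qcol]] <- NA_real_
    res[[qcol]][res$fitted] <- bh_adjust(res[[paste0("p_", nm)]][res$fitted])
  }
  res$direction <- interval_direction(res, fdr)
  res
}

interval_direction <- function(res, fdr) {
  vapply(seq_len(nrow(res)), function(i) {
    if (!isTRUE(res$fitted[i])) return(NA_character_)
    qs <- c(res$q_2v1[i], res$q_3v2[i], res$q_3v1[i])
    es <- c(res$est_2v1[i], res$est_3v2[i], res$est_3v1[i])
    sig <- which(is.finite(qs) & qs < fdr)
    if (!length(sig)) return("flat")
    pick <- if (3 %in% sig) 3L else sig[which.min(qs[sig])]
    if (es[pick] > 0) "up" else "down"
  }, character(1))
}

#' Orthogonal-polynomial gestational-age trend (term group)
#'
#' For each taxon, fits a negative-binomial mixed model (subject random
#' intercept, log-read-total offset) with orthogonal-polynomial terms of
#' gestational age of degree 1 to `max_degree`, keeps the degree minimizing
#' the AIC, and reports per-term Wald p-values, adjusted across phylotypes
#' within each polynomial term at a 10% FDR.
#'
#' @inheritParams interval_contrasts
#' @param max_degree Highest polynomial degree tried; default 7.
#' @return Tibble per taxon: `poly_degree`, linear-term estimate, per-term
#'   p/q values (list columns `term_p`, `term_q`), `direction`.
#' @export
polynomial_trend <- function(counts, meta, group = "term", max_degree = 7,
                             fdr = 0.1, control = model_control()) {
  if (max_degree < 1 || max_degree > 7) abort("max_degree must be in 1..7")
  meta <- align_metadata(counts, meta)
  meta <- meta[meta$group == group, , drop = FALSE]
  if (nrow(meta) == 0L) abort("no samples in the requested group")
  m <- count_matrix(counts)[meta$sample_id, , drop = FALSE]
  offset <- log_offsets(meta)
  basis_full <- orthogonal_basis(meta$gestational_age, max_degree)

  rows <- purrr::map(colnames(m), function(tx) {
    y <- m[, tx]
    fits <- vector("list", max_degree)
    aics <- rep(NA_real_, max_degree)
    for (d in seq_len(max_degree)) {
      design <- cbind(`(Intercept)` = 1, basis_full[, seq_len(d), drop = FALSE])
      f <- fit_count_model(y, design, offset, meta$subject_id,
                           family = "nblme", control = control)
      fits[[d]] <- f
      if (isTRUE(f$converged)) aics[d] <- f$aic
    }
    if (!any(is.finite(aics))) {
      return(tibble(taxon = tx, poly_degree = NA_integer_, aic = NA_real_,
                    linear_estimate = NA_real_,
                    term_p = list(rep(NA_real_, 0)), fitted = FALSE))
    }
    d_best <- which.min(aics)
    fit <- fits[[d_best]]
    td <- tidy(fit)
    pv <- td$p.value[-1]  # polynomial terms, intercept excluded
    tibble(taxon = tx, poly_degree = as.integer(d_best), aic = aics[d_best],
           linear_estimate = td$estimate[2],
           term_p = list(pv), fitted = TRUE)
  })
  res <- dplyr::bind_rows(rows)

  # within-term BH across phylotypes: term j adjusted over taxa of degree >= j
  maxd <- max(c(res$poly_degree, 1L), na.rm = TRUE)
  qlists <- lapply(seq_len(nrow(res)), function(i)
    rep(NA_real_, length(res$term_p[[i]])))
  for (j in seq_len(maxd)) {
    idx <- which(res$fitted & vapply(res$term_p, length, integer(1)) >= j)
    if (!length(idx)) next
    qj <- bh_adjust(vapply(idx, function(i) res$term_p[[i]][j], numeric(1)))
    for (k in seq_along(idx)) qlists[[idx[k]]][j] <- qj[k]
  }
  res$term_q <- qlists
  # a monotone direction claim requires the linear component itself to be
  # significant; higher-order terms alone indicate shape, not direction
  res$direction <- vapply(seq_len(nrow(res)), function(i) {
    if (!isTRUE(res$fitted[i])) return(NA_character_)
    q1 <- res$term_q[[i]][1]
    if (!is.finite(q1) || q1 >= fdr) return("flat")
    if (res$linear_estimate[i] > 0) "up" else "down"
  }, character(1))
  res
}

#' Full gestational-age trend analysis (term group)
#'
#' Runs both the three-window contrast analysis and the continuous
#' orthogonal-polynomial analysis and joins them by taxon.
#'
#' @inheritParams interval_contrasts
#' @inheritParams polynomial_trend
#' @return Tibble joining [interval_contrasts()] and [polynomial_trend()]
#'   columns (polynomial columns suffixed `_poly`).
#' @export
run_trend_analysis <- function(counts, meta, group = "term", fdr = 0.1,
                               max_degree = 7, control = model_control()) {
  ic <- interval_contrasts(counts, meta, group = group, fdr = fdr,
                           control = control)
  pt <- polynomial_trend(counts, meta, group = group, max_degree = max_degree,
                         fdr = fdr, control = control)
  dplyr::left_join(ic, pt, by = "taxon", suffix = c("", "_poly"))
}
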