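#' Signed fold change from a log-scale estimate
#'
#' Converts a model coefficient (difference in mean natural-log relative
#' abundance) into the signed fold-change reporting convention:
#' `exp(estimate)` when the estimate is nonnegative, and `-exp(-estimate)`
#' when it is negative, so a decrease is reported as the fold-decrease
#' magnitude carrying a minus sign (for example an estimate of -0.864 is a
#' -2.4-fold change). `abs(fold_change) >= 1` always.
#'
#' @param estimate Numeric vector of natural-log-scale estimates.
#' @return Numeric vector of signed fold changes (full precision; round to
#'   one decimal for display).
#' @export
#' @examples
#' fold_change(c(2.524, -0.864, 0))  # 12.48, -2.37, 1
fold_change <- function(estimate) {
  if (any(!is.finite(estimate))) abort("estimates must be finite")
  ifelse(estimate >= 0, exp(estimate), -exp(-estimate))
}

#' Benjamini-Hochberg adjustment across phylotypes
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`; `method = "BY"` gives the
#' Benjamini-Yekutieli variant). Output order matches input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  ok <- is.finite(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = method)
}

ladder_families <- c("plme", "nblme", "zinblme")

# Fit the three-family ladder for one response and pick the smallest-AIC
# converged fit; ties break toward the family with fewer parameters
# (the ladder is listed simplest first).
fit_model_ladder <- function(y, design, offset, subject,
                             families = ladder_families,
                             control = model_control()) {
  fits <- lapply(families, function(f) {
    fit_count_model(y, design, offset, subject, family = f, control = control)
  })
  names(fits) <- families
  aics <- vapply(fits, function(f) if (isTRUE(f$converged)) f$aic else NA_real_,
                 numeric(1))
  best <- NA_character_
  if (any(is.finite(aics))) {
    best <- names(aics)[which(aics <= min(aics, na.rm = TRUE) + 1e-8)][1]
  }
  list(fits = fits, aic = aics, best_family = best,
       best_fit = if (!is.na(best)) fits[[best]] else NULL)
}

#' Per-phylotype differential abundance between study groups
#'
#' For each taxon in a (prevalence-filtered) count table, fits the
#' PLME/NBLME/ZINBLME ladder with fixed effects intercept + group, a
#' log-read-total offset and a subject random intercept; retains the
#' smallest-AIC converged fit; computes the Wald estimate, 95% CI and
#' p-value of the group coefficient (preterm minus term, natural-log scale);
#' converts the estimate to a signed fold change; adjusts p-values across
#' the taxa whose ladder produced a fit (Benjamini-Hochberg); and calls
#' significance as `q_value < fdr` and `|fold_change| > fc_threshold`.
#'
#' @param counts Count tibble (already prevalence-filtered).
#' @param meta Metadata tibble aligned with `counts`.
#' @param fdr q-value threshold; default 0.1.
#' @param fc_threshold Fold-change magnitude threshold; default 1.5.
#' @param families Model families to include in the ladder.
#' @param control A [model_control()].
#' @return Tibble with one row per taxon: per-family AICs, `best_family`,
#'   `estimate`, `conf.low`, `conf.high`, `fold_change`, `p_value`,
#'   `q_value`, `significant`, `fitted` (FALSE when no family converged).
#' @export
run_group_comparison <- function(counts, meta, fdr = 0.1, fc_threshold = 1.5,
                                 families = ladder_families,
                                 control = model_control()) {
  meta <- align_metadata(counts, meta)
  m <- count_matrix(counts)
  m <- m[meta$sample_id, , drop = FALSE]
  offset <- log_offsets(meta)
  design <- cbind(`(Intercept)` = 1, grouppreterm = as.numeric(meta$group == "preterm"))

  rows <- purrr::map(colnames(m), function(tx) {
    lad <- fit_model_ladder(m[, tx], design, offset, meta$subject_id,
                            families = families, control = control)
    out <- tibble(taxon = tx,
                  aic_plme = unname(lad$aic["plme"]),
                  aic_nblme = unname(lad$aic["nblme"]),
                  aic_zinblme = unname(lad$aic["zinblme"]),
                  best_family = lad$best_family,
                  estimate = NA_real_, conf.low = NA_real_,
                  conf.high = NA_real_, fold_change = NA_real_,
                  p_value = NA_real_, fitted = !is.na(lad$best_family))
    if (out$fitted) {
      w <- wald_test(lad$best_fit, "grouppreterm")
      out$estimate <- w$estimate
      out$conf.low <- w$conf.low
      out$conf.high <- w$conf.high
      out$fold_change <- fold_change(w$estimate)
      out$p_value <- w$p.value
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- NA_real_
  res$q_value[res$fitted] <- bh_adjust(res$p_value[res$fitted])
  res$significant <- !is.na(res$q_value) & res$q_value < fdr &
    abs(res$fold_change) > fc_threshold
  res
}
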