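#' Shannon Diversity Index per sample
#'
#' \eqn{SDI = -\sum_{p_i > 0} p_i \ln p_i} over each sample's relative
#' abundances (natural log, the ecology convention). Zero for a
#' monodominant sample; at most `ln`(number of taxa).
#'
#' @param ra Relative-abundance tibble from [relative_abundance()].
#' @return Tibble `sample_id`, `sdi`.
#' @export
shannon_index <- function(ra) {
  m <- as.matrix(ra[taxon_names(ra)])
  sdi <- apply(m, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  tibble(sample_id = ra$sample_id, sdi = unname(sdi))
}

#' Compare Shannon diversity between groups with a linear mixed model
#'
#' SDI values are log-transformed to improve normality (values below `floor`
#' are floored first; monodominant samples have SDI near zero) and compared
#' between groups with a Gaussian linear mixed-effects model with a subject
#' random intercept (`nlme::lme`). Raw-scale medians and IQRs per group are
#' reported alongside the model estimate.
#'
#' @param sdi Tibble from [shannon_index()].
#' @param meta Metadata tibble.
#' @param floor Lower guard applied before the log transform; default 1e-6.
#' @param include_ga Also adjust for gestational age as a fixed covariate.
#' @return Object of class `diversity_comparison`: list with `per_sample`,
#'   `group_summary` (median/IQR of raw SDI), `estimate` (group effect on
#'   the log-SDI scale), `p_value`, and the fitted `lme` model.
#' @export
compare_diversity <- function(sdi, meta, floor = 1e-6, include_ga = FALSE) {
  df <- dplyr::inner_join(sdi, meta, by = "sample_id")
  n_subj <- df %>%
    dplyr::distinct(.data$subject_id, .data$group) %>%
    dplyr::count(.data$group)
  if (nrow(n_subj) < 2L || any(n_subj$n < 2L)) {
    abort("need at least two subjects in each group")
  }
  df$group <- factor(as.character(df$group), levels = c("term", "preterm"))
  df$log_sdi <- log(pmax(df$sdi, floor))
  if (sd(df$log_sdi) < 1e-12) {
    abort("all SDI values are identical; no variance to model")
  }
  fml <- if (include_ga) log_sdi ~ group + gestational_age else log_sdi ~ group
  fit <- nlme::lme(fixed = fml, random = ~ 1 | subject_id, data = df,
                   method = "REML")
  tt <- summary(fit)$tTable
  row <- grep("^grouppreterm$", rownames(tt))
  summary_tbl <- df %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(n = dplyr::n(),
                     median_sdi = median(.data$sdi),
                     iqr_lo = quantile(.data$sdi, 0.25),
                     iqr_hi = quantile(.data$sdi, 0.75),
                     .groups = "drop")
  structure(list(per_sample = df[c("sample_id", "subject_id", "group",
                                   "gestational_age", "sdi", "log_sdi")],
                 group_summary = summary_tbl,
                 estimate = unname(tt[row, "Value"]),
                 std_error = unname(tt[row, "Std.Error"]),
                 p_value = unname(tt[row, "p-value"]),
                 model = fit),
            class = "diversity_comparison")
}

#' @export
print.diversity_comparison <- function(x, ...) {
  cat("Shannon-diversity group comparison (Gaussian LME on log SDI)\n")
  s <- x$group_summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: median SDI %.2f (IQR %.2f to %.2f), n = %d\n",
                s$group[i], s$median_sdi[i], s$iqr_lo[i], s$iqr_hi[i], s$n[i]))
  }
  cat(sprintf("  group effect (log scale): %.3f, p = %.3g\n",
              x$estimate, x$p_value))
  invisible(x)
}

#' @export
glance.diversity_comparison <- function(x, ...) {
  tibble(estimate = x$estimate, std.error = x$std_error,
         p.value = x$p_value, n_samples = nrow(x$per_sample))
}
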