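#' Pipeline configuration
#'
#' Thresholds and model options binding all analysis stages, with the study
#' defaults: 25% prevalence filter, 10% FDR, 1.5-fold significance
#' threshold, three community state types clustered on Jensen-Shannon
#' divergence, 25 quadrature nodes and 3 optimizer restarts.
#'
#' @param min_prevalence Prevalence-filter threshold.
#' @param fdr False-discovery-rate threshold.
#' @param fc_threshold Fold-change magnitude threshold.
#' @param cst_k Number of community state types.
#' @param cst_metric `"jsd"` or `"js_distance"`.
#' @param max_degree Highest polynomial degree for the trend analysis.
#' @param nodes,restarts,rel_tol Model-fitting options (see [model_control()]).
#' @param seed Root seed for any randomness in fitting restarts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_prevalence = 0.25, fdr = 0.1,
                            fc_threshold = 1.5, cst_k = 3,
                            cst_metric = c("jsd", "js_distance"),
                            max_degree = 7, nodes = 25, restarts = 3,
                            rel_tol = 1e-8, seed = 1L) {
  cst_metric <- match.arg(cst_metric)
  stopifnot(min_prevalence > 0, min_prevalence <= 1, fdr > 0, fdr < 1,
            fc_threshold >= 1, cst_k >= 1)
  structure(list(min_prevalence = min_prevalence, fdr = fdr,
                 fc_threshold = fc_threshold, cst_k = as.integer(cst_k),
                 cst_metric = cst_metric, max_degree = as.integer(max_degree),
                 nodes = as.integer(nodes), restarts = as.integer(restarts),
                 rel_tol = rel_tol, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The YAML round trip is lossless: reading a written config reproduces it.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly ([write_pipeline_config()]); the config
#'   ([read_pipeline_config()]).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full longitudinal analysis
#'
#' Sequences all stages on a count table and metadata: prevalence filtering,
#' Jensen-Shannon/Ward community state typing with CST frequencies, the
#' per-phylotype group comparison (PLME/NBLME/ZINBLME ladder, AIC selection,
#' BH adjustment), gestational-age trend analyses in the term group, and the
#' Shannon-diversity comparison. Results are returned as a list and,
#' optionally, written as TSV/JSON files with a run manifest carrying the
#' configuration hash.
#'
#' @param counts Count tibble (or path to a count TSV).
#' @param meta Metadata tibble (or path to a metadata TSV).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `vagilong_analysis`: `filtered_counts`,
#'   `cst` (labelled clustering), `cst_frequencies`, `differential_abundance`,
#'   `trends`, `diversity`, `manifest`.
#' @export
run_full_analysis <- function(counts, meta, config = pipeline_config(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(counts)) counts <- with_stage("read", read_count_table(counts))
  if (is.character(meta)) meta <- with_stage("read", read_sample_metadata(meta, counts))
  meta <- with_stage("validate", validate_metadata(meta, counts))
  control <- model_control(nodes = config$nodes, restarts = config$restarts,
                           rel_tol = config$rel_tol)

  filtered <- with_stage("prevalence_filter",
                         prevalence_filter(counts, config$min_prevalence))
  ra <- with_stage("relative_abundance", relative_abundance(counts))

  cst <- with_stage("cst_typing", {
    div <- pairwise_divergence(ra, metric = config$cst_metric)
    label_csts(ward_cluster(div, k = config$cst_k), ra)
  })
  freqs <- with_stage("cst_frequencies", cst_frequencies(cst, meta))

  withr::local_seed(config$seed)
  diff <- with_stage("differential_abundance",
                     run_group_comparison(filtered, meta, fdr = config$fdr,
                                          fc_threshold = config$fc_threshold,
                                          control = control))
  trends <- with_stage("gestational_trends",
                       run_trend_analysis(filtered, meta, fdr = config$fdr,
                                          max_degree = config$max_degree,
                                          control = control))
  diversity <- with_stage("diversity",
                          compare_diversity(shannon_index(ra), meta))

  manifest <- list(
    package = "vagilong",
    version = as.character(utils::packageVersion("vagilong")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_samples = nrow(counts), n_taxa = length(taxon_names(counts)),
    n_taxa_retained = length(taxon_names(filtered)))

  res <- structure(list(filtered_counts = filtered, cst = cst,
                        cst_frequencies = freqs,
                        differential_abundance = diff, trends = trends,
                        diversity = diversity, manifest = manifest),
                   class = "vagilong_analysis")
  if (!is.null(out_dir)) write_analysis(res, meta, out_dir)
  res
}

write_analysis <- function(res, meta, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  asg <- dplyr::inner_join(res$cst$assignments, meta, by = "sample_id")
  readr::write_tsv(asg[c("sample_id", "subject_id", "gestational_age",
                         "cluster", "cst")],
                   file.path(out_dir, "cst_assignments.tsv"), progress = FALSE)
  readr::write_tsv(res$cst_frequencies,
                   file.path(out_dir, "cst_frequencies.tsv"), progress = FALSE)
  readr::write_tsv(res$differential_abundance,
                   file.path(out_dir, "differential_abundance.tsv"),
                   progress = FALSE)
  trends_flat <- dplyr::select(res$trends, -dplyr::any_of(c("term_p", "term_q")))
  readr::write_tsv(trends_flat, file.path(out_dir, "trends.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$diversity$per_sample,
                   file.path(out_dir, "shannon_diversity.tsv"), progress = FALSE)
  jsonlite::write_json(
    c(as.list(glance(res$diversity)),
      list(group_summary = res$diversity$group_summary)),
    file.path(out_dir, "diversity_summary.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.vagilong_analysis <- function(x, ...) {
  cat("Longitudinal vaginal-microbiota analysis\n")
  cat(sprintf("  %d taxa retained at %.0f%% prevalence\n",
              length(taxon_names(x$filtered_counts)),
              100 * x$manifest$config$min_prevalence))
  ov <- x$cst_frequencies[x$cst_frequencies$group == "overall", ]
  cat("  CST frequencies: ",
      paste(sprintf("%s %.1f%%", ov$cst, ov$pct), collapse = ", "), "\n")
  cat(sprintf("  differentially abundant taxa (group): %d of %d\n",
              sum(x$differential_abundance$significant, na.rm = TRUE),
              nrow(x$differential_abundance)))
  dir_tab <- table(x$trends$direction)
  cat("  gestational-age directions: ",
      paste(sprintf("%s %d", names(dir_tab), dir_tab), collapse = ", "), "\n")
  cat(sprintf("  diversity group effect: %.3f (p = %.3g)\n",
              x$diversity$estimate, x$diversity$p_value))
  invisible(x)
}
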