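#' Kullback-Leibler divergence between two community states
#'
#' \eqn{D_{KL}(p, q) = \sum_{i: p_i > 0} p_i \log_2(p_i / q_i)}. Terms with
#' `p[i] == 0` contribute zero (the limit of `x log x`). When `q` lacks
#' support where `p` has mass the divergence is infinite and `Inf` is
#' returned explicitly, never a capped large number.
#'
#' @param p,q Numeric probability vectors of equal length (each sums to 1).
#' @param base Logarithm base; base 2 (the default) bounds the derived
#'   Jensen-Shannon divergence by 1.
#' @return Nonnegative real, possibly `Inf`.
#' @export
kl_divergence <- function(p, q, base = 2) {
  check_state_pair(p, q)
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos], base = base))
}

#' Jensen-Shannon divergence between two community states
#'
#' The average of the KL divergences of `p` and `q` to their midpoint
#' `a = (p + q) / 2`, with base-2 logarithms so the value lies in `[0, 1]`:
#' 0 means the two community states are identical, 1 means they share no
#' support. Always finite, symmetric in its arguments.
#'
#' @inheritParams kl_divergence
#' @return Real in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  check_state_pair(p, q)
  a <- (p + q) / 2
  (kl_divergence(p, a) + kl_divergence(q, a)) / 2
}

#' Jensen-Shannon distance
#'
#' The square root of [js_divergence()]; a metric (satisfies the triangle
#' inequality).
#'
#' @inheritParams kl_divergence
#' @return Real in `[0, 1]`.
#' @export
js_distance <- function(p, q) sqrt(js_divergence(p, q))

check_state_pair <- function(p, q) {
  if (!is.numeric(p) || !is.numeric(q)) abort("community states must be numeric vectors")
  if (length(p) != length(q)) abort("community states have different dimensions")
  if (any(p < 0) || any(q < 0)) abort("community states must be nonnegative")
  invisible(TRUE)
}

#' Pairwise divergence matrix over community states
#'
#' Computes all pairwise Jensen-Shannon divergences (or distances) between
#' the rows of a relative-abundance tibble, using the entropy identity
#' \eqn{D_{JS}(p,q) = H((p+q)/2) - (H(p) + H(q))/2} with base-2 entropies.
#'
#' @param ra Relative-abundance tibble from [relative_abundance()].
#' @param metric `"jsd"` (divergence, the clustering default) or
#'   `"js_distance"` (its square root).
#' @return Symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
pairwise_divergence <- function(ra, metric = c("jsd", "js_distance")) {
  metric <- match.arg(metric)
  m <- as.matrix(ra[taxon_names(ra)])
  if (nrow(m) < 2L) abort("need at least two samples for a divergence matrix")
  rownames(m) <- ra$sample_id
  n <- nrow(m)
  h <- apply(m, 1L, entropy2)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    pi_row <- m[i, ]
    js <- vapply((i + 1L):n, function(j) {
      entropy2((pi_row + m[j, ]) / 2) - (h[i] + h[j]) / 2
    }, numeric(1))
    js <- pmin(pmax(js, 0), 1)
    d[i, (i + 1L):n] <- js
    d[(i + 1L):n, i] <- js
  }
  if (metric == "js_distance") d <- sqrt(d)
  d
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Ward-linkage clustering of a divergence matrix
#'
#' Agglomerative hierarchical clustering of samples with the classical Ward
#' criterion (`stats::hclust(method = "ward.D")`), which treats the supplied
#' dissimilarities as squared-Euclidean surrogates, applied directly to the
#' precomputed Jensen-Shannon divergence matrix. The tree is cut into
#' `k` clusters.
#'
#' @param div Symmetric divergence matrix from [pairwise_divergence()].
#' @param k Number of clusters (community state types); default 3.
#' @return An object of class `cst_clustering`: a list with `assignments`
#'   (tibble `sample_id`, `cluster`), the `hclust` tree, and `k`.
#' @export
ward_cluster <- function(div, k = 3) {
  if (!is.matrix(div) || nrow(div) != ncol(div)) abort("divergence matrix must be square")
  if (max(abs(div - t(div))) > 1e-8) abort("divergence matrix must be symmetric")
  n <- nrow(div)
  if (k < 1 || k > n) abort("k must be between 1 and the number of samples")
  hc <- hclust(as.dist(div), method = "ward.D")
  cl <- cutree(hc, k = k)
  structure(list(
    assignments = tibble(sample_id = rownames(div), cluster = as.integer(cl)),
    tree = hc, k = as.integer(k), labelled = FALSE
  ), class = "cst_clustering")
}

#' Label clusters as community state types
#'
#' Each cluster is labelled from its mean community state: clusters whose
#' total *Lactobacillus* relative abundance falls below `lacto_threshold`
#' are labelled `IV-B` (diverse anaerobe-rich); otherwise the cluster takes
#' the CST of its dominant indicator taxon (default: *L. crispatus* for CST
#' I, *L. iners* for CST III), or `other` when the dominant taxon matches no
#' indicator.
#'
#' @param clustering A `cst_clustering` from [ward_cluster()].
#' @param ra Relative-abundance tibble for the same samples.
#' @param reference_taxa Named character vector mapping CST labels to
#'   indicator taxa.
#' @param lacto_threshold Mean *Lactobacillus* total below which a cluster is
#'   `IV-B`; default 0.5.
#' @return The clustering with a `cst` column added to `assignments`.
#' @export
label_csts <- function(clustering, ra,
                       reference_taxa = c(I = "Lactobacillus crispatus",
                                          III = "Lactobacillus iners"),
                       lacto_threshold = 0.5) {
  stopifnot(inherits(clustering, "cst_clustering"))
  asg <- clustering$assignments
  m <- as.matrix(ra[taxon_names(ra)])
  rownames(m) <- ra$sample_id
  m <- m[asg$sample_id, , drop = FALSE]
  lacto <- grepl("^Lactobacillus", colnames(m))
  labels <- character(clustering$k)
  for (g in seq_len(clustering$k)) {
    centroid <- colMeans(m[asg$cluster == g, , drop = FALSE])
    if (sum(centroid[lacto]) < lacto_threshold) {
      labels[g] <- "IV-B"
    } else {
      dom <- names(centroid)[which.max(centroid)]
      hit <- names(reference_taxa)[reference_taxa == dom]
      labels[g] <- if (length(hit)) hit[1] else "other"
    }
  }
  clustering$assignments$cst <- labels[asg$cluster]
  clustering$cluster_labels <- labels
  clustering$labelled <- TRUE
  clustering
}

#' CST frequency table
#'
#' Percent frequency of each community state type per group and overall.
#' Percentages within each row sum to 100 (up to rounding).
#'
#' @param clustering A labelled `cst_clustering` (see [label_csts()]), or a
#'   tibble with `sample_id` and `cst` columns.
#' @param meta Metadata tibble.
#' @return Tibble with columns `group`, `cst`, `n`, `pct`; `group` includes
#'   an `"overall"` row set.
#' @export
cst_frequencies <- function(clustering, meta) {
  asg <- if (inherits(clustering, "cst_clustering")) clustering$assignments else clustering
  if (!"cst" %in% names(asg)) abort("clusters are unlabelled; run label_csts() first")
  df <- dplyr::inner_join(asg, meta, by = "sample_id")
  per_group <- df %>%
    dplyr::count(group = as.character(.data$group), .data$cst) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  overall <- df %>%
    dplyr::count(.data$cst) %>%
    dplyr::mutate(group = "overall", pct = 100 * .data$n / sum(.data$n)) %>%
    dplyr::select("group", "cst", "n", "pct")
  dplyr::bind_rows(overall, per_group)
}

#' @export
print.cst_clustering <- function(x, ...) {
  cat("Community state type clustering (Ward linkage, Jensen-Shannon)\n")
  cat(sprintf("  samples: %d, clusters: %d\n", nrow(x$assignments), x$k))
  if (isTRUE(x$labelled)) {
    tb <- table(x$assignments$cst)
    cat("  labels: ", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}
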