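#' Read a wide taxon-by-sample count table
#'
#' Reads the canonical on-disk format for 16S phylotype read counts: a UTF-8
#' tab-separated file whose first column is `sample_id` and whose remaining
#' columns are taxon names, with nonnegative integer cells. One row per
#' sample.
#'
#' @param path Path to a TSV file.
#' @return A count tibble: column `sample_id` followed by one integer column
#'   per taxon, validated by [validate_count_table()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tA\tB", "s1\t5\t0", "s2\t0\t7"), tf)
#' read_count_table(tf)
read_count_table <- function(path) {
  if (!file.exists(path)) abort(paste0("count table file not found: ", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, name_repair = "minimal")
  if (nrow(tbl) == 0L) abort("no samples: count table file is empty")
  if (names(tbl)[1] != "sample_id") {
    abort("first column of a count table must be 'sample_id'")
  }
  validate_count_table(tbl)
}

#' Write a count table to disk
#'
#' @param counts A validated count tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Validate a count tibble
#'
#' Enforces the count-table invariants: a `sample_id` character column with
#' unique ids, unique taxon column names, and nonnegative integer-valued
#' cells with a positive total per sample.
#'
#' @param counts A tibble with a `sample_id` column and taxon count columns.
#' @return The validated tibble (cells coerced to integer).
#' @export
validate_count_table <- function(counts) {
  counts <- as_tibble(counts, .name_repair = "minimal")
  if (!"sample_id" %in% names(counts)) abort("count table lacks a 'sample_id' column")
  if (nrow(counts) == 0L) abort("no samples: count table has zero rows")
  taxa <- names(counts)[names(counts) != "sample_id"]
  if (length(taxa) == 0L) abort("count table has no taxon columns")
  if (anyDuplicated(counts$sample_id)) abort("duplicate sample ids in count table")
  if (anyDuplicated(taxa)) abort("duplicate taxon names in count table")
  m <- as.matrix(counts[taxa])
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("malformed count in row %d ('%s'), column '%s'",
                  bad[1], counts$sample_id[bad[1]], taxa[bad[2]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count in row %d ('%s'), column '%s'",
                  bad[1], counts$sample_id[bad[1]], taxa[bad[2]]))
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer count in row %d ('%s'), column '%s'",
                  bad[1], counts$sample_id[bad[1]], taxa[bad[2]]))
  }
  counts[taxa] <- lapply(counts[taxa], function(x) as.integer(round(x)))
  counts
}

#' Extract the integer count matrix (samples x taxa) from a count tibble
#' @param counts A count tibble.
#' @return Integer matrix with sample ids as row names.
#' @export
count_matrix <- function(counts) {
  taxa <- setdiff(names(counts), "sample_id")
  m <- as.matrix(counts[taxa])
  storage.mode(m) <- "integer"
  rownames(m) <- counts$sample_id
  m
}

#' Taxon names of a count or relative-abundance tibble
#' @param counts A count or relative-abundance tibble.
#' @return Character vector of taxon column names.
#' @export
taxon_names <- function(counts) setdiff(names(counts), "sample_id")

#' Read per-sample metadata
#'
#' Reads a TSV with columns `sample_id, subject_id, group, gestational_age,
#' total_reads`, where `group` is `term` or `preterm`. When a count table is
#' supplied, `total_reads` is checked against the count-table row sums, which
#' are authoritative; any mismatch is an error. Gestational ages within a
#' subject must be strictly increasing (no duplicated visit ages).
#'
#' @param path Path to the metadata TSV.
#' @param counts Optional count tibble to cross-check against.
#' @return A metadata tibble with `group` as a factor (levels term, preterm).
#' @export
read_sample_metadata <- function(path, counts = NULL) {
  if (!file.exists(path)) abort(paste0("metadata file not found: ", path))
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    subject_id = readr::col_character(),
    group = readr::col_character(),
    gestational_age = readr::col_double(),
    total_reads = readr::col_double()
  ), progress = FALSE)
  validate_metadata(meta, counts)
}

#' Validate a metadata tibble against its count table
#' @param meta Metadata tibble.
#' @param counts Optional count tibble; if given, every sample must have
#'   exactly one metadata record and `total_reads` must equal the row sum.
#' @return The validated metadata tibble.
#' @export
validate_metadata <- function(meta, counts = NULL) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "subject_id", "group", "gestational_age", "total_reads")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("metadata lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample ids in metadata")
  bad_grp <- setdiff(unique(meta$group), c("term", "preterm"))
  if (length(bad_grp)) abort(paste0("unknown group label(s): ", paste(bad_grp, collapse = ", ")))
  meta$group <- factor(meta$group, levels = c("term", "preterm"))
  if (any(!is.finite(meta$total_reads)) || any(meta$total_reads <= 0)) {
    abort("total_reads must be a positive integer for every sample")
  }
  dup_ga <- meta %>%
    dplyr::count(.data$subject_id, .data$gestational_age) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(dup_ga)) {
    abort(sprintf("gestational ages must be strictly increasing within subject: subject '%s' has repeated GA %.1f",
                  dup_ga$subject_id[1], dup_ga$gestational_age[1]))
  }
  if (!is.null(counts)) {
    counts <- validate_count_table(counts)
    if (!setequal(counts$sample_id, meta$sample_id)) {
      abort("metadata and count table sample ids do not match one-to-one")
    }
    m <- count_matrix(counts)
    rs <- rowSums(m)[meta$sample_id]
    if (any(rs != meta$total_reads)) {
      bad <- meta$sample_id[which(rs != meta$total_reads)[1]]
      abort(sprintf("total_reads mismatch for sample '%s': metadata says %d, count-table row sum is %d",
                    bad, as.integer(meta$total_reads[meta$sample_id == bad]),
                    as.integer(rs[bad])))
    }
  }
  meta
}

#' Write metadata to disk
#' @param meta Metadata tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Convert counts to per-sample relative abundances (community states)
#'
#' Each sample's counts are divided by its total so the taxon columns sum
#' to one: the community state used by the divergence and diversity stages.
#'
#' @param counts A count tibble.
#' @return A tibble with the same shape, taxon columns in `[0, 1]` summing to
#'   1 per row.
#' @export
relative_abundance <- function(counts) {
  counts <- validate_count_table(counts)
  m <- count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(sprintf("sample '%s' has zero total reads; cannot form relative abundances",
                  counts$sample_id[which(tot == 0)[1]]))
  }
  ra <- m / tot
  dplyr::bind_cols(tibble(sample_id = counts$sample_id), as_tibble(ra))
}

#' Prevalence filter
#'
#' Retains taxa present (count >= 1) in at least `min_prevalence` of the
#' samples; the boundary is inclusive, so a taxon present in exactly 25% of
#' samples is kept at the default threshold. The sample set is unchanged.
#'
#' @param counts A count tibble.
#' @param min_prevalence Fraction of samples in `(0, 1]`; default 0.25.
#' @return The filtered count tibble (possibly with zero taxon columns).
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.25) {
  if (!is.numeric(min_prevalence) || min_prevalence <= 0 || min_prevalence > 1) {
    abort("min_prevalence must be in (0, 1]")
  }
  counts <- validate_count_table(counts)
  m <- count_matrix(counts)
  prev <- colMeans(m >= 1L)
  keep <- names(prev)[prev >= min_prevalence]
  counts[c("sample_id", keep)]
}

# Alignment check for downstream stages: metadata valid on its own and in
# one-to-one correspondence with the (possibly taxon-filtered) count table;
# the row-sum invariant is only enforced against the full table at load.
align_metadata <- function(counts, meta) {
  meta <- validate_metadata(meta)
  if (!setequal(counts$sample_id, meta$sample_id)) {
    abort("metadata and count table sample ids do not match one-to-one")
  }
  meta
}

#' Natural-log offsets from sample read totals
#'
#' The count models include the log of the total number of reads in a sample
#' as an offset, so coefficients describe relative (not absolute) abundance.
#'
#' @param meta Metadata tibble with `total_reads`.
#' @return Named numeric vector of `log(total_reads)`, in metadata order.
#' @export
log_offsets <- function(meta) {
  if (any(!is.finite(meta$total_reads)) || any(meta$total_reads <= 0)) {
    abort("total_reads must be positive to form log offsets")
  }
  setNames(log(meta$total_reads), meta$sample_id)
}
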