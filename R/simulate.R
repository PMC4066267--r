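#' Phylotype names used by the analysis-scale taxa
#'
#' The 21 phylotypes that pass the 25% prevalence filter in a vaginal 16S
#' survey of this design; remaining taxa are rare fillers.
#' @keywords internal
analysis_taxa <- c(
  "Prevotella genogroup 3", "Dialister sp. type 2", "Sneathia sanguinegens",
  "Parvimonas micra", "Gemella", "BVAB2", "Lactobacillus jensenii", "BVAB1",
  "Megasphaera sp. type 1", "Dialister propionicifaciens",
  "Lactobacillus coleohominis", "Gardnerella vaginalis",
  "Aerococcus christensenii", "Atopobium vaginae", "Lactobacillus crispatus",
  "Lactobacillus iners", "Eggerthella", "Lactobacillus vaginalis",
  "Ureaplasma parvum", "Atopobium rimae", "Lactobacillus gasseri")

ga_up_taxa <- c("Lactobacillus crispatus", "Lactobacillus jensenii",
                "Lactobacillus gasseri", "Lactobacillus vaginalis")
ga_down_taxa <- c("Eggerthella", "Parvimonas micra", "Dialister sp. type 2",
                  "Gemella", "BVAB1", "BVAB2", "Atopobium vaginae",
                  "Gardnerella vaginalis", "Atopobium rimae",
                  "Sneathia sanguinegens", "Ureaplasma parvum")

default_taxa <- function(n_taxa = 99) {
  if (n_taxa < length(analysis_taxa)) abort("n_taxa must be at least 21")
  c(analysis_taxa, sprintf("phylotype_%02d", seq_len(n_taxa - length(analysis_taxa)) + 21L))
}

# CST base composition profiles (rows: I, III, IV-B), normalized.
default_cst_profiles <- function(taxa) {
  set_w <- function(w, nm, v) { w[nm] <- v; w }
  base <- setNames(rep(3e-5, length(taxa)), taxa)      # rare fillers
  base[analysis_taxa] <- 0.0015                        # broad low-level floor
  p1 <- set_w(base, c("Lactobacillus crispatus", "Lactobacillus iners",
                      "Lactobacillus jensenii", "Lactobacillus gasseri",
                      "Lactobacillus vaginalis"),
              c(0.90, 0.03, 0.015, 0.01, 0.005))
  p3 <- set_w(base, c("Lactobacillus iners", "Lactobacillus crispatus",
                      "Lactobacillus jensenii", "Lactobacillus gasseri",
                      "Lactobacillus vaginalis"),
              c(0.90, 0.02, 0.01, 0.01, 0.005))
  p4 <- base
  p4[c("Gardnerella vaginalis", "BVAB1", "Atopobium vaginae",
       "Megasphaera sp. type 1", "Lactobacillus iners", "BVAB2",
       "Sneathia sanguinegens", "Prevotella genogroup 3")] <-
    c(0.24, 0.15, 0.12, 0.10, 0.08, 0.05, 0.04, 0.04)
  p4[c("Parvimonas micra", "Gemella", "Dialister sp. type 2",
       "Dialister propionicifaciens", "Atopobium rimae", "Eggerthella",
       "Aerococcus christensenii", "Ureaplasma parvum")] <- 0.02
  m <- rbind(I = p1, III = p3, `IV-B` = p4)
  m / rowSums(m)
}

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defaults encode the design of a nested case-control vaginal-microbiota
#' study: 72 term and 18 preterm subjects sampled every 4 weeks until 24
#' weeks of gestation and every 2 weeks thereafter (with partial
#' attendance), 99 taxa with compositions drawn around three community state
#' type profiles mixed 18.6/58.5/22.9 percent, sequencing depth log-normal
#' around a median of 7,548 reads, zero-inflated negative-binomial counts
#' with subject random intercepts, no group effect (the null design), and
#' gestational-age slopes sending four *Lactobacillus* spp. up and eleven
#' anaerobes down.
#'
#' @param n_term,n_preterm Numbers of subjects per group.
#' @param n_taxa Total taxa (21 analysis phylotypes plus rare fillers).
#' @param cst_mixture Weights over CSTs I, III, IV-B (must sum to 1).
#' @param concentration Dirichlet concentration around the CST profile.
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters.
#' @param sigma_b Subject random-intercept SD (natural-log scale).
#' @param group_effects Named per-taxon log fold effects of preterm vs term
#'   (default all zero).
#' @param ga_slopes Named per-taxon log-linear gestational-age coefficients
#'   per week (default: +0.15 for four *Lactobacillus* spp., -0.15 for
#'   eleven anaerobes, 0 otherwise; compositional renormalization dilutes a
#'   common tilt of co-dominant taxa, so realized relative-abundance trends
#'   are weaker than the planted coefficients).
#' @param zero_inflation Named per-taxon zero-inflation probabilities.
#' @param dispersion Named per-taxon NB size parameters.
#' @param attendance Probability a protocol visit is attended.
#' @param min_visits Minimum retained visits per subject.
#' @param entry_range Uniform range of entry gestational age (weeks).
#' @param ga_ref Gestational age (weeks) at which slopes are centred.
#' @param seed Integer seed; identical config and seed give identical output.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_term = 72, n_preterm = 18, n_taxa = 99,
                          cst_mixture = c(I = 0.186, III = 0.585, `IV-B` = 0.229),
                          concentration = 60,
                          depth_meanlog = log(7548), depth_sdlog = 0.42,
                          sigma_b = 0.5,
                          group_effects = NULL, ga_slopes = NULL,
                          zero_inflation = NULL, dispersion = NULL,
                          attendance = 0.35, min_visits = 2,
                          entry_range = c(7, 16), ga_ref = 26,
                          seed = 1L) {
  taxa <- default_taxa(n_taxa)
  if (abs(sum(cst_mixture) - 1) > 1e-8) abort("cst_mixture must sum to 1")
  fill_named <- function(x, default_fn) {
    out <- default_fn(taxa)
    if (!is.null(x)) {
      bad <- setdiff(names(x), taxa)
      if (length(bad)) abort(paste0("unknown taxa: ", paste(bad, collapse = ", ")))
      out[names(x)] <- x
    }
    out
  }
  structure(list(
    n_term = n_term, n_preterm = n_preterm, n_taxa = n_taxa, taxa = taxa,
    cst_mixture = cst_mixture, concentration = concentration,
    profiles = default_cst_profiles(taxa),
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    sigma_b = sigma_b,
    group_effects = fill_named(group_effects, function(t) setNames(rep(0, length(t)), t)),
    ga_slopes = fill_named(ga_slopes, function(t) {
      s <- setNames(rep(0, length(t)), t)
      s[ga_up_taxa] <- 0.15
      s[ga_down_taxa] <- -0.15
      s
    }),
    zero_inflation = fill_named(zero_inflation, function(t) {
      z <- setNames(rep(0.2, length(t)), t)
      z[grepl("^Lactobacillus", t)] <- 0.05
      z[grepl("^phylotype_", t)] <- 0.7
      z
    }),
    dispersion = fill_named(dispersion, function(t) setNames(rep(2, length(t)), t)),
    attendance = attendance, min_visits = min_visits,
    entry_range = entry_range, ga_ref = ga_ref, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Protocol visit schedule
#'
#' Visits every 4 weeks from study entry until 24 weeks of gestation, then
#' every 2 weeks until delivery; the first visit at or past 24 weeks starts
#' the 2-week cadence. Visits at or after delivery are not scheduled.
#'
#' @param entry_ga Entry gestational age (weeks), `< delivery_ga`.
#' @param delivery_ga Delivery gestational age (weeks).
#' @return Numeric vector of visit gestational ages.
#' @export
#' @examples
#' schedule_visits(10, 41)  # 10 14 18 22 26 28 30 32 34 36 38 40
schedule_visits <- function(entry_ga, delivery_ga) {
  if (entry_ga >= delivery_ga) abort("entry must precede delivery")
  visits <- numeric(0)
  t <- entry_ga
  while (t < delivery_ga) {
    visits <- c(visits, t)
    t <- t + if (t < 24) 4 else 2
  }
  visits
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a longitudinal two-group cohort with known ground truth
#'
#' Generates a taxon-by-sample count table, per-sample metadata and a ground
#' truth record under the model the analysis pipeline assumes: per-subject
#' CST assignment (mixture draw, persistent across visits), protocol visit
#' schedule with partial attendance, log-normal sequencing depths, sample
#' compositions drawn from a Dirichlet around the CST profile and tilted by
#' group effects and gestational-age slopes, then counts drawn multinomially
#' at the sampled depth from weights carrying subject-by-taxon random
#' intercepts, per-taxon gamma (negative-binomial) noise and a structural
#' zero mask — so each taxon's counts are approximately zero-inflated
#' negative binomial with a log-read-total offset, the data-generating
#' structure the model ladder assumes.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `counts` (count tibble),
#'   `metadata` (metadata tibble) and `truth` (list of per-taxon effects,
#'   per-subject CSTs, and the config).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  taxa <- cfg$taxa
  subjects <- tibble(
    subject_id = c(sprintf("T%02d", seq_len(cfg$n_term)),
                   sprintf("P%02d", seq_len(cfg$n_preterm))),
    group = c(rep("term", cfg$n_term), rep("preterm", cfg$n_preterm)))
  subjects$delivery_ga <- ifelse(
    subjects$group == "term",
    pmin(pmax(rnorm(nrow(subjects), 39.6, 1.0), 38), 42),
    pmin(pmax(rnorm(nrow(subjects), 30.5, 2.5), 21), 33.9))
  subjects$entry_ga <- runif(nrow(subjects), cfg$entry_range[1], cfg$entry_range[2])
  subjects$cst <- sample(names(cfg$cst_mixture), nrow(subjects),
                         replace = TRUE, prob = cfg$cst_mixture)

  # visit schedules with partial attendance
  visit_list <- lapply(seq_len(nrow(subjects)), function(i) {
    sched <- schedule_visits(subjects$entry_ga[i], subjects$delivery_ga[i])
    keep <- which(runif(length(sched)) < cfg$attendance)
    need <- min(length(sched), cfg$min_visits)
    if (length(keep) < need) {
      keep <- sort(sample(seq_along(sched), need))
    }
    sched[keep]
  })

  n_samp <- sum(lengths(visit_list))
  samp <- tibble(
    sample_id = sprintf("S%04d", seq_len(n_samp)),
    subject_id = rep(subjects$subject_id, lengths(visit_list)),
    group = rep(subjects$group, lengths(visit_list)),
    cst = rep(subjects$cst, lengths(visit_list)),
    gestational_age = round(unlist(visit_list), 1))

  # subject-by-taxon random intercepts
  b <- matrix(rnorm(nrow(subjects) * length(taxa), 0, cfg$sigma_b),
              nrow(subjects), length(taxa),
              dimnames = list(subjects$subject_id, taxa))

  depth <- pmax(round(rlnorm(n_samp, cfg$depth_meanlog, cfg$depth_sdlog)), 500)
  is_preterm <- samp$group == "preterm"

  counts <- matrix(0L, n_samp, length(taxa), dimnames = list(samp$sample_id, taxa))
  for (i in seq_len(n_samp)) {
    comp <- rdirichlet1(cfg$concentration * cfg$profiles[samp$cst[i], ])
    tilt <- cfg$ga_slopes * (samp$gestational_age[i] - cfg$ga_ref) +
      if (is_preterm[i]) cfg$group_effects else 0
    comp <- comp * exp(tilt)
    comp <- comp / sum(comp)
    # per-taxon gamma multipliers give NB overdispersion; the zero-inflation
    # mask gives structural zeros; conditioning on the drawn depth keeps the
    # library-size model exact while per-taxon marginals stay ~ ZINB
    g <- rgamma(length(taxa), shape = cfg$dispersion, rate = cfg$dispersion)
    lam <- comp * exp(b[samp$subject_id[i], ]) * g
    lam[runif(length(taxa)) < cfg$zero_inflation] <- 0
    if (all(lam == 0)) lam[which.max(comp)] <- 1
    counts[i, ] <- as.integer(rmultinom(1L, size = depth[i], prob = lam))
  }

  count_tbl <- dplyr::bind_cols(tibble(sample_id = samp$sample_id),
                                as_tibble(counts))
  meta <- tibble(sample_id = samp$sample_id, subject_id = samp$subject_id,
                 group = samp$group, gestational_age = samp$gestational_age,
                 total_reads = as.integer(rowSums(counts)))

  truth <- list(
    subjects = subjects,
    taxa = tibble(taxon = taxa,
                  group_effect = unname(cfg$group_effects),
                  ga_slope = unname(cfg$ga_slopes),
                  zero_inflation = unname(cfg$zero_inflation),
                  dispersion = unname(cfg$dispersion),
                  direction = ifelse(cfg$ga_slopes > 0, "up",
                                     ifelse(cfg$ga_slopes < 0, "down", "flat"))),
    sigma_b = cfg$sigma_b, config = cfg)

  structure(list(counts = count_tbl, metadata = meta, truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the canonical wide count TSV, the metadata TSV and a
#' `truth.json` with the generating parameters and per-taxon effects.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_sample_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- cohort$truth
  truth$config$profiles <- NULL  # large matrix; regenerable from the config
  jsonlite::write_json(
    list(subjects = truth$subjects, taxa = truth$taxa,
         sigma_b = truth$sigma_b, config = unclass(truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic longitudinal cohort: %d samples, %d subjects, %d taxa\n",
              nrow(x$counts), nrow(x$truth$subjects),
              length(taxon_names(x$counts))))
  cat(sprintf("  median depth %d reads; groups: %s\n",
              as.integer(median(x$metadata$total_reads)),
              paste(names(table(x$metadata$group)),
                    table(x$metadata$group), collapse = ", ", sep = "=")))
  invisible(x)
}
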