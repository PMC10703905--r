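#' Simulation configuration for a synthetic multi-omics cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate the
#' marginal characteristics of a community cohort of 3,106 adults with
#' coronary artery calcification (CAC) and myocardial infarction (MI)
#' outcomes: 45.2% prevalent CAC, a median Agatston score of 67.8 among those
#' with CAC, 2.1% prevalent MI, and an incident-MI rate giving about 1.9%
#' events over a mean follow-up of 8.2 years.
#'
#' @param n_samples Number of individuals.
#' @param n_genes Number of gene regions; every gene carries features in all
#'   three omics.
#' @param features_per_gene Named integer vector: features per gene for
#'   `genotype`, `methylation`, `expression`.
#' @param n_families Number of family clusters. `NULL` (default) draws family
#'   sizes uniformly on 1..6 until the cohort is covered; an explicit count
#'   spreads samples over that many families as evenly as possible (use
#'   `n_families = n_samples` for an unclustered cohort).
#' @param maf_range Length-2 numeric, bounds of the per-variant minor allele
#'   frequency, each in (0, 0.5].
#' @param omics_coverage Named fractions of the cohort with data in each
#'   omics; individuals contribute only to analyses for which they have data.
#' @param planted_effects List of [planted_effect()] objects (may be empty).
#' @param outcome_params An [outcome_params()] object.
#' @param family_icc_genotype Within-family correlation of the latent Gaussian
#'   copula behind genotype dosages (shared parental-allele component).
#' @param family_outcome_sd SD of the family-level random intercept on each
#'   outcome's linear predictor; 0 removes outcome clustering.
#' @param tech_effect_sd SD of per-feature loadings on the technical
#'   (batch-like) covariate of each omics; technical covariates perturb
#'   methylation and expression values only and never enter the outcomes.
#' @param seed Integer seed; the full bundle is a deterministic function of
#'   the configuration including the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 3106L,
                       n_genes = 2000L,
                       features_per_gene = c(genotype = 3L, methylation = 3L,
                                             expression = 3L),
                       n_families = NULL,
                       maf_range = c(0.05, 0.5),
                       omics_coverage = c(genotype = 0.944,
                                          methylation = 0.623,
                                          expression = 0.879),
                       planted_effects = list(),
                       outcome_params = transomix::outcome_params(),
                       family_icc_genotype = 0.3,
                       family_outcome_sd = 0.5,
                       tech_effect_sd = 0.2,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              features_per_gene = features_per_gene,
              n_families = if (is.null(n_families)) NULL else
                as.integer(n_families),
              maf_range = as.numeric(maf_range),
              omics_coverage = omics_coverage,
              planted_effects = planted_effects,
              outcome_params = outcome_params,
              family_icc_genotype = as.numeric(family_icc_genotype),
              family_outcome_sd = as.numeric(family_outcome_sd),
              tech_effect_sd = as.numeric(tech_effect_sd),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

OMICS_TYPES <- c("genotype", "methylation", "expression")
OUTCOME_NAMES <- c("cac_present", "cac_score", "mi_prevalent", "mi_incident")

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg)
    stop(sprintf("invalid sim_config: field '%s' %s", field, msg),
         call. = FALSE)
  if (length(cfg$n_samples) != 1L || is.na(cfg$n_samples) ||
      cfg$n_samples <= 0L)
    stop_cfg("n_samples", "must be a positive count")
  if (length(cfg$n_genes) != 1L || is.na(cfg$n_genes) || cfg$n_genes <= 0L)
    stop_cfg("n_genes", "must be a positive count")
  fpg <- cfg$features_per_gene
  if (!all(OMICS_TYPES %in% names(fpg)) || any(fpg[OMICS_TYPES] < 1))
    stop_cfg("features_per_gene",
             "must name genotype, methylation and expression with counts >= 1")
  mr <- cfg$maf_range
  if (length(mr) != 2L || any(!is.finite(mr)) || mr[1] > mr[2] ||
      mr[1] <= 0 || mr[2] > 0.5)
    stop_cfg("maf_range", "bounds must be ordered and within (0, 0.5]")
  cov <- cfg$omics_coverage
  if (!all(OMICS_TYPES %in% names(cov)) || any(cov[OMICS_TYPES] <= 0) ||
      any(cov[OMICS_TYPES] > 1))
    stop_cfg("omics_coverage", "must give fractions in (0, 1] per omics")
  if (!is.null(cfg$n_families) &&
      (cfg$n_families < 1L || cfg$n_families > cfg$n_samples))
    stop_cfg("n_families", "must be between 1 and n_samples")
  if (cfg$family_icc_genotype < 0 || cfg$family_icc_genotype >= 1)
    stop_cfg("family_icc_genotype", "must lie in [0, 1)")
  if (cfg$family_outcome_sd < 0)
    stop_cfg("family_outcome_sd", "must be >= 0")
  for (pe in cfg$planted_effects) {
    if (!inherits(pe, "planted_effect"))
      stop_cfg("planted_effects", "must be a list of planted_effect objects")
    if (pe$gene > cfg$n_genes)
      stop_cfg("planted_effects",
               sprintf("references gene index %d > n_genes", pe$gene))
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_cfg("seed", "must be a single integer")
  invisible(cfg)
}

#' Outcome-model parameters
#'
#' Marginal calibration targets for the four simulated outcomes. Intercepts of
#' the binary outcomes are solved numerically so realized expectations hit the
#' configured prevalences; the continuous CAC score is log-normal around the
#' configured log-median among individuals with CAC.
#'
#' @param cac_prevalence Fraction of the cohort with CAC (presence).
#' @param cac_score_log_median Log of the median Agatston score among
#'   CAC-positive individuals (default `log(67.8)`).
#' @param cac_score_log_sd Residual SD of log CAC score.
#' @param mi_prevalent_fraction Fraction with MI at baseline.
#' @param mi_incidence_rate Marginal incident-MI hazard, events per
#'   person-year (default solves to about 1.9% events over 8.2 years).
#' @param followup_years_mean Mean follow-up in years.
#' @param admin_censor_years Administrative censoring horizon in years.
#' @return A validated list of class `outcome_params`.
#' @export
outcome_params <- function(cac_prevalence = 0.452,
                           cac_score_log_median = log(67.8),
                           cac_score_log_sd = 2.3,
                           mi_prevalent_fraction = 0.021,
                           mi_incidence_rate = 0.00234,
                           followup_years_mean = 8.2,
                           admin_censor_years = 9.5) {
  op <- list(cac_prevalence = cac_prevalence,
             cac_score_log_median = cac_score_log_median,
             cac_score_log_sd = cac_score_log_sd,
             mi_prevalent_fraction = mi_prevalent_fraction,
             mi_incidence_rate = mi_incidence_rate,
             followup_years_mean = followup_years_mean,
             admin_censor_years = admin_censor_years)
  fr <- c("cac_prevalence", "mi_prevalent_fraction")
  for (f in fr)
    if (op[[f]] <= 0 || op[[f]] >= 1)
      stop(sprintf("invalid outcome_params: field '%s' must lie in (0,1)", f),
           call. = FALSE)
  pos <- c("cac_score_log_sd", "mi_incidence_rate", "followup_years_mean",
           "admin_censor_years")
  for (f in pos)
    if (!is.finite(op[[f]]) || op[[f]] <= 0)
      stop(sprintf("invalid outcome_params: field '%s' must be > 0", f),
           call. = FALSE)
  if (op$followup_years_mean > op$admin_censor_years)
    stop("invalid outcome_params: field 'followup_years_mean' exceeds the administrative censoring horizon",
         call. = FALSE)
  class(op) <- "outcome_params"
  op
}

#' Planted gene effect
#'
#' Declares a gene whose omics features carry a real association with one or
#' more outcomes. For each listed omics the gene's first feature is causal:
#' its centered value, taken on the omics' generative scale (allele dosage,
#' logit beta value, log expression), enters the outcome linear predictor
#' with coefficient `omics_effects[o] * outcome_effects[y]` (log-odds per
#' unit for binary outcomes, slope on the log scale for the CAC score, log
#' hazard ratio for incident MI). A "concordant" effect lists all three
#' omics; a "discordant"
#' (single- or dual-omics) effect lists a strict subset.
#'
#' @param gene 1-based gene index (must be `<= n_genes` of the config).
#' @param omics_effects Named numeric, subset of
#'   `c("genotype","methylation","expression")`.
#' @param outcome_effects Named numeric, subset of
#'   `c("cac_present","cac_score","mi_prevalent","mi_incident")`.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(gene, omics_effects, outcome_effects) {
  if (length(omics_effects) == 0 ||
      !all(names(omics_effects) %in% OMICS_TYPES))
    stop("planted_effect: omics_effects must be named by a subset of ",
         paste(OMICS_TYPES, collapse = ", "), call. = FALSE)
  if (length(outcome_effects) == 0 ||
      !all(names(outcome_effects) %in% OUTCOME_NAMES))
    stop("planted_effect: outcome_effects must be named by a subset of ",
         paste(OUTCOME_NAMES, collapse = ", "), call. = FALSE)
  structure(list(gene = as.integer(gene),
                 omics_effects = omics_effects,
                 outcome_effects = outcome_effects),
            class = "planted_effect")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d samples, %d genes, seed %d\n",
              x$n_samples, x$n_genes, x$seed))
  cat(sprintf("  features/gene: %s\n",
              paste(sprintf("%s=%d", OMICS_TYPES,
                            x$features_per_gene[OMICS_TYPES]),
                    collapse = ", ")))
  cat(sprintf("  planted effects: %d\n", length(x$planted_effects)))
  invisible(x)
}
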