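#' Construct an omics dataset
#'
#' A sample-by-feature numeric matrix tagged with its omics type. Genotype
#' values are allele dosages in \[0, 2\]; methylation values are beta values in
#' (0, 1); expression values are positive intensities.
#'
#' @param omics_type One of `"genotype"`, `"methylation"`, `"expression"`.
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids,feature_ids Character vectors matching the matrix
#'   dimensions; duplicates are rejected.
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(omics_type, values, sample_ids, feature_ids) {
  omics_type <- match.arg(omics_type, OMICS_TYPES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("omics_dataset: values must be a numeric matrix", call. = FALSE)
  if (nrow(values) != length(sample_ids) ||
      ncol(values) != length(feature_ids))
    stop("omics_dataset: matrix dimensions do not match id lists",
         call. = FALSE)
  if (anyDuplicated(sample_ids) || anyDuplicated(feature_ids))
    stop("omics_dataset: duplicate sample or feature ids", call. = FALSE)
  if (omics_type == "genotype" &&
      (min(values) < 0 || max(values) > 2))
    stop("omics_dataset: genotype dosages must lie in [0, 2]", call. = FALSE)
  if (omics_type == "methylation" &&
      (min(values) <= 0 || max(values) >= 1))
    stop("omics_dataset: methylation beta values must lie in (0, 1)",
         call. = FALSE)
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(omics_type = omics_type,
                 sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids),
                 values = values),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset '%s': %d samples x %d features\n",
              x$omics_type, length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

gene_ids <- function(n_genes) sprintf("G%04d", seq_len(n_genes))

feature_ids_for <- function(genes, omics, k) {
  code <- c(genotype = "gt", methylation = "cg", expression = "tx")[[omics]]
  as.vector(vapply(genes, function(g) sprintf("%s_%s%d", g, code, seq_len(k)),
                   character(k)))
}

# family assignment; sizes uniform on 1..6 unless n_families forced
assign_families <- function(n_samples, n_families = NULL) {
  if (is.null(n_families)) {
    sizes <- integer(0)
    while (sum(sizes) < n_samples)
      sizes <- c(sizes, sample.int(6L, size = 64L, replace = TRUE))
    fam <- rep(seq_along(sizes), sizes)[seq_len(n_samples)]
  } else {
    fam <- sort(rep_len(seq_len(n_families), n_samples))
  }
  sprintf("F%05d", fam)
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws a family-clustered cohort with three omics layers. Genotype dosages
#' are binomial(2, MAF) counts coupled within families through a Gaussian
#' copula (a shared parental-allele component); methylation beta values are
#' logit-normal; expression is log-normal. One standard-normal technical
#' covariate per omics perturbs methylation and expression features with
#' per-feature loadings. Each omics layer covers a random subset of the
#' cohort according to `omics_coverage`. The result is fully determined by
#' the configuration, including its seed.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `omics` (named list of three
#'   [omics_dataset()]s), `covariates` (one row per sample: `sample_id`,
#'   `family_id`, `age`, `sex`, `weight`, `height`, and one `tech_*` column
#'   per omics), and `map` (feature-to-gene map: `feature_id`, `gene_id`,
#'   `omics_type`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%05d", seq_len(n))
  family_id <- assign_families(n, config$n_families)
  fam_idx <- as.integer(factor(family_id, levels = unique(family_id)))
  n_fam <- max(fam_idx)

  sex <- stats::rbinom(n, 1L, 0.489)  # 1 = female
  age <- round(stats::rnorm(n, 57, 10), 1)
  height <- round(ifelse(sex == 1L, stats::rnorm(n, 162, 6.5),
                         stats::rnorm(n, 176, 7)), 1)
  weight <- round(ifelse(sex == 1L, stats::rnorm(n, 70, 13),
                         stats::rnorm(n, 86, 14)), 1)
  covariates <- data.frame(sample_id = sample_ids, family_id = family_id,
                           age = age, sex = sex, weight = weight,
                           height = height,
                           tech_genotype = stats::rnorm(n),
                           tech_methylation = stats::rnorm(n),
                           tech_expression = stats::rnorm(n),
                           stringsAsFactors = FALSE)

  genes <- gene_ids(config$n_genes)
  fpg <- config$features_per_gene
  map <- do.call(rbind, lapply(OMICS_TYPES, function(om) {
    data.frame(feature_id = feature_ids_for(genes, om, fpg[[om]]),
               gene_id = rep(genes, each = fpg[[om]]),
               omics_type = om, stringsAsFactors = FALSE)
  }))

  # genotype: Gaussian copula -> exact binomial(2, maf) marginals with
  # within-family correlation family_icc_genotype on the latent scale
  p_gt <- config$n_genes * fpg[["genotype"]]
  maf <- stats::runif(p_gt, config$maf_range[1], config$maf_range[2])
  icc <- config$family_icc_genotype
  fam_z <- matrix(stats::rnorm(n_fam * p_gt), n_fam, p_gt)
  z <- sqrt(icc) * fam_z[fam_idx, , drop = FALSE] +
    sqrt(1 - icc) * matrix(stats::rnorm(n * p_gt), n, p_gt)
  gt <- matrix(stats::qbinom(stats::pnorm(z), 2L, rep(maf, each = n)),
               n, p_gt)
  gt <- gt + 0.0  # dosages as numeric

  # methylation: logit-normal with per-feature mean and technical loading
  p_me <- config$n_genes * fpg[["methylation"]]
  mu_me <- stats::rnorm(p_me, 0, 1.5)
  load_me <- stats::rnorm(p_me, 0, config$tech_effect_sd)
  me <- stats::plogis(matrix(mu_me, n, p_me, byrow = TRUE) +
                        outer(covariates$tech_methylation, load_me) +
                        matrix(stats::rnorm(n * p_me, 0, 0.5), n, p_me))

  # expression: log-normal with per-feature mean and technical loading
  p_ex <- config$n_genes * fpg[["expression"]]
  mu_ex <- stats::rnorm(p_ex, 3, 1)
  load_ex <- stats::rnorm(p_ex, 0, config$tech_effect_sd)
  ex <- exp(matrix(mu_ex, n, p_ex, byrow = TRUE) +
              outer(covariates$tech_expression, load_ex) +
              matrix(stats::rnorm(n * p_ex), n, p_ex))

  values <- list(genotype = gt, methylation = me, expression = ex)
  omics <- lapply(OMICS_TYPES, function(om) {
    keep <- stats::runif(n) <= config$omics_coverage[[om]]
    if (!any(keep)) keep[1] <- TRUE
    omics_dataset(om, values[[om]][keep, , drop = FALSE],
                  sample_ids[keep],
                  map$feature_id[map$omics_type == om])
  })
  names(omics) <- OMICS_TYPES

  list(omics = omics, covariates = covariates, map = map)
}

# centered causal-feature contribution of planted effects to one outcome's
# linear predictor; samples missing an omics contribute 0 from that omics
planted_lp <- function(outcome, cohort, planted_effects, sample_ids) {
  lp <- numeric(length(sample_ids))
  for (pe in planted_effects) {
    oe <- unname(pe$outcome_effects[outcome])
    if (length(oe) != 1L || is.na(oe)) next
    gene <- sprintf("G%04d", pe$gene)
    if (!gene %in% cohort$map$gene_id)
      stop(sprintf("planted gene %s is absent from the feature map", gene),
           call. = FALSE)
    for (om in names(pe$omics_effects)) {
      ds <- cohort$omics[[om]]
      feats <- cohort$map$feature_id[cohort$map$gene_id == gene &
                                       cohort$map$omics_type == om]
      if (length(feats) == 0)
        stop(sprintf("planted gene %s has no %s features in the map",
                     gene, om), call. = FALSE)
      x <- ds$values[, feats[1]]
      # causal features act on their generative scale so effect sizes are
      # comparable across omics (dosage / logit beta / log expression)
      x <- switch(om, genotype = x, methylation = stats::qlogis(x),
                  expression = log(x))
      xc <- numeric(length(sample_ids))
      xc[match(ds$sample_ids, sample_ids)] <- x - mean(x)
      lp <- lp + pe$omics_effects[[om]] * oe * xc
    }
  }
  lp
}

solve_intercept <- function(eta, target) {
  stats::uniroot(function(b) mean(stats::plogis(b + eta)) - target,
                 lower = -30, upper = 30, tol = 1e-10)$root
}

#' Generate the four study outcomes for a synthetic cohort
#'
#' Simulates, for every sample: CAC presence (logistic, intercept solved so
#' the expected prevalence hits `cac_prevalence`); the continuous CAC score
#' (log-normal around `cac_score_log_median`, defined only where CAC is
#' present); prevalent MI (logistic, intercept solved to
#' `mi_prevalent_fraction`); and incident MI (exponential event times under a
#' proportional-hazards model with marginal rate `mi_incidence_rate`,
#' administratively censored). Age and sex shift all four risks (older, male
#' higher), a family-level random intercept induces within-family outcome
#' correlation, and planted effects act through each planted gene's causal
#' features. Individuals with prevalent MI are excluded from the incident-MI
#' risk set (`mi_time`/`mi_event` are `NA`).
#'
#' @param omics Named list of the three [omics_dataset()]s.
#' @param covariates Covariate table from [generate_cohort()].
#' @param config The [sim_config()] used to generate the cohort.
#' @param map Feature-to-gene map from [generate_cohort()].
#' @return A data frame (one row per sample): `sample_id`, `cac_present`,
#'   `cac_score` (`NA` where `cac_present == 0`), `mi_prevalent`, `mi_time`,
#'   `mi_event` (`NA` for prevalent-MI samples).
#' @export
generate_outcomes <- function(omics, covariates, config, map) {
  validate_sim_config(config)
  op <- config$outcome_params
  cohort <- list(omics = omics, covariates = covariates, map = map)
  n <- nrow(covariates)
  set.seed((config$seed %% 1000000L) * 2003L + 7L)

  fam_idx <- as.integer(factor(covariates$family_id,
                               levels = unique(covariates$family_id)))
  n_fam <- max(fam_idx)
  male <- 1 - covariates$sex
  ctr <- function(x) x - mean(x)
  fam_re <- function(sd) if (sd > 0)
    stats::rnorm(n_fam, 0, sd)[fam_idx] else numeric(n)

  # CAC presence
  eta <- ctr(0.08 * covariates$age + 0.8 * male) +
    fam_re(config$family_outcome_sd) +
    planted_lp("cac_present", cohort, config$planted_effects,
               covariates$sample_id)
  b0 <- solve_intercept(eta, op$cac_prevalence)
  cac_present <- stats::rbinom(n, 1L, stats::plogis(b0 + eta))

  # continuous CAC score among CAC-positive samples; the linear predictor is
  # centered within the positives so the configured log-median is the median
  eta_s <- 0.04 * covariates$age + 0.5 * male +
    fam_re(0.8 * config$family_outcome_sd) +
    planted_lp("cac_score", cohort, config$planted_effects,
               covariates$sample_id)
  pos <- cac_present == 1L
  cac_score <- rep(NA_real_, n)
  if (any(pos))
    cac_score[pos] <- exp(op$cac_score_log_median +
                            ctr(eta_s[pos]) +
                            stats::rnorm(sum(pos), 0, op$cac_score_log_sd))

  # prevalent MI
  eta_p <- ctr(0.09 * covariates$age + 1.0 * male) +
    fam_re(config$family_outcome_sd) +
    planted_lp("mi_prevalent", cohort, config$planted_effects,
               covariates$sample_id)
  b0p <- solve_intercept(eta_p, op$mi_prevalent_fraction)
  mi_prevalent <- stats::rbinom(n, 1L, stats::plogis(b0p + eta_p))

  # incident MI: exponential times, baseline normalized so the configured
  # rate is marginal; prevalent cases leave the risk set
  eta_i <- ctr(0.06 * covariates$age + 0.4 * male) +
    fam_re(config$family_outcome_sd) +
    planted_lp("mi_incident", cohort, config$planted_effects,
               covariates$sample_id)
  risk <- mi_prevalent == 0L
  mi_time <- rep(NA_real_, n); mi_event <- rep(NA_integer_, n)
  haz <- op$mi_incidence_rate * exp(eta_i[risk]) / mean(exp(eta_i[risk]))
  t_event <- stats::rexp(sum(risk)) / haz
  cens_lo <- max(2 * op$followup_years_mean - op$admin_censor_years, 0.1)
  t_cens <- stats::runif(sum(risk), cens_lo, op$admin_censor_years)
  mi_time[risk] <- pmin(t_event, t_cens)
  mi_event[risk] <- as.integer(t_event <= t_cens)

  data.frame(sample_id = covariates$sample_id,
             cac_present = cac_present, cac_score = cac_score,
             mi_prevalent = mi_prevalent, mi_time = mi_time,
             mi_event = mi_event, stringsAsFactors = FALSE)
}

#' Generate cohort and outcomes in one call
#'
#' @param config A [sim_config()] object.
#' @return The [generate_cohort()] bundle with an added `outcomes` element.
#' @export
simulate_study <- function(config) {
  cohort <- generate_cohort(config)
  cohort$outcomes <- generate_outcomes(cohort$omics, cohort$covariates,
                                       config, cohort$map)
  cohort
}
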