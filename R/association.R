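#' @useDynLib transomix, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# adjustment design: intercept, age, sex, weight, height, plus the omics'
# technical covariate when present
build_design <- function(covariates, omics_type) {
  Z <- cbind(1, covariates$age, covariates$sex, covariates$weight,
             covariates$height)
  colnames(Z) <- c("(Intercept)", "age", "sex", "weight", "height")
  tech <- paste0("tech_", omics_type)
  if (tech %in% names(covariates)) {
    Z <- cbind(Z, covariates[[tech]])
    colnames(Z)[ncol(Z)] <- tech
  }
  Z
}

# align an omics dataset with covariates and an outcome vector named by
# sample id; returns row indices and matched pieces
align_samples <- function(omics, covariates, outcome) {
  if (is.null(names(outcome)))
    stop("outcome vector must be named by sample_id", call. = FALSE)
  common <- intersect(omics$sample_ids,
                      intersect(covariates$sample_id,
                                names(outcome)[!is.na(outcome)]))
  if (length(common) == 0)
    stop("no samples shared between omics data, covariates and outcome",
         call. = FALSE)
  list(X = omics$values[match(common, omics$sample_ids), , drop = FALSE],
       covariates = covariates[match(common, covariates$sample_id), ,
                               drop = FALSE],
       y = unname(outcome[common]),
       sample_ids = common)
}

new_association_table <- function(omics, outcome_name, estimate, std_error,
                                  p_value, n_used, flag, model, cluster_var) {
  out <- data.frame(feature_id = omics$feature_ids,
                    omics_type = omics$omics_type,
                    outcome = outcome_name,
                    estimate = estimate, std_error = std_error,
                    p_value = p_value, n_used = n_used, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "model") <- model
  attr(out, "covariates") <- c("age", "sex", "weight", "height",
                               paste0("tech_", omics$omics_type))
  attr(out, "cluster") <- cluster_var
  class(out) <- c("association_table", "data.frame")
  out
}

wald_p <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)

# two-sided Wald p against t with G-1 df (the usual cluster-robust
# small-sample reference); falls back to normal for G <= 1
wald_p_t <- function(z, G) {
  if (is.finite(G) && G > 1)
    pmax(2 * stats::pt(-abs(z), df = G - 1), .Machine$double.xmin)
  else wald_p(z)
}

#' Feature-wise association with a binary outcome
#'
#' Regresses a binary outcome on every feature of one omics layer by logistic
#' regression adjusted for age, sex, weight, height and the omics' technical
#' covariate, with a cluster-robust sandwich variance (clusters = families,
#' G/(G-1) small-sample factor) and a two-sided Wald p-value referred to a
#' t distribution with G-1 degrees of freedom. Stands in for a
#' generalized-estimating-equation fit with exchangeable families: the
#' estimand is identical and the sandwich variance is the GEE
#' independence-working-model variance.
#'
#' Features whose fit fails (non-convergence, separation, singular
#' information) are flagged `degenerate` and assigned `p_value = 1` so that
#' downstream gene-level collapsing never drops a gene silently.
#'
#' @param omics An [omics_dataset()].
#' @param outcome Named 0/1 vector (names = sample ids); `NA`s are dropped.
#' @param covariates Covariate table with `sample_id`, `family_id`, `age`,
#'   `sex`, `weight`, `height` and optional `tech_*` columns.
#' @param outcome_name Label written to the table's `outcome` column.
#' @return An `association_table` data frame: `feature_id`, `omics_type`,
#'   `outcome`, `estimate` (log-odds per unit), `std_error`, `p_value`,
#'   `n_used`, `flag`.
#' @export
test_binary <- function(omics, outcome, covariates,
                        outcome_name = "binary") {
  al <- align_samples(omics, covariates, outcome)
  y <- as.numeric(al$y)
  if (length(unique(y)) < 2L)
    stop("binary outcome has a single class in the analysis sample",
         call. = FALSE)
  Z <- build_design(al$covariates, omics$omics_type)
  cl <- as.integer(factor(al$covariates$family_id)) - 1L
  G <- max(cl) + 1L
  fit <- .logit_scan_cpp(Z, al$X, y, cl, G)
  ok <- fit$ok == 1L
  est <- ifelse(ok, fit$estimate, NA_real_)
  se <- ifelse(ok, fit$se_robust, NA_real_)
  p <- ifelse(ok, wald_p_t(fit$estimate / fit$se_robust, G), 1)
  flag <- ifelse(ok, "ok", "degenerate")
  if (any(!ok))
    warning(sprintf("%d degenerate logistic fits flagged (p set to 1)",
                    sum(!ok)), call. = FALSE)
  out <- new_association_table(omics, outcome_name, est, se, p,
                               length(y), flag,
                               "logistic + cluster-robust sandwich",
                               "family_id")
  attr(out, "se_naive") <- ifelse(ok, fit$se_naive, NA_real_)
  out
}

#' Feature-wise association with the continuous CAC score
#'
#' Ordinary least squares of (by default log-transformed) CAC score on each
#' feature plus adjustment covariates, restricted to CAC-positive samples,
#' with a CR1 cluster-robust sandwich variance grouped on `family_id` and a
#' t(G-1) Wald p-value. A
#' declared approximation to a linear mixed model: for exchangeable family
#' clusters the fixed-effect estimand coincides and the sandwich variance is
#' valid without estimating variance components. Computed for all features at
#' once via Frisch-Waugh residualization, which reproduces the full-model
#' coefficient, residuals and sandwich variance exactly.
#'
#' @inheritParams test_binary
#' @param outcome Named positive vector (CAC score where present, `NA`
#'   elsewhere).
#' @param log_transform Log-transform the outcome before fitting (default
#'   `TRUE`; the Agatston score is heavy-tailed).
#' @return An `association_table` data frame (see [test_binary()]).
#' @export
test_continuous <- function(omics, outcome, covariates,
                            outcome_name = "continuous",
                            log_transform = TRUE) {
  al <- align_samples(omics, covariates, outcome)
  y <- if (log_transform) log(al$y) else al$y
  Z <- build_design(al$covariates, omics$omics_type)
  if (length(y) < ncol(Z) + 3L)
    stop(sprintf("too few usable samples (%d) for %d covariates",
                 length(y), ncol(Z)), call. = FALSE)
  cl <- factor(al$covariates$family_id)
  G <- nlevels(cl)
  qz <- qr(Z)
  ey <- qr.resid(qz, y)
  Xt <- qr.resid(qz, al$X)
  sxx <- colSums(Xt^2)
  ok <- sxx > 1e-10 * nrow(Xt)
  beta <- ifelse(ok, colSums(Xt * ey) / sxx, NA_real_)
  E <- ey - Xt * rep(ifelse(ok, beta, 0), each = nrow(Xt))
  S <- rowsum(Xt * E, cl)                      # cluster score sums, G x p
  meat <- colSums(S^2)
  # CR1 small-sample factor (G/(G-1) * (n-1)/(n-k)), the standard convention
  # for cluster-robust OLS
  n_obs <- nrow(Xt); k_par <- ncol(Z) + 1L
  cadj <- if (G > 1) G / (G - 1) * (n_obs - 1) / (n_obs - k_par) else 1
  v_rob <- cadj * meat / sxx^2
  sig2 <- colSums(E^2) / (nrow(Xt) - ncol(Z) - 1L)
  se <- ifelse(ok & v_rob > 0, sqrt(v_rob), NA_real_)
  p <- ifelse(ok & v_rob > 0, wald_p_t(beta / se, G), 1)
  flag <- ifelse(ok & v_rob > 0, "ok", "degenerate")
  if (any(flag == "degenerate"))
    warning(sprintf("%d degenerate linear fits flagged (p set to 1)",
                    sum(flag == "degenerate")), call. = FALSE)
  out <- new_association_table(omics, outcome_name,
                               ifelse(flag == "ok", beta, NA_real_),
                               se, p, length(y), flag,
                               if (log_transform)
                                 "OLS on log outcome + cluster-robust sandwich"
                               else "OLS + cluster-robust sandwich",
                               "family_id")
  attr(out, "se_naive") <- ifelse(flag == "ok", sqrt(sig2 / sxx), NA_real_)
  out
}

#' Feature-wise association with incident MI
#'
#' Cox proportional-hazards regression of time to incident MI on each feature
#' plus adjustment covariates, with a robust (grouped-jackknife) variance
#' clustered on `family_id`, as fitted by [survival::coxph()]. Prevalent-MI
#' samples must already carry `NA` times (they are outside the risk set).
#' Monotone-likelihood features (all events at one extreme) are flagged
#' degenerate with `p_value = 1`.
#'
#' @inheritParams test_binary
#' @param mi_time,mi_event Named follow-up time and 0/1 event vectors;
#'   samples with `NA` time are excluded.
#' @return An `association_table` data frame (see [test_binary()]), estimates
#'   on the log hazard-ratio scale.
#' @export
test_survival <- function(omics, mi_time, mi_event, covariates,
                          outcome_name = "mi_incident") {
  al <- align_samples(omics, covariates, mi_time)
  ev <- as.integer(mi_event[al$sample_ids])
  if (sum(ev) == 0L)
    stop("no incident events in the analysis sample", call. = FALSE)
  tech <- paste0("tech_", omics$omics_type)
  dd <- data.frame(time = al$y, event = ev,
                   age = al$covariates$age, sex = al$covariates$sex,
                   weight = al$covariates$weight,
                   height = al$covariates$height,
                   fam = al$covariates$family_id, x = 0)
  has_tech <- tech %in% names(al$covariates)
  if (has_tech) dd$tech <- al$covariates[[tech]]
  form <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ x + age + sex + weight + height",
    if (has_tech) "+ tech" else "", "+ cluster(fam)"))
  p_feat <- ncol(al$X)
  est <- se <- rep(NA_real_, p_feat)
  pv <- rep(1, p_feat)
  flag <- rep("degenerate", p_feat)
  for (j in seq_len(p_feat)) {
    dd$x <- al$X[, j]
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(form, data = dd, ties = "breslow"),
        warning = function(w) {
          if (grepl("infinite|converge|singular", conditionMessage(w)))
            invokeRestart("muffleWarning")
          else invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) next
    b <- unname(stats::coef(fit)["x"])
    v <- fit$var[1, 1]
    if (!is.finite(b) || !is.finite(v) || v <= 0 || abs(b) > 15) next
    est[j] <- b; se[j] <- sqrt(v); pv[j] <- wald_p(b / sqrt(v))
    flag[j] <- "ok"
  }
  if (any(flag == "degenerate"))
    warning(sprintf("%d degenerate Cox fits flagged (p set to 1)",
                    sum(flag == "degenerate")), call. = FALSE)
  new_association_table(omics, outcome_name, est, se, pv, nrow(dd), flag,
                        "Cox PH + robust cluster variance", "family_id")
}

#' Run all omics-by-outcome association scans
#'
#' Applies the stage-1 tests to every combination of the three omics layers
#' and the four outcomes: logistic for CAC presence and prevalent MI, linear
#' (on the log scale) for the CAC score among CAC-positive samples, and Cox
#' for incident MI with prevalent-MI samples excluded from the risk set. Each
#' sample contributes only to the analyses of omics layers for which it has
#' data.
#'
#' @param omics Named list of three [omics_dataset()]s.
#' @param outcomes Outcome table from [generate_outcomes()].
#' @param covariates Covariate table.
#' @param outcome_names Subset of the four outcomes to run (default all).
#' @param log_cac Log-transform the continuous CAC score (default `TRUE`).
#' @return Named list of `association_table`s, keys `"<omics>.<outcome>"`.
#' @export
run_associations <- function(omics, outcomes, covariates,
                             outcome_names = OUTCOME_NAMES,
                             log_cac = TRUE) {
  outcome_names <- match.arg(outcome_names, OUTCOME_NAMES,
                             several.ok = TRUE)
  vec <- function(col) stats::setNames(outcomes[[col]], outcomes$sample_id)
  tables <- list()
  for (om in names(omics)) {
    ds <- omics[[om]]
    for (oc in outcome_names) {
      tab <- switch(oc,
        cac_present = test_binary(ds, vec("cac_present"), covariates,
                                  outcome_name = "cac_present"),
        mi_prevalent = test_binary(ds, vec("mi_prevalent"), covariates,
                                   outcome_name = "mi_prevalent"),
        cac_score = test_continuous(ds, vec("cac_score"), covariates,
                                    outcome_name = "cac_score",
                                    log_transform = log_cac),
        mi_incident = test_survival(ds, vec("mi_time"), vec("mi_event"),
                                    covariates,
                                    outcome_name = "mi_incident"))
      tables[[paste(om, oc, sep = ".")]] <- tab
    }
  }
  tables
}
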