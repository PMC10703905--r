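# Stage-1 tests. The logistic and linear engines are hand-rolled for speed,
# so both are cross-checked here against glm/lm + sandwich::vcovCL.

library(survival)

make_oracle_frame <- function(b, j, outcome_col, omics = "genotype") {
  ds <- b$omics[[omics]]
  idx <- match(ds$sample_ids, b$covariates$sample_id)
  data.frame(y = b$outcomes[[outcome_col]][idx],
             x = ds$values[, j],
             age = b$covariates$age[idx], sex = b$covariates$sex[idx],
             weight = b$covariates$weight[idx],
             height = b$covariates$height[idx],
             tech = b$covariates[[paste0("tech_", omics)]][idx],
             fam = b$covariates$family_id[idx])
}

test_that("logistic scan reproduces glm + cluster sandwich", {
  skip_if_not_installed("sandwich")
  b <- simulate_study(small_config(n = 400, genes = 10, seed = 21))
  tb <- test_binary(b$omics$genotype, outcome_vec(b$outcomes, "cac_present"),
                    b$covariates, "cac_present")
  G <- length(unique(b$covariates$family_id))
  for (j in c(1L, 12L, 30L)) {
    dd <- make_oracle_frame(b, j, "cac_present")
    f <- stats::glm(y ~ x + age + sex + weight + height + tech, dd,
                    family = stats::binomial())
    v <- sandwich::vcovCL(f, cluster = dd$fam, type = "HC0", cadjust = TRUE)
    expect_equal(tb$estimate[j], unname(stats::coef(f)["x"]),
                 tolerance = 1e-6)
    expect_equal(tb$std_error[j], sqrt(v["x", "x"]), tolerance = 1e-4)
    z <- stats::coef(f)["x"] / sqrt(v["x", "x"])
    expect_equal(tb$p_value[j], unname(2 * stats::pt(-abs(z), G - 1)),
                 tolerance = 1e-4)
  }
  expect_true(all(tb$p_value > 0 & tb$p_value <= 1))
  expect_true(all(tb$std_error[tb$flag == "ok"] > 0))
})

test_that("linear scan reproduces lm + CR1 cluster sandwich exactly", {
  skip_if_not_installed("sandwich")
  b <- simulate_study(small_config(n = 500, genes = 10, seed = 22))
  tc <- test_continuous(b$omics$expression,
                        outcome_vec(b$outcomes, "cac_score"),
                        b$covariates, "cac_score")
  pos <- !is.na(b$outcomes$cac_score)
  for (j in c(3L, 17L)) {
    dd <- make_oracle_frame(b, j, "cac_score", omics = "expression")
    dd <- dd[pos[match(b$omics$expression$sample_ids,
                       b$outcomes$sample_id)], ]
    f <- stats::lm(log(y) ~ x + age + sex + weight + height + tech, dd)
    n <- nrow(dd); k <- 7L
    v <- sandwich::vcovCL(f, cluster = dd$fam, type = "HC0",
                          cadjust = TRUE) * (n - 1) / (n - k)
    expect_equal(tc$estimate[j], unname(stats::coef(f)["x"]),
                 tolerance = 1e-10)
    expect_equal(tc$std_error[j], sqrt(v["x", "x"]), tolerance = 1e-10)
  }
})

test_that("degenerate features are flagged, not fatal", {
  b <- simulate_study(small_config(n = 200, genes = 4, seed = 23))
  ds <- b$omics$genotype
  # a feature identical to the outcome: perfect separation
  y <- outcome_vec(b$outcomes, "cac_present")
  ds$values[, 1] <- y[ds$sample_ids]
  expect_warning(tb <- test_binary(ds, y, b$covariates), "degenerate")
  expect_identical(tb$flag[1], "degenerate")
  expect_identical(tb$p_value[1], 1)
  expect_true(is.na(tb$std_error[1]))
  # a constant feature in the linear test
  ds2 <- b$omics$genotype
  ds2$values[, 2] <- 1
  expect_warning(
    tc <- test_continuous(ds2, outcome_vec(b$outcomes, "cac_score"),
                          b$covariates),
    "degenerate")
  expect_identical(tc$flag[2], "degenerate")
  expect_identical(tc$p_value[2], 1)
})

test_that("single-class, all-censored and too-small inputs raise errors", {
  b <- simulate_study(small_config(n = 120, genes = 3, seed = 24))
  y1 <- outcome_vec(b$outcomes, "cac_present"); y1[] <- 1
  expect_error(test_binary(b$omics$genotype, y1, b$covariates),
               "single class")
  ev <- outcome_vec(b$outcomes, "mi_event"); ev[] <- 0L
  expect_error(test_survival(b$omics$genotype,
                             outcome_vec(b$outcomes, "mi_time"), ev,
                             b$covariates),
               "no incident events")
  ysc <- outcome_vec(b$outcomes, "cac_score")
  ysc[-(1:6)] <- NA  # 6 usable samples < covariates + 3
  expect_error(test_continuous(b$omics$genotype, ysc, b$covariates),
               "too few")
})

test_that("Wald p-values are invariant to affine rescaling of a feature", {
  b <- simulate_study(small_config(n = 300, genes = 6, seed = 25))
  ds <- b$omics$genotype
  ds2 <- ds
  ds2$values <- 2.5 * ds$values + 1 / 3
  tc1 <- test_continuous(ds, outcome_vec(b$outcomes, "cac_score"),
                         b$covariates)
  tc2 <- test_continuous(ds2, outcome_vec(b$outcomes, "cac_score"),
                         b$covariates)
  expect_equal(tc1$p_value, tc2$p_value, tolerance = 1e-8)
  expect_equal(tc2$estimate, tc1$estimate / 2.5, tolerance = 1e-8)
  tb1 <- test_binary(ds, outcome_vec(b$outcomes, "cac_present"),
                     b$covariates)
  tb2 <- test_binary(ds2, outcome_vec(b$outcomes, "cac_present"),
                     b$covariates)
  # iterative fit: agreement to solver tolerance
  expect_equal(tb1$p_value, tb2$p_value, tolerance = 1e-6)
})

test_that("cluster-robust variance exceeds naive variance under clustering", {
  cfg <- flat_config(n = 500, genes = 300, seed = 26,
                     family_outcome_sd = 1.2, family_icc_genotype = 0.5)
  b <- simulate_study(cfg)
  tb <- test_binary(b$omics$genotype, outcome_vec(b$outcomes, "cac_present"),
                    b$covariates)
  ratio <- tb$std_error / attr(tb, "se_naive")
  expect_gt(mean(ratio, na.rm = TRUE), 1.02)
})

test_that("singleton families reduce the sandwich to heteroskedasticity-robust", {
  skip_if_not_installed("sandwich")
  cfg <- flat_config(n = 150, genes = 5, seed = 27,
                     n_families = 150, family_outcome_sd = 0)
  b <- simulate_study(cfg)
  tc <- test_continuous(b$omics$genotype, outcome_vec(b$outcomes, "cac_score"),
                        b$covariates)
  pos <- !is.na(b$outcomes$cac_score)
  for (j in c(1L, 4L)) {
    dd <- make_oracle_frame(b, j, "cac_score")[pos, ]
    f <- stats::lm(log(y) ~ x + age + sex + weight + height + tech, dd)
    v <- sandwich::vcovHC(f, type = "HC1")
    expect_equal(tc$std_error[j], sqrt(v["x", "x"]), tolerance = 1e-8)
  }
})

test_that("null p-values are uniform for every engine", {
  cfg <- flat_config(n = 500, genes = 1000, seed = 28,
                     outcome_params = outcome_params(
                       mi_incidence_rate = 0.0165))
  b <- simulate_study(cfg)
  tb <- test_binary(b$omics$genotype, outcome_vec(b$outcomes, "cac_present"),
                    b$covariates)
  tc <- test_continuous(b$omics$genotype,
                        outcome_vec(b$outcomes, "cac_score"), b$covariates)
  expect_lt(suppressWarnings(
    stats::ks.test(tb$p_value, "punif")$statistic), 0.05)
  expect_lt(suppressWarnings(
    stats::ks.test(tc$p_value, "punif")$statistic), 0.05)
})

test_that("Cox scan matches coxph and recovers a planted hazard ratio", {
  cfg <- flat_config(n = 800, genes = 5, seed = 29,
                     planted_effects = list(
                       planted_effect(1, c(genotype = 1),
                                      c(mi_incident = 0.7))),
                     outcome_params = outcome_params(
                       mi_incidence_rate = 0.02))
  b <- simulate_study(cfg)
  ts <- test_survival(b$omics$genotype, outcome_vec(b$outcomes, "mi_time"),
                      outcome_vec(b$outcomes, "mi_event"), b$covariates)
  # direct coxph oracle on the planted feature
  ds <- b$omics$genotype
  idx <- match(ds$sample_ids, b$outcomes$sample_id)
  dd <- data.frame(time = b$outcomes$mi_time[idx],
                   event = b$outcomes$mi_event[idx],
                   x = ds$values[, 1],
                   age = b$covariates$age[idx], sex = b$covariates$sex[idx],
                   weight = b$covariates$weight[idx],
                   height = b$covariates$height[idx],
                   tech = b$covariates$tech_genotype[idx],
                   fam = b$covariates$family_id[idx])
  dd <- dd[!is.na(dd$time), ]
  f <- coxph(Surv(time, event) ~ x + age + sex + weight + height + tech +
               cluster(fam), data = dd, ties = "breslow")
  expect_equal(ts$estimate[1], unname(coef(f)["x"]), tolerance = 1e-8)
  expect_equal(ts$std_error[1], sqrt(f$var[1, 1]), tolerance = 1e-8)
  expect_lt(ts$p_value[1], 0.05)
  expect_identical(ts$n_used[1], nrow(dd))
})

test_that("run_associations yields 12 aligned tables honoring missing omics", {
  cfg <- sim_config(n_samples = 250, n_genes = 10, seed = 30,
                    omics_coverage = c(genotype = 1, methylation = 0.8,
                                       expression = 1))
  b <- simulate_study(cfg)
  tabs <- suppressWarnings(
    run_associations(b$omics, b$outcomes, b$covariates))
  expect_length(tabs, 12L)
  expect_setequal(names(tabs),
                  as.vector(outer(c("genotype", "methylation", "expression"),
                                  c("cac_present", "cac_score",
                                    "mi_prevalent", "mi_incident"),
                                  paste, sep = ".")))
  expect_identical(nrow(tabs[["genotype.cac_present"]]), 30L)
  # methylation analyses use ~80% of the cohort
  n_me <- tabs[["methylation.cac_present"]]$n_used[1]
  expect_lt(abs(n_me / 250 - 0.8), 0.1)
  # prevalent-MI samples are excluded from the incident risk set
  expect_identical(tabs[["genotype.mi_incident"]]$n_used[1],
                   sum(b$outcomes$mi_prevalent == 0L))
  # determinism
  tabs2 <- suppressWarnings(
    run_associations(b$omics, b$outcomes, b$covariates))
  expect_identical(tabs, tabs2)
})
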