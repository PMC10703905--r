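test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(omics_coverage = c(genotype = 0, methylation = 1,
                                             expression = 1)),
               "omics_coverage")
  expect_error(sim_config(n_genes = 5,
                          planted_effects = list(
                            planted_effect(9, c(genotype = 1),
                                           c(cac_present = 1)))),
               "gene index")
  expect_error(outcome_params(cac_prevalence = 1.2), "cac_prevalence")
  expect_error(outcome_params(mi_incidence_rate = -1), "mi_incidence_rate")
  expect_error(planted_effect(1, c(proteome = 1), c(cac_present = 1)),
               "omics_effects")
  expect_error(planted_effect(1, c(genotype = 1), c(stroke = 1)),
               "outcome_effects")
})

test_that("generated matrices have the documented shapes and ranges", {
  cfg <- sim_config(n_samples = 10, n_genes = 5,
                    features_per_gene = c(genotype = 2L, methylation = 2L,
                                          expression = 2L),
                    omics_coverage = full_coverage, seed = 1)
  b <- generate_cohort(cfg)
  expect_identical(dim(b$omics$genotype$values), c(10L, 10L))
  expect_true(all(b$omics$genotype$values >= 0 &
                    b$omics$genotype$values <= 2))
  expect_true(all(b$omics$methylation$values > 0 &
                    b$omics$methylation$values < 1))
  expect_true(all(b$omics$expression$values > 0))
  expect_identical(nrow(b$covariates), 10L)
  # map partitions features into genes, every gene covered in every omics
  expect_identical(sort(unique(b$map$gene_id)), sprintf("G%04d", 1:5))
  expect_identical(unname(table(b$map$omics_type)["genotype"]), 10L)
  expect_false(anyDuplicated(b$map$feature_id) > 0)
})

test_that("same config and seed reproduce the bundle exactly", {
  cfg <- small_config(n = 50, genes = 8, seed = 33)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1$omics$genotype$values, b2$omics$genotype$values)
  expect_identical(b1$omics$expression$values, b2$omics$expression$values)
  expect_identical(b1$covariates, b2$covariates)
  expect_identical(b1$outcomes, b2$outcomes)
})

test_that("dosage means match the binomial expectation 2*maf", {
  # independent draws (no family copula) so the binomial standard error is
  # the right yardstick for the +/- 0.02 band
  cfg <- sim_config(n_samples = 20000, n_genes = 4,
                    features_per_gene = c(genotype = 2L, methylation = 1L,
                                          expression = 1L),
                    maf_range = c(0.3, 0.3), omics_coverage = full_coverage,
                    family_icc_genotype = 0, seed = 5)
  b <- generate_cohort(cfg)
  mns <- colMeans(b$omics$genotype$values)
  expect_true(all(mns > 0.58 & mns < 0.62))
})

test_that("family copula induces within-family dosage correlation", {
  cfg <- sim_config(n_samples = 4000, n_genes = 2,
                    features_per_gene = c(genotype = 1L, methylation = 1L,
                                          expression = 1L),
                    omics_coverage = full_coverage,
                    family_icc_genotype = 0.5, seed = 8)
  b <- generate_cohort(cfg)
  x <- b$omics$genotype$values[, 1]
  fam <- b$covariates$family_id
  # correlation between members of the same family, via family-mean ANOVA
  fit <- stats::anova(stats::lm(x ~ fam))
  expect_gt(fit$`F value`[1], 1.3)  # strongly > 1 under clustering
})

test_that("default outcome marginals hit the configured cohort targets", {
  cfg <- sim_config(seed = 12)  # full default: n=3106
  b <- simulate_study(cfg)
  oc <- b$outcomes
  expect_lt(abs(mean(oc$cac_present) - 0.452), 0.02)
  med <- stats::median(oc$cac_score, na.rm = TRUE)
  expect_lt(abs(med - 67.8) / 67.8, 0.15)
  expect_lt(abs(mean(oc$mi_prevalent) - 0.021), 0.01)
  # incident events near 1.9% of the risk set
  expect_lt(abs(mean(oc$mi_event, na.rm = TRUE) - 0.019), 0.01)
  # structural invariants
  expect_true(all(is.na(oc$cac_score) == (oc$cac_present == 0L)))
  expect_true(all(is.na(oc$mi_time) == (oc$mi_prevalent == 1L)))
  expect_true(all(oc$mi_time <= 9.5, na.rm = TRUE))
  expect_true(all(oc$cac_score > 0, na.rm = TRUE))
  # omics coverage fractions near Table-style defaults
  expect_lt(abs(length(b$omics$methylation$sample_ids) / 3106 - 0.623), 0.03)
})

test_that("planted effects error when the gene is missing from the map", {
  cfg <- small_config(n = 40, genes = 3, seed = 2)
  b <- generate_cohort(cfg)
  cfg2 <- small_config(n = 40, genes = 10, seed = 2,
                       planted_effects = list(
                         planted_effect(9, c(genotype = 1),
                                        c(cac_present = 1))))
  # map from the 3-gene cohort lacks gene 9
  expect_error(generate_outcomes(b$omics, b$covariates, cfg2, b$map),
               "absent from the feature map")
})

test_that("fixtures round-trip losslessly and are byte-stable", {
  cfg <- small_config(n = 25, genes = 4, seed = 7)
  b <- simulate_study(cfg)
  d1 <- withr::local_tempdir()
  write_fixture(b, d1)
  rt <- read_fixture(d1)
  expect_identical(rt$omics$genotype$values, b$omics$genotype$values)
  expect_equal(rt$omics$methylation$values, b$omics$methylation$values,
               tolerance = 0)
  expect_equal(rt$omics$expression$values, b$omics$expression$values,
               tolerance = 0)
  expect_identical(rt$map, b$map)
  expect_equal(rt$covariates, b$covariates, tolerance = 0)
  expect_equal(rt$outcomes, b$outcomes, tolerance = 0)
  # byte-identical re-write
  d2 <- withr::local_tempdir()
  write_fixture(b, d2)
  f <- list.files(d1)
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
  expect_error(write_fixture(b, ""), "directory")
})
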