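---
title: "Trans-omic rank aggregation: model, assumptions and design choices"
author: "transomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-omic rank aggregation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transomix)
```

## The problem

Single-omics association studies of coronary disease apply stringent
genome-wide thresholds, which protects against false positives at a steep
cost in sensitivity. When a gene shows directionally concordant evidence
across several omics layers — a variant, a CpG site and a transcript all
associated with the same outcome — that convergence is itself evidence, even
if no single layer reaches its own genome-wide threshold. `transomix`
implements a three-stage pipeline that formalizes this idea for four coronary
phenotypes: presence of coronary artery calcification (CAC), the continuous
CAC (Agatston) score among those with any calcification, prevalent
myocardial infarction (MI), and incident MI under follow-up.

Because the motivating cohort data are access-controlled, the package ships
a synthetic multi-omics cohort generator calibrated to the published
marginals of a community cohort of 3,106 adults. Every downstream claim the
package makes is therefore testable end to end without any data download;
real feature-level association tables can be substituted at the stage-2
entry point (`read_association_table()`).

## Stage 1 — per-feature association with cluster-robust inference

Each feature of each omics layer (genotype dosage, methylation beta value,
expression intensity) is regressed on each outcome, adjusted for age, sex,
weight, height and one technical covariate per omics:

* **CAC presence, prevalent MI** — logistic regression; two-sided Wald test
  against $t_{G-1}$, with a cluster-robust sandwich variance grouped on
  family (`G` = number of families, `G/(G-1)` small-sample factor).
* **CAC score** — ordinary least squares on $\log(\text{CAC})$, restricted
  to CAC-positive samples, CR1 cluster-robust variance
  ($\tfrac{G}{G-1}\tfrac{n-1}{n-k}$), $t_{G-1}$ reference.
* **Incident MI** — Cox proportional hazards via `survival::coxph()` with a
  robust grouped-jackknife variance clustered on family; prevalent-MI
  samples are excluded from the risk set.

The motivating analyses used generalized estimating equations, linear mixed
models and pedigree-clustered Cox models. For exchangeable family clusters
all three estimate the same population-averaged association, and the
independence-working-model fit with a cluster-robust sandwich is a standard,
convergence-friendly realization of that estimand at per-feature scale: no
working correlation or variance components need to be estimated for each of
tens of thousands of fits. This is a declared approximation, not a
reimplementation of the original mixed models.

Numerical choices worth knowing about:

* The logistic scan is a hand-written IRLS in C++ (a per-feature `glm()` is
  ~50× slower at simulation-study scale); its estimates, robust standard
  errors and p-values are verified in the test suite against
  `glm()` + `sandwich::vcovCL()`.
* The linear scan is computed for all features at once by Frisch–Waugh
  residualization, which reproduces full-model coefficients, residuals and
  sandwich variances exactly (also verified against `lm()` + `vcovCL()`).
* Degenerate fits — separation, non-convergence, constant features, monotone
  partial likelihood — are never dropped: the record is flagged
  `degenerate` with `p_value = 1`, so gene-level collapsing cannot silently
  lose a gene.
* The CAC score is log-transformed by default (`log_cac = FALSE` turns this
  off); the Agatston score is strongly right-skewed and no transform was
  stated in the motivating analysis, so this is a package decision.

## Stage 2 — gene-level min-p collapsing

Each gene is represented, per omics and outcome, by its most significant
feature (`collapse_to_genes()`). No multiplicity correction is applied for
the number of features per gene — deliberately mirroring the motivating
analysis — which biases gene rankings toward feature-rich genes. The
metadata records `per_gene_correction = "none"`; ties are broken by the
lexicographically smallest feature id so outputs are reproducible.

## Stage 3 — robust rank aggregation and the trans-omic score

For one outcome, the three gene-level lists are truncated to their best 5%
(`ceiling(0.05 * N_o)` genes, where $N_o$ is the full gene universe of omics
$o$; ties at the boundary break by gene id). A gene at 1-based rank $k$ in
the truncated list of omics $o$ receives the normalized rank $r_o = k/N_o$;
genes absent from a truncated list receive $r_o = 1$, the least informative
value. With the gene's rank vector sorted ascending,
$r_{(1)} \le \dots \le r_{(n)}$ ($n = 3$ lists), the order-statistic beta
score is

$$\beta_k \;=\; \sum_{l=k}^{n} \binom{n}{l}\, r_{(k)}^{\,l}\,
  (1-r_{(k)})^{\,n-l} \;=\; P\!\left(\mathrm{Bin}(n, r_{(k)}) \ge k\right),$$

the probability under the shuffled-list null (independent uniform ranks)
that the $k$-th smallest rank is at most the observed $r_{(k)}$. The
trans-omic score is

$$\rho \;=\; \min\big(\,n \cdot \min_k \beta_k,\; 1\,\big),$$

the Bonferroni-corrected minimum beta score — a conservative p-value for the
null that the gene is unranked in every list. Whether published trans-omic
scores are corrected or raw minimum-beta values cannot be determined from
the text they appear in, so `aggregate_ranks()` emits both (`rho` and
`rho_uncorrected`). Holding $N_o$ at the full universe size for absent genes
preserves null validity under truncation; the test suite verifies
$P(\rho \le \alpha) \le \alpha$ empirically at 2,000 genes, and checks the
closed form against a Monte-Carlo permutation oracle
(`permutation_oracle()`), which literally samples sorted uniform rank
vectors. A gene appearing in none of the truncated lists would score
$\rho = 1$ and is omitted from the output to keep report tables finite.

`top_n_genes()` and `cross_outcome_overlap()` reproduce the result surfaces
of the motivating study: per-outcome top-10 tables with the per-omics
gene-level p-values alongside the score, and the set of genes appearing in
the top-100 list of more than one outcome.

## The synthetic cohort generator

`sim_config()` defaults encode the published cohort marginals: $n = 3106$;
45.2% prevalent CAC; median CAC score 67.8 among CAC-positive participants
(log-normal with residual SD 2.3, solved from the published interquartile
range 10.8–274.9); 2.1% prevalent MI; an incident-MI rate of 0.00234 events
per person-year (≈1.9% events over the mean 8.2-year follow-up);
administrative censoring uniform on 6.9–9.5 years so mean follow-up is 8.2
years; and per-omics coverage 94.4% (genotype), 62.3% (methylation), 87.9%
(expression), with samples contributing only to analyses for which they have
data.

Structure and distributions:

* **Families.** Sizes uniform on 1–6 (an explicit `n_families` overrides
  this; `n_families = n_samples` gives an unclustered cohort). Relatedness
  enters twice: a Gaussian-copula family component on genotype dosages
  (latent ICC 0.3, preserving exact Binomial(2, MAF) marginals) and a
  family-level random intercept (SD 0.5) on every outcome's linear
  predictor. Real pedigrees are not modeled; any exchangeable cluster
  structure exercises the cluster-robust machinery.
* **Omics.** Genotype: Binomial(2, MAF) dosages, MAF uniform on the
  configured range. Methylation: logit-normal beta values. Expression:
  log-normal intensities. One standard-normal technical covariate per omics
  perturbs methylation and expression features through per-feature loadings
  (batch-like structure); technical covariates never enter outcomes, so
  adjusting for them is harmless and the global null stays exactly null.
  The identity of the original technical covariates is unspecified in the
  motivating study; this stand-in is a declared guess.
* **Outcomes.** Binary outcomes are logistic with intercepts solved by
  bisection so the expected prevalence equals the target; older age and male
  sex raise all four risks (centered contributions, so calibration targets
  are unaffected). The CAC score's linear predictor is centered within the
  CAC-positive stratum, where the published median is defined. The
  incident-MI baseline hazard is normalized by the mean relative hazard so
  the configured rate is marginal.
* **Planted effects.** `planted_effect()` makes the first feature of a gene
  causal in each listed omics: its centered value, on the omics' generative
  scale (dosage / logit beta / log expression), enters the outcome linear
  predictor with coefficient `omics_effect × outcome_effect`. The generative
  scale keeps effect sizes comparable across omics; for genotype it
  coincides with the raw dosage scale, so a planted log-odds of 0.5 is
  recovered by the stage-1 logistic regression directly — the basis of the
  effect-recovery tests. A "concordant" gene lists all three omics, a
  single-omics gene a strict subset.

What the generator does **not** emulate: linkage disequilibrium and
imputation error, probe chemistry, realistic Mendelian transmission within
pedigrees, CT-derived Agatston computation, and genome-scale feature counts.
Passing tests therefore demonstrate the statistical machinery is correct
under a faithful but idealized cohort, not that the pipeline's operating
characteristics transfer unchanged to real genome-scale data.

## Problem sizes used in tests and drivers

Desk-scale study sizes are package choices: 2,000 gene regions × 3 features
per omics for the integration study, cohorts of 500–3,106 samples, 200
replicates for effect-recovery summaries, 500 replicates for score null
validity, 50 replicates (600 samples each) for the end-to-end concordance
study, and a 10^6-draw Monte-Carlo oracle for the beta scores. The
concordance study plants effects on CAC presence and runs the pipeline for
that outcome; matched per-omics effect sizes of 0.45 (per dosage unit), 0.6
(per logit-beta unit) and 0.3 (per log-expression unit) correspond to
roughly a quarter standard deviation of each generative scale — moderate,
realistic signals with partial power, which is exactly the regime where
cross-omics aggregation should matter.

## Known limitations

* The sandwich stand-ins estimate population-averaged associations; subject-
  specific (conditional) effect sizes under strong family heterogeneity are
  attenuated relative to planted conditional coefficients (visible as a few
  percent attenuation in logistic/Cox recovery).
* Min-p collapsing without per-gene correction favors feature-rich genes;
  interpret gene rankings accordingly.
* The Bonferroni correction of the minimum beta is conservative,
  increasingly so under truncation.
* Overlap reporting matches exact gene ids only; co-located genes sharing a
  locus are counted separately.
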