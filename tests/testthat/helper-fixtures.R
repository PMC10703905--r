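# shared fixtures: small fully-observed cohorts and hand-built gene tables

full_coverage <- c(genotype = 1, methylation = 1, expression = 1)

small_config <- function(n = 300, genes = 20, seed = 1, ...) {
  sim_config(n_samples = n, n_genes = genes,
             omics_coverage = full_coverage, seed = seed, ...)
}

# a cohort with one feature per gene per omics (feature count = gene count)
flat_config <- function(n, genes, seed = 1, ...) {
  sim_config(n_samples = n, n_genes = genes,
             features_per_gene = c(genotype = 1L, methylation = 1L,
                                   expression = 1L),
             omics_coverage = full_coverage, seed = seed, ...)
}

outcome_vec <- function(outcomes, col) {
  stats::setNames(outcomes[[col]], outcomes$sample_id)
}

# gene-level table with given p-values, in spec'd column layout
make_gene_table <- function(p, genes = sprintf("G%04d", seq_along(p)),
                            omics = "genotype", outcome = "cac_present") {
  data.frame(gene_id = genes, omics_type = omics, outcome = outcome,
             best_feature = paste0(genes, "_f1"), min_p = p,
             stringsAsFactors = FALSE)
}

# association table with given p-values for collapse tests
make_assoc_table <- function(feature_id, p, omics = "genotype",
                             outcome = "cac_present") {
  structure(data.frame(feature_id = feature_id, omics_type = omics,
                       outcome = outcome, estimate = 0, std_error = 1,
                       p_value = p, n_used = 100L, flag = "ok",
                       stringsAsFactors = FALSE),
            class = c("association_table", "data.frame"))
}
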