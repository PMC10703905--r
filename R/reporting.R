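#' Top-N genes by trans-omic score
#'
#' @param scores A score table from [aggregate_ranks()] (sorted ascending by
#'   `rho`, ties by `gene_id`).
#' @param n Number of rows to keep; if `n` exceeds the gene count all genes
#'   are returned with a warning.
#' @return The first `n` rows.
#' @export
top_n_genes <- function(scores, n = 10L) {
  if (nrow(scores) == 0)
    stop("top_n_genes: empty score list", call. = FALSE)
  if (n < 1L) stop("top_n_genes: n must be >= 1", call. = FALSE)
  if (n > nrow(scores)) {
    warning(sprintf("requested top %d of %d genes; returning all", n,
                    nrow(scores)), call. = FALSE)
    n <- nrow(scores)
  }
  out <- scores[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-outcome overlap of top-N gene sets
#'
#' Compares the top-N (default 100) genes with the lowest trans-omic scores
#' across outcomes and reports every gene appearing in at least two of the
#' sets, annotated with the outcomes it hits.
#'
#' @param score_list Named list (>= 2) of score tables, one per outcome.
#' @param n Top-set size per outcome.
#' @return List with `top_sets` (named list of gene-id vectors) and `overlap`
#'   (data frame `gene_id`, `n_outcomes`, `outcomes`, sorted by decreasing
#'   `n_outcomes` then `gene_id`).
#' @export
cross_outcome_overlap <- function(score_list, n = 100L) {
  if (length(score_list) < 2L)
    stop("cross_outcome_overlap: need score lists for >= 2 outcomes",
         call. = FALSE)
  top_sets <- lapply(score_list, function(s)
    top_n_genes(s, min(n, nrow(s)))$gene_id)
  tab <- table(unlist(top_sets))
  genes <- sort(names(tab[tab >= 2L]))
  hits <- vapply(genes, function(g)
    paste(names(top_sets)[vapply(top_sets, function(s) g %in% s, TRUE)],
          collapse = ","), "")
  overlap <- data.frame(gene_id = genes,
                        n_outcomes = as.integer(tab[genes]),
                        outcomes = unname(hits), stringsAsFactors = FALSE)
  overlap <- overlap[order(-overlap$n_outcomes, overlap$gene_id), ,
                     drop = FALSE]
  rownames(overlap) <- NULL
  list(top_sets = top_sets, overlap = overlap)
}

pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation %||% list()
  if (!is.null(sim$outcome_params))
    sim$outcome_params <- do.call(outcome_params, sim$outcome_params)
  if (!is.null(sim$planted_effects))
    sim$planted_effects <- lapply(sim$planted_effects, function(pe)
      planted_effect(pe$gene, unlist(pe$omics_effects),
                     unlist(pe$outcome_effects)))
  if (!is.null(sim$features_per_gene))
    sim$features_per_gene <- unlist(sim$features_per_gene)
  if (!is.null(sim$omics_coverage))
    sim$omics_coverage <- unlist(sim$omics_coverage)
  list(simulation = do.call(sim_config, sim),
       pipeline = raw$pipeline %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full trans-omics pipeline
#'
#' Orchestrates the three analysis stages over a synthetic cohort: simulate
#' (cohort + outcomes), associate (every omics against every outcome with
#' cluster-robust inference), collapse to gene level (min-p), aggregate each
#' outcome's three omics lists into trans-omic scores, and report (top-N
#' tables per outcome plus the cross-outcome top-100 overlap). All artifacts
#' are written as TSV under `out_dir` together with a `manifest.yaml` echoing
#' the seed and parameters; rerunning with the same configuration reproduces
#' every file byte for byte.
#'
#' @param config A [sim_config()], or the path to a YAML file with a
#'   `simulation:` block (fields of [sim_config()]) and an optional
#'   `pipeline:` block (`top_fraction`, `n_top`, `n_overlap`, `log_cac`).
#' @param out_dir Output directory.
#' @param top_fraction Fraction of each omics list entering aggregation.
#' @param n_top Rows in each per-outcome report (default 10).
#' @param n_overlap Top-set size for the overlap report (default 100).
#' @param outcome_names Outcomes to analyze (default all four).
#' @param log_cac Log-transform the continuous CAC score.
#' @return Invisibly, a list with `associations`, `gene_tables`, `scores`,
#'   `reports`, `overlap` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, top_fraction = 0.05, n_top = 10L,
                         n_overlap = 100L, outcome_names = OUTCOME_NAMES,
                         log_cac = TRUE) {
  if (is.character(config)) {
    cfgs <- pipeline_config_from_yaml(config)
    pl <- cfgs$pipeline
    top_fraction <- pl$top_fraction %||% top_fraction
    n_top <- pl$n_top %||% n_top
    n_overlap <- pl$n_overlap %||% n_overlap
    log_cac <- pl$log_cac %||% log_cac
    config <- cfgs$simulation
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("associations", "genelevel", "scores", "reports"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  bundle <- stage("simulate", simulate_study(config))
  assoc <- stage("associate", suppressWarnings(
    run_associations(bundle$omics, bundle$outcomes, bundle$covariates,
                     outcome_names = outcome_names, log_cac = log_cac)))
  for (key in names(assoc))
    write_association_table(assoc[[key]],
                            file.path(out_dir, "associations",
                                      paste0(key, ".tsv")))

  gene_tables <- stage("collapse", lapply(assoc, collapse_to_genes,
                                          map = bundle$map))
  for (key in names(gene_tables))
    write_gene_table(gene_tables[[key]],
                     file.path(out_dir, "genelevel", paste0(key, ".tsv")))

  cfg_rra <- rra_config(n_lists = length(bundle$omics),
                        top_fraction = top_fraction)
  scores <- stage("aggregate", {
    out <- list()
    for (oc in outcome_names) {
      keys <- paste(names(bundle$omics), oc, sep = ".")
      out[[oc]] <- aggregate_ranks(stats::setNames(gene_tables[keys],
                                                   names(bundle$omics)),
                                   cfg_rra)
    }
    out
  })
  for (oc in names(scores))
    write_score_table(scores[[oc]],
                      file.path(out_dir, "scores", paste0(oc, ".tsv")))

  reports <- stage("report", lapply(scores, top_n_genes, n = n_top))
  for (oc in names(reports))
    write_score_table(reports[[oc]],
                      file.path(out_dir, "reports",
                                paste0("top", n_top, "_", oc, ".tsv")))
  overlap <- NULL
  if (length(scores) >= 2L) {
    overlap <- cross_outcome_overlap(scores, n = n_overlap)
    write_tsv_exact(overlap$overlap,
                    file.path(out_dir, "reports", "overlap.tsv"))
  }

  manifest <- list(
    package = "transomix",
    package_version = as.character(utils::packageVersion("transomix")),
    seed = config$seed,
    n_samples = config$n_samples,
    n_genes = config$n_genes,
    n_planted_effects = length(config$planted_effects),
    outcomes = outcome_names,
    top_fraction = top_fraction,
    n_top = as.integer(n_top),
    n_overlap = as.integer(n_overlap),
    log_cac = log_cac,
    per_gene_correction = "none")
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(bundle = bundle, associations = assoc,
                 gene_tables = gene_tables, scores = scores,
                 reports = reports, overlap = overlap, manifest = manifest))
}
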