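#' Robust-rank-aggregation configuration
#'
#' @param n_lists Number of ranked lists being aggregated (3 omics here).
#' @param top_fraction Fraction of each omics' gene universe retained before
#'   aggregation (the study integrates the top 5%).
#' @param correction `"bonferroni"` (default: the minimum beta score is
#'   multiplied by `n_lists` and capped at 1, making the trans-omic score a
#'   conservative p-value) or `"none"`.
#' @return A list of class `rra_config`.
#' @export
rra_config <- function(n_lists = 3L, top_fraction = 0.05,
                       correction = c("bonferroni", "none")) {
  if (n_lists < 1L) stop("rra_config: n_lists must be >= 1", call. = FALSE)
  if (top_fraction <= 0 || top_fraction > 1)
    stop("rra_config: top_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(n_lists = as.integer(n_lists),
                 top_fraction = top_fraction,
                 correction = match.arg(correction)),
            class = "rra_config")
}

#' Truncate a gene-level association list to its top fraction
#'
#' Sorts genes ascending by `min_p` (ties broken by `gene_id`) and keeps the
#' best `ceiling(fraction * n_universe)` genes, where the universe is the full
#' set of genes tested in that omics.
#'
#' @param gene_records A gene-level table from [collapse_to_genes()].
#' @param fraction Fraction in (0, 1].
#' @param n_universe Size of the gene universe (default: number of rows).
#' @return The retained rows, sorted; attribute `n_universe` records the
#'   universe size used for rank normalization.
#' @export
truncate_top_fraction <- function(gene_records, fraction,
                                  n_universe = nrow(gene_records)) {
  if (nrow(gene_records) == 0)
    stop("truncate_top_fraction: empty gene list", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("truncate_top_fraction: fraction must lie in (0, 1]", call. = FALSE)
  ord <- order(gene_records$min_p, gene_records$gene_id)
  keep <- min(ceiling(fraction * n_universe), nrow(gene_records))
  out <- gene_records[ord[seq_len(keep)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_universe") <- n_universe
  out
}

#' Normalized ranks across truncated omics lists
#'
#' For a gene at 1-based rank k in the truncated list of omics o with gene
#' universe of size N_o, the normalized rank is k / N_o. Genes absent from a
#' truncated list take the least informative value 1 for that list. The
#' output covers the union of genes appearing in at least one list.
#'
#' @param lists Named list of truncated gene-level tables (one per omics),
#'   each ordered as returned by [truncate_top_fraction()].
#' @param universe Named list of character vectors: the full set of genes
#'   tested per omics (defines N_o and legal membership).
#' @return Numeric matrix of normalized ranks, rownames = gene ids (sorted),
#'   one column per list; attribute `present` is the matching logical mask.
#' @export
normalized_ranks <- function(lists, universe) {
  stopifnot(length(lists) >= 1, !is.null(names(lists)),
            all(names(lists) %in% names(universe)))
  all_genes <- sort(unique(unlist(lapply(lists, function(l) l$gene_id))))
  if (length(all_genes) == 0)
    stop("normalized_ranks: all truncated lists are empty", call. = FALSE)
  r <- matrix(1, length(all_genes), length(lists),
              dimnames = list(all_genes, names(lists)))
  present <- matrix(FALSE, length(all_genes), length(lists),
                    dimnames = dimnames(r))
  for (o in names(lists)) {
    g <- lists[[o]]$gene_id
    bad <- setdiff(g, universe[[o]])
    if (length(bad) > 0)
      stop("normalized_ranks: genes outside the '", o, "' universe: ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    n_o <- length(universe[[o]])
    r[match(g, all_genes), o] <- seq_along(g) / n_o
    present[match(g, all_genes), o] <- TRUE
  }
  attr(r, "present") <- present
  r
}

#' Order-statistic beta scores of a normalized-rank vector
#'
#' With the rank vector r sorted ascending, the k-th beta score is the null
#' probability that the k-th smallest of n independent uniform ranks is at
#' most r_(k):
#' \deqn{\beta_k = \sum_{l=k}^{n} \binom{n}{l} r_{(k)}^{l} (1-r_{(k)})^{n-l}
#'   = P(\mathrm{Bin}(n, r_{(k)}) \ge k).}
#' A small beta score at some k means the gene sits higher in at least k of
#' the n lists than expected by chance (the shuffled-list null).
#'
#' @param r Numeric vector of normalized ranks, each in (0, 1].
#' @return Numeric vector of n beta scores (ordered by k, following the
#'   internally sorted r).
#' @export
beta_scores <- function(r) {
  if (length(r) == 0) stop("beta_scores: empty rank vector", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1))
    stop("beta_scores: rank components must lie in (0, 1]", call. = FALSE)
  rs <- sort(r)
  n <- length(rs)
  stats::pbinom(seq_len(n) - 1L, n, rs, lower.tail = FALSE)
}

# vectorized beta scores for a genes x lists rank matrix: row-sorts, then
# applies P(Bin(n, r_(k)) >= k) columnwise
beta_scores_matrix <- function(r) {
  n <- ncol(r)
  m <- nrow(r)
  rs <- matrix(r[order(row(r), r)], nrow = m, byrow = TRUE)
  b <- rs
  for (k in seq_len(n))
    b[, k] <- stats::pbinom(k - 1L, n, rs[, k], lower.tail = FALSE)
  dimnames(b) <- list(rownames(r), paste0("k", seq_len(n)))
  b
}

#' Trans-omic score from beta scores
#'
#' The trans-omic score is the minimum beta score over k; with the default
#' Bonferroni correction it is multiplied by the number of lists and capped
#' at 1, making it a conservative p-value for the null that the gene's ranks
#' are uniform in every list.
#'
#' @param beta Numeric vector of beta scores.
#' @param config An [rra_config()].
#' @return List with `rho` (the trans-omic score), `rho_uncorrected`
#'   (minimum beta) and `min_k` (index attaining the minimum).
#' @export
rho_score <- function(beta, config = rra_config(n_lists = length(beta))) {
  if (length(beta) == 0) stop("rho_score: empty beta vector", call. = FALSE)
  min_k <- which.min(beta)
  rho_raw <- beta[min_k]
  rho <- if (config$correction == "bonferroni")
    min(config$n_lists * rho_raw, 1) else rho_raw
  list(rho = unname(rho), rho_uncorrected = unname(rho_raw),
       min_k = unname(min_k))
}

#' Aggregate per-omics gene lists into trans-omic scores
#'
#' The stage-3 chain for one outcome: truncate each omics' gene-level list to
#' its top fraction, convert list positions to normalized ranks (absent genes
#' take rank 1), compute order-statistic beta scores per gene, and score each
#' gene by the (Bonferroni-corrected) minimum beta. The per-omics gene-level
#' minimum p-values are carried along for reporting.
#'
#' @param gene_tables Named list of gene-level tables (one per omics) from
#'   [collapse_to_genes()], all for the same outcome.
#' @param config An [rra_config()]; `n_lists` must equal
#'   `length(gene_tables)`.
#' @return Data frame sorted ascending by (`rho`, `gene_id`): `gene_id`,
#'   `rho`, `rho_uncorrected`, `min_k`, and one `p_<omics>` column per list
#'   (`NA` where the gene was not tested in that omics).
#' @export
aggregate_ranks <- function(gene_tables, config = rra_config()) {
  stopifnot(length(gene_tables) >= 1, !is.null(names(gene_tables)))
  if (config$n_lists != length(gene_tables))
    stop("aggregate_ranks: config$n_lists must match the number of lists",
         call. = FALSE)
  nonempty <- vapply(gene_tables, nrow, 0L) > 0
  if (!any(nonempty))
    stop("aggregate_ranks: all gene lists are empty", call. = FALSE)
  universe <- lapply(gene_tables, function(t) t$gene_id)
  trunc <- lapply(gene_tables, function(t) {
    if (nrow(t) == 0) t else truncate_top_fraction(t, config$top_fraction)
  })
  r <- normalized_ranks(trunc, universe)
  b <- beta_scores_matrix(r)
  min_k <- max.col(-b, ties.method = "first")
  rho_raw <- b[cbind(seq_len(nrow(b)), min_k)]
  rho <- if (config$correction == "bonferroni")
    pmin(config$n_lists * rho_raw, 1) else rho_raw
  out <- data.frame(gene_id = rownames(r), rho = rho,
                    rho_uncorrected = rho_raw, min_k = min_k,
                    stringsAsFactors = FALSE)
  for (o in names(gene_tables)) {
    gt <- gene_tables[[o]]
    out[[paste0("p_", o)]] <- gt$min_p[match(out$gene_id, gt$gene_id)]
  }
  out <- out[order(out$rho, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("transomic_scores", "data.frame")
  out
}

#' Monte-Carlo permutation oracle for the beta/rho scores
#'
#' Estimates each beta score as the fraction of sorted uniform rank vectors
#' whose k-th order statistic falls at or below the observed k-th smallest
#' rank — the "randomly shuffled ranked list" null made literal. Used as an
#' independent check of the closed-form [beta_scores()]; any multiplicity
#' correction is applied outside.
#'
#' @param r Numeric rank vector, components in (0, 1].
#' @param n_draws Number of Monte-Carlo draws (>= 1e4).
#' @param seed Integer seed.
#' @return List with `beta` (estimated beta scores) and `rho` (their
#'   minimum, the uncorrected score).
#' @export
permutation_oracle <- function(r, n_draws = 1e5, seed = 1L) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1))
    stop("permutation_oracle: rank components must lie in (0, 1]",
         call. = FALSE)
  if (n_draws < 1e4)
    stop("permutation_oracle: n_draws must be >= 1e4", call. = FALSE)
  n <- length(r)
  rs <- sort(r)
  set.seed(seed)
  u <- matrix(stats::runif(n_draws * n), n_draws, n)
  us <- matrix(u[order(row(u), u)], nrow = n_draws, byrow = TRUE)
  beta <- vapply(seq_len(n), function(k) mean(us[, k] <= rs[k]), 0)
  list(beta = beta, rho = min(beta))
}
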