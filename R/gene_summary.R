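#' Collapse feature-level associations to gene level (min-p)
#'
#' Represents every gene by its most significant feature within one omics
#' layer: the most significant variant, CpG site or transcript stands for the
#' gene's association with the outcome. Ties in p-value are broken by the
#' lexicographically smallest `feature_id` so outputs are reproducible; genes
#' whose features are all degenerate keep `min_p = 1`. No multiplicity
#' correction is applied for the number of features per gene — a documented
#' bias favouring feature-rich genes, recorded in the table's metadata.
#'
#' @param table An `association_table` for one omics-by-outcome pair.
#' @param map Feature-to-gene map (`feature_id`, `gene_id`, `omics_type`).
#' @return A data frame with one row per gene having at least one tested
#'   feature: `gene_id`, `omics_type`, `outcome`, `best_feature`, `min_p`,
#'   sorted by `gene_id`. Metadata attribute `per_gene_correction = "none"`.
#' @importFrom data.table data.table setorder
#' @export
collapse_to_genes <- function(table, map) {
  stopifnot(is.data.frame(table), is.data.frame(map))
  om <- unique(table$omics_type)
  oc <- unique(table$outcome)
  if (length(om) != 1L || length(oc) != 1L)
    stop("collapse_to_genes expects a table for a single omics x outcome pair",
         call. = FALSE)
  sub <- map[map$omics_type == om, c("feature_id", "gene_id")]
  idx <- match(table$feature_id, sub$feature_id)
  if (anyNA(idx))
    stop("unmapped feature ids for omics '", om, "': ",
         paste(utils::head(table$feature_id[is.na(idx)], 10),
               collapse = ", "), call. = FALSE)
  dt <- data.table::data.table(gene_id = sub$gene_id[idx],
                               feature_id = table$feature_id,
                               p_value = table$p_value)
  data.table::setorder(dt, gene_id, p_value, feature_id)
  res <- dt[, list(best_feature = feature_id[1L], min_p = p_value[1L]),
            by = "gene_id"]
  out <- data.frame(gene_id = res$gene_id, omics_type = om, outcome = oc,
                    best_feature = res$best_feature, min_p = res$min_p,
                    stringsAsFactors = FALSE)
  attr(out, "per_gene_correction") <- "none"
  class(out) <- c("gene_association", "data.frame")
  out
}
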