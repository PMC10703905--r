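# TSV writers/readers for every pipeline artifact. All numeric columns are
# written with full precision (17 significant digits) so fixtures round-trip
# losslessly and identical inputs give byte-identical files.

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(".")
    s <- sprintf("%.15g", v)  # prefer the short form when it round-trips
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, "")
}

write_tsv_exact <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  for (j in which(!num)) out[[j]] <- ifelse(is.na(df[[j]]), ".",
                                            as.character(df[[j]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

read_tsv_exact <- function(path, numeric_cols = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = c(".", ""),
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (is.null(numeric_cols)) return(df)
  for (j in intersect(numeric_cols, names(df)))
    df[[j]] <- as.numeric(df[[j]])
  df
}

write_matrix_tsv <- function(ds, path) {
  df <- data.frame(sample_id = ds$sample_ids, stringsAsFactors = FALSE)
  vals <- as.data.frame(ds$values, optional = TRUE)
  names(vals) <- ds$feature_ids
  write_tsv_exact(cbind(df, vals), path)
}

read_matrix_tsv <- function(path, omics_type) {
  df <- read_tsv_exact(path)
  sample_ids <- df$sample_id
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  omics_dataset(omics_type, m, sample_ids, colnames(m))
}

#' Write a simulated study bundle to a directory of TSV files
#'
#' Writes the three omics matrices (`genotype.tsv`, `methylation.tsv`,
#' `expression.tsv`; header `sample_id` then one column per feature, `.` for
#' missing), the feature-to-gene map (`feature_map.tsv`), the covariate table
#' (`covariates.tsv`) and, when present, the outcome table (`outcomes.tsv`,
#' `cac_score` empty where CAC is absent). Files round-trip losslessly
#' through [read_fixture()] and are byte-identical across runs for the same
#' bundle.
#'
#' @param bundle A bundle from [generate_cohort()] or [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  if (is.null(dir) || !nzchar(dir))
    stop("write_fixture: empty directory name", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir))
    stop("write_fixture: cannot create directory ", dir, call. = FALSE)
  for (om in names(bundle$omics))
    write_matrix_tsv(bundle$omics[[om]], file.path(dir, paste0(om, ".tsv")))
  write_tsv_exact(bundle$map, file.path(dir, "feature_map.tsv"))
  write_tsv_exact(bundle$covariates, file.path(dir, "covariates.tsv"))
  if (!is.null(bundle$outcomes))
    write_tsv_exact(bundle$outcomes, file.path(dir, "outcomes.tsv"))
  invisible(dir)
}

#' Read a study bundle written by [write_fixture()]
#'
#' @param dir Directory containing the fixture TSVs.
#' @return A bundle list (`omics`, `covariates`, `map`, and `outcomes` if
#'   present on disk).
#' @export
read_fixture <- function(dir) {
  if (!dir.exists(dir))
    stop("read_fixture: no such directory ", dir, call. = FALSE)
  omics <- lapply(stats::setNames(OMICS_TYPES, OMICS_TYPES), function(om)
    read_matrix_tsv(file.path(dir, paste0(om, ".tsv")), om))
  covariates <- read_tsv_exact(file.path(dir, "covariates.tsv"),
                               numeric_cols = c("age", "sex", "weight",
                                                "height", "tech_genotype",
                                                "tech_methylation",
                                                "tech_expression"))
  covariates$sex <- as.integer(covariates$sex)
  map <- read_tsv_exact(file.path(dir, "feature_map.tsv"))
  out <- list(omics = omics, covariates = covariates, map = map)
  ofile <- file.path(dir, "outcomes.tsv")
  if (file.exists(ofile)) {
    oc <- read_tsv_exact(ofile, numeric_cols = c("cac_present", "cac_score",
                                                 "mi_prevalent", "mi_time",
                                                 "mi_event"))
    oc$cac_present <- as.integer(oc$cac_present)
    oc$mi_prevalent <- as.integer(oc$mi_prevalent)
    oc$mi_event <- as.integer(oc$mi_event)
    out$outcomes <- oc
  }
  out
}

#' Write or read a feature-level association table
#'
#' The TSV (`feature_id`, `omics_type`, `outcome`, `estimate`, `std_error`,
#' `p_value`, `n_used`, `flag`) is also the entry point for real-data mode:
#' pre-computed association tables in this dialect can be fed directly into
#' [collapse_to_genes()].
#'
#' @param table An `association_table`.
#' @param path File path.
#' @return `path` (writer) or the table (reader).
#' @export
write_association_table <- function(table, path) {
  write_tsv_exact(table[, c("feature_id", "omics_type", "outcome",
                            "estimate", "std_error", "p_value", "n_used",
                            "flag")], path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  df <- read_tsv_exact(path, numeric_cols = c("estimate", "std_error",
                                              "p_value", "n_used"))
  df$n_used <- as.integer(df$n_used)
  class(df) <- c("association_table", "data.frame")
  df
}

write_gene_table <- function(table, path) {
  write_tsv_exact(table[, c("gene_id", "omics_type", "outcome",
                            "best_feature", "min_p")], path)
}

read_gene_table <- function(path) {
  df <- read_tsv_exact(path, numeric_cols = "min_p")
  class(df) <- c("gene_association", "data.frame")
  df
}

# score TSV mirrors the published table layout: gene, trans-omic score, then
# one p-value column per omics (blank where the gene was untested)
write_score_table <- function(scores, path) {
  cols <- c("gene_id", "rho", "rho_uncorrected",
            grep("^p_", names(scores), value = TRUE))
  out <- scores[, cols]
  for (j in grep("^p_", names(out)))
    out[[j]] <- ifelse(is.na(out[[j]]), "", fmt_num(out[[j]]))
  write_tsv_exact(out, path)
}

read_score_table <- function(path) {
  df <- read_tsv_exact(path)
  for (j in setdiff(names(df), "gene_id")) df[[j]] <- as.numeric(df[[j]])
  df
}
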