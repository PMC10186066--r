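#' Read a differential-expression result table
#'
#' Consumes the tabular export of a DESeq2-style differential-expression
#' analysis: one row per gene with a log2 fold change, a raw p-value and a
#' BH-adjusted p-value.  Column names are matched against a synonym map so
#' that common export dialects (with or without an explicit id column header)
#' work out of the box; extra columns are ignored.  Missing adjusted p-values
#' (independent filtering sets them to `NA`) are preserved as missing and are
#' never coerced to 0 or 1; downstream they count as non-significant.
#'
#' @param path Path to the TSV.
#' @param species Species name attached to every record.
#' @param col_map Named list mapping the roles `id`, `log2fc`, `pvalue`,
#'   `padj` to acceptable header names (first match wins).
#' @return `data.frame` with columns gene_id, species, log2fc, pvalue, padj.
#' @export
read_de_table <- function(path, species,
                          col_map = list(
                            id = c("gene_id", "gene", "id", "row", "rn", "V1"),
                            log2fc = c("log2FoldChange", "log2fc", "logFC"),
                            pvalue = c("pvalue", "p_value", "PValue"),
                            padj = c("padj", "p_adj", "FDR", "qvalue"))) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  pick <- function(role, required = TRUE) {
    hit <- intersect(col_map[[role]], names(dt))
    if (!length(hit)) {
      if (required) {
        stop("DE table ", path, " has no column for '", role,
             "' (accepted: ", paste(col_map[[role]], collapse = ", "),
             "); found headers: ", paste(names(dt), collapse = ", "))
      }
      return(NA_character_)
    }
    hit[[1L]]
  }
  idcol <- pick("id", required = FALSE)
  if (is.na(idcol)) idcol <- names(dt)[[1L]]  # DESeq2 writes ids unnamed
  out <- data.frame(
    gene_id = as.character(dt[[idcol]]),
    species = species,
    log2fc = as.numeric(dt[[pick("log2fc")]]),
    pvalue = as.numeric(dt[[pick("pvalue")]]),
    padj = as.numeric(dt[[pick("padj")]]),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$gene_id))) stop("DE table ", path, ": empty gene id")
  bad <- !is.na(out$padj) & (out$padj < 0 | out$padj > 1)
  if (any(bad)) stop("DE table ", path, ": padj outside [0,1]")
  out
}

#' Read all per-species DE tables of a run
#'
#' @param paths Named character vector: species -> path.
#' @param ... Passed to [read_de_table()].
#' @return One combined `data.frame` of DE records.
#' @export
read_de_tables <- function(paths, ...) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  do.call(rbind, lapply(names(paths), function(sp) {
    read_de_table(paths[[sp]], sp, ...)
  }))
}

#' Significant genes per species
#'
#' A gene is significant iff its adjusted p-value is present and
#' `padj <= alpha`.  Duplicated gene ids within a species keep their first
#' occurrence (a warning is emitted once).
#'
#' @param de_records DE record `data.frame` (see [read_de_table()]).
#' @param alpha Adjusted-p significance cutoff in (0, 1]; default 0.05.
#' @param min_abs_log2fc Optional additional threshold on `|log2fc|`
#'   (default 0 = no fold-change filter; significance is direction-blind).
#' @return Named list: species -> character vector of significant gene ids.
#' @export
significant_genes <- function(de_records, alpha = 0.05, min_abs_log2fc = 0) {
  stopifnot(alpha > 0, alpha <= 1)
  dup <- duplicated(de_records[, c("species", "gene_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicated DE record(s); first occurrence wins")
    de_records <- de_records[!dup, , drop = FALSE]
  }
  sig <- !is.na(de_records$padj) & de_records$padj <= alpha &
    (is.na(de_records$log2fc) | abs(de_records$log2fc) >= min_abs_log2fc)
  split(de_records$gene_id[sig], de_records$species[sig])
}
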