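#' Keep only the longest isoform per gene in a peptide FASTA
#'
#' Collapses isoform-level protein records to one record per gene: the
#' longest sequence wins; on equal lengths the lexicographically smallest
#' isoform id wins (deterministic across platforms).  The output header is
#' the bare gene id; an isoform-to-gene mapping table is written alongside.
#'
#' The gene id is derived from the record id by `gene_id_rule`, a regular
#' expression whose match is deleted (default: a trailing `.1` / `_T01` /
#' `-T2`-style isoform suffix).
#'
#' @param fasta_in Input peptide FASTA path.
#' @param fasta_out Output FASTA path.
#' @param mapping_out Optional path for the two-column isoform/gene TSV.
#' @param gene_id_rule Regex removed from the record id to obtain the gene id.
#' @return Invisibly, a `data.frame` with columns isoform_id, gene_id, kept.
#' @export
filter_longest_isoform <- function(fasta_in, fasta_out,
                                   mapping_out = NULL,
                                   gene_id_rule = "([._-]T?\\d+)$") {
  seqs <- Biostrings::readAAStringSet(fasta_in)
  ids <- sub("\\s.*$", "", names(seqs))  # FASTA id = header up to whitespace
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genes <- sub(gene_id_rule, "", ids)
  if (any(!nzchar(genes))) {
    stop("gene_id_rule deletes the whole id for: ",
         paste(ids[!nzchar(genes)], collapse = ", "))
  }
  ord <- order(genes, -Biostrings::width(seqs), ids, method = "radix")
  keep_idx <- ord[!duplicated(genes[ord])]
  keep_idx <- sort(keep_idx)  # preserve input record order
  # collision check: two distinct kept records must not share a gene header
  kept_genes <- genes[keep_idx]
  if (anyDuplicated(kept_genes)) {
    stop("header collision after isoform shortening: ",
         paste(unique(kept_genes[duplicated(kept_genes)]), collapse = ", "))
  }
  out <- seqs[keep_idx]
  names(out) <- kept_genes
  Biostrings::writeXStringSet(out, fasta_out, width = 80L)
  mapping <- data.frame(isoform_id = ids, gene_id = genes,
                        kept = seq_along(ids) %in% keep_idx,
                        stringsAsFactors = FALSE)
  if (!is.null(mapping_out)) {
    data.table::fwrite(mapping, mapping_out, sep = "\t")
  }
  invisible(mapping)
}
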