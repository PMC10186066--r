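#' Per-hypothesis orthogroup summary table
#'
#' Integrates, for every OG and restricted to the species named by the
#' hypothesis: per-species gene counts, the boolean expansion call,
#' per-species counts of significant differentially expressed genes (DEGs),
#' the total gene number, the presence/absence membership pattern and the
#' conserved flag (>= 1 gene from every hypothesis species).
#'
#' Significant genes that are not assigned to any OG are allowed (they are
#' counted nowhere); one message reports how many were seen.
#'
#' @param table An `og_table`.
#' @param calls Call table for this hypothesis (one element of [call_all()]).
#' @param deg_sets Named list species -> significant gene ids (see
#'   [significant_genes()]).
#' @param hyp The `hypothesis`.
#' @return `data.frame` with columns og_id, `count_<species>`, expanded,
#'   `deg_<species>`, total_genes, conserved, membership_pattern
#'   (comma-separated species with >= 1 gene).
#' @export
summarize_ogs <- function(table, calls, deg_sets, hyp) {
  stopifnot(inherits(table, "og_table"))
  sp <- hypothesis_species(hyp)
  counts <- og_counts(table, sp)
  if (!setequal(calls$og_id, rownames(counts))) {
    stop("calls and orthogroup table disagree on og ids")
  }
  expanded <- stats::setNames(calls$expanded, calls$og_id)[rownames(counts)]
  deg <- matrix(0L, nrow(counts), length(sp),
                dimnames = list(rownames(counts), sp))
  assigned <- 0L
  seen <- 0L
  for (s in sp) {
    sig <- unique(deg_sets[[s]])
    seen <- seen + length(sig)
    if (!length(sig)) next
    for (og in rownames(counts)) {
      hits <- sum(table$rows[[og]][[s]] %in% sig)
      deg[og, s] <- hits
      assigned <- assigned + hits
    }
  }
  if (seen > assigned) {
    message(seen - assigned,
            " significant gene(s) not assigned to any orthogroup")
  }
  present <- counts >= 1L
  pattern <- apply(present, 1L, function(p) paste(sp[p], collapse = ","))
  df <- data.frame(og_id = rownames(counts), stringsAsFactors = FALSE)
  for (s in sp) df[[paste0("count_", s)]] <- counts[, s]
  df$expanded <- unname(expanded)
  for (s in sp) df[[paste0("deg_", s)]] <- deg[, s]
  df$total_genes <- as.integer(rowSums(counts))
  df$conserved <- as.logical(rowSums(present) == length(sp))
  df$membership_pattern <- unname(pattern)
  rownames(df) <- NULL
  df
}

#' Presence/absence membership pattern counts
#'
#' Assigns every OG to exactly one presence pattern over `species_subset`
#' (the set of species with >= 1 gene) and counts OGs per pattern — the
#' numbers behind a Venn/UpSet intersection plot.  The full-set pattern count
#' is the number of conserved OGs.  Singleton genes are genes in OGs of total
#' size one plus any genes in `unassigned` (genes placed in no OG).
#'
#' @param table An `og_table`.
#' @param species_subset Non-empty character vector of species.
#' @param unassigned Optional character vector of genes outside all OGs.
#' @return List with `patterns` (named integer vector, names are
#'   comma-separated species sets, `"<none>"` for OGs empty in the subset),
#'   `conserved` (integer), `singleton_genes` (integer).
#' @export
membership_counts <- function(table, species_subset = NULL,
                              unassigned = character(0)) {
  stopifnot(inherits(table, "og_table"))
  if (is.null(species_subset)) species_subset <- table$species_order
  if (!length(species_subset)) stop("species_subset must be non-empty")
  counts <- og_counts(table, species_subset)
  present <- counts >= 1L
  pat <- apply(present, 1L, function(p) {
    if (!any(p)) "<none>" else paste(species_subset[p], collapse = ",")
  })
  patterns <- if (length(pat)) table(pat) else table(character(0))
  patterns <- stats::setNames(as.integer(patterns), names(patterns))
  full <- paste(species_subset, collapse = ",")
  singletons <- sum(rowSums(counts) == 1L) + length(unique(unassigned))
  list(patterns = patterns,
       conserved = if (full %in% names(patterns)) patterns[[full]] else 0L,
       singleton_genes = as.integer(singletons))
}

#' OG size distribution
#'
#' Histogram of total gene counts over a set of OGs, e.g. to compare all OGs
#' against the conserved subset side by side.
#'
#' @param total_genes Integer vector of per-OG total gene counts (e.g. the
#'   `total_genes` column of [summarize_ogs()], possibly filtered).
#' @return Named integer vector: size -> number of OGs, sizes ascending.
#' @export
size_distribution <- function(total_genes) {
  if (!length(total_genes)) return(stats::setNames(integer(0), character(0)))
  tab <- table(total_genes)
  stats::setNames(as.integer(tab), names(tab))
}
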