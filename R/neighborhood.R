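#' Read an all-vs-all protein hit table (BLAST/DIAMOND outfmt 6)
#'
#' The standard 12-column tabular dialect: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path Path to the TSV (no header).
#' @return `data.frame` with the 12 standard columns.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) != 12L) {
    stop("hit table must have 12 columns (outfmt 6), found ", ncol(dt))
  }
  data.table::setnames(dt, cols)
  df <- as.data.frame(dt)
  df$qseqid <- as.character(df$qseqid)
  df$sseqid <- as.character(df$sseqid)
  if (any(df$bitscore < 0)) stop("negative bitscore in hit table")
  if (any(df$evalue < 0)) stop("negative evalue in hit table")
  df
}

#' Best hit per query
#'
#' Self-hits (query equals subject) are removed first.  Per query the hit
#' with the maximum bitscore wins; ties are broken by minimum evalue, then by
#' lexicographically smallest subject id, making the choice deterministic and
#' independent of row order.
#'
#' @param hits Hit `data.frame` (see [read_hits()]).
#' @return `data.frame`, one row per query, same columns as `hits`.
#' @export
best_hits <- function(hits) {
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits across species
#'
#' RBH is defined across species pairs: for each ordered species pair the
#' best cross-species hit per query is computed, and an unordered gene pair
#' (a, b) is reported iff a's best hit in b's species is b and vice versa.
#' Within-species hits never form RBH pairs.
#'
#' @param hits Hit `data.frame` (a single concatenated all-vs-all table is
#'   fine; directions are inferred from `species_map`).
#' @param species_map Named character vector gene_id -> species covering
#'   every gene in `hits`.
#' @return `data.frame` with columns gene_a, gene_b (gene_a < gene_b),
#'   bitscore_ab, bitscore_ba, evalue_ab, evalue_ba; sorted by gene_a,
#'   gene_b.
#' @export
reciprocal_best_hits <- function(hits, species_map) {
  genes <- unique(c(hits$qseqid, hits$sseqid))
  missing <- setdiff(genes, names(species_map))
  if (length(missing)) {
    stop("gene(s) absent from species map: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "")
  }
  if (!nrow(hits)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      bitscore_ab = numeric(0), bitscore_ba = numeric(0),
                      evalue_ab = numeric(0), evalue_ba = numeric(0),
                      stringsAsFactors = FALSE))
  }
  qsp <- unname(species_map[hits$qseqid])
  ssp <- unname(species_map[hits$sseqid])
  cross <- hits[qsp != ssp, , drop = FALSE]
  if (!nrow(cross)) {
    return(reciprocal_best_hits(cross[0, ], species_map))
  }
  # best hit per (query, target species)
  tsp <- unname(species_map[cross$sseqid])
  ord <- order(cross$qseqid, tsp, -cross$bitscore, cross$evalue,
               cross$sseqid, method = "radix")
  cross <- cross[ord, , drop = FALSE]
  tsp <- tsp[ord]
  best <- cross[!duplicated(paste(cross$qseqid, tsp, sep = "\r")), ,
                drop = FALSE]
  key <- paste(best$qseqid, best$sseqid, sep = "\r")
  rkey <- paste(best$sseqid, best$qseqid, sep = "\r")
  recip <- key %in% rkey
  ab <- best[recip & best$qseqid < best$sseqid, , drop = FALSE]
  if (!nrow(ab)) return(reciprocal_best_hits(cross[0, ], species_map))
  back <- best[recip & best$qseqid > best$sseqid, , drop = FALSE]
  bidx <- match(paste(ab$sseqid, ab$qseqid, sep = "\r"),
                paste(back$qseqid, back$sseqid, sep = "\r"))
  out <- data.frame(gene_a = ab$qseqid, gene_b = ab$sseqid,
                    bitscore_ab = ab$bitscore,
                    bitscore_ba = back$bitscore[bidx],
                    evalue_ab = ab$evalue,
                    evalue_ba = back$evalue[bidx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most similar additional orthogroups of a focal OG
#'
#' Candidate OGs are scored by the number of RBH links connecting focal-OG
#' genes to their genes; the top `n` are returned, ranked by link count
#' (descending), then maximum linking bitscore (descending), then og id
#' (ascending).  Genes without an OG assignment act as one-gene pseudo-OGs
#' named `singleton:<gene>`, so strong singleton neighbors are reportable.
#'
#' @param focal_og Focal og id.
#' @param rbh_pairs RBH `data.frame` (see [reciprocal_best_hits()]).
#' @param membership Named character vector gene_id -> og_id (see
#'   [og_membership()]); genes absent from it become singleton pseudo-OGs.
#' @param n Maximum number of additional OGs (>= 0).
#' @param focal_genes Genes of the focal OG; defaults to the genes mapped to
#'   `focal_og` by `membership`.
#' @param hits Optional hit `data.frame`; when supplied, `extended_hits`
#'   contains every hit with query or subject in the focal OG or a selected
#'   additional OG.
#' @return List of class `og_neighborhood`: focal, neighbors (`data.frame`
#'   og_id, link_count, max_bitscore), extended_hits (or NULL).
#' @export
additional_ogs <- function(focal_og, rbh_pairs, membership, n = 5L,
                           focal_genes = NULL, hits = NULL) {
  stopifnot(n >= 0)
  og_of <- function(g) {
    og <- unname(membership[g])
    miss <- is.na(og)
    og[miss] <- paste0("singleton:", g[miss])
    og
  }
  if (is.null(focal_genes)) {
    focal_genes <- names(membership)[membership == focal_og]
  }
  neighbors <- data.frame(og_id = character(0), link_count = integer(0),
                          max_bitscore = numeric(0), stringsAsFactors = FALSE)
  if (nrow(rbh_pairs)) {
    a_in <- rbh_pairs$gene_a %in% focal_genes
    b_in <- rbh_pairs$gene_b %in% focal_genes
    # for links out of the focal OG take the non-focal end and the stronger
    # of the two directed bitscores
    sel <- xor(a_in, b_in)
    if (any(sel)) {
      other <- ifelse(a_in[sel], rbh_pairs$gene_b[sel], rbh_pairs$gene_a[sel])
      score <- pmax(rbh_pairs$bitscore_ab[sel], rbh_pairs$bitscore_ba[sel])
      og <- og_of(other)
      keep <- og != focal_og
      if (any(keep)) {
        og_k <- og[keep]
        sc_k <- score[keep]
        link_count <- tapply(sc_k, og_k, length)
        max_bs <- tapply(sc_k, og_k, max)
        neighbors <- data.frame(og_id = names(link_count),
                                link_count = as.integer(link_count),
                                max_bitscore = as.numeric(max_bs),
                                stringsAsFactors = FALSE)
      }
    }
  }
  ord <- order(-neighbors$link_count, -neighbors$max_bitscore,
               neighbors$og_id, method = "radix")
  neighbors <- neighbors[ord, , drop = FALSE]
  neighbors <- utils::head(neighbors, n)
  rownames(neighbors) <- NULL
  extended <- NULL
  if (!is.null(hits)) {
    sel_genes <- focal_genes
    for (og in neighbors$og_id) {
      sel_genes <- c(sel_genes,
                     if (startsWith(og, "singleton:"))
                       sub("^singleton:", "", og)
                     else names(membership)[membership == og])
    }
    keep <- hits$qseqid %in% sel_genes | hits$sseqid %in% sel_genes
    if (n == 0L) keep <- hits$qseqid %in% sel_genes &
        hits$sseqid %in% sel_genes
    extended <- hits[keep, , drop = FALSE]
    rownames(extended) <- NULL
  }
  structure(list(focal = focal_og, neighbors = neighbors,
                 extended_hits = extended),
            class = "og_neighborhood")
}

#' Neighborhoods for every expanded OG of a hypothesis
#'
#' @param expanded Character vector of expanded og ids.
#' @param rbh_pairs RBH pairs.
#' @param membership gene -> og map.
#' @param n Neighbors per OG.
#' @param hits Optional hit table for extended hits.
#' @return `data.frame` with columns focal, rank, neighbor, link_count,
#'   max_bitscore (zero rows when nothing is linked).
#' @export
neighborhood_table <- function(expanded, rbh_pairs, membership, n = 5L,
                               hits = NULL) {
  res <- lapply(expanded, function(og) {
    nb <- additional_ogs(og, rbh_pairs, membership, n = n, hits = NULL)$neighbors
    if (!nrow(nb)) return(NULL)
    data.frame(focal = og, rank = seq_len(nrow(nb)), neighbor = nb$og_id,
               link_count = nb$link_count, max_bitscore = nb$max_bitscore,
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(focal = character(0), rank = integer(0),
                      neighbor = character(0), link_count = integer(0),
                      max_bitscore = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
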