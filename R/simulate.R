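#' Configuration for the synthetic-data generator
#'
#' The generator emulates the post-upstream inputs of a small comparative
#' RNA-seq experiment: an Orthofinder-style orthogroup table over a few
#' plant species, per-species differential-expression tables, an all-vs-all
#' protein hit table with recoverable reciprocal-best-hit structure, a toy
#' GO ontology with per-gene annotations, and the species / hypotheses
#' tables that drive the analysis — together with truth tables recording
#' every planted signal.
#'
#' Defaults describe a three-species grass-like setup: 500 OGs, geometric
#' family sizes with mean 3 genes per species, 6% of OGs planted as
#' expansions in the first species at factor 3 with a one-gene margin,
#' background DEG rate 5% versus 50% inside expanded families, and one
#' planted biological-process GO term at study rate 0.6 versus background
#' rate 0.1.  Background OGs are actively kept non-expanded at the written
#' hypothesis cutoffs so that the truth table is exact.
#'
#' @param species Character vector of species names.
#' @param ploidy Integer ploidies (recycled).
#' @param n_ogs Number of orthogroups.
#' @param mean_family_size Mean per-species gene count of a present family
#'   (geometric).
#' @param absent_rate Probability that a species is absent from an OG.
#' @param expanded_fraction Fraction of OGs planted as expanded.
#' @param expanded_in Species planted to expand (subset of `species`).
#' @param expansion_factor True planted factor (>= calling factor + 1 for
#'   exact recovery).
#' @param expansion_margin Extra genes beyond the factor (>= 1).
#' @param call_factor,call_difference Cutoffs written to hypotheses.tsv.
#' @param deg_rate_background,deg_rate_in_expanded Per-gene probabilities of
#'   drawing the adjusted p-value from the signal component.
#' @param n_go_terms Number of (non-root) BP terms in the toy ontology.
#' @param planted_term_study_rate,planted_term_background_rate Annotation
#'   rates of the planted enriched term in expanded vs other OGs.
#' @param base_term_rate Annotation rate of every other term in any OG.
#' @param mu_in,mu_out,sigma_hits Bitscore model: within-OG hits ~
#'   Normal(mu_in, sigma), sibling-OG hits ~ Normal(mu_out, sigma),
#'   mu_in > mu_out.
#' @param seed Integer seed; all outputs are byte-reproducible from
#'   (config, seed).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(species = c("Hordeum_vulgare", "Zea_mays",
                                   "Oryza_sativa"),
                       ploidy = 2L,
                       n_ogs = 500L,
                       mean_family_size = 3,
                       absent_rate = 0.15,
                       expanded_fraction = 0.06,
                       expanded_in = species[[1L]],
                       expansion_factor = 3,
                       expansion_margin = 1L,
                       call_factor = 2,
                       call_difference = 1L,
                       deg_rate_background = 0.05,
                       deg_rate_in_expanded = 0.5,
                       n_go_terms = 50L,
                       planted_term_study_rate = 0.6,
                       planted_term_background_rate = 0.1,
                       base_term_rate = 0.08,
                       mu_in = 300, mu_out = 150, sigma_hits = 20,
                       seed = 1L) {
  stopifnot(length(species) >= 2L, n_ogs >= 1L, mean_family_size >= 1,
            absent_rate >= 0, absent_rate < 1,
            expanded_fraction >= 0, expanded_fraction <= 1,
            all(expanded_in %in% species),
            expansion_factor >= 1, expansion_margin >= 0,
            call_factor >= 1, call_difference >= 0,
            deg_rate_background >= 0, deg_rate_background <= 1,
            deg_rate_in_expanded >= 0, deg_rate_in_expanded <= 1,
            planted_term_study_rate >= 0, planted_term_study_rate <= 1,
            planted_term_background_rate >= 0,
            planted_term_background_rate <= 1,
            mu_in > mu_out)
  if (expansion_factor < call_factor) {
    stop("planted expansion_factor must be >= the calling factor")
  }
  structure(list(
    species = species,
    ploidy = rep_len(as.integer(ploidy), length(species)),
    n_ogs = as.integer(n_ogs),
    mean_family_size = mean_family_size,
    absent_rate = absent_rate,
    expanded_fraction = expanded_fraction,
    expanded_in = expanded_in,
    expansion_factor = expansion_factor,
    expansion_margin = as.integer(expansion_margin),
    call_factor = call_factor,
    call_difference = as.integer(call_difference),
    deg_rate_background = deg_rate_background,
    deg_rate_in_expanded = deg_rate_in_expanded,
    n_go_terms = as.integer(n_go_terms),
    planted_term_study_rate = planted_term_study_rate,
    planted_term_background_rate = planted_term_background_rate,
    base_term_rate = base_term_rate,
    mu_in = mu_in, mu_out = mu_out, sigma_hits = sigma_hits,
    seed = as.integer(seed)
  ), class = "sim_config")
}

sp_abbrev <- function(species) {
  ab <- vapply(strsplit(species, "_", fixed = TRUE), function(parts) {
    paste0(toupper(substr(parts[[1L]], 1L, 1L)),
           substr(parts[[length(parts)]], 1L, 2L))
  }, character(1))
  make.unique(ab, sep = "")
}

#' Generate a complete synthetic input set
#'
#' Writes every file the analysis consumes plus truth tables under
#' `out_dir/truth/`.  Running twice with the same config yields
#' byte-identical files.
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects: table (`og_table`),
#'   de (records), hits, go_map, graph path, truth (list), and all file
#'   paths.
#' @export
generate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  set.seed(config$seed)
  sp <- config$species
  ab <- sp_abbrev(sp)
  n <- config$n_ogs

  ## --- orthogroup counts with planted expansions -------------------------
  p_geom <- 1 / config$mean_family_size
  counts <- matrix(0L, n, length(sp), dimnames = list(NULL, sp))
  for (j in seq_along(sp)) {
    present <- stats::runif(n) >= config$absent_rate
    counts[, j] <- ifelse(present, 1L + stats::rgeom(n, p_geom), 0L)
  }
  n_exp <- round(config$expanded_fraction * n)
  planted <- if (n_exp > 0) sort(sample.int(n, n_exp)) else integer(0)
  compared <- setdiff(sp, config$expanded_in)
  for (i in planted) {
    base <- pmax(counts[i, compared], 1L)      # comparison species present
    counts[i, compared] <- base
    target <- ceiling(config$expansion_factor * max(base)) +
      config$expansion_margin
    counts[i, config$expanded_in] <- as.integer(target)
  }
  ## keep background OGs non-expanded at the calling cutoffs: if a focal
  ## species would qualify against every comparison species, pin its count
  ## to the smallest comparison count (breaks both factor and difference)
  bg <- setdiff(seq_len(n), planted)
  for (i in bg) {
    for (a in config$expanded_in) {
      if (all(pairwise_expanded(counts[i, a], counts[i, compared],
                                config$call_factor,
                                config$call_difference))) {
        counts[i, a] <- min(counts[i, compared])
      }
    }
  }

  ## --- gene ids and og_table ---------------------------------------------
  og_ids <- sprintf("N0.HOG%07d", seq_len(n) - 1L)
  next_idx <- stats::setNames(rep(1L, length(sp)), sp)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cells <- vector("list", length(sp))
    names(cells) <- sp
    for (j in seq_along(sp)) {
      cnt <- counts[i, j]
      if (cnt > 0L) {
        idx <- next_idx[[sp[j]]] + seq_len(cnt) - 1L
        next_idx[[sp[j]]] <- next_idx[[sp[j]]] + cnt
        cells[[sp[j]]] <- sprintf("%s_g%05d", ab[[j]], idx)
      } else {
        cells[[sp[j]]] <- character(0)
      }
    }
    rows[[i]] <- cells
  }
  names(rows) <- og_ids
  table <- structure(list(rows = rows, species_order = sp),
                     class = "og_table")
  og_path <- file.path(out_dir, "orthogroups.tsv")
  write_orthogroups(table, og_path)

  ## --- DE tables ----------------------------------------------------------
  expanded_ids <- og_ids[planted]
  de_paths <- character(0)
  truth_deg <- list()
  de_all <- list()
  for (j in seq_along(sp)) {
    genes <- unlist(lapply(rows, function(cells) cells[[sp[j]]]),
                    use.names = FALSE)
    gene_og <- rep(og_ids, vapply(rows, function(cells)
      length(cells[[sp[j]]]), integer(1)))
    in_exp <- gene_og %in% expanded_ids & sp[j] %in% config$expanded_in
    rate <- ifelse(in_exp, config$deg_rate_in_expanded,
                   config$deg_rate_background)
    signal <- stats::runif(length(genes)) < rate
    padj <- ifelse(signal, stats::rbeta(length(genes), 0.5, 20),
                   stats::runif(length(genes)))
    pvalue <- padj * stats::runif(length(genes))
    log2fc <- ifelse(signal, stats::rnorm(length(genes), 0, 3),
                     stats::rnorm(length(genes), 0, 0.5))
    # independent filtering occasionally leaves padj missing
    padj[!signal & stats::runif(length(genes)) < 0.02] <- NA_real_
    df <- data.frame(gene_id = genes, log2FoldChange = round(log2fc, 4),
                     pvalue = signif(pvalue, 6), padj = signif(padj, 6),
                     stringsAsFactors = FALSE)
    path <- file.path(out_dir, paste0("de_", sp[j], ".tsv"))
    data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
    de_paths[sp[j]] <- path
    truth_deg[[sp[j]]] <- data.frame(gene_id = genes, species = sp[j],
                                     signal = signal,
                                     stringsAsFactors = FALSE)
    de_all[[sp[j]]] <- data.frame(gene_id = genes, species = sp[j],
                                  log2fc = df$log2FoldChange,
                                  pvalue = df$pvalue, padj = df$padj,
                                  stringsAsFactors = FALSE)
  }

  ## --- hit table: within-OG + sibling-OG structure ------------------------
  hit_rows <- list()
  mk_hits <- function(g1, g2, mu) {
    # both directions, near-symmetric bitscores
    bs <- stats::rnorm(length(g1), mu, config$sigma_hits)
    bs <- pmax(bs, 30)
    bs2 <- pmax(bs + stats::rnorm(length(g1), 0, 2), 30)
    len <- 150L + stats::rpois(length(g1), 50)
    data.frame(
      qseqid = c(g1, g2), sseqid = c(g2, g1),
      pident = round(pmin(stats::rnorm(2 * length(g1), 60, 10), 100), 1),
      length = rep(len, 2L), mismatch = rep(30L, 2L * length(g1)),
      gapopen = rep(2L, 2L * length(g1)),
      qstart = 1L, qend = rep(len, 2L), sstart = 1L, send = rep(len, 2L),
      evalue = signif(10^(-c(bs, bs2) / 10), 4),
      bitscore = round(c(bs, bs2), 1), stringsAsFactors = FALSE)
  }
  ## each planted OG donates one "extra" duplicate that hits a partner OG
  ## lacking the focal species: both genes are each other's best hit in the
  ## respective species, so every expanded OG has a recoverable RBH neighbor
  focal_sp <- config$expanded_in[[1L]]
  partner_used <- logical(n)
  excluded <- character(0)
  candidates <- which(counts[, focal_sp] == 0L & rowSums(counts) > 0L)
  ci <- 1L
  for (i in planted) {
    x <- rev(rows[[i]][[focal_sp]])[[1L]]
    while (ci <= length(candidates) && partner_used[candidates[ci]]) {
      ci <- ci + 1L
    }
    if (ci > length(candidates)) break
    j <- candidates[[ci]]
    partner_used[[j]] <- TRUE
    sps <- names(which(vapply(rows[[j]], length, integer(1)) > 0L))
    y <- rows[[j]][[sps[[1L]]]][[1L]]
    excluded <- c(excluded, x)
    hit_rows[[length(hit_rows) + 1L]] <- mk_hits(x, y, config$mu_out)
  }
  for (i in seq_len(n)) {
    genes_by_sp <- rows[[i]]
    flat <- unlist(genes_by_sp, use.names = FALSE)
    spv <- rep(names(genes_by_sp), lengths(genes_by_sp))
    keep <- !flat %in% excluded
    flat <- flat[keep]
    spv <- spv[keep]
    if (length(flat) >= 2L) {
      pr <- utils::combn(seq_along(flat), 2L)
      cross <- spv[pr[1L, ]] != spv[pr[2L, ]]
      if (any(cross)) {
        hit_rows[[length(hit_rows) + 1L]] <-
          mk_hits(flat[pr[1L, cross]], flat[pr[2L, cross]], config$mu_in)
      }
    }
  }
  ## sibling-OG links with complementary species coverage: an OG with
  ## species A but not B is paired with an OG with B but not A, so the
  ## linking genes are each other's best cross-species hit (recoverable
  ## RBH structure between distinct OGs)
  for (a in seq_along(sp)) {
    for (b in seq_along(sp)) {
      if (a >= b) next
      has_a <- counts[, a] > 0L & counts[, b] == 0L & !partner_used
      has_b <- counts[, b] > 0L & counts[, a] == 0L & !partner_used
      ia <- which(has_a)
      ib <- which(has_b)
      m <- min(length(ia), length(ib))
      if (m == 0L) next
      g_a <- vapply(ia[seq_len(m)], function(i) rows[[i]][[sp[a]]][[1L]],
                    character(1))
      g_b <- vapply(ib[seq_len(m)], function(i) rows[[i]][[sp[b]]][[1L]],
                    character(1))
      hit_rows[[length(hit_rows) + 1L]] <- mk_hits(g_a, g_b, config$mu_out)
    }
  }
  hits <- do.call(rbind, hit_rows)
  hits_path <- file.path(out_dir, "hits.tsv")
  data.table::fwrite(hits, hits_path, sep = "\t", col.names = FALSE,
                     quote = FALSE)

  ## --- toy ontology + annotations -----------------------------------------
  root <- "GO:0008150"
  term_ids <- sprintf("GO:%07d", 1e6 + seq_len(config$n_go_terms))
  obo_path <- file.path(out_dir, "ontology.obo")
  obo <- c("format-version: 1.2", "",
           "[Term]", paste0("id: ", root), "name: biological_process",
           "namespace: biological_process", "")
  parents <- character(config$n_go_terms)
  for (t in seq_len(config$n_go_terms)) {
    parent <- if (t <= 5L) root else
      term_ids[[sample.int(t - 1L, 1L)]]
    parents[[t]] <- parent
    obo <- c(obo, "[Term]", paste0("id: ", term_ids[[t]]),
             paste0("name: synthetic process ", t),
             "namespace: biological_process",
             paste0("is_a: ", parent, " ! parent"), "")
  }
  writeLines(obo, obo_path)
  planted_term <- term_ids[[config$n_go_terms]]  # a leaf-ish late term
  anno <- list()
  add_anno <- function(anno, og_i, term) {
    flat <- unlist(rows[[og_i]], use.names = FALSE)
    if (!length(flat)) return(anno)
    g <- flat[[sample.int(length(flat), 1L)]]
    anno[[g]] <- unique(c(anno[[g]], term))
    anno
  }
  is_study <- seq_len(n) %in% planted
  for (i in seq_len(n)) {
    r <- if (is_study[[i]]) config$planted_term_study_rate
         else config$planted_term_background_rate
    if (stats::runif(1) < r) anno <- add_anno(anno, i, planted_term)
    for (t in utils::head(term_ids, -1L)) {
      if (stats::runif(1) < config$base_term_rate) {
        anno <- add_anno(anno, i, t)
      }
    }
  }
  go_path <- file.path(out_dir, "go_map.tsv")
  anno_genes <- sort(names(anno))
  writeLines(vapply(anno_genes, function(g)
    paste(g, paste(sort(anno[[g]]), collapse = ", "), sep = "\t"),
    character(1)), go_path)

  ## --- species, hypotheses, tree, peptides --------------------------------
  species_path <- file.path(out_dir, "species.tsv")
  data.table::fwrite(
    data.frame(species = sp, ploidy = config$ploidy,
               go_annotation = basename(go_path)),
    species_path, sep = "\t", quote = FALSE)
  hyp_path <- file.path(out_dir, "hypotheses.tsv")
  data.table::fwrite(
    data.frame(hypothesis = 1L, name = "planted_expansion",
               expanded_in = paste(config$expanded_in, collapse = ";"),
               compared_to = paste(compared, collapse = ";"),
               Nmin_expanded_in = length(config$expanded_in),
               min_expansion_factor = config$call_factor,
               min_expansion_difference = config$call_difference),
    hyp_path, sep = "\t", quote = FALSE)
  tree_path <- file.path(out_dir, "tree.nwk")
  writeLines(paste0("(", paste(sp, collapse = ","), ");"), tree_path)
  fasta_path <- file.path(out_dir, "proteins.fa")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  fa <- character(0)
  for (g in utils::head(unlist(rows[[1L]], use.names = FALSE), 3L)) {
    for (iso in 1:2) {
      seqlen <- 20L + 10L * iso
      fa <- c(fa, paste0(">", g, ".", iso),
              paste(sample(aa, seqlen, replace = TRUE), collapse = ""))
    }
  }
  writeLines(fa, fasta_path)

  ## --- truth tables --------------------------------------------------------
  truth_exp_path <- file.path(out_dir, "truth", "expansions.tsv")
  data.table::fwrite(data.frame(og_id = og_ids,
                                expanded_true = is_study),
                     truth_exp_path, sep = "\t", quote = FALSE)
  truth_deg_path <- file.path(out_dir, "truth", "degs.tsv")
  data.table::fwrite(do.call(rbind, truth_deg), truth_deg_path, sep = "\t",
                     quote = FALSE)
  truth_term_path <- file.path(out_dir, "truth", "terms.tsv")
  data.table::fwrite(
    data.frame(term_id = planted_term,
               study_rate = config$planted_term_study_rate,
               background_rate = config$planted_term_background_rate),
    truth_term_path, sep = "\t", quote = FALSE)

  invisible(list(
    table = table, de = do.call(rbind, de_all), hits = hits,
    planted_term = planted_term, expanded_true = og_ids[planted],
    paths = list(orthogroups = og_path, de = de_paths, hits = hits_path,
                 go_map = go_path, obo = obo_path, species = species_path,
                 hypotheses = hyp_path, tree = tree_path,
                 fasta = fasta_path,
                 truth_expansions = truth_exp_path,
                 truth_degs = truth_deg_path,
                 truth_terms = truth_term_path)
  ))
}

#' Precision and recall of expansion calls against planted truth
#'
#' @param called Character vector of og ids called expanded.
#' @param truth Character vector of og ids planted as expanded.
#' @param universe Optional full og id vector (for the confusion counts).
#' @return List with tp, fp, fn, precision, recall (NA when undefined).
#' @export
truth_compare <- function(called, truth, universe = NULL) {
  called <- unique(called)
  truth <- unique(truth)
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  fn <- length(setdiff(truth, called))
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
}
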