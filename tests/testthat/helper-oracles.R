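# Independent brute-force oracles used by the property and acceptance
# tests.  These deliberately re-derive each result with naive loops so they
# share no code path with the package implementation.

oracle_pairwise <- function(a, b, factor, difference) {
  a >= 1 && a >= factor * b && (a - b) >= difference
}

# scalar re-implementation of the whole expansion decision
oracle_call <- function(counts, hyp) {
  qual <- logical(length(hyp$expanded_in))
  names(qual) <- hyp$expanded_in
  for (a in hyp$expanded_in) {
    per <- logical(length(hyp$compared_to))
    for (j in seq_along(hyp$compared_to)) {
      b <- hyp$compared_to[[j]]
      per[[j]] <- oracle_pairwise(counts[[a]], counts[[b]],
                                  hyp$min_expansion_factor,
                                  hyp$min_expansion_difference)
    }
    qual[[a]] <- if (hyp$comparison == "all") all(per) else any(per)
  }
  list(qualifying = qual, expanded = sum(qual) >= hyp$nmin_expanded_in)
}

# build an og_table directly from a counts matrix
og_table_from_counts <- function(counts, species = colnames(counts),
                                 prefix = "g") {
  n <- nrow(counts)
  ids <- sprintf("N0.HOG%07d", seq_len(n) - 1L)
  k <- 0L
  rows <- lapply(seq_len(n), function(i) {
    cells <- lapply(seq_along(species), function(j) {
      cnt <- counts[i, j]
      if (cnt == 0L) return(character(0))
      out <- sprintf("%s_%s_%d_%d", prefix, species[[j]], i, seq_len(cnt))
      out
    })
    names(cells) <- species
    cells
  })
  names(rows) <- ids
  structure(list(rows = rows, species_order = species), class = "og_table")
}

random_counts <- function(n_ogs, n_species, max_count = 10L) {
  species <- paste0("sp", seq_len(n_species))
  matrix(sample(0:max_count, n_ogs * n_species, replace = TRUE),
         n_ogs, n_species, dimnames = list(NULL, species))
}

random_hypothesis <- function(species) {
  k <- sample(seq_len(length(species) - 1L), 1L)
  expanded_in <- sample(species, k)
  compared_to <- sample(setdiff(species, expanded_in),
                        sample(seq_len(length(species) - k), 1L))
  hypothesis(index = 1L, name = "rand",
             expanded_in = expanded_in, compared_to = compared_to,
             nmin_expanded_in = sample(seq_along(expanded_in), 1L),
             min_expansion_factor = sample(c(1, 1.5, 2, 3), 1L),
             min_expansion_difference = sample(0:3, 1L),
             comparison = sample(c("all", "any"), 1L))
}

# exact integer-arithmetic hypergeometric tail; valid while every binomial
# coefficient is below 2^53 (N <= 55)
oracle_hyper_exact <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# O(n^2) reciprocal-best-hits
oracle_rbh <- function(hits, species_map) {
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  best_of <- function(q, target_sp) {
    cand <- hits[hits$qseqid == q &
                   species_map[hits$sseqid] == target_sp, , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    cand <- cand[order(-cand$bitscore, cand$evalue, cand$sseqid,
                       method = "radix"), , drop = FALSE]
    cand$sseqid[[1L]]
  }
  genes <- sort(unique(c(hits$qseqid, hits$sseqid)))
  pairs <- character(0)
  for (a in genes) for (b in genes) {
    if (a >= b) next
    if (species_map[[a]] == species_map[[b]]) next
    if (identical(best_of(a, species_map[[b]]), b) &&
        identical(best_of(b, species_map[[a]]), a)) {
      pairs <- c(pairs, paste(a, b))
    }
  }
  sort(pairs)
}

random_hit_table <- function(genes, n_rows) {
  q <- sample(genes, n_rows, replace = TRUE)
  s <- sample(genes, n_rows, replace = TRUE)
  data.frame(qseqid = q, sseqid = s,
             pident = round(runif(n_rows, 30, 100), 1),
             length = sample(50:500, n_rows, replace = TRUE),
             mismatch = sample(0:50, n_rows, replace = TRUE),
             gapopen = sample(0:5, n_rows, replace = TRUE),
             qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
             evalue = signif(10^runif(n_rows, -50, -1), 3),
             bitscore = round(runif(n_rows, 50, 500), 1),
             stringsAsFactors = FALSE)
}

# iterative worklist closure over a DAG (independent of the recursive
# memoized implementation)
oracle_closure <- function(graph, id, use_part_of = FALSE) {
  seen <- character(0)
  work <- id
  while (length(work)) {
    t <- work[[1L]]
    work <- work[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    p <- graph[[t]]$is_a
    if (use_part_of) p <- c(p, graph[[t]]$part_of)
    work <- c(work, intersect(p, names(graph)))
  }
  sort(seen)
}

random_dag <- function(n_terms) {
  ids <- sprintf("T%04d", seq_len(n_terms))
  terms <- lapply(seq_len(n_terms), function(t) {
    parents <- if (t == 1L) character(0) else
      ids[sample.int(t - 1L, min(sample(0:2, 1L), t - 1L))]
    list(id = ids[[t]], name = paste("term", t),
         namespace = "biological_process",
         is_a = parents, part_of = character(0), obsolete = FALSE)
  })
  names(terms) <- ids
  structure(terms, class = "ontology")
}
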