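#' Read a minimal OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas: `id`, `name`, `namespace`, `is_a` parents,
#' `relationship: part_of` parents and the `is_obsolete` flag.  All other
#' stanza types and tags are ignored.  The resulting graph must be acyclic;
#' cycles are detected lazily by the propagation code.
#'
#' @param path Path to the .obo file.
#' @return Object of class `ontology`: named list term_id -> list(name,
#'   namespace, is_a, part_of, obsolete).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", ln)  # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(name = NA_character_, namespace = NA_character_,
                  is_a = character(0), part_of = character(0),
                  obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # some other stanza type
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) next
    key <- kv[[2L]]
    val <- trimws(kv[[3L]])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "relationship") {
      rel <- strsplit(val, "\\s+")[[1L]]
      if (length(rel) >= 2L && rel[[1L]] == "part_of") {
        cur$part_of <- c(cur$part_of, rel[[2L]])
      }
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas in ", path)
  structure(terms, class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  ns <- table(vapply(x, function(t) t$namespace, character(1)))
  cat("ontology:", length(x), "terms (",
      paste(names(ns), as.integer(ns), collapse = ", "), ")\n")
  invisible(x)
}

sort_terms <- function(x) {
  if (is.null(x)) character(0) else sort(unique(x))
}

norm_namespace <- function(ns) {
  map <- c(BP = "biological_process", MF = "molecular_function",
           CC = "cellular_component")
  if (ns %in% names(map)) map[[ns]] else ns
}

term_parents <- function(graph, id, use_part_of = FALSE) {
  t <- graph[[id]]
  if (is.null(t)) return(character(0))
  p <- t$is_a
  if (use_part_of) p <- c(p, t$part_of)
  p[p %in% names(graph)]
}

#' All ancestors (inclusive closure) of ontology terms
#'
#' Memoized DFS over `is_a` (and optionally `part_of`) edges; a cycle raises
#' a hard error.
#'
#' @param graph An `ontology`.
#' @param ids Term ids.
#' @param use_part_of Follow `part_of` edges too (default off).
#' @return Named list id -> character vector of the term plus all ancestors.
#' @export
term_ancestors <- function(graph, ids, use_part_of = FALSE) {
  memo <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    key <- id
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (id %in% stack) {
      stop("cycle detected in ontology at term ", id)
    }
    out <- id
    for (p in term_parents(graph, id, use_part_of)) {
      out <- union(out, visit(p, c(stack, id)))
    }
    memo[[key]] <- out
    out
  }
  stats::setNames(lapply(ids, visit, stack = character(0)), ids)
}

#' Depth of each ontology term
#'
#' Longest is_a path from a root (a term with no parents); roots have
#' depth 0.
#'
#' @param graph An `ontology`.
#' @param use_part_of Include part_of edges.
#' @return Named integer vector over all non-obsolete terms.
#' @export
term_depths <- function(graph, use_part_of = FALSE) {
  ids <- names(graph)
  memo <- new.env(parent = emptyenv())
  depth <- function(id, stack) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    if (id %in% stack) stop("cycle detected in ontology at term ", id)
    p <- term_parents(graph, id, use_part_of)
    d <- if (!length(p)) 0L else
      1L + max(vapply(p, depth, integer(1), stack = c(stack, id)))
    memo[[id]] <- d
    d
  }
  stats::setNames(vapply(ids, depth, integer(1), stack = character(0)), ids)
}

#' Read a gene-to-GO annotation map
#'
#' TSV with two columns: gene id and a comma-separated list of GO term ids
#' (no header).
#'
#' @param path Path to the TSV.
#' @return Named list gene_id -> character vector of term ids.
#' @export
read_go_map <- function(path) {
  if (!file.exists(path)) stop("GO map not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 1L) next
    gene <- fields[[1L]]
    terms <- if (length(fields) >= 2L) split_gene_list(fields[[2L]])
             else character(0)
    out[[gene]] <- unique(c(out[[gene]], terms))
  }
  out
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term.  Terms absent from the graph are dropped (reported once);
#' obsolete terms are dropped.
#'
#' @param annotations Named list gene_id -> term ids.
#' @param graph An `ontology`.
#' @param use_part_of Propagate across part_of edges too.
#' @return Named list gene_id -> closed term set (sorted).
#' @export
propagate <- function(annotations, graph, use_part_of = FALSE) {
  all_terms <- unique(unlist(annotations, use.names = FALSE))
  obsolete <- names(graph)[vapply(graph, function(t) t$obsolete, logical(1))]
  known <- setdiff(intersect(all_terms, names(graph)), obsolete)
  unknown <- setdiff(all_terms, names(graph))
  if (length(unknown)) {
    message("dropping ", length(unknown),
            " annotation term(s) absent from the ontology")
  }
  anc <- term_ancestors(graph, known, use_part_of = use_part_of)
  anc <- lapply(anc, setdiff, y = obsolete)
  lapply(annotations, function(terms) {
    terms <- intersect(terms, known)
    sort_terms(unlist(anc[terms], use.names = FALSE))
  })
}

#' Term sets per orthogroup
#'
#' The term set of an OG is the union of the (already propagated) term sets
#' of its member genes.  Unannotated OGs keep an empty set — they still
#' count in enrichment backgrounds.
#'
#' @param table An `og_table`.
#' @param gene_terms Named list gene_id -> term ids (see [propagate()]).
#' @return Named list og_id -> sorted term vector.
#' @export
og_term_sets <- function(table, gene_terms) {
  stopifnot(inherits(table, "og_table"))
  lapply(table$rows, function(cells) {
    genes <- unlist(cells, use.names = FALSE)
    sort_terms(unlist(gene_terms[intersect(genes, names(gene_terms))],
                      use.names = FALSE))
  })
}

term_og_index <- function(og_terms) {
  # invert og -> terms into term -> og ids
  if (!length(og_terms)) return(list())
  og <- rep(names(og_terms), lengths(og_terms))
  tm <- unlist(og_terms, use.names = FALSE)
  split(og, tm)
}

#' Classic GO-term over-representation test over OG sets
#'
#' For every term of the requested namespace annotated (after propagation)
#' to at least `min_annotated` background OGs, tests whether the study set
#' is enriched for OGs carrying the term: urn N = background size,
#' K = background OGs with the term, n = study size, k = study OGs with the
#' term, p = upper-tail hypergeometric ([hypergeom_sf()]).  Benjamini-
#' Hochberg adjusted p-values are computed across the tested terms.
#'
#' @param study_ogs Character vector of study og ids (must be a subset of
#'   the background).
#' @param background_ogs Character vector of background og ids.
#' @param og_terms Named list og_id -> term set (see [og_term_sets()]).
#' @param graph An `ontology`.
#' @param namespace `"BP"`, `"MF"`, `"CC"` or a full namespace string;
#'   `NULL` tests every namespace together.
#' @param min_annotated Minimum background annotation count per tested term.
#' @return `data.frame`: term_id, name, namespace, k, n, K, N, p_raw, p_adj,
#'   neg_log10_p, og_ids (comma-joined study members) — sorted by p_raw
#'   then term_id.
#' @export
go_test <- function(study_ogs, background_ogs, og_terms, graph,
                    namespace = "BP", min_annotated = 3L) {
  stopifnot(min_annotated >= 1L)
  extra <- setdiff(study_ogs, background_ogs)
  if (length(extra)) {
    stop("study OG(s) not in background: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  empty <- data.frame(term_id = character(0), name = character(0),
                      namespace = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      neg_log10_p = numeric(0), og_ids = character(0),
                      stringsAsFactors = FALSE)
  if (!length(study_ogs)) {
    warning("empty study set; returning no enrichment results")
    return(empty)
  }
  idx <- term_og_index(og_terms[background_ogs])
  if (!is.null(namespace)) {
    ns <- norm_namespace(namespace)
    keep <- vapply(names(idx), function(t) {
      !is.null(graph[[t]]) && identical(graph[[t]]$namespace, ns)
    }, logical(1))
    idx <- idx[keep]
  }
  idx <- idx[lengths(idx) >= min_annotated]
  if (!length(idx)) return(empty)
  N <- length(unique(background_ogs))
  n <- length(unique(study_ogs))
  rows <- lapply(names(idx), function(t) {
    bg_with <- unique(idx[[t]])
    st_with <- intersect(bg_with, study_ogs)
    K <- length(bg_with)
    k <- length(st_with)
    data.frame(term_id = t,
               name = if (!is.null(graph[[t]])) graph[[t]]$name
                      else NA_character_,
               namespace = if (!is.null(graph[[t]])) graph[[t]]$namespace
                           else NA_character_,
               k = k, n = n, K = K, N = N,
               p_raw = hypergeom_sf(N, K, n, k),
               og_ids = paste(sort(st_with), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$neg_log10_p <- -log10(out$p_raw)
  out <- out[order(out$p_raw, out$term_id, method = "radix"), ]
  out <- out[, c("term_id", "name", "namespace", "k", "n", "K", "N",
                 "p_raw", "p_adj", "neg_log10_p", "og_ids")]
  rownames(out) <- NULL
  out
}

#' GO over-representation with elim decorrelation
#'
#' Bottom-up variant of [go_test()]: terms are processed by decreasing DAG
#' depth, and whenever a term's raw p-value falls below `elim_alpha` its
#' annotated study and background OGs are removed from the annotation sets
#' of all its ancestors before those are tested.  With `elim_alpha = 0` the
#' procedure reduces exactly to the classic test.
#'
#' @inheritParams go_test
#' @param elim_alpha Raw-p threshold below which a term's OGs are eliminated
#'   from its ancestors (default 0.01).
#' @param use_part_of Follow part_of edges when finding ancestors.
#' @return Same shape as [go_test()].
#' @export
elim_test <- function(study_ogs, background_ogs, og_terms, graph,
                      namespace = "BP", min_annotated = 3L,
                      elim_alpha = 0.01, use_part_of = FALSE) {
  stopifnot(min_annotated >= 1L, elim_alpha >= 0)
  extra <- setdiff(study_ogs, background_ogs)
  if (length(extra)) {
    stop("study OG(s) not in background: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  if (!length(study_ogs)) {
    warning("empty study set; returning no enrichment results")
    return(go_test(character(0), background_ogs, og_terms, graph,
                   namespace, min_annotated))
  }
  idx <- term_og_index(og_terms[background_ogs])
  if (!is.null(namespace)) {
    ns <- norm_namespace(namespace)
    keep <- vapply(names(idx), function(t) {
      !is.null(graph[[t]]) && identical(graph[[t]]$namespace, ns)
    }, logical(1))
    idx <- idx[keep]
  }
  idx <- idx[lengths(idx) >= min_annotated]
  if (!length(idx)) {
    return(go_test(character(0), background_ogs, og_terms, graph,
                   namespace, min_annotated)[0, ])
  }
  depths <- term_depths(graph, use_part_of = use_part_of)
  terms <- names(idx)
  terms <- terms[order(-depths[terms], terms, method = "radix")]
  anc <- term_ancestors(graph, terms, use_part_of = use_part_of)
  removed <- stats::setNames(vector("list", length(terms)), terms)
  N <- length(unique(background_ogs))
  n <- length(unique(study_ogs))
  rows <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    t <- terms[[i]]
    bg_with <- setdiff(unique(idx[[t]]), removed[[t]])
    st_with <- intersect(bg_with, study_ogs)
    K <- length(bg_with)
    k <- length(st_with)
    p <- hypergeom_sf(N, K, n, k)
    rows[[i]] <- data.frame(
      term_id = t,
      name = if (!is.null(graph[[t]])) graph[[t]]$name else NA_character_,
      namespace = if (!is.null(graph[[t]])) graph[[t]]$namespace
                  else NA_character_,
      k = k, n = n, K = K, N = N, p_raw = p,
      og_ids = paste(sort(st_with), collapse = ","),
      stringsAsFactors = FALSE)
    if (p < elim_alpha) {
      for (a in setdiff(anc[[t]], t)) {
        if (a %in% terms) removed[[a]] <- union(removed[[a]], idx[[t]])
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$neg_log10_p <- -log10(out$p_raw)
  out <- out[order(out$p_raw, out$term_id, method = "radix"), ]
  out <- out[, c("term_id", "name", "namespace", "k", "n", "K", "N",
                 "p_raw", "p_adj", "neg_log10_p", "og_ids")]
  rownames(out) <- NULL
  out
}

#' Induced ancestor subgraph of selected terms
#'
#' All ancestors of the selected terms plus the is_a (and optionally
#' part_of) edges connecting them, in deterministic (child, parent) order —
#' the input for a GO-subgraph plot of the top enriched terms.
#'
#' @param terms Selected term ids.
#' @param graph An `ontology`.
#' @param use_part_of Include part_of edges.
#' @return `data.frame` with columns child, parent, relation.
#' @export
induced_subgraph <- function(terms, graph, use_part_of = FALSE) {
  unknown <- setdiff(terms, names(graph))
  if (length(unknown)) {
    stop("term(s) not in ontology: ", paste(unknown, collapse = ", "))
  }
  if (!length(terms)) {
    return(data.frame(child = character(0), parent = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  }
  nodes <- sort(unique(unlist(term_ancestors(graph, terms,
                                             use_part_of = use_part_of),
                              use.names = FALSE)))
  edges <- list()
  for (child in nodes) {
    for (p in intersect(graph[[child]]$is_a, nodes)) {
      edges[[length(edges) + 1L]] <- data.frame(
        child = child, parent = p, relation = "is_a",
        stringsAsFactors = FALSE)
    }
    if (use_part_of) {
      for (p in intersect(graph[[child]]$part_of, nodes)) {
        edges[[length(edges) + 1L]] <- data.frame(
          child = child, parent = p, relation = "part_of",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(child = character(0), parent = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, edges)
  out <- out[order(out$child, out$parent, method = "radix"), ]
  rownames(out) <- NULL
  out
}
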