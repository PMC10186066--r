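#' Assemble and validate a run configuration
#'
#' Central configuration for [run_all()].  All referenced input files must
#' exist at validation time; analysis stages are switched on by supplying
#' their inputs (e.g. no `hits` file = no neighborhood stage).
#'
#' @param orthogroups Path to the orthogroup table (required).
#' @param hypotheses Path to the hypotheses TSV (required).
#' @param species Path to the species table (optional; required for ploidy
#'   normalization and species-name validation).
#' @param de Named character vector species -> DE table path, or a directory
#'   containing `de_<species>.tsv` files.
#' @param hits Path to the all-vs-all hit table (optional).
#' @param go_map Path to the gene -> GO map (optional, with `obo`).
#' @param obo Path to the ontology (optional, with `go_map`).
#' @param tree Path to a newick species tree (opaque pass-through).
#' @param out_dir Bundle output directory.
#' @param alpha DEG significance cutoff on adjusted p (default 0.05).
#' @param comparison `"all"` or `"any"` compared_to aggregation.
#' @param neighborhood_n Additional OGs per expanded OG (default 5).
#' @param go_namespace Namespace for GO enrichment (default `"BP"`).
#' @param min_annotated Minimum background annotation per tested GO term.
#' @param go_algorithm `"classic"` or `"elim"`.
#' @param elim_alpha Elimination threshold for the elim algorithm.
#' @param ploidy_normalize Apply ploidy adjustment to counts.
#' @param prefix_species Prefix gene ids with their species on read.
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(orthogroups, hypotheses, species = NULL, de = NULL,
                       hits = NULL, go_map = NULL, obo = NULL, tree = NULL,
                       out_dir = "ogxpand_out", alpha = 0.05,
                       comparison = c("all", "any"), neighborhood_n = 5L,
                       go_namespace = "BP", min_annotated = 3L,
                       go_algorithm = c("classic", "elim"),
                       elim_alpha = 0.01,
                       ploidy_normalize = FALSE, prefix_species = FALSE,
                       seed = 1L) {
  comparison <- match.arg(comparison)
  go_algorithm <- match.arg(go_algorithm)
  stopifnot(alpha > 0, alpha <= 1, neighborhood_n >= 0, min_annotated >= 1)
  if (!is.null(de) && length(de) == 1L && is.null(names(de)) &&
      dir.exists(de)) {
    files <- list.files(de, pattern = "^de_.*\\.tsv$", full.names = TRUE)
    de <- stats::setNames(files, sub("^de_(.*)\\.tsv$", "\\1",
                                     basename(files)))
  }
  must_exist <- c(orthogroups = orthogroups, hypotheses = hypotheses,
                  species = species, hits = hits, go_map = go_map,
                  obo = obo, tree = tree, de)
  missing <- must_exist[!vapply(must_exist, file.exists, logical(1))]
  if (length(missing)) {
    stop("input file(s) not found: ",
         paste(paste0(names(missing), "=", missing), collapse = ", "))
  }
  if (xor(is.null(go_map), is.null(obo))) {
    stop("GO enrichment needs both go_map and obo")
  }
  structure(list(
    orthogroups = orthogroups, hypotheses = hypotheses, species = species,
    de = de, hits = hits, go_map = go_map, obo = obo, tree = tree,
    out_dir = out_dir, alpha = alpha, comparison = comparison,
    neighborhood_n = as.integer(neighborhood_n),
    go_namespace = go_namespace, min_annotated = as.integer(min_annotated),
    go_algorithm = go_algorithm, elim_alpha = elim_alpha,
    ploidy_normalize = isTRUE(ploidy_normalize),
    prefix_species = isTRUE(prefix_species),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a run configuration from a JSON (or YAML) file
#'
#' Keys mirror the arguments of [run_config()]; `de` may be a directory or
#' a named map.  YAML needs the `yaml` package; JSON always works.
#'
#' @param path Config file; `.json`, `.yaml`/`.yml`.
#' @param overrides Named list of values that win over the file's.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(path)
  pathify <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
    if (!is.null(names(p))) names(out) <- names(p)
    out
  }
  for (key in c("orthogroups", "hypotheses", "species", "de", "hits",
                "go_map", "obo", "tree")) {
    if (!is.null(cfg[[key]])) cfg[[key]] <- pathify(unlist(cfg[[key]]))
  }
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes, for every hypothesis: expansion calling, the OG summary and
#' membership statistics, reciprocal-best-hit neighborhoods of the expanded
#' OGs (when a hit table is supplied) and GO-term enrichment of the
#' expanded set against all OGs (when an ontology and annotation map are
#' supplied).  Results are assembled into a [results_bundle()] and written
#' to `config$out_dir`.
#'
#' @param config A `run_config`.
#' @param write Write the bundle to `config$out_dir` (default TRUE).
#' @return The `results_bundle`, invisibly when written.
#' @export
run_all <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  profiles <- if (!is.null(config$species)) read_species(config$species)
  hyps <- read_hypotheses(config$hypotheses, species_profiles = profiles)
  hyps <- lapply(hyps, function(h) {
    h$comparison <- config$comparison
    h$ploidy_normalize <- config$ploidy_normalize
    h
  })
  table <- read_orthogroups(config$orthogroups,
                            prefix_species = config$prefix_species)
  de <- if (!is.null(config$de)) read_de_tables(config$de)
  deg_sets <- if (!is.null(de)) significant_genes(de, alpha = config$alpha)
              else list()
  membership <- og_membership(table)
  species_map <- gene_species_map(table)

  hits <- NULL
  rbh <- NULL
  if (!is.null(config$hits)) {
    hits <- read_hits(config$hits)
    rbh <- reciprocal_best_hits(hits, species_map)
  }
  graph <- NULL
  og_terms <- NULL
  anno <- NULL
  if (!is.null(config$obo)) {
    graph <- read_obo(config$obo)
    anno <- read_go_map(config$go_map)
    og_terms <- og_term_sets(table, propagate(anno, graph))
  }

  tables <- list()
  tables$hypotheses <- as.data.frame(
    data.table::fread(config$hypotheses, sep = "\t", colClasses = "character"))
  if (!is.null(profiles)) tables$species <- profiles
  if (!is.null(de)) tables$de_table <- de
  tables$og_genes <- data.frame(
    og_id = unname(membership),
    species = unname(species_map[names(membership)]),
    gene_id = names(membership),
    stringsAsFactors = FALSE)
  if (!is.null(anno)) {
    tables$annotations <- data.frame(
      gene_id = names(anno),
      terms = vapply(anno, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
  }

  calls <- call_all(table, hyps, species_profiles = profiles)
  for (i in seq_along(hyps)) {
    hyp <- hyps[[i]]
    tag <- paste0("hypothesis_", hyp$index)
    htab <- calls[[tag]]
    tables[[paste0("expansion_calls.", tag)]] <- htab
    summ <- summarize_ogs(table, htab, deg_sets, hyp)
    tables[[paste0("og_summary.", tag)]] <- summ
    mc <- membership_counts(table, hypothesis_species(hyp))
    tables[[paste0("membership_counts.", tag)]] <- data.frame(
      pattern = names(mc$patterns), og_count = unname(mc$patterns),
      stringsAsFactors = FALSE)
    exp_ogs <- expanded_ogs(htab)
    if (!is.null(rbh)) {
      tables[[paste0("neighborhood.", tag)]] <-
        neighborhood_table(exp_ogs, rbh, membership,
                           n = config$neighborhood_n)
    }
    if (!is.null(og_terms)) {
      enr <- if (length(exp_ogs)) {
        if (config$go_algorithm == "elim") {
          elim_test(exp_ogs, names(table$rows), og_terms, graph,
                    namespace = config$go_namespace,
                    min_annotated = config$min_annotated,
                    elim_alpha = config$elim_alpha)
        } else {
          go_test(exp_ogs, names(table$rows), og_terms, graph,
                  namespace = config$go_namespace,
                  min_annotated = config$min_annotated)
        }
      } else {
        go_test(character(0), names(table$rows), og_terms, graph,
                namespace = config$go_namespace,
                min_annotated = config$min_annotated)
      }
      tables[[paste0("go_enrichment.", tag)]] <- enr
    }
  }
  tree <- if (!is.null(config$tree)) readLines(config$tree)
  bundle <- results_bundle(tables, tree = tree,
                           config = unclass(config), seed = config$seed)
  if (write) {
    write_bundle(bundle, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}
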