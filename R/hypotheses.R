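#' Read the hypotheses table
#'
#' Each row declares one expansion question: the species set expected to show
#' gene-family expansion (`expanded_in`) versus the species set expected not
#' to (`compared_to`), plus the numeric cutoffs that define "expanded".
#' Species lists are semicolon-separated (commas are reserved for the gene
#' lists of the orthogroup table).
#'
#' Required columns: `hypothesis` (integer index), `name`, `expanded_in`,
#' `compared_to`, `Nmin_expanded_in`, `min_expansion_factor`,
#' `min_expansion_difference`.
#'
#' @param path Path to the hypotheses TSV.
#' @param species_profiles Optional species profile table (see
#'   [read_species()]); when supplied, every species named by a hypothesis
#'   must be a known species.
#' @return List of `hypothesis` objects.
#' @export
read_hypotheses <- function(path, species_profiles = NULL) {
  if (!file.exists(path)) stop("hypotheses table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          header = TRUE)
  req <- c("hypothesis", "name", "expanded_in", "compared_to",
           "Nmin_expanded_in", "min_expansion_factor",
           "min_expansion_difference")
  missing <- setdiff(req, names(dt))
  if (length(missing)) {
    stop("hypotheses table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  dt <- as.data.frame(dt)
  lapply(seq_len(nrow(dt)), function(i) {
    row <- dt[i, , drop = FALSE]
    hypothesis(
      index = parse_num(row$hypothesis, "hypothesis", integer = TRUE),
      name = row$name,
      expanded_in = split_species_list(row$expanded_in),
      compared_to = split_species_list(row$compared_to),
      nmin_expanded_in = parse_num(row$Nmin_expanded_in, "Nmin_expanded_in",
                                   integer = TRUE),
      min_expansion_factor = parse_num(row$min_expansion_factor,
                                       "min_expansion_factor"),
      min_expansion_difference = parse_num(row$min_expansion_difference,
                                           "min_expansion_difference",
                                           integer = TRUE),
      known_species = if (!is.null(species_profiles))
        species_profiles$name else NULL
    )
  })
}

split_species_list <- function(x) {
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  out[nzchar(out)]
}

parse_num <- function(x, what, integer = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("non-numeric value for ", what, ": '", x, "'")
  if (integer && v != round(v)) stop(what, " must be an integer, got ", x)
  if (integer) as.integer(v) else v
}

#' Construct a hypothesis
#'
#' @param index Integer index used to namespace outputs.
#' @param name Human-readable hypothesis name.
#' @param expanded_in Character vector of species expected to show expansion.
#' @param compared_to Character vector of species expected not to.
#' @param nmin_expanded_in Minimum number of `expanded_in` species that must
#'   fulfil the expansion criteria for the OG to be called expanded.
#' @param min_expansion_factor Minimum count ratio (focal / comparison).
#' @param min_expansion_difference Minimum count difference (additional genes).
#' @param ploidy_normalize Divide counts by ploidy/2 before comparing.
#' @param comparison `"all"` (a focal species must exceed every comparison
#'   species; default) or `"any"` (at least one).
#' @param known_species Optional vector of valid species names to check
#'   against.
#' @return An object of class `hypothesis`.
#' @export
hypothesis <- function(index, name, expanded_in, compared_to,
                       nmin_expanded_in = 1L,
                       min_expansion_factor = 2,
                       min_expansion_difference = 0L,
                       ploidy_normalize = FALSE,
                       comparison = c("all", "any"),
                       known_species = NULL) {
  comparison <- match.arg(comparison)
  expanded_in <- as.character(expanded_in)
  compared_to <- as.character(compared_to)
  if (!length(expanded_in) || !length(compared_to)) {
    stop("hypothesis '", name, "': expanded_in and compared_to must be ",
         "non-empty")
  }
  overlap <- intersect(expanded_in, compared_to)
  if (length(overlap)) {
    stop("hypothesis '", name, "': species in both expanded_in and ",
         "compared_to: ", paste(overlap, collapse = ", "))
  }
  if (!is.null(known_species)) {
    unk <- setdiff(c(expanded_in, compared_to), known_species)
    if (length(unk)) {
      stop("hypothesis '", name, "': unknown species: ",
           paste(unk, collapse = ", "))
    }
  }
  nmin_expanded_in <- as.integer(nmin_expanded_in)
  if (nmin_expanded_in < 1L) stop("Nmin_expanded_in must be >= 1")
  if (nmin_expanded_in > length(expanded_in)) {
    stop("hypothesis '", name, "': Nmin_expanded_in (", nmin_expanded_in,
         ") exceeds number of expanded_in species (", length(expanded_in), ")")
  }
  if (min_expansion_factor < 1) stop("min_expansion_factor must be >= 1")
  if (min_expansion_difference < 0) stop("min_expansion_difference must be >= 0")
  structure(list(
    index = as.integer(index), name = name,
    expanded_in = expanded_in, compared_to = compared_to,
    nmin_expanded_in = nmin_expanded_in,
    min_expansion_factor = as.numeric(min_expansion_factor),
    min_expansion_difference = as.integer(min_expansion_difference),
    ploidy_normalize = isTRUE(ploidy_normalize),
    comparison = comparison
  ), class = "hypothesis")
}

#' @export
print.hypothesis <- function(x, ...) {
  cat(sprintf("hypothesis %d '%s': {%s} expanded vs {%s}; nmin=%d factor=%g diff=%d (%s)\n",
              x$index, x$name,
              paste(x$expanded_in, collapse = ";"),
              paste(x$compared_to, collapse = ";"),
              x$nmin_expanded_in, x$min_expansion_factor,
              x$min_expansion_difference, x$comparison))
  invisible(x)
}

#' All species named by a hypothesis
#' @param hyp A `hypothesis`.
#' @return Character vector (expanded_in first, then compared_to).
#' @export
hypothesis_species <- function(hyp) c(hyp$expanded_in, hyp$compared_to)

#' Read the species profile table
#'
#' TSV with columns `species` (or `name`), `ploidy` and optionally
#' `go_annotation` (a path, or a sentinel string when no annotation file is
#' available).
#'
#' @param path Path to the species TSV.
#' @return `data.frame` with columns name, ploidy, go_annotation.
#' @export
read_species <- function(path) {
  if (!file.exists(path)) stop("species table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  namecol <- intersect(c("species", "name"), names(dt))[1]
  if (is.na(namecol)) stop("species table needs a 'species' or 'name' column")
  if (!"ploidy" %in% names(dt)) stop("species table needs a 'ploidy' column")
  ploidy <- vapply(dt$ploidy, parse_num, numeric(1), what = "ploidy",
                   integer = TRUE)
  if (any(ploidy < 1)) stop("ploidy must be >= 1")
  nm <- dt[[namecol]]
  if (anyDuplicated(nm)) {
    stop("duplicate species name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  data.frame(name = nm, ploidy = as.integer(ploidy),
             go_annotation = if ("go_annotation" %in% names(dt))
               dt$go_annotation else NA_character_,
             stringsAsFactors = FALSE)
}
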