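#' Ploidy-adjusted gene counts for one orthogroup row
#'
#' With `normalize = FALSE` the raw per-species gene counts are returned.
#' With `normalize = TRUE` every count is rescaled to a diploid-equivalent
#' copy number, `count * 2 / ploidy`, so that e.g. a tetraploid's duplicated
#' complement does not register as an expansion by itself.
#'
#' @param row Named list species -> gene id vector (one `og_table` row), or a
#'   named numeric vector of counts.
#' @param species_profiles Species profile table (see [read_species()]);
#'   required when `normalize = TRUE`.
#' @param normalize Apply the ploidy adjustment (default off).
#' @return Named numeric vector of (possibly adjusted) counts.
#' @export
adjusted_counts <- function(row, species_profiles = NULL, normalize = FALSE) {
  counts <- if (is.numeric(row)) row else vapply(row, length, integer(1))
  counts <- as.numeric(counts)
  names(counts) <- if (is.numeric(row)) names(row) else names(row)
  if (any(counts < 0)) stop("negative gene count")
  if (!normalize) return(counts)
  if (is.null(species_profiles)) {
    stop("species_profiles required when normalize = TRUE")
  }
  ploidy <- stats::setNames(species_profiles$ploidy, species_profiles$name)
  missing <- setdiff(names(counts), names(ploidy))
  if (length(missing)) {
    stop("no ploidy for species: ", paste(missing, collapse = ", "))
  }
  p <- ploidy[names(counts)]
  if (any(p < 1)) stop("ploidy must be >= 1")
  counts * 2 / p
}

#' Pairwise expansion predicate
#'
#' A focal count is expanded relative to a comparison count iff all of
#' `count_a >= 1`, `count_a >= factor * count_b` and
#' `count_a - count_b >= difference` hold.  The `count_a >= 1` guard keeps an
#' absent family (count 0 vs 0) from qualifying through a vacuous factor
#' condition; equality at `count_a = factor * count_b` counts as expanded.
#'
#' @param count_a Focal-species count (>= 0).
#' @param count_b Comparison-species count (>= 0).
#' @param factor Minimum expansion factor (>= 1).
#' @param difference Minimum number of additional genes (>= 0).
#' @return Logical (vectorized over the counts).
#' @export
pairwise_expanded <- function(count_a, count_b, factor = 2, difference = 0L) {
  stopifnot(all(count_a >= 0), all(count_b >= 0))
  count_a >= 1 & count_a >= factor * count_b &
    count_a - count_b >= difference
}

#' Evaluate one hypothesis on one orthogroup
#'
#' An `expanded_in` species qualifies iff [pairwise_expanded()] holds against
#' every `compared_to` species (`comparison = "all"`, the default) or against
#' at least one (`"any"`).  The OG is expanded iff at least
#' `nmin_expanded_in` focal species qualify.
#'
#' @param row Named list species -> gene vector, or named numeric counts.
#' @param hyp A `hypothesis`.
#' @param species_profiles Species profiles (needed for ploidy normalization).
#' @return List of class `expansion_call` with elements og_id (may be NA),
#'   hypothesis, counts (raw), adjusted (numeric, equals counts when
#'   normalization is off), qualifying (named logical over expanded_in),
#'   expanded (logical).
#' @export
call_expansion <- function(row, hyp, species_profiles = NULL) {
  sp_needed <- hypothesis_species(hyp)
  nm <- names(row)
  missing <- setdiff(sp_needed, nm)
  if (length(missing)) {
    stop("species missing from orthogroup row: ",
         paste(missing, collapse = ", "))
  }
  raw <- if (is.numeric(row)) as.numeric(row[sp_needed]) else
    as.numeric(vapply(row[sp_needed], length, integer(1)))
  names(raw) <- sp_needed
  adj <- adjusted_counts(raw, species_profiles,
                         normalize = hyp$ploidy_normalize)
  qualifying <- vapply(hyp$expanded_in, function(a) {
    ok <- pairwise_expanded(adj[[a]], adj[hyp$compared_to],
                            hyp$min_expansion_factor,
                            hyp$min_expansion_difference)
    if (hyp$comparison == "all") all(ok) else any(ok)
  }, logical(1))
  structure(list(
    og_id = NA_character_,
    hypothesis = hyp$index,
    counts = raw,
    adjusted = adj,
    qualifying = qualifying,
    expanded = sum(qualifying) >= hyp$nmin_expanded_in
  ), class = "expansion_call")
}

#' Evaluate hypotheses over a whole orthogroup table
#'
#' @param table An `og_table`.
#' @param hypotheses List of `hypothesis` objects (a single one is accepted).
#' @param species_profiles Optional species profiles.
#' @return Named list (one element per hypothesis, named `hypothesis_<index>`)
#'   of `data.frame`s with columns og_id, `count_<species>`,
#'   `qualifying_<species>`, expanded — rows in table order.
#' @export
call_all <- function(table, hypotheses, species_profiles = NULL) {
  stopifnot(inherits(table, "og_table"))
  if (inherits(hypotheses, "hypothesis")) hypotheses <- list(hypotheses)
  out <- lapply(hypotheses, function(hyp) {
    sp <- hypothesis_species(hyp)
    counts <- og_counts(table, sp)
    if (hyp$ploidy_normalize) {
      if (is.null(species_profiles)) {
        stop("species_profiles required when ploidy_normalize is on")
      }
      ploidy <- stats::setNames(species_profiles$ploidy,
                                species_profiles$name)
      missing <- setdiff(sp, names(ploidy))
      if (length(missing)) {
        stop("no ploidy for species: ", paste(missing, collapse = ", "))
      }
      adj <- sweep(counts, 2L, ploidy[sp], function(cnt, p) cnt * 2 / p)
    } else {
      adj <- counts * 1.0
    }
    qual <- matrix(NA, nrow(counts), length(hyp$expanded_in),
                   dimnames = list(rownames(counts), hyp$expanded_in))
    for (a in hyp$expanded_in) {
      ok <- matrix(TRUE, nrow(counts), length(hyp$compared_to))
      for (j in seq_along(hyp$compared_to)) {
        b <- hyp$compared_to[[j]]
        ok[, j] <- pairwise_expanded(adj[, a], adj[, b],
                                     hyp$min_expansion_factor,
                                     hyp$min_expansion_difference)
      }
      qual[, a] <- if (hyp$comparison == "all") rowSums(!ok) == 0L
                   else rowSums(ok) > 0L
    }
    expanded <- rowSums(qual) >= hyp$nmin_expanded_in
    df <- data.frame(og_id = rownames(counts), stringsAsFactors = FALSE)
    for (s in sp) df[[paste0("count_", s)]] <- counts[, s]
    for (a in hyp$expanded_in) df[[paste0("qualifying_", a)]] <- qual[, a]
    df$expanded <- expanded
    rownames(df) <- NULL
    df
  })
  names(out) <- vapply(hypotheses, function(h)
    paste0("hypothesis_", h$index), character(1))
  out
}

#' Expanded OG ids of one call table
#' @param calls One element of the [call_all()] result.
#' @return Character vector of og ids with `expanded == TRUE`.
#' @export
expanded_ogs <- function(calls) calls$og_id[calls$expanded]
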