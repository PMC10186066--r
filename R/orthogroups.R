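#' Read an Orthofinder-style hierarchical orthogroup table
#'
#' Parses the `N0.tsv` dialect written by Orthofinder's hierarchical
#' orthogroup inference: a tab-separated file whose header is
#' `HOG`, `OG`, `Gene Tree Parent Clade` followed by one column per species,
#' with the genes of one orthogroup (OG) in one species separated by `", "`.
#'
#' Empty cells become empty gene vectors (the species key is always present).
#' Gene identifiers must be unique across the whole table; annotations whose
#' gene ids collide between species can be disambiguated with
#' `prefix_species = TRUE`, which rewrites every id as `species:gene`.
#'
#' @param path Path to the orthogroup TSV.
#' @param prefix_species Prefix every gene id with `species:` to guarantee
#'   global uniqueness across species.
#' @return An object of class `og_table`: a list with elements
#'   `rows` (named list: og_id -> named list: species -> character vector of
#'   gene ids) and `species_order` (character vector of species columns in
#'   file order).
#' @export
read_orthogroups <- function(path, prefix_species = FALSE) {
  if (!file.exists(path)) stop("orthogroup table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("orthogroup table is empty: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L) {
    stop("orthogroup table header must have >= 4 columns (HOG, OG, ",
         "Gene Tree Parent Clade, species...); found ", length(header))
  }
  species <- header[-(1:3)]
  if (anyDuplicated(species)) {
    stop("duplicate species columns: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  ncol_expected <- length(header)
  rows <- vector("list", length(lines) - 1L)
  ids <- character(length(lines) - 1L)
  if (length(rows)) {
    for (i in seq_along(rows)) {
      fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
      # a trailing empty cell is dropped by strsplit; pad it back
      if (length(fields) < ncol_expected) {
        fields <- c(fields, rep("", ncol_expected - length(fields)))
      }
      if (length(fields) != ncol_expected) {
        stop("ragged orthogroup row at line ", i + 1L, ": expected ",
             ncol_expected, " columns, found ", length(fields))
      }
      ids[[i]] <- fields[[1L]]
      cells <- lapply(fields[-(1:3)], split_gene_list)
      names(cells) <- species
      rows[[i]] <- cells
    }
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate orthogroup id(s): ", paste(dup, collapse = ", "))
  }
  names(rows) <- ids
  if (prefix_species) {
    rows <- lapply(rows, function(cells) {
      for (sp in names(cells)) {
        if (length(cells[[sp]])) cells[[sp]] <- paste0(sp, ":", cells[[sp]])
      }
      cells
    })
  }
  tab <- structure(list(rows = rows, species_order = species),
                   class = "og_table")
  all_genes <- unlist(lapply(rows, unlist), use.names = FALSE)
  dupg <- unique(all_genes[duplicated(all_genes)])
  if (length(dupg)) {
    stop("gene id(s) appear in more than one orthogroup/species cell: ",
         paste(utils::head(dupg, 5L), collapse = ", "),
         if (length(dupg) > 5L) " ..." else "",
         "; use prefix_species = TRUE if ids collide between species")
  }
  tab
}

split_gene_list <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell)) return(character(0))
  trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
}

#' Per-species gene counts of an orthogroup table
#'
#' @param table An `og_table`.
#' @param species Optional subset of species columns.
#' @return Integer matrix, one row per OG, one column per species.
#' @export
og_counts <- function(table, species = NULL) {
  stopifnot(inherits(table, "og_table"))
  if (is.null(species)) species <- table$species_order
  missing <- setdiff(species, table$species_order)
  if (length(missing)) {
    stop("species not in orthogroup table: ", paste(missing, collapse = ", "))
  }
  m <- matrix(0L, nrow = length(table$rows), ncol = length(species),
              dimnames = list(names(table$rows), species))
  for (i in seq_along(table$rows)) {
    m[i, ] <- vapply(table$rows[[i]][species], length, integer(1))
  }
  m
}

#' Map every gene id to its orthogroup
#'
#' @param table An `og_table`.
#' @return Named character vector gene_id -> og_id.
#' @export
og_membership <- function(table) {
  stopifnot(inherits(table, "og_table"))
  genes <- lapply(table$rows, function(cells) unlist(cells, use.names = FALSE))
  n <- lengths(genes)
  stats::setNames(rep(names(table$rows), n), unlist(genes, use.names = FALSE))
}

#' Map every gene id to its species
#'
#' @param table An `og_table`.
#' @return Named character vector gene_id -> species.
#' @export
gene_species_map <- function(table) {
  stopifnot(inherits(table, "og_table"))
  out <- character(0)
  for (cells in table$rows) {
    for (sp in names(cells)) {
      g <- cells[[sp]]
      if (length(g)) out[g] <- sp
    }
  }
  out
}

#' @export
print.og_table <- function(x, ...) {
  cat("og_table:", length(x$rows), "orthogroups x",
      length(x$species_order), "species\n")
  cat("species:", paste(x$species_order, collapse = ", "), "\n")
  invisible(x)
}

#' Write an orthogroup table in the N0.tsv dialect
#'
#' @param table An `og_table`.
#' @param path Output path.
#' @export
write_orthogroups <- function(table, path) {
  stopifnot(inherits(table, "og_table"))
  header <- paste(c("HOG", "OG", "Gene Tree Parent Clade",
                    table$species_order), collapse = "\t")
  body <- vapply(names(table$rows), function(id) {
    cells <- vapply(table$rows[[id]][table$species_order],
                    function(g) paste(g, collapse = ", "), character(1))
    paste(c(id, sub("^N0\\.", "", id), "n0", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
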