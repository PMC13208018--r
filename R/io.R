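#' Construct a per-species dataset
#'
#' Lightweight container for one species: sparse integer counts (genes x
#' cells), a normalized matrix filled in by [lognormalize()], and per-cell
#' metadata accumulated by the trajectory and staging steps.
#'
#' @param species species label.
#' @param counts sparse (or dense) genes-by-cells matrix of nonnegative
#'   integer counts with row and column names.
#' @param cell_meta optional data frame with one row per cell.
#' @return object of class `species_dataset`.
#' @export
species_dataset <- function(species, counts, cell_meta = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene (row) and cell (column) names")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be nonnegative integers")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(counts), stringsAsFactors = FALSE)
  }
  stopifnot(nrow(cell_meta) == ncol(counts))
  structure(list(species = species, counts = counts,
                 gene_ids = rownames(counts), cell_ids = colnames(counts),
                 normalized = NULL, cell_meta = cell_meta),
            class = "species_dataset")
}

#' @export
print.species_dataset <- function(x, ...) {
  cat("species_dataset:", x$species, "-", nrow(x$counts), "genes x",
      ncol(x$counts), "cells;",
      if (is.null(x$normalized)) "not normalized" else "normalized",
      "\n")
  invisible(x)
}

# Open a path as a connection, transparently handling gzip.
.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

# Read the first tab-separated field of each line (features/barcodes files).
.read_id_column <- function(path, what) {
  con <- .open_maybe_gz(path)
  lines <- readLines(con)
  if (inherits(con, "connection")) close(con)
  if (length(lines) == 0) stop("empty ", what, " file: ", path)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
}

#' Read a 10x-style count triplet (MTX + features + barcodes)
#'
#' @param mtx_path Matrix Market file of genes x cells integer counts.
#' @param features_path TSV whose first column holds gene ids (one per row).
#' @param barcodes_path TSV of cell barcodes (one per row).
#' @param species species label attached to the dataset.
#' @return a [species_dataset()].
#' @export
read_counts <- function(mtx_path, features_path, barcodes_path, species = "unknown") {
  for (p in c(mtx_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(.open_maybe_gz(mtx_path))
  feats <- .read_id_column(features_path, "features")
  bcs <- .read_id_column(barcodes_path, "barcodes")
  if (nrow(m) != length(feats))
    stop("dimension mismatch: ", mtx_path, " declares ", nrow(m),
         " genes but ", features_path, " lists ", length(feats))
  if (ncol(m) != length(bcs))
    stop("dimension mismatch: ", mtx_path, " declares ", ncol(m),
         " cells but ", barcodes_path, " lists ", length(bcs))
  dimnames(m) <- list(feats, bcs)
  species_dataset(species, m)
}

#' Write a dataset as an MTX + features + barcodes triplet
#'
#' @param ds a [species_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(ds, dir) {
  stopifnot(inherits(ds, "species_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(ds$counts, file.path(dir, "matrix.mtx"))
  writeLines(ds$gene_ids, file.path(dir, "features.tsv"))
  writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Construct an ortholog map
#'
#' Stores (species_gene_id, reference_symbol) pairs and flags, per pair,
#' whether the pair is bidirectionally unique within the table (one-to-one).
#' Exact duplicate rows are collapsed with a warning.
#'
#' @param pairs data frame with columns `species_gene_id` and
#'   `reference_symbol`.
#' @return object of class `ortholog_map` with elements `pairs` (including an
#'   `is_one_to_one` column).
#' @export
ortholog_map <- function(pairs) {
  stopifnot(all(c("species_gene_id", "reference_symbol") %in% names(pairs)))
  pairs <- pairs[, c("species_gene_id", "reference_symbol")]
  dup <- duplicated(pairs)
  if (any(dup)) {
    warning(sum(dup), " duplicate ortholog rows collapsed")
    pairs <- pairs[!dup, ]
  }
  pairs$is_one_to_one <- !(duplicated(pairs$species_gene_id) |
                             duplicated(pairs$species_gene_id, fromLast = TRUE) |
                             duplicated(pairs$reference_symbol) |
                             duplicated(pairs$reference_symbol, fromLast = TRUE))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs), class = "ortholog_map")
}

#' Read an ortholog table from TSV
#'
#' Expects at least two tab-separated columns: species gene id and reference
#' symbol. Version suffixes after a final "." on gene ids (Ensembl-style,
#' e.g. `ENSG0001.5`) are stripped. Malformed rows (missing fields) raise an
#' error naming the line.
#'
#' @param tsv_path path to the table (optionally gzipped). A header line is
#'   detected if the first row equals the canonical column names.
#' @return an [ortholog_map()].
#' @export
read_ortholog_table <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("file not found: ", tsv_path)
  con <- .open_maybe_gz(tsv_path)
  lines <- readLines(con)
  if (inherits(con, "connection")) close(con)
  if (length(lines) == 0) stop("empty ortholog table: ", tsv_path)
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- identical(tolower(first[1:2]),
                          c("species_gene_id", "reference_symbol"))
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f) length(f) < 2 || any(!nzchar(f[1:2])),
                      logical(1)))
  if (length(bad) > 0)
    stop("malformed ortholog row at line ", bad[1] + offset, " of ", tsv_path)
  ids <- vapply(fields, `[`, character(1), 1)
  syms <- vapply(fields, `[`, character(1), 2)
  ids <- sub("\\.[0-9]+$", "", ids)  # strip version suffixes
  ortholog_map(data.frame(species_gene_id = ids, reference_symbol = syms,
                          stringsAsFactors = FALSE))
}

#' Harmonize a dataset's gene identifiers to reference symbols
#'
#' Retains only genes with a bidirectionally unique (one-to-one) ortholog
#' pair, renames them to the reference symbol, and sorts rows by symbol for
#' deterministic downstream order. Counts of retained genes are unchanged and
#' cell order is preserved. Genes whose id already equals a one-to-one
#' reference symbol are kept as-is, which makes the operation idempotent.
#'
#' @param ds a [species_dataset()].
#' @param map an [ortholog_map()].
#' @return the harmonized [species_dataset()].
#' @export
harmonize_to_reference <- function(ds, map) {
  stopifnot(inherits(ds, "species_dataset"), inherits(map, "ortholog_map"))
  p <- map$pairs[map$pairs$is_one_to_one, ]
  sym_of <- stats::setNames(p$reference_symbol, p$species_gene_id)
  new_sym <- ifelse(ds$gene_ids %in% names(sym_of), sym_of[ds$gene_ids],
                    ifelse(ds$gene_ids %in% p$reference_symbol, ds$gene_ids,
                           NA_character_))
  keep <- which(!is.na(new_sym))
  if (length(keep) == 0)
    stop("no genes retained after harmonization for species '", ds$species,
         "'; check that the ortholog map matches this species")
  out <- ds$counts[keep, , drop = FALSE]
  rownames(out) <- new_sym[keep]
  out <- out[order(rownames(out)), , drop = FALSE]
  res <- species_dataset(ds$species, out, cell_meta = ds$cell_meta)
  res$normalized <- NULL  # normalization must be redone on the new gene space
  res
}

#' Common ortholog set across harmonized datasets
#'
#' @param datasets list of at least two harmonized [species_dataset()]s.
#' @return sorted character vector: intersection of gene symbols.
#' @export
common_ortholog_set <- function(datasets) {
  if (length(datasets) < 2) stop("need at least two datasets")
  sets <- lapply(datasets, function(d) d$gene_ids)
  common <- Reduce(intersect, sets)
  if (length(common) == 0) stop("empty common ortholog set across datasets")
  sort(common)
}
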