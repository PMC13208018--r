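#' Library-size log-normalization
#'
#' Per cell, values become `ln(1 + scale * count / library_size)` with
#' `scale = 10000`, the standard single-cell convention.
#'
#' @param counts sparse genes-by-cells count matrix, or a
#'   [species_dataset()] (in which case the dataset is returned with its
#'   `normalized` slot filled).
#' @param scale_factor target library size (default 10000).
#' @return normalized sparse matrix, or the updated dataset.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  if (inherits(counts, "species_dataset")) {
    ds <- counts
    ds$normalized <- lognormalize(ds$counts, scale_factor)
    return(ds)
  }
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    stop("cells with zero library size: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "")
  }
  x <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  # scale each column by scale_factor / libsize, then log1p on nonzeros
  per_col <- rep.int(scale_factor / lib, diff(x@p))
  x@x <- log1p(x@x * per_col)
  x
}

# Row means and variances of a sparse matrix without densifying.
.sparse_row_stats <- function(m) {
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  n <- ncol(m)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' PCA embedding on highly variable genes
#'
#' Selects the `n_hvg` genes with the largest variance of normalized
#' expression, centers and unit-scales each gene, and returns the top
#' `n_pcs` principal components of the cells. Component signs follow a
#' deterministic convention: the gene loading with the largest magnitude is
#' made positive.
#'
#' @param normalized genes-by-cells normalized matrix.
#' @param n_pcs number of components (default 10).
#' @param n_hvg number of highly variable genes (default 500).
#' @return cells-by-`n_pcs` matrix with cell ids as row names.
#' @export
embed_pca <- function(normalized, n_pcs = 10, n_hvg = 500) {
  if (n_pcs <= 0) stop("n_pcs must be positive")
  if (n_pcs >= min(dim(normalized))) stop("n_pcs must be below min(genes, cells)")
  st <- .sparse_row_stats(normalized)
  n_hvg <- min(n_hvg, nrow(normalized))
  hvg <- order(st$var, decreasing = TRUE)[seq_len(n_hvg)]
  m <- as.matrix(normalized[hvg, , drop = FALSE])
  sds <- sqrt(st$var[hvg])
  ok <- sds > 0
  m <- (m[ok, , drop = FALSE] - st$mean[hvg][ok]) / sds[ok]
  pc <- stats::prcomp(t(m), center = FALSE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  for (j in seq_len(ncol(emb))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- colnames(normalized)
  emb
}

#' OPC root score
#'
#' Mean normalized expression of the progenitor markers per cell; used to
#' anchor the trajectory at the OPC state.
#'
#' @param normalized genes-by-cells normalized matrix.
#' @param marker_symbols progenitor marker symbols; markers absent from the
#'   matrix are dropped with a warning.
#' @return numeric per-cell score.
#' @export
opc_root_score <- function(normalized, marker_symbols) {
  present <- intersect(marker_symbols, rownames(normalized))
  missing <- setdiff(marker_symbols, present)
  if (length(missing) > 0)
    warning("markers absent from matrix: ", paste(missing, collapse = ", "))
  if (length(present) == 0)
    stop("none of the root markers are present in the matrix")
  score <- Matrix::colMeans(normalized[present, , drop = FALSE])
  stats::setNames(as.numeric(score), colnames(normalized))
}

#' Select trajectory root cells and root node
#'
#' Cells in the top `fraction` of the root score form the root set; the root
#' node is the single cell nearest (Euclidean, in the embedding) to the
#' centroid of that set.
#'
#' @param root_score per-cell numeric score.
#' @param embedding cells-by-PCs matrix aligned with `root_score`.
#' @param fraction top fraction of cells to keep (default 0.10).
#' @return list with `root_cells` (integer indices), `root_node` (single
#'   index), `threshold`.
#' @export
select_root <- function(root_score, embedding, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1, length(root_score) == nrow(embedding))
  n <- length(root_score)
  if (length(unique(root_score)) == 1) {
    warning("constant root score; taking the first cells in index order")
    root_cells <- seq_len(max(1, ceiling(fraction * n)))
  } else {
    thr <- stats::quantile(root_score, 1 - fraction, names = FALSE)
    root_cells <- which(root_score >= thr)
  }
  centroid <- colMeans(embedding[root_cells, , drop = FALSE])
  d2 <- rowSums(sweep(embedding, 2, centroid)^2)
  root_node <- which.min(d2)
  list(root_cells = root_cells, root_node = root_node,
       threshold = if (exists("thr", inherits = FALSE)) thr else NA_real_)
}

#' Graph-geodesic pseudotime from a root cell
#'
#' Builds a symmetric k-nearest-neighbor graph on the embedding with
#' Euclidean edge weights and takes shortest-path distance from the root cell
#' as pseudotime. If the graph is disconnected, k is doubled until it
#' connects (each escalation is reported via `message()`). Pseudotime is also
#' returned min-max scaled to \[0,1\].
#'
#' @param embedding cells-by-PCs matrix.
#' @param root_node integer index of the root cell.
#' @param k_neighbors initial neighborhood size (default 15).
#' @return list with `pseudotime`, `pseudotime_norm`, and the final `k`.
#' @export
compute_pseudotime <- function(embedding, root_node, k_neighbors = 15) {
  n <- nrow(embedding)
  if (n < 2) stop("need at least two cells to compute pseudotime")
  D <- as.matrix(stats::dist(embedding))
  k <- min(max(1, k_neighbors), n - 1)
  repeat {
    nn <- apply(D, 1, function(row) order(row)[2:(k + 1)])  # (k x n), self excluded
    from <- rep(seq_len(n), each = k)
    to <- as.vector(nn)
    w <- D[cbind(from, to)]
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, weight = w),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
    if (igraph::is_connected(g) || k >= n - 1) break
    k <- min(2 * k, n - 1)
    message("kNN graph disconnected; escalating k to ", k)
  }
  if (!igraph::is_connected(g))
    stop("kNN graph cannot be connected even at k = n - 1")
  pt <- as.numeric(igraph::distances(g, v = as.character(root_node),
                                     weights = igraph::E(g)$weight))
  names(pt) <- rownames(embedding)
  rng <- range(pt)
  if (rng[1] == rng[2]) stop("degenerate pseudotime (all cells equidistant)")
  list(pseudotime = pt, pseudotime_norm = (pt - rng[1]) / (rng[2] - rng[1]), k = k)
}

#' Denoise an embedding by local neighbor averaging
#'
#' Replaces each cell's coordinates by the mean over itself and its k nearest
#' neighbors. This is the discrete analogue of projecting cells onto a
#' principal curve: orthogonal sampling noise shrinks while the position
#' along the trajectory is preserved. Being a linear, distance-based map it
#' commutes with uniform scaling of the embedding.
#'
#' @param embedding cells-by-PCs matrix.
#' @param k neighborhood size (default 15).
#' @return smoothed matrix of the same shape.
#' @export
smooth_embedding <- function(embedding, k = 15) {
  n <- nrow(embedding)
  k <- min(k, n - 1)
  D <- as.matrix(stats::dist(embedding))
  nn <- apply(D, 1, function(row) order(row)[seq_len(k + 1)])  # includes self
  out <- t(apply(nn, 2, function(ix) colMeans(embedding[ix, , drop = FALSE])))
  dimnames(out) <- dimnames(embedding)
  out
}

#' Run the full trajectory step on one dataset
#'
#' Normalizes, embeds, optionally denoises the embedding, scores and selects
#' the root, and computes normalized pseudotime; results are stored in the
#' dataset's `cell_meta`.
#'
#' @param ds a harmonized [species_dataset()].
#' @param markers progenitor marker symbols for the root score.
#' @param n_pcs,n_hvg,k_neighbors,root_fraction see the underlying functions.
#' @param smooth logical; denoise the embedding by one pass of
#'   [smooth_embedding()] with `k_neighbors` neighbors before the graph is
#'   built (default TRUE).
#' @return the dataset with `normalized` filled and `cell_meta` gaining
#'   `root_score`, `pseudotime`, `pseudotime_norm`; the embedding and root
#'   info are attached as `ds$embedding` and `ds$root`.
#' @export
run_trajectory <- function(ds, markers = stage_gene_sets()$opc, n_pcs = 10,
                           n_hvg = 500, k_neighbors = 15, root_fraction = 0.10,
                           smooth = TRUE) {
  ds <- lognormalize(ds)
  emb <- embed_pca(ds$normalized, n_pcs = n_pcs, n_hvg = n_hvg)
  if (smooth) emb <- smooth_embedding(emb, k = k_neighbors)
  score <- opc_root_score(ds$normalized, markers)
  root <- select_root(score, emb, fraction = root_fraction)
  pt <- compute_pseudotime(emb, root$root_node, k_neighbors = k_neighbors)
  ds$embedding <- emb
  ds$root <- root
  ds$cell_meta$root_score <- as.numeric(score)
  ds$cell_meta$pseudotime <- as.numeric(pt$pseudotime)
  ds$cell_meta$pseudotime_norm <- as.numeric(pt$pseudotime_norm)
  ds
}

#' Min-max normalize pseudotime within each species
#'
#' Cross-species comparability is by relative trajectory position only, so
#' each species' pseudotime is independently scaled to \[0,1\].
#'
#' @param datasets named list of datasets whose `cell_meta` has `pseudotime`.
#' @return the list with `pseudotime_norm` (re)computed per species.
#' @export
normalize_pseudotime_atlas <- function(datasets) {
  lapply(datasets, function(ds) {
    pt <- ds$cell_meta$pseudotime
    if (is.null(pt)) stop("pseudotime missing for species ", ds$species)
    rng <- range(pt)
    if (rng[1] == rng[2]) stop("constant pseudotime for species ", ds$species)
    ds$cell_meta$pseudotime_norm <- (pt - rng[1]) / (rng[2] - rng[1])
    ds
  })
}
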