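#' Reference stage centroids
#'
#' Mean normalized expression per stage over the reference cells, restricted
#' to the supplied feature symbols.
#'
#' @param reference_normalized genes-by-cells normalized reference matrix.
#' @param reference_stage_labels per-cell stage labels (OPC/COP/MOL).
#' @param feature_symbols features to use (must be rows of the reference).
#' @return stages-by-features numeric matrix.
#' @export
stage_centroids <- function(reference_normalized, reference_stage_labels,
                            feature_symbols) {
  stages <- .stage_levels[.stage_levels %in% unique(as.character(reference_stage_labels))]
  absent <- setdiff(.stage_levels, stages)
  if (length(absent) > 0)
    stop("reference is missing stage(s): ", paste(absent, collapse = ", "))
  feats <- intersect(feature_symbols, rownames(reference_normalized))
  if (length(feats) < 2) stop("fewer than 2 features present in the reference")
  m <- reference_normalized[feats, , drop = FALSE]
  cent <- t(vapply(.stage_levels, function(st) {
    cols <- reference_stage_labels == st
    if (sum(cols) < 3)
      warning("stage ", st, " has fewer than 3 reference cells")
    as.numeric(Matrix::rowMeans(m[, cols, drop = FALSE]))
  }, numeric(length(feats))))
  dimnames(cent) <- list(.stage_levels, feats)
  cent
}

#' Centroid prediction scores for query cells
#'
#' Correlates each query cell with each reference stage centroid over the
#' shared features (Spearman by default, robust to depth differences) and
#' converts correlations into probabilities with a softmax at the given
#' temperature. Constant (zero-variance) query cells get a uniform row and
#' are flagged.
#'
#' @param query_normalized genes-by-cells normalized query matrix.
#' @param centroids stages-by-features matrix from [stage_centroids()].
#' @param temperature softmax temperature (default 0.02, calibrated on the
#'   default synthetic atlas so that clearly within-stage OPC and MOL query
#'   cells assign most of their probability mass to their own stage); lower
#'   is sharper.
#' @param method correlation method, `"spearman"` (default) or `"pearson"`.
#' @param query_stage_labels optional per-cell query stage labels; when given,
#'   the stage-by-stage heatmap of mean probabilities is computed.
#' @return object of class `prediction_scores`: list with `per_cell`
#'   (query cells x reference stages probabilities), `heatmap` (query stages
#'   x reference stages, or NULL), `shared_features`, `flat_cells` (indices
#'   of zero-variance cells).
#' @export
predict_scores <- function(query_normalized, centroids, temperature = 0.02,
                           method = c("spearman", "pearson"),
                           query_stage_labels = NULL) {
  method <- match.arg(method)
  shared <- intersect(colnames(centroids), rownames(query_normalized))
  if (length(shared) < 2) stop("fewer than 2 shared features with the reference")
  q <- as.matrix(query_normalized[shared, , drop = FALSE])
  cmat <- t(centroids[, shared, drop = FALSE])  # features x stages
  if (method == "spearman") {
    q <- apply(q, 2, rank)
    cmat <- apply(cmat, 2, rank)
  }
  flat <- which(apply(q, 2, stats::sd) == 0)
  cors <- suppressWarnings(stats::cor(q, cmat))  # cells x stages
  cors[is.na(cors)] <- 0
  # temperature-scaled softmax, numerically stable; temperature -> 0 gives a
  # one-hot argmax row, -> Inf a uniform row
  logits <- cors / max(temperature, .Machine$double.eps)
  logits <- logits - apply(logits, 1, max)
  ex <- exp(logits)
  probs <- ex / rowSums(ex)
  if (length(flat) > 0) probs[flat, ] <- 1 / ncol(probs)
  dimnames(probs) <- list(colnames(query_normalized), rownames(centroids))
  heatmap <- NULL
  if (!is.null(query_stage_labels)) {
    stopifnot(length(query_stage_labels) == nrow(probs))
    heatmap <- t(vapply(.stage_levels, function(st) {
      rows <- query_stage_labels == st
      if (!any(rows)) return(rep(NA_real_, ncol(probs)))
      colMeans(probs[rows, , drop = FALSE])
    }, numeric(ncol(probs))))
    dimnames(heatmap) <- list(.stage_levels, rownames(centroids))
  }
  structure(list(per_cell = probs, heatmap = heatmap,
                 shared_features = shared, flat_cells = flat),
            class = "prediction_scores")
}

#' Randomly downsample cells of a dataset
#'
#' Uniform, seeded subset of cell columns without regard to composition;
#' original column order is preserved.
#'
#' @param ds a [species_dataset()].
#' @param n number of cells to keep.
#' @param seed integer seed.
#' @return the subsetted dataset (counts, normalized matrix if present, and
#'   cell_meta rows).
#' @export
downsample_cells <- function(ds, n = 2300, seed = 0L) {
  stopifnot(inherits(ds, "species_dataset"))
  total <- ncol(ds$counts)
  if (n > total)
    stop("cannot downsample to ", n, " cells: dataset has ", total)
  keep <- sort(with_seed(seed, sample.int(total, n)))
  out <- ds
  out$counts <- ds$counts[, keep, drop = FALSE]
  if (!is.null(ds$normalized)) out$normalized <- ds$normalized[, keep, drop = FALSE]
  out$cell_ids <- ds$cell_ids[keep]
  out$cell_meta <- ds$cell_meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  if (!is.null(ds$embedding)) out$embedding <- ds$embedding[keep, , drop = FALSE]
  out
}

#' Cross-species stage mapping of one query against a reference
#'
#' Selects the reference's most variable genes intersected with the query's
#' gene space as features, builds stage centroids, and scores the query cells.
#'
#' @param reference dataset with `normalized` and `cell_meta$stage`.
#' @param query dataset with `normalized` and `cell_meta$stage`.
#' @param n_features number of reference variable genes to consider
#'   (default 500).
#' @param temperature softmax temperature.
#' @param method correlation method.
#' @return a `prediction_scores` object (heatmap rows are query stages).
#' @export
crossmap_species <- function(reference, query, n_features = 500,
                             temperature = 0.02, method = "spearman") {
  for (d in list(reference, query)) {
    if (is.null(d$normalized) || is.null(d$cell_meta$stage))
      stop("reference and query must be normalized and staged")
  }
  st <- .sparse_row_stats(reference$normalized)
  ord <- rownames(reference$normalized)[order(st$var, decreasing = TRUE)]
  feats <- intersect(ord, rownames(query$normalized))
  feats <- utils::head(feats, n_features)
  cent <- stage_centroids(reference$normalized, reference$cell_meta$stage, feats)
  predict_scores(query$normalized, cent, temperature = temperature,
                 method = method, query_stage_labels = query$cell_meta$stage)
}
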