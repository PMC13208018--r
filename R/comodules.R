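#' Pseudotime-binned pseudobulk means for one species
#'
#' Averages normalized expression of the selected genes within equal-width
#' bins of normalized pseudotime (right-closed last bin). Empty bins are
#' linearly interpolated from their neighbors and flagged.
#'
#' @param normalized genes-by-cells normalized matrix.
#' @param pseudotime_norm per-cell pseudotime in \[0,1\].
#' @param gene_subset gene symbols to include (must be rows of `normalized`).
#' @param n_bins number of bins (default 10).
#' @return genes-by-bins numeric matrix with attribute
#'   `"interpolated_bins"` (integer vector, possibly empty).
#' @export
pseudobulk_bins <- function(normalized, pseudotime_norm, gene_subset, n_bins = 10) {
  stopifnot(all(pseudotime_norm >= 0 & pseudotime_norm <= 1))
  missing <- setdiff(gene_subset, rownames(normalized))
  if (length(missing) > 0)
    stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  idx <- pmin(floor(pseudotime_norm * n_bins) + 1L, n_bins)
  m <- normalized[gene_subset, , drop = FALSE]
  out <- matrix(NA_real_, length(gene_subset), n_bins,
                dimnames = list(gene_subset, paste0("bin", seq_len(n_bins))))
  present <- sort(unique(idx))
  for (b in present) out[, b] <- Matrix::rowMeans(m[, idx == b, drop = FALSE])
  empty <- setdiff(seq_len(n_bins), present)
  if (length(empty) == n_bins) stop("all pseudotime bins are empty")
  if (length(empty) > 0) {
    for (g in seq_len(nrow(out))) {
      out[g, empty] <- stats::approx(present, out[g, present], xout = empty,
                                     rule = 2)$y
    }
  }
  attr(out, "interpolated_bins") <- as.integer(empty)
  out
}

#' Concatenate per-species pseudobulk matrices and z-score per gene
#'
#' Columns are concatenated in species order; each gene row is centered and
#' scaled by its population standard deviation across all bins and species.
#' Zero-variance rows are dropped with a warning.
#'
#' @param per_species_bins named list of genes-by-bins matrices with
#'   identical row sets.
#' @return z-scored genes-by-(species x bins) matrix; column names are
#'   `species.bin`; attribute `"species"` maps columns to species.
#' @export
zscore_concat <- function(per_species_bins) {
  stopifnot(length(per_species_bins) >= 1)
  genes <- rownames(per_species_bins[[1]])
  for (m in per_species_bins) stopifnot(identical(rownames(m), genes))
  mat <- do.call(cbind, per_species_bins)
  if (ncol(mat) < 2) stop("need at least 2 columns to z-score")
  colnames(mat) <- unlist(lapply(names(per_species_bins), function(s)
    paste(s, colnames(per_species_bins[[s]]), sep = ".")))
  mu <- rowMeans(mat)
  sd_pop <- sqrt(rowMeans((mat - mu)^2))
  degenerate <- sd_pop == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " constant gene rows dropped before z-scoring")
    mat <- mat[!degenerate, , drop = FALSE]
    mu <- mu[!degenerate]; sd_pop <- sd_pop[!degenerate]
  }
  z <- (mat - mu) / sd_pop
  attr(z, "species") <- rep(names(per_species_bins),
                            vapply(per_species_bins, ncol, integer(1)))
  z
}

#' Ward clustering of temporal profiles, cut into k modules
#'
#' Hierarchical clustering with `ward.D2` linkage on Euclidean distances
#' (i.e. Ward's variance criterion applied to unsquared Euclidean input, the
#' semantics distinguishing `ward.D2` from `ward.D`) and a flat cut into `k`
#' modules. Module ids are relabeled 1..k by descending mean expression in
#' the earliest bins (then by size), so module numbering follows temporal
#' order rather than dendrogram order.
#'
#' @param mat z-scored genes-by-columns matrix from [zscore_concat()].
#' @param k number of modules (default 4).
#' @param early_bins how many leading bins per species define "early"
#'   expression for the relabeling (default 2).
#' @return object of class `module_atlas`: list with `assignment` (named
#'   integer vector gene -> module), `k`, `dendrogram` (hclust), `sizes`.
#' @export
ward_cluster_cut <- function(mat, k = 4, early_bins = 2) {
  if (k > nrow(mat)) stop("k exceeds the number of genes")
  hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  species_of <- attr(mat, "species")
  if (is.null(species_of)) {
    early_cols <- seq_len(min(early_bins, ncol(mat)))
  } else {
    bin_index <- unlist(lapply(unique(species_of), function(s)
      seq_len(sum(species_of == s))))
    early_cols <- which(bin_index <= early_bins)
  }
  early_mean <- vapply(seq_len(k), function(cl)
    mean(mat[raw == cl, early_cols, drop = FALSE]), numeric(1))
  sizes <- as.numeric(table(factor(raw, levels = seq_len(k))))
  new_order <- order(-early_mean, -sizes)
  relabel <- integer(k); relabel[new_order] <- seq_len(k)
  assignment <- stats::setNames(relabel[raw], rownames(mat))
  structure(list(assignment = assignment, k = k, dendrogram = hc,
                 sizes = as.integer(table(factor(assignment, levels = seq_len(k))))),
            class = "module_atlas")
}

#' Module dynamics: mean z per module, species, and bin
#'
#' @param atlas a [ward_cluster_cut()] result.
#' @param mat the matrix the atlas was cut from.
#' @return data frame with `module`, `species`, `bin`, `mean_z`.
#' @export
module_dynamics <- function(atlas, mat) {
  stopifnot(inherits(atlas, "module_atlas"),
            all(names(atlas$assignment) %in% rownames(mat)))
  species_of <- attr(mat, "species")
  if (is.null(species_of)) species_of <- rep("all", ncol(mat))
  bin_of <- unlist(lapply(unique(species_of), function(s)
    seq_len(sum(species_of == s))))
  rows <- lapply(seq_len(atlas$k), function(mod) {
    members <- names(atlas$assignment)[atlas$assignment == mod]
    if (length(members) == 0) stop("module ", mod, " is empty")
    sub <- mat[members, , drop = FALSE]
    data.frame(module = mod, species = species_of, bin = bin_of,
               mean_z = colMeans(sub), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Binned LOESS expression curve of one gene along pseudotime
#'
#' Mean normalized expression in `n_bins` equal-width pseudotime bins,
#' followed by a locally weighted degree-1 regression (tricube weights,
#' `span` fraction of the bins) evaluated at all bin centers.
#'
#' @param normalized genes-by-cells normalized matrix.
#' @param gene gene symbol (one row).
#' @param pseudotime_norm per-cell pseudotime in \[0,1\].
#' @param n_bins number of bins (default 20).
#' @param span LOESS span (default 0.6).
#' @return data frame with `bin_center`, `mean_expr` (NA for empty bins),
#'   `fitted`.
#' @export
loess_curves <- function(normalized, gene, pseudotime_norm, n_bins = 20,
                         span = 0.6) {
  if (!gene %in% rownames(normalized)) stop("gene not present: ", gene)
  idx <- pmin(floor(pseudotime_norm * n_bins) + 1L, n_bins)
  v <- as.numeric(normalized[gene, ])
  means <- as.numeric(tapply(v, factor(idx, levels = seq_len(n_bins)), mean))
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  ok <- !is.na(means)
  if (sum(ok) < 5) stop("fewer than 5 non-empty pseudotime bins for ", gene)
  df <- data.frame(x = centers[ok], y = means[ok])
  fit <- stats::loess(y ~ x, data = df, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  fitted <- stats::predict(fit, newdata = data.frame(x = centers))
  data.frame(bin_center = centers, mean_expr = means, fitted = as.numeric(fitted))
}
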