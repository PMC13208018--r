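#' Expression-bin-matched module score
#'
#' Control-gene-corrected gene-set score per cell (the Tirosh scheme used by
#' standard single-cell toolkits): genes are placed into `n_bins`
#' equal-frequency bins by average normalized expression; for each set gene,
#' `n_ctrl` control genes are sampled from its bin (with replacement when the
#' bin is smaller than `n_ctrl`); the score is the mean over set genes minus
#' the mean over the pooled controls, per cell.
#'
#' @param normalized genes-by-cells normalized matrix.
#' @param gene_set character vector of gene symbols; the intersection with
#'   the matrix rows must be non-empty.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl controls sampled per set gene (default 100).
#' @param seed integer seed for control sampling.
#' @return numeric per-cell score.
#' @export
module_score <- function(normalized, gene_set, n_bins = 24, n_ctrl = 100, seed = 0L) {
  genes <- rownames(normalized)
  set_idx <- which(genes %in% gene_set)
  if (length(set_idx) == 0)
    stop("gene set has empty intersection with the matrix")
  n_bins <- min(n_bins, nrow(normalized))
  avg <- Matrix::rowMeans(normalized)
  # equal-frequency bins of the average-expression ranking
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(set_idx, function(i) {
      pool <- which(bin == bin[i])
      sample_safe(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  set_mean <- Matrix::colMeans(normalized[set_idx, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(normalized[ctrl_idx, , drop = FALSE])
  stats::setNames(as.numeric(set_mean - ctrl_mean), colnames(normalized))
}

#' Binned, smoothed module-score curves along pseudotime
#'
#' Averages each stage's per-cell scores in equal-width pseudotime bins on
#' \[0,1\], linearly interpolates empty bins, and applies a centered moving
#' average.
#'
#' @param scores named list of per-cell score vectors (one per stage).
#' @param pseudotime_norm per-cell normalized pseudotime in \[0,1\].
#' @param n_curve_bins number of bins (default 50).
#' @param smooth_window moving-average width (odd; default 3).
#' @return matrix of `n_curve_bins` rows x stages, with attribute
#'   `"midpoints"` giving bin centers.
#' @export
binned_score_curves <- function(scores, pseudotime_norm, n_curve_bins = 50,
                                smooth_window = 3) {
  stopifnot(all(pseudotime_norm >= 0 & pseudotime_norm <= 1))
  nb <- n_curve_bins
  idx <- pmin(floor(pseudotime_norm * nb) + 1L, nb)
  mids <- (seq_len(nb) - 0.5) / nb
  curves <- vapply(scores, function(sc) {
    stopifnot(length(sc) == length(pseudotime_norm))
    m <- tapply(sc, factor(idx, levels = seq_len(nb)), mean)
    m <- as.numeric(m)
    empty <- is.na(m)
    if (mean(empty) > 0.5)
      stop("more than half of the pseudotime bins are empty; use fewer bins")
    if (any(empty))
      m[empty] <- stats::approx(mids[!empty], m[!empty], xout = mids[empty],
                                rule = 2)$y
    .moving_average(m, smooth_window)
  }, numeric(nb))
  attr(curves, "midpoints") <- mids
  curves
}

# Centered moving average; edge bins average over the available window, so a
# constant curve is left exactly unchanged.
.moving_average <- function(x, w) {
  if (w <= 1) return(x)
  h <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Stage boundaries from module-score crossovers
#'
#' The OPC/COP boundary is the midpoint of the first bin where the COP curve
#' meets or exceeds the OPC curve for at least two consecutive bins; the
#' COP/MOL boundary likewise for MOL over COP, searched only beyond the first
#' boundary. When a crossing is absent the boundary falls back to the bin
#' minimizing the absolute curve difference, with a flag; if the second
#' boundary does not exceed the first it is pushed one bin width later, with
#' a flag.
#'
#' @param curves matrix from [binned_score_curves()] with columns `opc`,
#'   `cop`, `mol`.
#' @return object of class `stage_boundaries`: list with `b1`, `b2`,
#'   `curves`, `flags` (character vector).
#' @export
find_crossovers <- function(curves) {
  stopifnot(all(c("opc", "cop", "mol") %in% colnames(curves)))
  mids <- attr(curves, "midpoints")
  if (is.null(mids)) mids <- (seq_len(nrow(curves)) - 0.5) / nrow(curves)
  binw <- if (nrow(curves) > 1) mids[2] - mids[1] else 1
  flags <- character(0)

  first_sustained <- function(ge) {
    # first index where ge holds for >= 2 consecutive bins (or the final bin)
    n <- length(ge)
    for (i in seq_len(n)) {
      if (ge[i] && (i == n || ge[i + 1])) return(i)
    }
    NA_integer_
  }

  i1 <- first_sustained(curves[, "cop"] >= curves[, "opc"])
  if (is.na(i1)) {
    flags <- c(flags, "no_crossing_opc_cop")
    i1 <- which.min(abs(curves[, "cop"] - curves[, "opc"]))
  }
  b1 <- mids[i1]

  later <- which(mids > b1)
  if (length(later) == 0) later <- nrow(curves)
  ge2 <- curves[later, "mol"] >= curves[later, "cop"]
  j <- first_sustained(ge2)
  if (is.na(j)) {
    flags <- c(flags, "no_crossing_cop_mol")
    j <- which.min(abs(curves[later, "mol"] - curves[later, "cop"]))
  }
  b2 <- mids[later[j]]
  if (b2 <= b1) {
    flags <- c(flags, "boundary_order_forced")
    b2 <- b1 + binw
  }
  structure(list(b1 = b1, b2 = b2, curves = curves, flags = flags),
            class = "stage_boundaries")
}

#' Assign stage labels from pseudotime and boundaries
#'
#' OPC below the first boundary, COP up to (excluding) the second, MOL at and
#' beyond the second (the top interval is right-closed).
#'
#' @param pseudotime_norm per-cell normalized pseudotime.
#' @param boundaries a [find_crossovers()] result (or list with `b1`, `b2`).
#' @return factor of stage labels with levels OPC, COP, MOL.
#' @export
assign_stages <- function(pseudotime_norm, boundaries) {
  stopifnot(boundaries$b1 < boundaries$b2)
  factor(ifelse(pseudotime_norm < boundaries$b1, "OPC",
                ifelse(pseudotime_norm < boundaries$b2, "COP", "MOL")),
         levels = .stage_levels)
}

#' Run module-score staging on one dataset
#'
#' Computes the three stage module scores, their binned curves along
#' normalized pseudotime, the crossover boundaries, and per-cell stage
#' labels (stored in `cell_meta$stage`).
#'
#' @param ds dataset with `normalized` and `cell_meta$pseudotime_norm`.
#' @param gene_sets a [stage_gene_sets()] list.
#' @param n_bins,n_ctrl module-score binning parameters.
#' @param n_curve_bins,smooth_window curve parameters.
#' @param seed seed for control-gene sampling.
#' @return the dataset with `cell_meta$stage` plus `ds$boundaries` and
#'   `ds$stage_scores`.
#' @export
run_staging <- function(ds, gene_sets = stage_gene_sets(), n_bins = 24,
                        n_ctrl = 100, n_curve_bins = 50, smooth_window = 3,
                        seed = 0L) {
  if (is.null(ds$normalized)) stop("dataset must be normalized first")
  pt <- ds$cell_meta$pseudotime_norm
  if (is.null(pt)) stop("pseudotime_norm missing; run the trajectory step first")
  scores <- lapply(seq_along(gene_sets), function(i) {
    module_score(ds$normalized, gene_sets[[i]], n_bins = n_bins,
                 n_ctrl = n_ctrl, seed = child_seed(seed, i))
  })
  names(scores) <- names(gene_sets)
  curves <- binned_score_curves(scores, pt, n_curve_bins = n_curve_bins,
                                smooth_window = smooth_window)
  bounds <- find_crossovers(curves)
  ds$cell_meta$stage <- as.character(assign_stages(pt, bounds))
  ds$boundaries <- bounds
  ds$stage_scores <- scores
  ds
}
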