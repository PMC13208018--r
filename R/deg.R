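#' Exact two-sided Mann-Whitney p by enumeration
#'
#' Enumerates all assignments of the pooled values to a group of size `n1`
#' and returns the probability of a U statistic at least as far from its null
#' mean as the observed one. Handles ties exactly. Intended for small groups
#' (both sizes <= 8).
#'
#' @param x,y numeric vectors (group values).
#' @return two-sided exact p-value.
#' @keywords internal
.wilcox_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- n1 * n2 / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Tie-corrected normal approximation (with continuity correction) for the
# two-sided Mann-Whitney test, given pooled ranks and group-1 rank sum.
.wilcox_normal_p <- function(r1_sum, n1, n2, tie_table) {
  n <- n1 + n2
  u <- r1_sum - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_term <- sum(tie_table^3 - tie_table)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' One-vs-rest Wilcoxon rank-sum test per gene
#'
#' Two-sided Mann-Whitney test of the cells in `stage` against all other
#' cells, per gene. Uses exact enumeration when both groups have at most
#' `exact_max` cells, and a tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param normalized genes-by-cells matrix (any matrix-like with rownames).
#' @param stage_labels per-cell stage labels.
#' @param stage the stage to contrast against the rest.
#' @param exact_max largest group size for exact enumeration (default 8).
#' @return data frame with columns `gene`, `statistic` (U), `p_value`.
#' @export
wilcoxon_one_vs_rest <- function(normalized, stage_labels, stage, exact_max = 8) {
  in_grp <- stage_labels == stage
  n1 <- sum(in_grp); n2 <- sum(!in_grp)
  if (n1 == 0) stop("stage '", stage, "' has no cells")
  if (n1 < 3 || n2 < 3) stop("each group needs at least 3 cells")
  m <- as.matrix(normalized)
  exact <- max(n1, n2) <= exact_max
  genes <- rownames(m)
  if (exact) {
    p <- apply(m, 1, function(v) .wilcox_exact_p(v[in_grp], v[!in_grp]))
    u <- apply(m, 1, function(v) {
      r <- rank(v); sum(r[in_grp]) - n1 * (n1 + 1) / 2
    })
  } else {
    ranks <- t(apply(m, 1, rank))
    r1 <- rowSums(ranks[, in_grp, drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    p <- vapply(seq_len(nrow(m)), function(i) {
      tie_table <- table(m[i, ])
      .wilcox_normal_p(r1[i], n1, n2, as.numeric(tie_table))
    }, numeric(1))
  }
  data.frame(gene = genes, statistic = as.numeric(u), p_value = as.numeric(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Log2 fold change with unit pseudocount
#'
#' `log2((mean_in + 1) / (mean_out + 1))`, with means on the expm1 scale of
#' the normalized data (the convention of the standard single-cell marker
#' test).
#'
#' @param mean_in,mean_out nonnegative group means.
#' @return numeric log2 fold change.
#' @export
log2_fold_change <- function(mean_in, mean_out) {
  if (any(mean_in < 0) || any(mean_out < 0)) stop("means must be nonnegative")
  log2((mean_in + 1) / (mean_out + 1))
}

#' Call stage-enriched genes for one species
#'
#' For each stage, tests every gene one-vs-rest (Wilcoxon), computes the
#' expm1-scale log2 fold change and expression fractions, applies multiple
#' testing correction, and keeps genes that are significantly upregulated in
#' the stage: adjusted p below `alpha`, log2 fold change above `lfc_min`, and
#' `max(pct_in, pct_out)` above `min_pct`.
#'
#' @param normalized genes-by-cells normalized matrix, already restricted to
#'   the gene universe of interest (typically the common ortholog set).
#' @param stage_labels per-cell stage labels.
#' @param species species label recorded in the output.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc_min log2 fold-change threshold (default 0.25).
#' @param min_pct expression-fraction threshold (default 0.1).
#' @param correction multiple-testing method (default `"bonferroni"`),
#'   applied across the tested genes within each stage.
#' @return data frame of DEG records (`species`, `gene`, `stage`, `log2fc`,
#'   `p_value`, `p_adjusted`, `pct_in`, `pct_out`) with attribute
#'   `"dynamic_genes"`: the union of passing genes over the three stages.
#' @export
call_stage_degs <- function(normalized, stage_labels, species = "unknown",
                            alpha = 0.05, lfc_min = 0.25, min_pct = 0.1,
                            correction = "bonferroni") {
  if (nrow(normalized) == 0) stop("empty gene universe")
  stages <- intersect(.stage_levels, unique(as.character(stage_labels)))
  m <- as.matrix(normalized)
  expr_frac <- function(cols) rowMeans(m[, cols, drop = FALSE] > 0)
  expm1_mean <- function(cols) rowMeans(expm1(m[, cols, drop = FALSE]))
  records <- lapply(stages, function(st) {
    in_grp <- stage_labels == st
    if (sum(in_grp) < 3 || sum(!in_grp) < 3) {
      warning("skipping stage ", st, " for ", species, ": too few cells")
      return(NULL)
    }
    wt <- wilcoxon_one_vs_rest(normalized, stage_labels, st)
    lfc <- log2_fold_change(expm1_mean(in_grp), expm1_mean(!in_grp))
    pin <- expr_frac(in_grp); pout <- expr_frac(!in_grp)
    padj <- stats::p.adjust(wt$p_value, method = correction)
    keep <- padj < alpha & lfc > lfc_min & pmax(pin, pout) > min_pct
    data.frame(species = species, gene = wt$gene, stage = st,
               log2fc = lfc, p_value = wt$p_value, p_adjusted = padj,
               pct_in = pin, pct_out = pout,
               row.names = NULL, stringsAsFactors = FALSE)[keep, ]
  })
  out <- do.call(rbind, records)
  if (is.null(out)) out <- data.frame(species = character(0), gene = character(0),
                                      stage = character(0), log2fc = numeric(0),
                                      p_value = numeric(0), p_adjusted = numeric(0),
                                      pct_in = numeric(0), pct_out = numeric(0))
  rownames(out) <- NULL
  attr(out, "dynamic_genes") <- sort(unique(out$gene))
  out
}

#' Transcription-factor conservation across species
#'
#' Restricts DEG records to a supplied TF symbol list, counts per (TF, stage)
#' the number of species detecting it, classifies TFs as `shared` (detected
#' in at least `shared_min` species in the same stage) or `species_specific`
#' (exactly one species, in that stage), and ranks the top species-specific
#' TFs per species by log2 fold change.
#'
#' @param deg_tables list of per-species DEG data frames (or one combined
#'   data frame with a `species` column).
#' @param tf_symbols character vector of TF gene symbols.
#' @param shared_min species count for the `shared` class (default 4).
#' @param top_n_specific species-specific TFs reported per species (default 5).
#' @return list with `by_stage` (TF x stage detection counts and class) and
#'   `top_specific` (per-species top species-specific TFs).
#' @export
tf_conservation <- function(deg_tables, tf_symbols, shared_min = 4,
                            top_n_specific = 5) {
  if (length(tf_symbols) == 0) stop("empty TF list")
  deg <- if (is.data.frame(deg_tables)) deg_tables else do.call(rbind, deg_tables)
  tf <- deg[deg$gene %in% tf_symbols, , drop = FALSE]
  if (nrow(tf) == 0) {
    return(list(by_stage = data.frame(gene = character(0), stage = character(0),
                                      n_species = integer(0), class = character(0)),
                top_specific = data.frame()))
  }
  agg <- stats::aggregate(species ~ gene + stage, data = tf,
                          FUN = function(s) length(unique(s)))
  names(agg)[names(agg) == "species"] <- "n_species"
  agg$class <- ifelse(agg$n_species >= shared_min, "shared",
                      ifelse(agg$n_species == 1, "species_specific", "intermediate"))
  specific_keys <- paste(agg$gene, agg$stage)[agg$class == "species_specific"]
  sp <- tf[paste(tf$gene, tf$stage) %in% specific_keys, , drop = FALSE]
  top <- do.call(rbind, lapply(split(sp, sp$species), function(d) {
    d <- d[order(-d$log2fc), ]
    utils::head(d[, c("species", "gene", "stage", "log2fc")], top_n_specific)
  }))
  if (is.null(top)) top <- data.frame()
  rownames(top) <- NULL
  list(by_stage = agg[order(agg$gene, agg$stage), ], top_specific = top)
}
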