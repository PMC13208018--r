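#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' that seeded operations (module-score control sampling, downsampling) do
#' not perturb the randomness of surrounding code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a run seed
#'
#' Fixed per-stage offsets decouple the random streams of pipeline stages:
#' changing one stage's parameters does not perturb another stage's draws.
#'
#' @param seed integer run seed.
#' @param offset fixed integer offset identifying the stage.
#' @return integer seed below 2^31.
#' @keywords internal
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L))
}

#' Adjusted Rand index between two partitions
#'
#' Standard pair-counting agreement between two labelings of the same items,
#' corrected for chance. Used to score module recovery against planted
#' temporal shapes.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar; 1 for identical partitions, ~0 at random.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Precision/recall F1 between a predicted and a true gene set
#'
#' @param predicted,truth character vectors of gene symbols.
#' @return numeric F1 (0 when either set is empty and the other is not).
#' @export
set_f1 <- function(predicted, truth) {
  predicted <- unique(predicted)
  truth <- unique(truth)
  if (length(predicted) == 0 && length(truth) == 0) return(1)
  tp <- length(intersect(predicted, truth))
  if (tp == 0) return(0)
  precision <- tp / length(predicted)
  recall <- tp / length(truth)
  2 * precision * recall / (precision + recall)
}

# Sample that never interprets a length-1 x as 1:x.
sample_safe <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Spearman rank correlation (thin wrapper kept for readability).
spearman <- function(x, y) stats::cor(x, y, method = "spearman")
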