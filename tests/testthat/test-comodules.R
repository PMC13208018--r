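test_that("pseudobulk bins average within equal-width pseudotime intervals", {
  n <- 5000
  pt <- seq(0, 1, length.out = n)
  m <- Matrix::Matrix(matrix(pt, nrow = 1, dimnames = list("g1", paste0("c", 1:n))),
                      sparse = TRUE)
  pb <- pseudobulk_bins(m, pt, "g1", n_bins = 10)
  expect_equal(as.numeric(pb), seq(0.05, 0.95, by = 0.1), tolerance = 1e-3)
  # constant gene stays constant; one cell per bin reproduces those cells
  m2 <- Matrix::Matrix(matrix(2, 1, 10, dimnames = list("g1", paste0("c", 1:10))),
                       sparse = TRUE)
  pt2 <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(pseudobulk_bins(m2, pt2, "g1") == 2))
  m3 <- Matrix::Matrix(matrix(1:10, 1, 10, dimnames = dimnames(m2)), sparse = TRUE)
  expect_equal(as.numeric(pseudobulk_bins(m3, pt2, "g1")), 1:10)
  # empty bins are interpolated and flagged
  pt4 <- c(0.05, 0.05, 0.95)
  m4 <- Matrix::Matrix(matrix(c(0, 0, 9), 1, dimnames = list("g1", paste0("c", 1:3))),
                       sparse = TRUE)
  pb4 <- pseudobulk_bins(m4, pt4, "g1", n_bins = 10)
  expect_equal(length(attr(pb4, "interpolated_bins")), 8)
  expect_equal(as.numeric(pb4), seq(0, 9, by = 1))
  expect_error(pseudobulk_bins(m4, pt4, "missing"), "absent")
})

test_that("z-scoring uses the population sd across all concatenated bins", {
  m <- matrix(c(0, 1), 1, dimnames = list("g1", NULL))
  z <- zscore_concat(list(s1 = m[, 1, drop = FALSE], s2 = m[, 2, drop = FALSE]))
  expect_equal(as.numeric(z), c(-1, 1))
  expect_warning(
    z2 <- zscore_concat(list(s1 = matrix(c(1, 2), 2, 1,
                                         dimnames = list(c("a", "b"), NULL)),
                             s2 = matrix(c(1, 5), 2, 1,
                                         dimnames = list(c("a", "b"), NULL)))),
    "constant")
  expect_equal(rownames(z2), "b")
  expect_lt(abs(mean(z2)), 1e-12)
})

test_that("ward cut separates orthogonal temporal patterns exactly", {
  base <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  m <- base[rep(1:4, each = 2), ]
  rownames(m) <- paste0("g", 1:8)
  atlas <- ward_cluster_cut(m, k = 4)
  expect_equal(atlas$sizes, rep(2L, 4))
  expect_equal(adjusted_rand_index(atlas$assignment, rep(1:4, each = 2)), 1)
  # k = 1 puts everything together; k beyond the gene count errors
  expect_true(all(ward_cluster_cut(m, k = 1)$assignment == 1))
  expect_error(ward_cluster_cut(m, k = 9), "exceeds")
})

test_that("module recovery is invariant to gene row order", {
  res <- tiny_pipeline()
  z <- res$modules$matrix
  ref <- res$modules$atlas$assignment
  set.seed(8)
  for (i in 1:5) {
    perm <- sample(nrow(z))
    zp <- z[perm, ]
    attr(zp, "species") <- attr(z, "species")
    got <- ward_cluster_cut(zp, k = 4)$assignment
    expect_equal(adjusted_rand_index(got[names(ref)], ref), 1)
  }
})

test_that("module dynamics are member means and conserve the column mean", {
  res <- tiny_pipeline()
  z <- res$modules$matrix
  atlas <- res$modules$atlas
  dyn <- res$modules$dynamics
  # single-module weighted mean per column equals the overall column mean
  w <- atlas$sizes / sum(atlas$sizes)
  col1 <- dyn[dyn$species == attr(z, "species")[1] & dyn$bin == 1, ]
  expect_equal(sum(col1$mean_z * w[col1$module]), mean(z[, 1]))
  # a planted late-rising module increases across bins in every species
  g <- res$truth$genes
  lr_mod <- unique(atlas$assignment[names(atlas$assignment) %in%
                                      g$symbol[g$shape == "late_rising"]])
  expect_length(lr_mod, 1)
  for (sp in unique(dyn$species)) {
    d <- dyn[dyn$module == lr_mod & dyn$species == sp, ]
    expect_gte(cor(d$mean_z, d$bin, method = "spearman"), 0.9)
  }
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(10)
  for (i in 1:5) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("degree-1 LOESS reproduces linear input and tracks a noisy sigmoid", {
  n <- 4000
  pt <- seq(0, 1, length.out = n)
  lin <- Matrix::Matrix(matrix(2 * pt + 1, 1, dimnames = list("g1", paste0("c", 1:n))),
                        sparse = TRUE)
  fit <- loess_curves(lin, "g1", pt)
  # bin means of a line are linear up to grid-edge effects of order 1/n
  expect_equal(fit$fitted, 2 * fit$bin_center + 1, tolerance = 1e-3)
  cst <- Matrix::Matrix(matrix(3, 1, n, dimnames = dimnames(lin)), sparse = TRUE)
  expect_true(all(abs(loess_curves(cst, "g1", pt)$fitted - 3) < 1e-9))
  # noisy sigmoid: fitted curve within 0.1 RMS of the noiseless curve
  set.seed(15)
  sig <- plogis((pt - 0.5) / 0.1)
  noisy <- Matrix::Matrix(matrix(sig + rnorm(n, sd = 0.3), 1,
                                 dimnames = dimnames(lin)), sparse = TRUE)
  fit2 <- loess_curves(noisy, "g1", pt)
  truth <- plogis((fit2$bin_center - 0.5) / 0.1)
  expect_lt(sqrt(mean((fit2$fitted - truth)^2)), 0.1)
  expect_error(loess_curves(lin, "g1", rep(0.5, n)), "non-empty")
})
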