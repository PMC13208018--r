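mk_norm <- function(m, genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  dimnames(m) <- list(genes, paste0("c", seq_len(ncol(m))))
  m
}

test_that("exact Wilcoxon p matches enumeration on the canonical example", {
  m <- mk_norm(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1))
  labels <- c("OPC", "OPC", "OPC", "MOL", "MOL", "MOL")
  res <- wilcoxon_one_vs_rest(m, labels, "OPC")
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)  # U = 0, 2/20 splits
  # fully tied data: p = 1
  m2 <- mk_norm(matrix(rep(2, 6), nrow = 1))
  expect_equal(wilcoxon_one_vs_rest(m2, labels, "OPC")$p_value, 1)
  # swapping group labels leaves the two-sided p unchanged
  res_swap <- wilcoxon_one_vs_rest(m, labels, "MOL")
  expect_equal(res$p_value, res_swap$p_value)
})

test_that("exact path equals the enumeration oracle, with and without ties", {
  set.seed(11)
  for (n1 in 3:6) for (rep in 1:3) {
    n2 <- sample(3:6, 1)
    x <- sample(1:4, n1, replace = TRUE)   # heavy ties
    y <- sample(2:6, n2, replace = TRUE)
    m <- mk_norm(matrix(c(x, y), nrow = 1))
    labels <- c(rep("OPC", n1), rep("MOL", n2))
    p_impl <- wilcoxon_one_vs_rest(m, labels, "OPC")$p_value
    expect_equal(p_impl, enum_wilcox_p(x, y), tolerance = 1e-12)
  }
  # without ties, base wilcox.test's exact p is an independent oracle
  for (rep in 1:5) {
    x <- rnorm(5); y <- rnorm(6)
    m <- mk_norm(matrix(c(x, y), nrow = 1))
    labels <- c(rep("A", 5), rep("B", 6))
    p_impl <- wilcoxon_one_vs_rest(m, labels, "A")$p_value
    expect_equal(p_impl, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal approximation stays within 0.05 of the exact p for small groups", {
  set.seed(12)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    m <- mk_norm(matrix(c(x, y), nrow = 1))
    labels <- c(rep("A", 6), rep("B", 6))
    p_exact <- wilcoxon_one_vs_rest(m, labels, "A", exact_max = 8)$p_value
    p_norm <- wilcoxon_one_vs_rest(m, labels, "A", exact_max = 0)$p_value
    expect_lt(abs(p_exact - p_norm), 0.05)
  }
  # large-sample path agrees closely with base R's corrected normal approx
  set.seed(13)
  x <- rnorm(40); y <- rnorm(50) + 0.5
  m <- mk_norm(matrix(c(x, y), nrow = 1))
  labels <- c(rep("A", 40), rep("B", 50))
  p_impl <- wilcoxon_one_vs_rest(m, labels, "A")$p_value
  p_base <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_impl, p_base, tolerance = 1e-10)
})

test_that("log2 fold change uses unit pseudocounts", {
  expect_equal(log2_fold_change(3, 1), 1)
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(-1, 0), "nonnegative")
})

test_that("stage DEG calling keeps exactly the constructed positives", {
  set.seed(14)
  n_per <- 40
  labels <- rep(c("OPC", "COP", "MOL"), each = n_per)
  base <- matrix(rpois(6 * 3 * n_per, 3), nrow = 6)
  # genes 1 and 2 strongly up in OPC; the rest exchangeable
  base[1, labels == "OPC"] <- base[1, labels == "OPC"] + 30
  base[2, labels == "OPC"] <- base[2, labels == "OPC"] + 25
  norm <- lognormalize(Matrix::Matrix(mk_norm(base), sparse = TRUE))
  deg <- call_stage_degs(norm, labels, species = "toy")
  opc_hits <- deg$gene[deg$stage == "OPC"]
  expect_setequal(opc_hits, c("g1", "g2"))
  expect_true(all(deg$p_adjusted >= deg$p_value))
  expect_true(all(deg$log2fc > 0.25))
  # impossible threshold empties the table
  deg0 <- call_stage_degs(norm, labels, species = "toy", alpha = 0)
  expect_equal(nrow(deg0), 0)
  expect_error(call_stage_degs(norm[0, ], labels), "empty gene universe")
})

test_that("on synthetic data no gene is enriched in all three stages", {
  res <- tiny_pipeline()
  deg <- res$deg
  per_species_stage_counts <- tapply(deg$stage, list(deg$gene, deg$species),
                                     function(s) length(unique(s)))
  expect_true(all(per_species_stage_counts <= 2, na.rm = TRUE))
})

test_that("planted dynamic genes are recovered in their peak stage", {
  res <- tiny_pipeline()
  tr <- res$truth
  for (sp in c("chicken", "human")) {
    deg_sp <- res$deg[res$deg$species == sp, ]
    planted <- tr$genes[!is.na(tr$genes$shape) & tr$dynamic[, sp] &
                          tr$genes$symbol %in% res$common_genes, ]
    hit <- mapply(function(g, st) any(deg_sp$gene == g & deg_sp$stage == st),
                  planted$symbol, planted$peak_stage)
    expect_gt(mean(hit), 0.8)
  }
})

test_that("TF conservation classifies by same-stage species counts", {
  rec <- function(sp, gene, stage, lfc) data.frame(
    species = sp, gene = gene, stage = stage, log2fc = lfc,
    p_value = 1e-10, p_adjusted = 1e-8, pct_in = 0.5, pct_out = 0.1)
  deg <- rbind(
    rec(c("s1", "s2", "s3", "s4"), "TfA", "OPC", 1),         # shared at OPC
    rec(c("s1", "s2", "s3"), "TfB", "OPC", 1),               # 3 at OPC...
    rec(c("s4", "s5"), "TfB", "MOL", 1),                     # ...2 at MOL
    rec("s1", paste0("Tf", letters[3:9]), "MOL", seq(7, 1))) # 7 specific in s1
  tf <- tf_conservation(deg, unique(deg$gene))
  by <- tf$by_stage
  expect_equal(by$class[by$gene == "TfA"], "shared")
  expect_false(any(by$class[by$gene == "TfB"] == "shared"))
  top1 <- tf$top_specific[tf$top_specific$species == "s1", ]
  expect_equal(nrow(top1), 5)
  expect_equal(top1$gene, paste0("Tf", letters[3:7]))  # descending log2fc
  expect_error(tf_conservation(deg, character(0)), "empty TF list")
})
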