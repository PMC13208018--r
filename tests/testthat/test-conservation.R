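test_that("detection matrix is union-of-genes by species membership", {
  det <- detection_matrix(list(s1 = c("A", "B"), s2 = "B"))
  expect_equal(dim(det), c(2, 2))
  expect_equal(det["A", ], c(s1 = TRUE, s2 = FALSE))
  expect_equal(det["B", ], c(s1 = TRUE, s2 = TRUE))
  expect_equal(nrow(detection_matrix(list(s1 = character(0), s2 = character(0)))), 0)
})

test_that("sharing classes follow the species-count thresholds", {
  det <- rbind(all5 = rep(TRUE, 5),
               four = c(TRUE, TRUE, TRUE, TRUE, FALSE),
               three = c(TRUE, TRUE, TRUE, FALSE, FALSE),
               two = c(TRUE, TRUE, FALSE, FALSE, FALSE),
               one = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  colnames(det) <- paste0("s", 1:5)
  cls <- classify_sharing(det)
  expect_equal(cls$share_class,
               c("high_shared", "high_shared", "intermediate_shared",
                 "intermediate_shared", "species_restricted"))
  expect_equal(cls$is_core, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("clade exclusivity requires the full clade and excludes core genes", {
  clades <- c(fugu = "teleost", mudskipper = "teleost", chicken = "amniote",
              mouse = "amniote", human = "amniote")
  det <- rbind(amn = c(FALSE, FALSE, TRUE, TRUE, TRUE),
               tel = c(TRUE, TRUE, FALSE, FALSE, FALSE),
               core = rep(TRUE, 5),
               partial = c(FALSE, FALSE, TRUE, TRUE, FALSE),
               cross = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  colnames(det) <- names(clades)
  cls <- clade_exclusive(det, clades)
  expect_equal(unname(cls), c("amniote_exclusive", "teleost_exclusive",
                              "none", "mixed", "mixed"))
  expect_error(clade_exclusive(det, clades[-1]), "missing species")
})

test_that("stage assignment is modal with developmental-order tie-breaking", {
  rec <- function(sp, gene, stage, lfc = 1) data.frame(
    species = sp, gene = gene, stage = stage, log2fc = lfc,
    p_value = 0, p_adjusted = 0, pct_in = 1, pct_out = 0)
  deg <- rbind(rec(c("s1", "s2", "s3"), "gMaj", c("OPC", "OPC", "MOL")),
               rec(c("s1", "s2"), "gTie", c("OPC", "MOL")),
               rec(c("s1", "s2"), "gTie2", c("COP", "MOL")),
               # within one species, the larger fold change picks the stage
               rec("s1", "gDouble", "MOL", lfc = 3),
               rec("s1", "gDouble", "OPC", lfc = 1))
  sa <- stage_enrichment_assignment(deg)
  got <- setNames(sa$per_gene$stage, sa$per_gene$gene)
  expect_equal(got[["gMaj"]], "OPC")
  expect_equal(got[["gTie"]], "OPC")   # tie -> earliest stage
  expect_equal(got[["gTie2"]], "COP")
  expect_equal(got[["gDouble"]], "MOL")
  sa2 <- stage_enrichment_assignment(deg, gene_groups = list(grp = c("gMaj", "gTie")))
  gp <- sa2$group_proportions
  expect_equal(sum(gp$proportion), 1)
  expect_equal(gp$proportion[gp$stage == "OPC"], 1)
})

test_that("intersection counts tally exact patterns and conserve totals", {
  det <- rbind(A = c(TRUE, FALSE), B = c(TRUE, FALSE), C = c(TRUE, TRUE))
  colnames(det) <- c("sp1", "sp2")
  ic <- intersection_counts(det)
  expect_equal(ic$count[ic$pattern == "sp1"], 2)
  expect_equal(ic$count[ic$pattern == "sp1;sp2"], 1)
  expect_equal(sum(ic$count), 3)
})

test_that("pipeline conservation outputs are mutually consistent", {
  res <- tiny_pipeline()
  sharing <- res$conservation$sharing
  cls <- res$conservation$clade_class
  ic <- res$conservation$intersections
  # share classes partition detected genes
  expect_equal(sum(unlist(table(sharing$share_class))), nrow(sharing))
  # high-shared count equals the intersection-count mass at >= 4 species
  expect_equal(sum(ic$count[ic$n_species >= 4]),
               sum(sharing$share_class == "high_shared"))
  expect_equal(sum(ic$count), nrow(sharing))
  # core, amniote-exclusive, and teleost-exclusive sets are pairwise disjoint
  core <- sharing$gene[sharing$is_core]
  amn <- names(cls)[cls == "amniote_exclusive"]
  tel <- names(cls)[cls == "teleost_exclusive"]
  expect_length(intersect(core, amn), 0)
  expect_length(intersect(core, tel), 0)
  expect_length(intersect(amn, tel), 0)
  # the amniote-exclusive pattern in the UpSet table matches the recovered set
  amn_pattern <- ic$pattern == "chicken;mouse;human"
  if (any(amn_pattern)) expect_equal(ic$count[amn_pattern], length(amn))
})

test_that("OPC-biased amniote-only genes dominate that group's stage profile", {
  res <- tiny_pipeline()
  gp <- res$conservation$stage_assignment$group_proportions
  opc_amn <- gp$proportion[gp$group == "amniote_exclusive" & gp$stage == "OPC"]
  expect_gt(opc_amn, 0.5)
})

test_that("hypergeometric enrichment matches enumeration and hand-computed BH", {
  universe <- paste0("g", 1:10)
  gene_set <- paste0("g", 1:5)
  ann <- data.frame(term = "T1", gene = paste0("g", c(1, 2, 3, 4)))
  res <- hypergeom_enrichment(gene_set, universe, ann)
  expect_equal(res$p_value, 6 / 252, tolerance = 1e-12)
  # independent enumeration oracle over all C(10,5) draws
  draws <- utils::combn(10, 5)
  k_obs <- 4
  hits <- sum(apply(draws, 2, function(d) sum(d <= 4) >= k_obs))
  expect_equal(res$p_value, hits / ncol(draws), tolerance = 1e-12)
  # BH step-up on (0.01, 0.02, 0.03): all adjusted to 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"), rep(0.03, 3))
  # empty term has p = 1; sets outside the universe are rejected
  ann2 <- rbind(ann, data.frame(term = "T0", gene = "absent"))
  res2 <- hypergeom_enrichment(gene_set, universe, ann2)
  expect_equal(res2$p_value[res2$term == "T0"], 1)
  expect_error(hypergeom_enrichment(c("g1", "zz"), universe, ann), "zz")
})
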