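test_that("temporal profiles hit their analytic landmarks", {
  basal <- 0.05
  # sigmoid midpoint: late_rising at its inflection returns half the amplitude
  expect_equal(temporal_profile("late_rising", 0.6, 1), basal + 0.5)
  # Gaussian peak of the mid-trajectory transient
  expect_equal(temporal_profile("transient_mid", 0.6, 2), basal + 2)
  # saturated sigmoid: early_declining at t = 1 is numerically at the floor
  expect_lt(temporal_profile("early_declining", 1, 1) - basal, 1e-3)
  expect_equal(temporal_profile("early_declining", 1, 1),
               basal + (1 - plogis((1 - 0.3) / 0.08)))
})

test_that("temporal_profile validates its inputs", {
  expect_error(temporal_profile("sideways", 0.5, 1), "sideways")
  expect_error(temporal_profile("late_rising", 1.2, 1), "\\[0, 1\\]")
  expect_error(temporal_profile("late_rising", 0.5, -1), "amplitude")
})

test_that("marker amplitudes make marker profiles cross at the planted thresholds", {
  th <- c(0.35, 0.65)
  a <- marker_amplitudes_for_thresholds(th, a_opc = 2)
  u <- function(s, t, A) temporal_profile(s, t, A, basal = 0)
  expect_equal(u("early_declining", th[1], a[["opc"]]),
               u("transient_mid", th[1], a[["cop"]]), tolerance = 1e-12)
  expect_equal(u("transient_mid", th[2], a[["cop"]]),
               u("late_rising", th[2], a[["mol"]]), tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  a1 <- simulate_atlas(tiny_sim_config(seed = 7L))
  a2 <- simulate_atlas(tiny_sim_config(seed = 7L))
  for (s in names(a1$datasets)) {
    expect_identical(a1$datasets[[s]]$counts, a2$datasets[[s]]$counts)
    expect_identical(a1$ortholog_maps[[s]]$pairs, a2$ortholog_maps[[s]]$pairs)
  }
  expect_identical(a1$truth$cells, a2$truth$cells)
})

test_that("clade-exclusive genes are planted with zero amplitude outside their clade", {
  tr <- tiny_atlas()$truth
  amn_only <- tr$genes$symbol[tr$genes$class == "amniote_only"]
  tel_only <- tr$genes$symbol[tr$genes$class == "teleost_only"]
  for (sp in c("fugu", "mudskipper")) {
    expect_true(all(tr$amplitude[amn_only, sp] == 0))
    expect_false(any(tr$dynamic[amn_only, sp]))
  }
  for (sp in c("chicken", "mouse", "human")) {
    expect_true(all(tr$amplitude[tel_only, sp] == 0))
    expect_true(all(tr$amplitude[amn_only, sp] > 0))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_counts = c(core = 700, amniote_only = 0,
                                           teleost_only = 0,
                                           species_restricted = 0, flat = 0)),
               "sum to n_genes")
  expect_error(sim_config(clade_partition = c(fugu = "teleost")),
               "cover all species")
  expect_error(sim_config(shape_mix = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(class_counts = c(core = 5, amniote_only = 60,
                                           teleost_only = 20,
                                           species_restricted = 60,
                                           flat = 455)),
               "marker genes")
})

# Reconstruct the per-cell NB mean matrix of one species from ground truth.
reconstruct_mu <- function(atlas, sp) {
  tr <- atlas$truth
  tc <- tr$cells[tr$cells$species == sp, ]
  g <- tr$genes
  basal <- atlas$config$basal
  mu <- matrix(0, nrow(g), nrow(tc))
  for (shp in unique(g$shape[!is.na(g$shape)])) {
    gi <- which(tr$dynamic[, sp] & g$shape == shp & !is.na(g$shape))
    if (!length(gi)) next
    mu[gi, ] <- g$amplitude[gi] %o%
      temporal_profile(shp, tc$latent_time, 1, basal = 0) + basal
  }
  off <- which(!tr$dynamic[, sp])
  mu[off, ] <- g$off_mean[off]
  sweep(mu, 2, tc$depth_factor, `*`)
}

test_that("disabling dropout recovers the pure negative-binomial zero mass", {
  cfg <- tiny_sim_config(seed = 21L,
                         dropout_logit_params = c(intercept = -1.5, slope = -Inf))
  cfg$n_cells_per_species <- 800
  atlas <- simulate_atlas(cfg)
  mu <- reconstruct_mu(atlas, "human")
  size <- 1 / cfg$nb_dispersion
  zero_frac <- function(m) 1 - Matrix::nnzero(m) / prod(dim(m))
  zero_expected <- mean((1 + cfg$nb_dispersion * mu)^(-size))
  expect_lt(abs(zero_frac(atlas$datasets$human$counts) - zero_expected), 0.02)
  # and with the default dropout on, extra zeros appear
  cfg2 <- tiny_sim_config(seed = 21L)
  cfg2$n_cells_per_species <- 800
  atlas2 <- simulate_atlas(cfg2)
  expect_gt(zero_frac(atlas2$datasets$human$counts), zero_expected)
})

test_that("per-gene empirical means track the NB x dropout expectation", {
  cfg <- sim_config(n_cells_per_species = 1500, n_genes = 120,
                    class_counts = c(core = 16, amniote_only = 12,
                                     teleost_only = 6, species_restricted = 10,
                                     flat = 76), seed = 5L)
  atlas <- simulate_atlas(cfg)
  for (sp in c("chicken", "human")) {
    expected <- atlas$truth$expected_mean[, sp]
    observed <- Matrix::rowMeans(atlas$datasets[[sp]]$counts)
    hi <- expected >= 0.5
    expect_true(all(abs(observed[hi] - expected[hi]) / expected[hi] < 0.10))
  }
})

test_that("ortholog tables are bidirectionally unique outside the planted noise", {
  atlas <- tiny_atlas()
  for (sp in names(atlas$ortholog_maps)) {
    om <- atlas$ortholog_maps[[sp]]$pairs
    noisy <- unlist(atlas$truth$ortholog_noise[[sp]])
    clean <- om[!(om$reference_symbol %in% noisy), ]
    expect_true(all(clean$is_one_to_one))
    expect_false(any(duplicated(clean$species_gene_id)))
    expect_false(any(duplicated(clean$reference_symbol)))
  }
})

test_that("truth_report tallies classes, shapes, and peak-stage proportions", {
  atlas <- tiny_atlas()
  rep <- truth_report(atlas$truth)
  cc <- tiny_sim_config()$class_counts
  got <- setNames(rep$classes$n_genes, as.character(rep$classes$class))
  expect_equal(got[names(cc)], cc, ignore_attr = TRUE)
  expect_equal(sum(rep$classes$n_genes), 120)
  # proportions sum to 1 within every class
  sums <- tapply(rep$peak_stage_by_class$proportion,
                 rep$peak_stage_by_class$class, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # peak stages agree with a fine-grid argmax of the profiles
  grid <- seq(0, 1, length.out = 1001)
  g <- atlas$truth$genes
  dyn <- g[!is.na(g$shape), ]
  for (shp in unique(dyn$shape)) {
    prof <- temporal_profile(shp, grid, 1, basal = 0)
    t_peak <- grid[which.max(prof)]
    expected_stage <- if (t_peak < 0.35) "OPC" else if (t_peak < 0.65) "COP" else "MOL"
    expect_true(all(dyn$peak_stage[dyn$shape == shp] == expected_stage))
  }
})

test_that("teleost COP depletion thins only the teleost COP window", {
  cfg <- tiny_sim_config(seed = 9L, teleost_cop_depletion = TRUE)
  atlas <- simulate_atlas(cfg)
  cells <- atlas$truth$cells
  frac_cop <- tapply(cells$true_stage == "COP", cells$species, mean)
  expect_lt(mean(frac_cop[c("fugu", "mudskipper")]),
            0.5 * mean(frac_cop[c("chicken", "mouse", "human")]))
  expect_equal(sum(cells$species == "chicken"), 220)
})

test_that("a written atlas round-trips through the standard formats", {
  atlas <- tiny_atlas()
  dir <- withr::local_tempdir()
  write_atlas(atlas, dir)
  ds <- read_counts(file.path(dir, "fugu", "matrix.mtx"),
                    file.path(dir, "fugu", "features.tsv"),
                    file.path(dir, "fugu", "barcodes.tsv"), species = "fugu")
  expect_equal(as.matrix(ds$counts), as.matrix(atlas$datasets$fugu$counts))
  om <- read_ortholog_table(file.path(dir, "orthologs_fugu.tsv"))
  expect_equal(om$pairs, atlas$ortholog_maps$fugu$pairs)
})
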