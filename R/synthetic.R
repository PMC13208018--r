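#' Canonical oligodendrocyte stage marker sets
#'
#' Progenitor (OPC), committed precursor (COP), and myelinating
#' oligodendrocyte (MOL) marker genes used both for rooting the trajectory
#' and for module-score staging. These are the standard lineage markers:
#' Pdgfra/Nkx2-2/Sox2/Cspg5/Tnr for OPC, Fyn/Tcf7l2 for the transition state,
#' and the myelin genes Plp1/Mag/Mbp/Mog for MOL.
#'
#' @param opc,cop,mol character vectors of reference gene symbols.
#' @return list with elements `opc`, `cop`, `mol`.
#' @export
stage_gene_sets <- function(opc = c("Pdgfra", "Nkx2-2", "Sox2", "Cspg5", "Tnr"),
                            cop = c("Fyn", "Tcf7l2"),
                            mol = c("Plp1", "Mag", "Mbp", "Mog")) {
  sets <- list(opc = opc, cop = cop, mol = mol)
  if (any(lengths(sets) == 0)) stop("every stage gene set must be non-empty")
  sets
}

.shape_levels <- c("early_declining", "late_rising", "transient_mid", "early_transient")
.stage_levels <- c("OPC", "COP", "MOL")

#' Temporal expression profile of a dynamic gene
#'
#' Mean expression (arbitrary units, before depth scaling) of a gene with the
#' given temporal shape at latent differentiation time `t` in \[0,1\]. The four
#' shapes are the generator's analogue of the four temporal module dynamics
#' observed along the OPC-to-MOL axis: a declining progenitor program, a
#' rising myelination program, a mid-trajectory transient, and an early
#' transient. All profiles sit on a small basal floor so that means are
#' strictly positive.
#'
#' @param shape one of `"early_declining"`, `"late_rising"`,
#'   `"transient_mid"`, `"early_transient"`.
#' @param t numeric vector of latent times in \[0,1\].
#' @param amplitude positive scalar amplitude.
#' @param basal nonnegative basal floor added to every profile.
#' @return numeric vector of nonnegative means, same length as `t`.
#' @export
temporal_profile <- function(shape, t, amplitude, basal = 0.05) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  if (length(amplitude) != 1 || amplitude < 0) stop("amplitude must be a nonnegative scalar")
  core <- switch(shape,
    early_declining = 1 - stats::plogis((t - 0.3) / 0.08),
    late_rising     = stats::plogis((t - 0.6) / 0.08),
    transient_mid   = exp(-(t - 0.6)^2 / (2 * 0.12^2)),
    early_transient = exp(-(t - 0.15)^2 / (2 * 0.1^2)),
    stop("unknown temporal shape: '", shape, "'")
  )
  amplitude * core + basal
}

#' Marker amplitudes consistent with planted stage thresholds
#'
#' Solves for COP and MOL marker amplitudes so that the OPC/COP marker
#' profiles cross exactly at the first stage threshold and the COP/MOL
#' profiles at the second. This makes the ground truth self-consistent: the
#' planted stage boundaries coincide with the crossover points of the marker
#' programs that define the stages.
#'
#' @param thresholds length-2 numeric, latent-time stage thresholds.
#' @param a_opc OPC marker amplitude (sets the overall scale).
#' @return named numeric vector `c(opc=, cop=, mol=)`.
#' @keywords internal
marker_amplitudes_for_thresholds <- function(thresholds, a_opc = 2) {
  b1 <- thresholds[1]; b2 <- thresholds[2]
  u <- function(shape, t) temporal_profile(shape, t, amplitude = 1, basal = 0)
  a_cop <- a_opc * u("early_declining", b1) / u("transient_mid", b1)
  a_mol <- a_cop * u("transient_mid", b2) / u("late_rising", b2)
  c(opc = a_opc, cop = a_cop, mol = a_mol)
}

#' Configuration for the synthetic five-species atlas
#'
#' Defines the study conditions of the simulated cross-species atlas: species
#' and clade structure, per-class gene counts with planted conservation
#' patterns, temporal shape mixes, sequencing depth, negative-binomial noise,
#' mean-dependent dropout, and ortholog-table noise.
#'
#' @param species_names character vector of species labels.
#' @param clade_partition named character vector mapping each species to
#'   `"amniote"` or `"teleost"`.
#' @param n_cells_per_species positive integer, scalar or named per species.
#' @param n_genes total number of genes.
#' @param class_counts named integer vector with entries `core`,
#'   `amniote_only`, `teleost_only`, `species_restricted`, `flat`, summing to
#'   `n_genes`. `core` must be at least the number of planted marker genes (11).
#' @param shape_mix proportions of the four temporal shapes among dynamic
#'   genes (order: early_declining, late_rising, transient_mid,
#'   early_transient); must sum to 1.
#' @param shape_mix_amniote_only,shape_mix_teleost_only shape mixes for the
#'   clade-exclusive classes; defaults bias amniote-only genes toward
#'   OPC-peaking shapes and teleost-only genes toward MOL-peaking shapes.
#' @param stage_thresholds latent-time thresholds separating OPC/COP and
#'   COP/MOL ground-truth stages.
#' @param depth_per_species expected library-size scale per species (counts);
#'   scalar or named vector.
#' @param depth_sdlog lognormal sd of per-cell depth factors.
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp * mu^2),
#'   shared across genes.
#' @param dropout_logit_params length-2 numeric `(intercept, slope)`; the
#'   probability that an observed count is zeroed is
#'   `plogis(intercept + slope * mu)`. A slope of `-Inf` disables dropout.
#' @param ortholog_noise length-2 named numeric `(one_to_many, missing)`:
#'   fractions of non-marker genes per species whose ortholog entry is
#'   duplicated (breaking bidirectional uniqueness) or removed.
#' @param teleost_cop_depletion logical; if `TRUE`, teleost cells whose latent
#'   time falls in the COP window are thinned to `cop_keep_fraction`.
#' @param cop_keep_fraction fraction of COP-window teleost cells kept when
#'   depletion is on.
#' @param basal basal expression floor.
#' @param marker_amplitude_opc amplitude of the OPC markers; COP/MOL marker
#'   amplitudes are derived so marker crossovers coincide with
#'   `stage_thresholds` (see [marker_amplitudes_for_thresholds()]).
#' @param seed integer seed for the generator.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(species_names = c("fugu", "mudskipper", "chicken", "mouse", "human"),
                       clade_partition = c(fugu = "teleost", mudskipper = "teleost",
                                           chicken = "amniote", mouse = "amniote",
                                           human = "amniote"),
                       n_cells_per_species = 1500,
                       n_genes = 600,
                       class_counts = c(core = 60, amniote_only = 60, teleost_only = 20,
                                        species_restricted = 60, flat = 400),
                       shape_mix = c(early_declining = 0.31, late_rising = 0.35,
                                     transient_mid = 0.17, early_transient = 0.17),
                       shape_mix_amniote_only = c(early_declining = 0.55, late_rising = 0.15,
                                                  transient_mid = 0.10, early_transient = 0.20),
                       shape_mix_teleost_only = c(early_declining = 0.20, late_rising = 0.50,
                                                  transient_mid = 0.15, early_transient = 0.15),
                       stage_thresholds = c(0.35, 0.65),
                       depth_per_species = c(fugu = 1500, mudskipper = 1200, chicken = 2500,
                                             mouse = 800, human = 2000),
                       depth_sdlog = 0.3,
                       nb_dispersion = 0.3,
                       dropout_logit_params = c(intercept = -1.5, slope = -0.5),
                       ortholog_noise = c(one_to_many = 0.01, missing = 0.01),
                       teleost_cop_depletion = FALSE,
                       cop_keep_fraction = 0.3,
                       basal = 0.05,
                       marker_amplitude_opc = 2,
                       seed = 0L) {
  cfg <- list(
    species_names = species_names,
    clade_partition = clade_partition,
    n_cells_per_species = n_cells_per_species,
    n_genes = as.integer(n_genes),
    class_counts = class_counts,
    shape_mix = shape_mix,
    shape_mix_amniote_only = shape_mix_amniote_only,
    shape_mix_teleost_only = shape_mix_teleost_only,
    stage_thresholds = stage_thresholds,
    depth_per_species = depth_per_species,
    depth_sdlog = depth_sdlog,
    nb_dispersion = nb_dispersion,
    dropout_logit_params = dropout_logit_params,
    ortholog_noise = ortholog_noise,
    teleost_cop_depletion = teleost_cop_depletion,
    cop_keep_fraction = cop_keep_fraction,
    basal = basal,
    marker_amplitudes = marker_amplitudes_for_thresholds(stage_thresholds,
                                                         marker_amplitude_opc),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; stops with an informative message on violation.
#' @export
validate_sim_config <- function(cfg) {
  if (!all(cfg$species_names %in% names(cfg$clade_partition)))
    stop("clade_partition must cover all species")
  if (!all(cfg$clade_partition[cfg$species_names] %in% c("amniote", "teleost")))
    stop("clade_partition values must be 'amniote' or 'teleost'")
  n_cells <- .per_species(cfg$n_cells_per_species, cfg$species_names, "n_cells_per_species")
  if (any(n_cells <= 0)) stop("n_cells_per_species must be positive")
  depth <- .per_species(cfg$depth_per_species, cfg$species_names, "depth_per_species")
  if (any(depth <= 0)) stop("depth_per_species must be positive")
  req <- c("core", "amniote_only", "teleost_only", "species_restricted", "flat")
  if (!all(req %in% names(cfg$class_counts)))
    stop("class_counts must name: ", paste(req, collapse = ", "))
  if (any(cfg$class_counts < 0)) stop("class_counts must be nonnegative")
  if (sum(cfg$class_counts) != cfg$n_genes)
    stop("class_counts must sum to n_genes (", cfg$n_genes, "), got ",
         sum(cfg$class_counts))
  n_marker <- length(unlist(stage_gene_sets()))
  if (cfg$class_counts[["core"]] < n_marker)
    stop("class_counts['core'] must be at least ", n_marker,
         " to host the planted marker genes")
  for (nm in c("shape_mix", "shape_mix_amniote_only", "shape_mix_teleost_only")) {
    mix <- cfg[[nm]]
    if (abs(sum(mix) - 1) > 1e-8) stop(nm, " must sum to 1")
    if (length(mix) != 4) stop(nm, " must have 4 entries")
  }
  if (length(cfg$stage_thresholds) != 2 ||
      !(0 < cfg$stage_thresholds[1] && cfg$stage_thresholds[1] < cfg$stage_thresholds[2] &&
        cfg$stage_thresholds[2] < 1))
    stop("stage_thresholds must satisfy 0 < b1 < b2 < 1")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (any(cfg$ortholog_noise < 0) || sum(cfg$ortholog_noise) >= 1)
    stop("ortholog_noise fractions must be nonnegative and sum below 1")
  invisible(cfg)
}

# Recycle a scalar or validate a named per-species vector.
.per_species <- function(x, species, what) {
  if (length(x) == 1 && is.null(names(x))) {
    stats::setNames(rep(x, length(species)), species)
  } else {
    if (!all(species %in% names(x)))
      stop(what, " must be a scalar or a named vector covering all species")
    x[species]
  }
}

.stage_from_latent <- function(t, thresholds) {
  factor(ifelse(t < thresholds[1], "OPC",
                ifelse(t < thresholds[2], "COP", "MOL")),
         levels = .stage_levels)
}

# Peak stage of a unit-amplitude shape: argmax of the profile on a fine grid,
# mapped through the stage thresholds.
.peak_stage <- function(shape, thresholds, grid_n = 1001) {
  grid <- seq(0, 1, length.out = grid_n)
  prof <- temporal_profile(shape, grid, amplitude = 1, basal = 0)
  as.character(.stage_from_latent(grid[which.max(prof)], thresholds))
}

# Species gene-id prefix ("FUG_", "MUD_", ...) so harmonization is a real step.
.species_prefix <- function(species) toupper(substr(species, 1, 3))

#' Simulate a multi-species single-cell atlas with planted ground truth
#'
#' Generates, for each species, a sparse gene-by-cell count matrix along a
#' shared latent differentiation axis (OPC to COP to MOL), together with
#' per-species ortholog tables and a ground-truth record. Genes belong to
#' planted conservation classes: `core` (dynamic in every species, including
#' the stage marker genes), `amniote_only`, `teleost_only`,
#' `species_restricted` (dynamic in exactly one species), and `flat`.
#' Dynamic genes follow one of four temporal shapes; counts are negative
#' binomial around depth-scaled profile means, with mean-dependent dropout.
#' Ortholog tables contain configurable fractions of one-to-many and missing
#' entries among non-marker genes.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_atlas` with elements:
#'   \describe{
#'     \item{datasets}{named list of [species_dataset()] objects (rows are
#'       species-specific gene ids).}
#'     \item{ortholog_maps}{named list of [ortholog_map()] objects.}
#'     \item{truth}{`ground_truth` list: `genes` (symbol, class, shape,
#'       amplitude, peak_stage, host_species, off_mean), `cells` (species,
#'       cell_id, latent_time, depth_factor, true_stage), `amplitude` gene-by-species
#'       matrix, `dynamic` gene-by-species logical matrix, `expected_mean`
#'       gene-by-species analytic post-dropout means, `ortholog_noise`
#'       per-species lists of perturbed symbols.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_atlas <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  species <- config$species_names
  clades <- config$clade_partition[species]
  n_genes <- config$n_genes
  markers <- stage_gene_sets()
  marker_syms <- unlist(markers, use.names = FALSE)
  n_marker <- length(marker_syms)

  ## ---- gene-level truth ----
  cc <- config$class_counts
  other_syms <- sprintf("g%04d", seq_len(n_genes - n_marker))
  symbols <- c(marker_syms, other_syms)
  gene_class <- c(
    rep("core", n_marker),
    rep("core", cc[["core"]] - n_marker),
    rep("amniote_only", cc[["amniote_only"]]),
    rep("teleost_only", cc[["teleost_only"]]),
    rep("species_restricted", cc[["species_restricted"]]),
    rep("flat", cc[["flat"]])
  )

  draw_shapes <- function(n, mix) {
    if (n == 0) return(character(0))
    sample(.shape_levels, n, replace = TRUE, prob = mix)
  }
  shapes <- rep(NA_character_, n_genes)
  shapes[seq_len(n_marker)] <- c(rep("early_declining", length(markers$opc)),
                                 rep("transient_mid", length(markers$cop)),
                                 rep("late_rising", length(markers$mol)))
  idx_core_extra <- which(gene_class == "core")[-seq_len(n_marker)]
  shapes[idx_core_extra] <- draw_shapes(length(idx_core_extra), config$shape_mix)
  shapes[gene_class == "amniote_only"] <-
    draw_shapes(cc[["amniote_only"]], config$shape_mix_amniote_only)
  shapes[gene_class == "teleost_only"] <-
    draw_shapes(cc[["teleost_only"]], config$shape_mix_teleost_only)
  shapes[gene_class == "species_restricted"] <-
    draw_shapes(cc[["species_restricted"]], config$shape_mix)

  marker_amp <- config$marker_amplitudes
  amplitude <- rep(NA_real_, n_genes)
  amplitude[seq_len(n_marker)] <- c(rep(marker_amp[["opc"]], length(markers$opc)),
                                    rep(marker_amp[["cop"]], length(markers$cop)),
                                    rep(marker_amp[["mol"]], length(markers$mol)))
  idx_dyn_other <- which(gene_class %in% c("core", "amniote_only", "teleost_only",
                                           "species_restricted") & is.na(amplitude))
  amplitude[idx_dyn_other] <- stats::rlnorm(length(idx_dyn_other),
                                            meanlog = log(2), sdlog = 0.35)

  # Baseline expression when a gene is not dynamic in a species: flat genes
  # get a gene-specific low mean, switched-off dynamic genes sit at the basal
  # floor.
  off_mean <- rep(config$basal, n_genes)
  idx_flat <- which(gene_class == "flat")
  off_mean[idx_flat] <- stats::runif(length(idx_flat), 0.1, 0.8)

  host <- rep(NA_character_, n_genes)
  idx_restricted <- which(gene_class == "species_restricted")
  host[idx_restricted] <- rep_len(species, length(idx_restricted))

  peak_stage <- rep(NA_character_, n_genes)
  dyn_idx <- which(!is.na(shapes))
  peak_lookup <- vapply(.shape_levels, .peak_stage,
                        character(1), thresholds = config$stage_thresholds)
  peak_stage[dyn_idx] <- peak_lookup[shapes[dyn_idx]]

  dynamic <- matrix(FALSE, n_genes, length(species),
                    dimnames = list(symbols, species))
  for (s in species) {
    dynamic[, s] <- (gene_class == "core") |
      (gene_class == "amniote_only" & clades[[s]] == "amniote") |
      (gene_class == "teleost_only" & clades[[s]] == "teleost") |
      (gene_class == "species_restricted" & !is.na(host) & host == s)
  }
  amp_mat <- dynamic * 1
  amp_mat[dynamic] <- rep(amplitude, length(species))[as.vector(dynamic)] # amplitude recycled per column
  dimnames(amp_mat) <- dimnames(dynamic)

  ## ---- per-species ortholog noise (gene-level, drawn before cells) ----
  eligible <- setdiff(symbols, marker_syms)
  n_multi <- round(config$ortholog_noise[["one_to_many"]] * n_genes)
  n_miss <- round(config$ortholog_noise[["missing"]] * n_genes)
  noise <- lapply(species, function(s) {
    picked <- sample_safe(eligible, n_multi + n_miss)
    list(one_to_many = picked[seq_len(n_multi)],
         missing = if (n_miss > 0) picked[n_multi + seq_len(n_miss)] else character(0))
  })
  names(noise) <- species

  ## ---- per-species cells and counts ----
  n_cells <- .per_species(config$n_cells_per_species, species, "n_cells_per_species")
  depth <- .per_species(config$depth_per_species, species, "depth_per_species")
  drop_par <- config$dropout_logit_params
  size <- 1 / config$nb_dispersion

  datasets <- list()
  cell_rows <- list()
  expected_mean <- matrix(NA_real_, n_genes, length(species),
                          dimnames = list(symbols, species))

  for (s in species) {
    nc <- n_cells[[s]]
    t_c <- stats::runif(nc)
    if (config$teleost_cop_depletion && clades[[s]] == "teleost") {
      in_cop <- t_c >= config$stage_thresholds[1] & t_c < config$stage_thresholds[2]
      keep <- !in_cop | (stats::runif(nc) < config$cop_keep_fraction)
      t_c <- t_c[keep]
      nc <- length(t_c)
    }
    f_c <- stats::rlnorm(nc, meanlog = log(depth[[s]] / 2000), sdlog = config$depth_sdlog)

    mu <- matrix(0, n_genes, nc)
    for (shp in .shape_levels) {
      gi <- which(dynamic[, s] & shapes == shp)
      if (length(gi) == 0) next
      prof <- temporal_profile(shp, t_c, amplitude = 1, basal = 0)
      mu[gi, ] <- amplitude[gi] %o% prof + config$basal
    }
    gi_off <- which(!dynamic[, s])
    if (length(gi_off) > 0) mu[gi_off, ] <- off_mean[gi_off]
    mu <- sweep(mu, 2, f_c, `*`)

    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                     nrow = n_genes)
    slope <- drop_par[[2]]
    if (is.finite(slope)) {
      p_drop <- stats::plogis(drop_par[[1]] + slope * mu)
    } else {
      p_drop <- matrix(if (slope < 0) 0 else 1, n_genes, nc)
    }
    counts[stats::runif(length(counts)) < p_drop] <- 0L
    expected_mean[, s] <- rowMeans(mu * (1 - p_drop))

    gene_ids <- paste0(.species_prefix(s), "_", symbols)
    cell_ids <- sprintf("%s_cell%05d", s, seq_len(nc))
    dimnames(counts) <- list(gene_ids, cell_ids)
    cm <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                  "CsparseMatrix"), "dMatrix")
    datasets[[s]] <- species_dataset(s, cm)
    cell_rows[[s]] <- data.frame(species = s, cell_id = cell_ids,
                                 latent_time = t_c, depth_factor = f_c,
                                 true_stage = as.character(
                                   .stage_from_latent(t_c, config$stage_thresholds)),
                                 stringsAsFactors = FALSE)
  }

  ## ---- ortholog tables ----
  ortholog_maps <- lapply(species, function(s) {
    ids <- paste0(.species_prefix(s), "_", symbols)
    tab <- data.frame(species_gene_id = ids, reference_symbol = symbols,
                      stringsAsFactors = FALSE)
    ns <- noise[[s]]
    tab <- tab[!(tab$reference_symbol %in% ns$missing), ]
    if (length(ns$one_to_many) > 0) {
      dup <- data.frame(
        species_gene_id = paste0(.species_prefix(s), "_", ns$one_to_many, "alt"),
        reference_symbol = ns$one_to_many, stringsAsFactors = FALSE)
      tab <- rbind(tab, dup)
    }
    ortholog_map(tab)
  })
  names(ortholog_maps) <- species

  truth <- list(
    genes = data.frame(symbol = symbols, class = gene_class, shape = shapes,
                       amplitude = amplitude, peak_stage = peak_stage,
                       host_species = host, off_mean = off_mean,
                       stringsAsFactors = FALSE),
    cells = do.call(rbind, cell_rows),
    amplitude = amp_mat,
    dynamic = dynamic,
    expected_mean = expected_mean,
    ortholog_noise = noise,
    stage_thresholds = config$stage_thresholds
  )
  class(truth) <- "ground_truth"

  structure(list(datasets = datasets, ortholog_maps = ortholog_maps,
                 truth = truth, config = config),
            class = "sim_atlas")
}

#' Summarize planted ground truth
#'
#' Tabulates planted conservation-class sizes, temporal-shape sizes, and
#' per-class peak-stage proportions.
#'
#' @param truth the `truth` element of a [simulate_atlas()] result.
#' @return list of data frames `classes`, `shapes`, `peak_stage_by_class`.
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  g <- truth$genes
  classes <- as.data.frame(table(class = g$class), responseName = "n_genes")
  shapes <- as.data.frame(table(shape = g$shape[!is.na(g$shape)]),
                          responseName = "n_genes")
  dyn <- g[!is.na(g$peak_stage), ]
  peak <- do.call(rbind, lapply(split(dyn, dyn$class), function(d) {
    p <- prop.table(table(factor(d$peak_stage, levels = .stage_levels)))
    data.frame(class = d$class[1], stage = names(p),
               proportion = as.numeric(p), stringsAsFactors = FALSE)
  }))
  rownames(peak) <- NULL
  stopifnot(sum(classes$n_genes) == nrow(g))
  list(classes = classes, shapes = shapes, peak_stage_by_class = peak)
}

#' Write a simulated atlas to disk in standard formats
#'
#' Each species becomes a directory with `matrix.mtx` (genes x cells, integer
#' counts), `features.tsv`, and `barcodes.tsv`; ortholog tables are written as
#' two-column TSVs, ground truth as TSVs, and the configuration as YAML.
#'
#' @param atlas a [simulate_atlas()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "sim_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(atlas$datasets)) {
    write_counts(atlas$datasets[[s]], file.path(dir, s))
    om <- atlas$ortholog_maps[[s]]
    utils::write.table(om$pairs[, c("species_gene_id", "reference_symbol")],
                       file.path(dir, paste0("orthologs_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(atlas$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(atlas$truth$cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- atlas$config
  cfg_plain <- lapply(unclass(cfg), function(x) if (is.numeric(x) || is.logical(x) || is.character(x)) x else x)
  yaml::write_yaml(cfg_plain, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
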