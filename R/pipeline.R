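#' Build a pipeline run configuration
#'
#' Bundles the synthetic-atlas block (or input paths) with every stage's
#' parameters and one global seed. Exactly one of `simulate` / `input_paths`
#' must be supplied.
#'
#' @param simulate a [sim_config()] describing the synthetic atlas, or NULL.
#' @param input_paths named list per species with elements `mtx`, `features`,
#'   `barcodes`, `orthologs`, or NULL.
#' @param clade_partition named species -> clade vector; defaults to the
#'   simulate block's partition.
#' @param reference_species reference for cross-species mapping (default
#'   `"mouse"`).
#' @param markers a [stage_gene_sets()] list.
#' @param n_pcs,n_hvg,k_neighbors,root_fraction trajectory parameters.
#' @param smooth_embedding denoise the PCA embedding by neighbor averaging
#'   before the pseudotime graph is built (default TRUE).
#' @param score_bins,score_ctrl,curve_bins,smooth_window staging parameters.
#' @param alpha,lfc_min,min_pct,correction DEG parameters.
#' @param high_min species count defining high-shared genes (default 4).
#' @param module_bins,k_modules co-expression module parameters.
#' @param crossmap_features,temperature,downsample_n cross-mapping parameters
#'   (`downsample_n = NULL` disables the downsampling pass).
#' @param seed global run seed, fanned out to per-stage child seeds.
#' @param outdir optional output directory for artifacts and report.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = sim_config(), input_paths = NULL,
                       clade_partition = NULL, reference_species = "mouse",
                       markers = stage_gene_sets(), n_pcs = 10, n_hvg = 500,
                       k_neighbors = 15, root_fraction = 0.10,
                       smooth_embedding = TRUE,
                       score_bins = 24, score_ctrl = 100, curve_bins = 50,
                       smooth_window = 3, alpha = 0.05, lfc_min = 0.25,
                       min_pct = 0.1, correction = "bonferroni", high_min = 4,
                       module_bins = 10, k_modules = 4, crossmap_features = 500,
                       temperature = 0.02, downsample_n = NULL, seed = 0L,
                       outdir = NULL) {
  if (is.null(clade_partition) && !is.null(simulate))
    clade_partition <- simulate$clade_partition
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' @param config a [run_config()].
#' @return character vector of violations (empty when runnable).
#' @export
validate_config <- function(config) {
  v <- character(0)
  if (is.null(config$simulate) == is.null(config$input_paths))
    v <- c(v, "exactly one of simulate / input_paths must be supplied")
  if (is.null(config$seed)) v <- c(v, "seed must be set")
  if (is.null(config$clade_partition))
    v <- c(v, "clade_partition must be supplied")
  species <- if (!is.null(config$simulate)) config$simulate$species_names
             else names(config$input_paths)
  if (!is.null(species)) {
    if (!is.null(config$clade_partition) &&
        !all(species %in% names(config$clade_partition)))
      v <- c(v, "clade_partition must cover all species")
    if (config$high_min > length(species))
      v <- c(v, sprintf("high_min (%d) exceeds the number of species (%d)",
                        config$high_min, length(species)))
    if (!config$reference_species %in% species)
      v <- c(v, "reference_species is not among the species")
  }
  for (fld in c("n_pcs", "n_hvg", "k_neighbors", "score_bins", "score_ctrl",
                "curve_bins", "module_bins", "k_modules", "crossmap_features"))
    if (config[[fld]] <= 0) v <- c(v, paste(fld, "must be positive"))
  if (config$root_fraction <= 0 || config$root_fraction > 1)
    v <- c(v, "root_fraction must be in (0, 1]")
  if (config$temperature <= 0) v <- c(v, "temperature must be positive")
  if (config$alpha < 0 || config$alpha > 1) v <- c(v, "alpha must be in [0, 1]")
  if (config$smooth_window < 1) v <- c(v, "smooth_window must be >= 1")
  v
}

#' Read a run configuration from YAML
#'
#' Scalar fields of the YAML override the [run_config()] defaults; a
#' `simulate:` block overrides [sim_config()] defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulate
  y$simulate <- NULL
  sim <- if (is.null(sim_args)) sim_config() else {
    for (nm in c("clade_partition", "class_counts", "depth_per_species",
                 "shape_mix", "shape_mix_amniote_only", "shape_mix_teleost_only",
                 "ortholog_noise", "dropout_logit_params", "n_cells_per_species"))
      if (!is.null(sim_args[[nm]]) && is.list(sim_args[[nm]]))
        sim_args[[nm]] <- unlist(sim_args[[nm]])
    do.call(sim_config, sim_args)
  }
  args <- c(list(simulate = sim), y)
  do.call(run_config, args)
}

#' Run the full cross-species pipeline
#'
#' simulate (or load) -> harmonize -> trajectory -> staging -> stage DEGs ->
#' conservation taxonomy -> temporal co-expression modules -> cross-species
#' stage mapping, with a machine-readable run report. Deterministic for a
#' fixed config and seed.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with elements `datasets`,
#'   `common_genes`, `deg` (combined records), `dynamic_lists`,
#'   `conservation` (sharing table, clade classes, stage assignment,
#'   intersection counts), `modules` (atlas, matrix, dynamics), `crossmap`
#'   (per-query prediction scores), `truth` (when simulated), and `report`.
#' @export
run_pipeline <- function(config = run_config()) {
  violations <- validate_config(config)
  if (length(violations) > 0)
    stop("invalid configuration:\n  - ", paste(violations, collapse = "\n  - "))
  seed <- config$seed
  report <- list()

  ## ---- inputs ----
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- child_seed(seed, 11L)
    atlas <- simulate_atlas(sim)
    datasets <- atlas$datasets
    maps <- atlas$ortholog_maps
    truth <- atlas$truth
  } else {
    datasets <- list(); maps <- list(); truth <- NULL
    for (s in names(config$input_paths)) {
      p <- config$input_paths[[s]]
      datasets[[s]] <- read_counts(p$mtx, p$features, p$barcodes, species = s)
      maps[[s]] <- read_ortholog_table(p$orthologs)
    }
  }
  species <- names(datasets)
  clades <- config$clade_partition

  ## ---- harmonization ----
  datasets <- lapply(datasets, function(ds)
    tryCatch(harmonize_to_reference(ds, maps[[ds$species]]),
             error = function(e) stop("[harmonize:", ds$species, "] ",
                                      conditionMessage(e))))
  common <- common_ortholog_set(datasets)
  report$species <- lapply(datasets, function(ds)
    list(cells = ncol(ds$counts), genes_retained = nrow(ds$counts)))
  report$common_ortholog_set_size <- length(common)

  ## ---- trajectory + staging ----
  datasets <- lapply(datasets, function(ds) {
    ds <- tryCatch(
      run_trajectory(ds, markers = config$markers$opc, n_pcs = config$n_pcs,
                     n_hvg = config$n_hvg, k_neighbors = config$k_neighbors,
                     root_fraction = config$root_fraction,
                     smooth = config$smooth_embedding),
      error = function(e) stop("[trajectory:", ds$species, "] ",
                               conditionMessage(e)))
    tryCatch(
      run_staging(ds, gene_sets = config$markers, n_bins = config$score_bins,
                  n_ctrl = config$score_ctrl, n_curve_bins = config$curve_bins,
                  smooth_window = config$smooth_window,
                  seed = child_seed(seed, 13L)),
      error = function(e) stop("[staging:", ds$species, "] ",
                               conditionMessage(e)))
  })
  datasets <- normalize_pseudotime_atlas(datasets)
  report$boundaries <- lapply(datasets, function(ds)
    list(b1 = ds$boundaries$b1, b2 = ds$boundaries$b2,
         flags = as.list(ds$boundaries$flags)))

  ## ---- stage DEGs on the common ortholog set ----
  deg_tables <- lapply(datasets, function(ds) {
    tryCatch(
      call_stage_degs(ds$normalized[common, , drop = FALSE],
                      ds$cell_meta$stage, species = ds$species,
                      alpha = config$alpha, lfc_min = config$lfc_min,
                      min_pct = config$min_pct, correction = config$correction),
      error = function(e) stop("[deg:", ds$species, "] ", conditionMessage(e)))
  })
  dynamic_lists <- lapply(deg_tables, attr, "dynamic_genes")
  deg <- do.call(rbind, deg_tables)
  rownames(deg) <- NULL
  report$deg_counts <- lapply(deg_tables, function(d)
    as.list(table(factor(d$stage, levels = .stage_levels))))

  ## ---- conservation taxonomy ----
  det <- detection_matrix(dynamic_lists)
  sharing <- classify_sharing(det, high_min = config$high_min)
  clade_cls <- clade_exclusive(det, clades)
  groups <- list(
    core = sharing$gene[sharing$is_core],
    amniote_exclusive = names(clade_cls)[clade_cls == "amniote_exclusive"],
    teleost_exclusive = names(clade_cls)[clade_cls == "teleost_exclusive"])
  stage_assign <- stage_enrichment_assignment(deg, gene_groups = groups)
  upset <- intersection_counts(det)
  report$conservation <- list(
    n_detected = nrow(det),
    share_classes = as.list(table(sharing$share_class)),
    n_core = sum(sharing$is_core),
    n_amniote_exclusive = length(groups$amniote_exclusive),
    n_teleost_exclusive = length(groups$teleost_exclusive))

  ## ---- temporal co-expression modules on high-shared genes ----
  high_shared <- sharing$gene[sharing$share_class == "high_shared"]
  modules <- NULL
  if (length(high_shared) >= config$k_modules) {
    bins <- lapply(datasets, function(ds)
      pseudobulk_bins(ds$normalized, ds$cell_meta$pseudotime_norm,
                      gene_subset = high_shared, n_bins = config$module_bins))
    z <- zscore_concat(bins)
    atlas_mod <- ward_cluster_cut(z, k = config$k_modules)
    modules <- list(atlas = atlas_mod, matrix = z,
                    dynamics = module_dynamics(atlas_mod, z),
                    high_shared = high_shared)
    report$modules <- list(n_high_shared = length(high_shared),
                           sizes = as.list(atlas_mod$sizes))
  } else {
    report$modules <- list(n_high_shared = length(high_shared),
                           note = "too few high-shared genes for clustering")
  }

  ## ---- cross-species stage mapping ----
  ref <- datasets[[config$reference_species]]
  queries <- setdiff(species, config$reference_species)
  crossmap <- lapply(queries, function(qs) {
    q <- datasets[[qs]]
    if (!is.null(config$downsample_n) && ncol(q$counts) > config$downsample_n)
      q <- downsample_cells(q, n = config$downsample_n,
                            seed = child_seed(seed, 17L))
    crossmap_species(ref, q, n_features = config$crossmap_features,
                     temperature = config$temperature)
  })
  names(crossmap) <- queries
  report$crossmap <- lapply(crossmap, function(ps)
    list(heatmap = apply(ps$heatmap, 1, as.list)))

  ## ---- recovery metrics against planted truth ----
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- recovery_metrics(datasets, truth, sharing, clade_cls, modules)
    report$recovery <- recovery
  }

  result <- structure(list(datasets = datasets, common_genes = common,
                           deg = deg, dynamic_lists = dynamic_lists,
                           conservation = list(sharing = sharing,
                                               clade_class = clade_cls,
                                               stage_assignment = stage_assign,
                                               intersections = upset,
                                               detections = det),
                           modules = modules, crossmap = crossmap,
                           truth = truth, report = report, config = config),
                      class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_artifacts(result, config$outdir)
  result
}

#' Recovery metrics against planted ground truth
#'
#' @param datasets staged datasets (with cell_meta).
#' @param truth planted `ground_truth`.
#' @param sharing output of [classify_sharing()].
#' @param clade_cls output of [clade_exclusive()].
#' @param modules module list from the pipeline (or NULL).
#' @return nested list of per-species and global recovery metrics.
#' @keywords internal
recovery_metrics <- function(datasets, truth, sharing, clade_cls, modules) {
  per_species <- lapply(datasets, function(ds) {
    tc <- truth$cells[truth$cells$species == ds$species, ]
    tc <- tc[match(ds$cell_ids, tc$cell_id), ]
    list(pseudotime_spearman = spearman(ds$cell_meta$pseudotime, tc$latent_time),
         stage_accuracy = mean(ds$cell_meta$stage == tc$true_stage))
  })
  g <- truth$genes
  f1 <- list(
    core = set_f1(sharing$gene[sharing$is_core], g$symbol[g$class == "core"]),
    amniote_exclusive = set_f1(names(clade_cls)[clade_cls == "amniote_exclusive"],
                               g$symbol[g$class == "amniote_only"]),
    teleost_exclusive = set_f1(names(clade_cls)[clade_cls == "teleost_exclusive"],
                               g$symbol[g$class == "teleost_only"]),
    species_restricted = set_f1(sharing$gene[sharing$share_class == "species_restricted"],
                                g$symbol[g$class == "species_restricted"]))
  module_ari <- NULL
  if (!is.null(modules)) {
    genes <- names(modules$atlas$assignment)
    planted <- g$shape[match(genes, g$symbol)]
    ok <- !is.na(planted)
    if (sum(ok) >= 2)
      module_ari <- adjusted_rand_index(modules$atlas$assignment[ok], planted[ok])
  }
  list(per_species = per_species, class_f1 = f1, module_ari = module_ari)
}

#' Write pipeline artifacts and the JSON run report
#'
#' @param result a `pipeline_result`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  for (ds in result$datasets)
    wt(ds$cell_meta, paste0("cell_meta_", ds$species, ".tsv"))
  wt(result$deg, "deg_records.tsv")
  cons <- result$conservation$sharing
  cons$clade_class <- result$conservation$clade_class[cons$gene]
  sa <- result$conservation$stage_assignment$per_gene
  cons$stage_assignment <- sa$stage[match(cons$gene, sa$gene)]
  wt(cons, "conservation.tsv")
  wt(result$conservation$intersections, "intersection_counts.tsv")
  if (!is.null(result$modules)) {
    wt(data.frame(gene = names(result$modules$atlas$assignment),
                  module = as.integer(result$modules$atlas$assignment)),
       "module_assignment.tsv")
    wt(result$modules$dynamics, "module_dynamics.tsv")
    merge_tab <- as.data.frame(result$modules$atlas$dendrogram$merge)
    names(merge_tab) <- c("left", "right")
    merge_tab$height <- result$modules$atlas$dendrogram$height
    wt(merge_tab, "module_linkage.tsv")
  }
  hm <- do.call(rbind, lapply(names(result$crossmap), function(qs) {
    h <- result$crossmap[[qs]]$heatmap
    data.frame(query = qs, query_stage = rep(rownames(h), ncol(h)),
               reference_stage = rep(colnames(h), each = nrow(h)),
               mean_score = as.vector(h), stringsAsFactors = FALSE)
  }))
  wt(hm, "crossmap_heatmaps.tsv")
  writeLines(report_json(result$report), file.path(outdir, "run_report.json"))
  invisible(outdir)
}

#' Serialize a run report deterministically
#'
#' @param report the pipeline report list.
#' @return a JSON string (fixed 10-digit precision so identical runs are
#'   byte-identical).
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                                null = "null", na = "null", pretty = TRUE))
}
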