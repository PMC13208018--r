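# oligotraj

Cross-species comparison of oligodendrocyte differentiation programs from
single-cell RNA-seq counts.

Oligodendrocytes mature along a conserved trajectory — proliferative
progenitors (OPC) pass through a transient committed precursor state (COP)
into myelin-forming oligodendrocytes (MOL). Given per-species gene × cell
count matrices and one-to-one ortholog tables, `oligotraj` determines which
parts of this differentiation program are shared across vertebrates and
which are clade- or species-specific:

* **Ortholog harmonization** — only bidirectionally unique one-to-one pairs
  are kept and renamed to reference (mouse) symbols; analyses run on the
  common ortholog set across species.
* **Trajectory** — log-normalization, PCA on highly variable genes, an OPC
  root score over progenitor markers (*Pdgfra, Nkx2-2, Sox2, Cspg5, Tnr*),
  and pseudotime as kNN-graph geodesic distance from the root cell, min-max
  scaled per species.
* **Staging** — expression-bin-matched module scores for the OPC/COP/MOL
  marker sets; stage boundaries at the pseudotime where the COP score first
  exceeds the OPC score (and MOL exceeds COP).
* **Stage DEGs** — one-vs-rest Wilcoxon per stage with adjusted p < 0.05,
  log2 fold change > 0.25 (unit-pseudocount, expm1-scale means), and
  expression fraction > 0.1.
* **Conservation taxonomy** — genes detected in all 5 species are
  *evolutionary core*; ≥ 4 species *high-shared*; 2–3 *intermediate*; 1
  *species-restricted*; genes dynamic in every amniote but no teleost (or
  vice versa) are *clade-exclusive*. Stage assignment is the modal stage
  across detecting species; UpSet-style intersection counts and
  hypergeometric term enrichment (BH-adjusted) are included.
* **Temporal modules** — high-shared genes are pseudobulked into 10
  pseudotime bins per species, z-scored across the concatenated bins, and
  cut into k = 4 modules by Ward (ward.D2) clustering.
* **Cross-species stage mapping** — query cells are scored against
  reference stage centroids by Spearman correlation with a softmax, giving
  query-stage × reference-stage prediction heatmaps, with seeded
  downsampling for robustness checks.

A synthetic five-species atlas generator (two teleosts, three amniotes, a
shared latent OPC→COP→MOL axis, planted conservation classes and temporal
shapes, negative-binomial counts with dropout, and noisy ortholog tables)
makes every step testable by parameter recovery. See the methods vignette
(`vignettes/methods.Rmd`) for the model, parameter defaults, and design
rationale.

## Worked example

Simulate a five-species atlas (400 cells per species for speed) and run the
full pipeline:

```r
library(oligotraj)

cfg <- run_config(simulate = sim_config(n_cells_per_species = 400, seed = 1))
res <- run_pipeline(cfg)

res$report$common_ortholog_set_size
#> [1] 545

res$report$conservation[c("n_core", "n_amniote_exclusive", "n_teleost_exclusive")]
#> $n_core
#> [1] 55
#> $n_amniote_exclusive
#> [1] 53
#> $n_teleost_exclusive
#> [1] 17

res$datasets$fugu$boundaries[c("b1", "b2")]
#> $b1
#> [1] 0.33
#> $b2
#> [1] 0.69

round(res$crossmap$fugu$heatmap, 3)
#>       OPC   COP   MOL
#> OPC 0.765 0.231 0.004
#> COP 0.027 0.433 0.540
#> MOL 0.000 0.008 0.992
```

Reading the output: of 600 simulated genes, 545 survive ortholog
harmonization in all five species; 55 are recovered as evolutionary core
(planted: 60) and the clade-exclusive asymmetry is recovered directionally
(53 amniote-exclusive vs 17 teleost-exclusive; planted 60 vs 20). Fugu's
stage boundaries land at normalized pseudotime 0.33 and 0.69, and its
prediction-score heatmap against the mouse-analogue reference shows the
diagonal OPC and MOL correspondence; the COP row is spread toward MOL, the
expected behavior for a transient intermediate at this depth. Against the
planted truth, this run recovers the four temporal modules with an adjusted
Rand index of 0.97 and per-species stage accuracies of 0.83–0.92.

Ground truth for any simulated run is in `res$truth`, recovery metrics in
`res$report$recovery`, and `run_config(outdir = ...)` writes all tables
(DEG records, conservation, intersections, module assignments, crossmap
heatmaps) as TSV plus a JSON run report.

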