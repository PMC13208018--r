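# Shared fixtures, built in code and memoized for the session.

tiny_sim_config <- function(seed = 7L, ...) {
  sim_config(
    n_cells_per_species = 220,
    n_genes = 120,
    class_counts = c(core = 16, amniote_only = 12, teleost_only = 6,
                     species_restricted = 10, flat = 76),
    seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_atlas <- function() memo("tiny_atlas", simulate_atlas(tiny_sim_config()))

tiny_pipeline <- function() memo("tiny_pipeline", {
  run_pipeline(run_config(simulate = tiny_sim_config(), n_hvg = 100, seed = 3L))
})

# The default study conditions (5 species x 1500 cells x 600 genes), used by
# the acceptance tests; computed once.
default_pipeline <- function() memo("default_pipeline", {
  run_pipeline(run_config(seed = 0L))
})

# Small harmonized + normalized single species from the tiny atlas.
tiny_species <- function(sp = "human") memo(paste0("tiny_species_", sp), {
  at <- tiny_atlas()
  lognormalize(harmonize_to_reference(at$datasets[[sp]], at$ortholog_maps[[sp]]))
})

# Independent enumeration oracle for the two-sided Mann-Whitney p-value:
# walks every split of the pooled values and counts splits whose U statistic
# deviates from the null mean at least as much as the observed one.
enum_wilcox_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (n - n1) / 2
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  splits <- utils::combn(n, n1)
  hits <- 0
  for (j in seq_len(ncol(splits))) {
    if (abs(u_of(splits[, j]) - mu) >= abs(u_obs - mu) - 1e-12) hits <- hits + 1
  }
  hits / ncol(splits)
}
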