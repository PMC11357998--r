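# Shared helpers for the simulation-based tests.

# Rand index between two flat partitions.
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      agree <- agree + as.integer((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# A minimal two-sex table with independent noise, no structure.
null_table <- function(n, seed) {
  cohort_scenario("null_panel", n = n, seed = seed, n_phenotypes = 1)$data
}

# Evaluate a trajectory over the standard grid for both sexes (male block
# then female block), matching the fit_trajectories layout.
trajectory_shape <- function(spec, grid_points = 300) {
  grid <- seq(20, 80, length.out = grid_points)
  c(trajectory_mean(spec, grid, rep("M", grid_points)),
    trajectory_mean(spec, grid, rep("F", grid_points)))
}
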