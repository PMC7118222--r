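# Shared small-scale fixtures, built once per test run.

# desk-scale configuration: 600-voxel grid, short runs, 4+4+4 subjects
tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             grid_dims = c(10L, 10L, 6L), n_timepoints = 60L,
             n_per_group = c(control = 4L, patient_dpp = 4L,
                             patient_dt = 4L),
             network_fraction = 0.2,
             planted_clusters = list(
               planted_effect(0.3, 0.9, 0.9, 0.3,
                              center = c(0.30, 0.30, 0.55), size = 10L),
               planted_effect(0.3, 0.9, 0.3, 0.3,
                              center = c(0.70, 0.65, 0.45), size = 10L)),
             ...)
}

# medium configuration used for ICA recovery checks
ica_config <- function(seed = 1) {
  sim_config(seed = seed, grid_dims = c(14L, 16L, 12L),
             n_timepoints = 150L,
             n_per_group = c(control = 5L, patient_dpp = 5L,
                             patient_dt = 5L),
             network_fraction = 0.12, base_loading = 0.7, local_sd = 0.3,
             planted_clusters = list(
               planted_effect(0.6, 0.9, 0.9, 0.6,
                              center = c(0.30, 0.30, 0.55), size = 12L)))
}

# cached tiny cohort (with voxel data) shared across test files
.fixture_env <- new.env(parent = emptyenv())
tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny)) .fixture_env$tiny <-
      generate_cohort(tiny_config(seed = 42))
  .fixture_env$tiny
}

# coarse hyperparameter grid for fast LOO tests
fast_grid <- function() svm_grid(c_exp = c(-3, 9), gamma_exp = c(-9, 1),
                                 by = 4)

# single-cell grid when the search itself is not under test
point_grid <- function() list(C = 1, gamma = 0.25)

# brute-force framewise displacement oracle
fd_oracle <- function(p, radius = 50) {
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))[-1]) {
    s <- 0
    for (j in 1:3) s <- s + abs(p[i, j] - p[i - 1, j])
    for (j in 4:6) s <- s + radius * abs(p[i, j] - p[i - 1, j])
    out[i] <- s
  }
  out
}

# exhaustive label-propagation clustering oracle (independent of the BFS
# implementation): iteratively replaces each foreground voxel's label by
# the minimum over its neighbourhood until a fixed point
label_oracle <- function(bin, connectivity = 26) {
  d <- dim(bin)
  lab <- array(0L, d)
  lab[bin] <- seq_len(sum(bin))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  idx <- which(bin)
  crd <- arrayInd(idx, d)
  repeat {
    changed <- FALSE
    for (k in seq_along(idx)) {
      for (o in seq_len(nrow(offs))) {
        nb <- crd[k, ] + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        l2 <- lab[nb[1], nb[2], nb[3]]
        if (l2 > 0 && l2 < lab[idx[k]]) {
          lab[idx[k]] <- l2
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # canonical relabelling to 1..K and per-label sizes
  u <- sort(unique(lab[lab > 0]))
  sizes <- vapply(u, function(l) sum(lab == l), 0L)
  list(n = length(u), sizes = sort(sizes))
}
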