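# Shared fixtures: tiny grids, index-built masks, small seeded cohorts.

tiny_grid <- function(shape = c(8, 8, 8), vox = c(2, 2, 2)) {
  grid_spec(shape, vox)
}

mask_from_idx <- function(idx, grid, id = "p", arm = "A") {
  arr <- array(0L, dim = grid$shape)
  arr[idx] <- 1L
  lesion_mask(arr, grid, patient_id = id, modality = arm)
}

random_masks <- function(n, grid, p = 0.3, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    arr <- array(as.integer(stats::runif(n_voxels(grid)) < p),
                 dim = grid$shape)
    lesion_mask(arr, grid, patient_id = sprintf("p%02d", i))
  })
}

small_cohort <- function(n = 16, seed = 5, ...) {
  generate_cohort(cohort_params(
    n_patients = n, grid = grid_spec(c(16, 16, 16), c(4, 4, 4)),
    seed = seed, ...))
}

# Independent scalar 1-D zero-padded Gaussian convolution (loop form),
# used as the smoothing oracle.
conv1d_oracle <- function(v, sigma, radius = max(1L, ceiling(4 * sigma))) {
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  g <- g / sum(g)
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (o in -radius:radius) {
      j <- i + o
      if (j >= 1 && j <= n) out[i] <- out[i] + g[o + radius + 1] * v[j]
    }
  }
  out
}
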