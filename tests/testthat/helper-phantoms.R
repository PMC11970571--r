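# Small-cohort spec factories used across tests.

small_spec <- function(n_patients = 3, grid = 24, seed = 1, ...) {
  cohort_spec(n_patients = n_patients,
              grid_shape = rep(grid, 3),
              roi_radii_mm = list(meanlog = log(c(8, 7, 7.5)), sdlog = 0.12),
              seed = seed, ...)
}

# tiny grid for replicate-heavy Monte-Carlo loops
tiny_spec <- function(n_patients = 47, seed = 1, ...) {
  cohort_spec(n_patients = n_patients,
              grid_shape = c(12, 12, 12),
              roi_radii_mm = list(meanlog = log(c(4, 3.5, 3.8)), sdlog = 0.15),
              n_fiducials = 0,
              seed = seed, ...)
}

# identity-transform modality params, optionally noise-free
identity_modalities <- function(noise_sd = 0) {
  list(T2w = list(transform = "identity", gamma = 1, gain = 1, offset = 0,
                  noise_sd = noise_sd),
       CT = list(transform = "identity", gamma = 1, gain = 1, offset = 0,
                 noise_sd = noise_sd),
       CBCT = list(transform = "identity", gamma = 1, gain = 1, offset = 0,
                   noise_sd = noise_sd))
}

roi_means <- function(pat) {
  vapply(pat$volumes, function(v) mean(v$values[pat$mask$inside]), 0)
}

# two-sided null band for the Spearman coefficient at sample size n
spearman_null_band <- function(n, n_sim = 5000, probs = c(0.025, 0.975)) {
  r <- replicate(n_sim, {
    x <- sample.int(n)
    y <- sample.int(n)
    cor(x, y, method = "spearman")
  })
  quantile(r, probs)
}
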