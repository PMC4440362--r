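# shared fixture builders (everything is generated in code at test time)

# coarse-resolution spec used where a full acquisition is simulated but the
# paper-resolution grid would be needlessly large for the check at hand
coarse_spec <- function(types = c(thin = 1), seed = 1, sbi = c(1, rep(0, 9)),
                        noise_sd = 0.02, jitter = 3, drift = 0.1, ...) {
  phantom_spec(spacing = c(8, 8, 25), n_spines_per_type = types,
               sbi_distribution = sbi, nonsynaptic_fraction = 0,
               neck_synapse_fraction = 0, noise_sd = noise_sd,
               slice_jitter_px = jitter, intensity_drift = drift,
               rng_seed = seed, ...)
}

# single-spine label-only phantom at the acquisition resolution, with the
# neck-base attachment point attached to the spine mask
clean_spine_mask <- function(type, seed) {
  spec <- phantom_spec(spacing = c(3.7, 3.7, 25),
                       n_spines_per_type = setNames(1L, type),
                       nonsynaptic_fraction = 1, rng_seed = seed)
  ph <- build_phantom(spec, render_intensity = FALSE)
  truth <- ph$truth
  sid <- truth$id[truth$category == "spine" & truth$labeled]
  m <- object_mask(ph$segmentation, sid)
  b <- attr(truth, "bases")
  attr(m, "base_nm") <- c(b$x[1], b$y[1], b$z[1])
  attr(m, "truth") <- truth
  m
}

# a stack of n copies of one textured slice (statistically homogeneous,
# the setting in which per-slice gain recovery is well-posed)
homogeneous_stack <- function(n = 8, seed = 1, ny = 48, nx = 56) {
  set.seed(seed)
  sl <- matrix(runif(ny * nx, 0.3, 0.7), ny, nx)
  image_stack(array(rep(sl, n), c(ny, nx, n)), c(10, 10, 25))
}

# random blobby mask (union of ellipsoids) for isoperimetric sweeps
random_blob_mask <- function(seed, d = c(18L, 18L, 12L),
                             spacing = c(10, 10, 22)) {
  set.seed(seed)
  a <- array(FALSE, d)
  g <- as.matrix(expand.grid(y = seq_len(d[1]), x = seq_len(d[2]),
                             z = seq_len(d[3])))
  for (e in seq_len(sample(1:4, 1))) {
    c0 <- c(runif(1, 5, d[1] - 4), runif(1, 5, d[2] - 4),
            runif(1, 4, d[3] - 3))
    rr <- runif(3, 2, 4.5)
    inside <- ((g[, 1] - c0[1]) / rr[1])^2 + ((g[, 2] - c0[2]) / rr[2])^2 +
      ((g[, 3] - c0[3]) / rr[3])^2 <= 1
    a[g[inside, , drop = FALSE]] <- TRUE
  }
  if (!any(a)) {
    ball <- ((g[, 1] - 9)^2 + (g[, 2] - 9)^2 + (g[, 3] - 6)^2) <= 9
    a[g[ball, , drop = FALSE]] <- TRUE
  }
  mask_from_array(a, spacing)
}

# piecewise linear-then-flat responses for breakpoint recovery
two_regime_data <- function(seed, n = 200, thr = 5e7, slope = 1e-6,
                            noise = 2) {
  set.seed(seed)
  x <- runif(n, 0, 1e8)
  y <- ifelse(x < thr, slope * x, slope * thr) + rnorm(n, 0, noise)
  list(x = x, y = y, thr = thr)
}
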