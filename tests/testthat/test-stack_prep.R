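test_that("stack write/read round trip is exact and keeps spacing", {
  ramp <- quantize_intensity(array(seq(0, 1, length.out = 48), c(4, 4, 3)))
  st <- image_stack(ramp, c(3.7, 3.7, 25))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path, c(3.7, 3.7, 25))
  expect_identical(dim(back$grid), dim(st$grid))
  expect_equal(back$grid, st$grid, tolerance = 0)
  expect_equal(unname(back$spacing), c(3.7, 3.7, 25))
})

test_that("unreadable and malformed stack files are rejected", {
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "cannot read")
  junk <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", junk)
  expect_error(read_stack(junk))
  expect_error(image_stack(array(c(1, NA), c(1, 1, 2))), "finite")
})

test_that("alignment undoes the generator's recorded jitter exactly", {
  spec <- coarse_spec(c(thin = 1), seed = 7, noise_sd = 0.02, jitter = 3,
                      drift = 0.1)
  ph <- build_phantom(spec)
  art <- apply_acquisition_artifacts(ph$stack, spec)
  al <- align_translation(art$stack, max_shift_px = 8)
  sh <- al$alignment$shifts
  expect_identical(sh$cum_dy, -unname(art$jitter[, "dy"]))
  expect_identical(sh$cum_dx, -unname(art$jitter[, "dx"]))
})

test_that("an already-aligned stack is returned unchanged", {
  st <- homogeneous_stack(n = 5, seed = 3)
  set.seed(4)
  st$grid <- st$grid + array(rnorm(length(st$grid), 0, 0.01), dim(st$grid))
  al <- align_translation(st, max_shift_px = 4)
  expect_true(all(al$alignment$shifts$dy == 0))
  expect_true(all(al$alignment$shifts$dx == 0))
  expect_equal(al$stack$grid, st$grid)
})

test_that("shifts beyond the search window are boundary-limited", {
  set.seed(5)
  sl <- matrix(runif(80 * 90), 80, 90)
  sm <- array(0, c(80, 90, 2))
  sm[, , 1] <- sl
  sm[, , 2] <- rbind(sl[-(1:3), ], sl[1:3, ])  # shift well beyond window 2
  st <- image_stack(sm, c(10, 10, 25))
  al <- align_translation(st, max_shift_px = 2)
  expect_true(al$alignment$shifts$boundary_limited[2])
  expect_lte(max(abs(al$alignment$shifts[2, c("dy", "dx")])), 2)
})

test_that("flat slices get zero shift with a warning", {
  sm <- array(0.5, c(20, 20, 3))
  set.seed(1)
  sm[, , 2] <- matrix(runif(400), 20, 20)
  st <- image_stack(sm, c(10, 10, 25))
  expect_warning(al <- align_translation(st, max_shift_px = 3), "flat")
  expect_true(all(al$alignment$shifts$dy == 0))
})

test_that("normalization equalizes drifted copies of one slice", {
  st <- homogeneous_stack(n = 8, seed = 11)
  set.seed(12)
  drift <- runif(8, 0.8, 1.2)
  for (k in 1:8) st$grid[, , k] <- st$grid[, , k] * drift[k]
  norm <- normalize_slices(st)
  mu <- apply(norm$grid, 3, mean)
  expect_lt(max(abs(mu / mean(mu) - 1)), 1e-6)
  # recovered gains proportional to the inverse applied drift
  gains <- attr(norm, "normalization")$gain
  rel <- gains * drift
  expect_lt(max(abs(rel / mean(rel) - 1)), 0.01)
})

test_that("generator-recorded drift factors are recovered (noiseless)", {
  st <- homogeneous_stack(n = 10, seed = 21)
  spec <- phantom_spec(n_spines_per_type = c(thin = 0), noise_sd = 0,
                       slice_jitter_px = 0, intensity_drift = 0.15,
                       rng_seed = 8)
  art <- apply_acquisition_artifacts(st, spec)
  gains <- attr(normalize_slices(art$stack), "normalization")$gain
  rel <- gains * art$drift
  expect_lt(max(abs(rel / mean(rel) - 1)), 0.01)
})

test_that("normalization is idempotent and handles constant slices", {
  st <- homogeneous_stack(n = 6, seed = 31)
  st$grid[, , 3] <- 0.42  # degenerate slice
  once <- normalize_slices(st)
  twice <- normalize_slices(once)
  expect_equal(twice$grid, once$grid, tolerance = 1e-9)
  flat <- image_stack(array(0.3, c(8, 8, 4)), c(10, 10, 25))
  nf <- normalize_slices(flat)
  expect_equal(sd(nf$grid), 0)
})

test_that("blur is identity at radius 0, conserves mass, keeps the mean", {
  st <- homogeneous_stack(n = 3, seed = 41)
  expect_equal(blur_stack(st, 0)$grid, st$grid)
  expect_error(blur_stack(st, -1), ">= 0")

  imp <- array(0, c(41, 41, 1))
  imp[21, 21, 1] <- 5
  bi <- blur_stack(image_stack(imp, c(10, 10, 25)), 10)
  expect_equal(sum(bi$grid), 5, tolerance = 1e-6)

  # interior-supported image: reflective boundaries preserve the mean
  blob <- array(0.2, c(60, 60, 2))
  ys <- matrix(rep(1:60, 60), 60)
  blob[, , 1] <- 0.2 + 0.5 * exp(-((ys - 30)^2 + (t(ys) - 30)^2) / 50)
  blob[, , 2] <- blob[, , 1]
  bb <- blur_stack(image_stack(blob, c(10, 10, 25)), 10)
  expect_equal(mean(bb$grid), mean(blob), tolerance = 1e-6)
})

test_that("label volumes round trip exactly through 16-bit TIFF", {
  set.seed(51)
  lab <- array(sample(0:7, 4 * 5 * 3, replace = TRUE), c(4, 5, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_labels(lab, path)
  expect_identical(read_labels(path), lab)
})
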