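test_that("empty spec yields pure background and empty tables", {
  spec <- phantom_spec(n_spines_per_type = c(thin = 0))
  ph <- build_phantom(spec)
  expect_equal(nrow(ph$truth), 0L)
  expect_true(all(ph$segmentation$labels == 0L))
  expect_equal(nrow(ph$segmentation$objects), 0L)
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- coarse_spec(c(thin = 1, mushroom = 1), seed = 4,
                      sbi = c(.5, .5, rep(0, 8)))
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a$segmentation$labels, b$segmentation$labels)
  expect_identical(a$stack$grid, b$stack$grid)
  expect_identical(a$truth, b$truth)
})

test_that("concentrated SBi distribution produces the requested wiring", {
  # a bouton with SBi 7 contacts the labeled spine plus 6 unlabeled elements
  spec <- coarse_spec(c(mushroom = 1), seed = 42,
                      sbi = c(rep(0, 6), 1, rep(0, 3)))
  ph <- build_phantom(spec, render_intensity = FALSE)
  b <- ph$truth[ph$truth$category == "bouton", ]
  expect_equal(nrow(b), 1L)
  expect_equal(b$sbi, 7L)
  syn <- ph$truth[ph$truth$category == "synaptic_junction", ]
  expect_equal(nrow(syn), 7L)
  expect_true(all(syn$bouton_id == b$id))
  posts <- ph$truth[match(syn$post_id, ph$truth$id), ]
  expect_equal(sum(posts$labeled), 1L)
  expect_equal(sum(!posts$labeled), 6L)
})

test_that("ground-truth SBi matches label adjacency in the rendered grid", {
  spec <- coarse_spec(c(thin = 2, mushroom = 1), seed = 9,
                      sbi = c(.3, .4, .3, rep(0, 7)))
  ph <- build_phantom(spec, render_intensity = FALSE)
  g <- build_graph(ph$segmentation)
  truth_b <- ph$truth[ph$truth$category == "bouton", ]
  got <- g$boutons$sbi[match(truth_b$id, g$boutons$bouton_id)]
  expect_equal(got, truth_b$sbi)
})

test_that("rasterized ball volume converges to the analytic value", {
  m <- digitize_ball(200, c(10, 10, 10))  # radius = 20 voxels
  expect_lt(abs(measure_volume(m) - 4 / 3 * pi * 200^3) /
              (4 / 3 * pi * 200^3), 0.01)
})

test_that("geometry overflow and impossible specs are rejected", {
  spec <- phantom_spec(grid_shape = c(50, 50, 8),
                       n_spines_per_type = c(mushroom = 1))
  expect_error(build_phantom(spec), "geometry overflow")
  bad <- phantom_spec(n_spines_per_type = c(branched = 1))
  bad$geometry_ranges$branched$branch_count <- c(1, 1)
  expect_error(build_phantom(bad), "impossible spec")
  expect_error(phantom_spec(sbi_distribution = rep(0.2, 10)),
               "sbi_distribution")
  expect_error(phantom_spec(spacing = c(0, 3.7, 25)), "spacing")
})

test_that("acquisition artifacts are reproducible, bounded, and optional", {
  spec <- coarse_spec(c(thin = 1), seed = 2, noise_sd = 0, jitter = 0,
                      drift = 0)
  ph <- build_phantom(spec)
  art0 <- apply_acquisition_artifacts(ph$stack, spec)
  expect_identical(art0$stack$grid, ph$stack$grid)  # identity case

  spec3 <- coarse_spec(c(thin = 1), seed = 2, noise_sd = 0, jitter = 3,
                       drift = 0)
  a1 <- apply_acquisition_artifacts(ph$stack, spec3)
  a2 <- apply_acquisition_artifacts(ph$stack, spec3)
  expect_identical(a1$jitter, a2$jitter)
  expect_true(all(abs(a1$jitter) <= 3))
  expect_true(all(a1$jitter[1, ] == 0))

  specn <- coarse_spec(c(thin = 1), seed = 2, noise_sd = 0.05, jitter = 0,
                       drift = 0)
  an <- apply_acquisition_artifacts(ph$stack, specn)
  v0 <- apply(ph$stack$grid, 3, function(s) var(as.vector(s)))
  v1 <- apply(an$stack$grid, 3, function(s) var(as.vector(s)))
  expect_true(all(v1 > v0))

  # different seeds give different noise fields
  specm <- specn
  specm$rng_seed <- 77L
  am <- apply_acquisition_artifacts(ph$stack, specm)
  expect_false(identical(an$stack$grid, am$stack$grid))
})

test_that("the population sampler reflects the spec type mixture", {
  spec <- phantom_spec(n_spines_per_type = c(thin = 3, mushroom = 1))
  set.seed(1)
  pop <- sample_spine_population(spec, 400)
  expect_setequal(unique(pop$type), c("thin", "mushroom"))
  expect_gt(mean(pop$type == "thin"), 0.6)
  expect_true(all(pop$volume_nm3 > 0))
  # mushroom spines are larger than thin spines on average
  expect_gt(mean(pop$volume_nm3[pop$type == "mushroom"]),
            mean(pop$volume_nm3[pop$type == "thin"]))
})

test_that("phantom artifacts round-trip through disk", {
  spec <- coarse_spec(c(stubby = 1), seed = 6)
  ph <- build_phantom(spec)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  lab <- read_labels(file.path(dir, "labels.tif"))
  expect_identical(lab, ph$segmentation$labels)
  st <- read_stack(file.path(dir, "stack.tif"), spec$spacing)
  expect_equal(st$grid, quantize_intensity(ph$stack$grid),
               tolerance = 1e-12)
  tr <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(tr), nrow(ph$truth))
})
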