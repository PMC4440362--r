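test_that("seed growing recovers a uniform dark cube exactly", {
  g <- array(200 / 255, c(20, 20, 8))
  g[6:12, 7:14, 3:6] <- 10 / 255
  st <- image_stack(g, c(10, 10, 25))
  m <- seed_grow(st, c(8, 8, 4), threshold = 100 / 255)
  expect_identical(m$idx, which(g == 10 / 255))
})

test_that("seed growing stays inside the seeded component", {
  g <- array(0.8, c(20, 30, 6))
  g[4:8, 4:8, 2:4] <- 0.1    # blob A
  g[12:16, 20:26, 2:4] <- 0.1  # blob B
  st <- image_stack(g, c(10, 10, 25))
  mA <- seed_grow(st, c(5, 5, 3), threshold = 0.3)
  expect_identical(mA$idx, which(g == 0.1 & slice.index(g, 2) <= 15))
  # oracle: connected component labels of the thresholded set
  lab <- array(spinemorph:::cpp_label_components(as.logical(g <= 0.3),
                                                 dim(g), 26L), dim(g))
  expect_identical(mA$idx, which(lab == lab[5, 5, 3]))
})

test_that("seed choice within a component does not change the mask", {
  g <- array(0.8, c(15, 15, 6))
  g[3:10, 4:12, 2:5] <- 0.1
  st <- image_stack(g, c(10, 10, 25))
  m1 <- seed_grow(st, c(4, 3, 2), threshold = 0.3)
  m2 <- seed_grow(st, c(12, 10, 5), threshold = 0.3)
  expect_identical(m1$idx, m2$idx)
  expect_error(seed_grow(st, c(1, 1, 1), threshold = 0.3), "predicate")
})

test_that("grown mask tracks ground truth through the blurred companion", {
  spec <- phantom_spec(spacing = c(3.7, 3.7, 25),
                       n_spines_per_type = c(thin = 1, mushroom = 1),
                       sbi_distribution = c(1, rep(0, 9)),
                       nonsynaptic_fraction = 0, neck_synapse_fraction = 0,
                       noise_sd = 0, slice_jitter_px = 0,
                       intensity_drift = 0, rng_seed = 3)
  ph <- build_phantom(spec)
  bl <- blur_stack(ph$stack, 10)
  lab <- ph$segmentation$labels
  co <- which(lab == 1L, arr.ind = TRUE)
  grown <- seed_grow(bl, round(colMeans(co))[c(2, 1, 3)], threshold = 0.35)
  syn_ids <- ph$truth$id[ph$truth$category == "synaptic_junction"]
  keep <- grown$idx[!(lab[grown$idx] %in% syn_ids)]
  gt <- sum(lab %in% ph$truth$id[ph$truth$category %in%
                                   c("dendrite_shaft", "spine") &
                                   ph$truth$labeled])
  expect_lt(abs(length(keep) / gt - 1), 0.05)
})

test_that("painted labels import with categories and stay unmerged", {
  lab <- array(0L, c(8, 8, 4))
  lab[2:3, 2:3, 2] <- 1L
  lab[4:5, 2:3, 2] <- 2L  # touches label 1
  lab[6, 6, 3] <- 3L
  sidecar <- data.frame(id = 1:3,
                        category = c("synaptic_junction",
                                     "synaptic_junction", "bouton"))
  seg <- import_labels(lab, sidecar, c(10, 10, 25))
  expect_equal(nrow(seg$objects), 3L)
  expect_equal(sort(unique(seg$labels[seg$labels > 0])), 1:3)
  # two touching junction labels remain two objects
  expect_equal(sum(seg$objects$category == "synaptic_junction"), 2L)
  expect_error(import_labels(lab, sidecar[-2, ], c(10, 10, 25)),
               "absent from the object table")
  expect_error(import_labels(lab, sidecar, c(10, 10, 25),
                             reference_dim = c(9, 8, 4)), "shape")
})

test_that("a bare cylinder yields no spines and an unchanged shaft", {
  a <- array(FALSE, c(25, 60, 11))
  for (z in 1:11) for (y in 1:25)
    if ((y - 13)^2 * 100 + (z - 6)^2 * 625 <= 100^2) a[y, 4:57, z] <- TRUE
  m <- mask_from_array(a, c(10, 10, 25))
  res <- split_dendrite(m)
  expect_length(res$spines, 0)
  expect_identical(sort(res$shaft$idx), m$idx)
})

test_that("spine isolation conserves voxels and finds true attachments", {
  spec <- phantom_spec(spacing = c(3.7, 3.7, 25),
                       n_spines_per_type = c(thin = 1, mushroom = 1),
                       nonsynaptic_fraction = 1, noise_sd = 0,
                       slice_jitter_px = 0, intensity_drift = 0,
                       rng_seed = 13)
  ph <- build_phantom(spec, render_intensity = FALSE)
  lab <- ph$segmentation$labels
  den <- voxel_mask(which(lab > 0L), dim(lab), spec$spacing)
  res <- split_dendrite(den)
  # conservation and disjointness
  all_idx <- c(res$shaft$idx, unlist(lapply(res$spines, `[[`, "idx")))
  expect_identical(sort(all_idx), den$idx)
  expect_equal(length(all_idx), length(unique(all_idx)))
  expect_length(res$spines, 2)
  # per-spine recovery vs ground truth on the binary phantom
  bases <- attr(ph$truth, "bases")
  for (sid in ph$truth$id[ph$truth$category == "spine"]) {
    tidx <- which(lab == sid)
    iou <- max(vapply(res$spines, function(m)
      length(intersect(m$idx, tidx)) / length(union(m$idx, tidx)),
      numeric(1)))
    expect_gte(iou, 0.9)
  }
  # cut plane within 2 z-slices (50 nm) of the true neck base
  for (m in res$spines) {
    b <- attr(m, "base_nm")
    dd <- sqrt((bases$x - b[1])^2 + (bases$y - b[2])^2 +
                 (bases$z - b[3])^2)
    expect_lt(min(dd), 50)
  }
})

test_that("branched spines come out of the dendrite split as one mask", {
  spec <- phantom_spec(spacing = c(3.7, 3.7, 25),
                       n_spines_per_type = c(branched = 1),
                       nonsynaptic_fraction = 1, rng_seed = 17)
  ph <- build_phantom(spec, render_intensity = FALSE)
  lab <- ph$segmentation$labels
  den <- voxel_mask(which(lab > 0L), dim(lab), spec$spacing)
  res <- split_dendrite(den)
  expect_length(res$spines, 1)
  f <- extract_features(res$spines[[1]])
  expect_gte(f$head_count, 2L)
})

test_that("otsu threshold separates a bimodal stack", {
  set.seed(2)
  g <- array(c(rnorm(4000, 0.2, 0.02), rnorm(4000, 0.7, 0.02)),
             c(20, 20, 20))
  th <- otsu_threshold(image_stack(g, c(10, 10, 25)))
  expect_gt(th, 0.3)
  expect_lt(th, 0.6)
})
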