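fib_spacing <- c(3.7, 3.7, 25)

test_that("voxel-counting volume matches closed-form arithmetic", {
  one <- voxel_mask(1, c(1, 1, 1), fib_spacing)
  expect_equal(measure_volume(one), 342.25)
  block <- mask_from_array(array(TRUE, c(10, 10, 10)), fib_spacing)
  expect_equal(measure_volume(block), 342250)
  expect_error(measure_volume(voxel_mask(integer(0), c(2, 2, 2),
                                         fib_spacing)), "empty")
})

test_that("voxel-face surface area matches hand-counted faces", {
  one <- voxel_mask(1, c(1, 1, 1), fib_spacing)
  expect_equal(measure_surface_area(one), 2 * 3.7^2 + 4 * 3.7 * 25)
  bar <- mask_from_array(array(TRUE, c(1, 2, 1)), fib_spacing) # 2 along x
  expect_equal(measure_surface_area(bar), 609.76)
})

test_that("digitized-ball estimators converge to the analytic sphere", {
  m <- digitize_ball(200, c(10, 10, 10))  # r = 20 voxels
  va <- 4 / 3 * pi * 200^3
  aa <- 4 * pi * 200^2
  expect_lt(abs(measure_volume(m) - va) / va, 0.01)
  ratio <- measure_surface_area(m, "voxel_face") / aa
  expect_gt(ratio, 1.45)
  expect_lt(ratio, 1.55)
  expect_lt(abs(measure_surface_area(m, "mesh") - aa) / aa, 0.03)
  expect_lt(abs(eq_diameter(measure_volume(m)) - 400) / 400, 0.01)
})

test_that("sphericity has its closed-form values and ordering", {
  expect_equal(sphericity(4 / 3 * pi * 100^3, 4 * pi * 100^2), 1,
               tolerance = 1e-12)
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  expect_equal(round(sphericity(1, 6), 4), 0.806)
  # elongated shapes score lower than compact shapes of equal volume
  iso <- c(10, 10, 10)
  cube <- mask_from_array(array(TRUE, c(8, 8, 8)), iso)
  rod <- mask_from_array(array(TRUE, c(2, 128, 2)), iso)
  expect_equal(measure_volume(cube), measure_volume(rod))
  s_cube <- sphericity(measure_volume(cube), measure_surface_area(cube))
  s_rod <- sphericity(measure_volume(rod), measure_surface_area(rod))
  expect_gt(s_cube, s_rod)
  expect_error(sphericity(0, 1), "positive")
  expect_error(eq_diameter(-1), "positive")
})

test_that("mesh sphericity respects the isoperimetric bound on random shapes", {
  worst <- 0
  for (s in 1:60) {
    m <- random_blob_mask(s)
    st <- mesh_surface_stats(m)
    worst <- max(worst, sphericity(st["volume"], st["area"]))
  }
  expect_lte(worst, 1 + 1e-9)
})

test_that("scaling the spacing scales volume and area as k^3 and k^2", {
  set.seed(8)
  m <- random_blob_mask(3)
  k <- 2.5
  mk <- voxel_mask(m$idx, m$dim, m$spacing * k)
  expect_equal(measure_volume(mk), k^3 * measure_volume(m))
  expect_equal(measure_surface_area(mk), k^2 * measure_surface_area(m))
  expect_equal(sphericity(measure_volume(mk), measure_surface_area(mk)),
               sphericity(measure_volume(m), measure_surface_area(m)))
})

test_that("synapse records compose volume, area and sphericity", {
  one <- voxel_mask(1, c(1, 1, 1), fib_spacing)
  rec <- measure_synapse(one, id = 5L)
  expect_equal(rec$volume_nm3, 342.25)
  expect_equal(rec$eq_diameter_nm, (6 * 342.25 / pi)^(1 / 3))
  expect_equal(rec$method, "voxel_face")
  expect_error(measure_synapse(voxel_mask(integer(0), c(2, 2, 2),
                                          fib_spacing)), "empty")
  # disc junction of known radius and thickness measures near analytic
  r <- 150; h <- 40
  d <- c(91, 91, 9)
  g <- as.matrix(expand.grid(y = 1:91, x = 1:91, z = 1:9))
  px <- (g[, "x"] - 46) * 3.7; py <- (g[, "y"] - 46) * 3.7
  pz <- (g[, "z"] - 5) * 25
  a <- array(FALSE, d)
  a[g[px^2 + py^2 <= r^2 & abs(pz) <= h, ]] <- TRUE
  disc <- mask_from_array(a, fib_spacing)
  va <- pi * r^2 * 75  # slices at -25, 0, +25 nm fall inside |z| <= 40
  expect_lt(abs(measure_volume(disc) - va) / va, 0.05)
})

test_that("branched spines split into one mask per true head", {
  for (s in 1:2) {
    m <- clean_spine_mask("branched", 500 + s)
    hd <- attr(attr(m, "truth"), "heads")
    sb <- split_branched(m)
    expect_true(sb$branched)
    expect_equal(length(sb$masks), nrow(hd))
    arrs <- lapply(sb$masks, function(mm) {
      a <- array(FALSE, mm$dim); a[mm$idx] <- TRUE; a
    })
    hits <- vapply(arrs, function(a)
      sum(vapply(seq_len(nrow(hd)), function(i) {
        v <- round(c(hd$y[i] / 3.7, hd$x[i] / 3.7, hd$z[i] / 25)) + 1
        a[v[1], v[2], v[3]]
      }, logical(1))), integer(1))
    expect_true(all(hits == 1L))  # exactly one true head centroid per mask
    # voxel additivity: split volumes sum to the input volume
    expect_equal(sum(vapply(sb$masks, measure_volume, numeric(1))),
                 measure_volume(m))
  }
})

test_that("single-headed spines pass through branched splitting", {
  m <- clean_spine_mask("thin", 61)
  sb <- split_branched(m)
  expect_false(sb$branched)
  expect_length(sb$masks, 1)
  expect_identical(sb$masks[[1]]$idx, m$idx)
})
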