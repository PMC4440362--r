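#' Phantom specification
#'
#' Parametric description of a synthetic FIB/SEM-like scene: a DAB-dark
#' dendritic shaft running through the volume, spines of the five
#' morphological classes (thin, filopodial, stubby, mushroom, branched)
#' attached to it, asymmetric synaptic junctions on spine heads or necks,
#' and presynaptic boutons each contacting the labeled spine plus
#' `SBi - 1` unlabeled postsynaptic elements.  The defaults encode the
#' acquisition geometry of the emulated experiment (3.7 nm/px in XY, 25 nm
#' in Z) and connectivity rates in the ranges reported for mature granule
#' cells (about 2\% non-synaptic spines, about 3\% neck synapses, SBi from
#' 1 to 10 with a long right tail).
#'
#' @param grid_shape voxels per axis `c(x, y, z)`, or `NULL` to auto-size
#'   the grid around the generated scene.
#' @param spacing voxel spacing in nm, `c(x, y, z)`.
#' @param n_spines_per_type named counts over
#'   `thin, filopodial, stubby, mushroom, branched` (missing names = 0).
#' @param geometry_ranges per-type min/max geometry (nm); see
#'   [default_geometry_ranges()].
#' @param sbi_distribution probability over SBi = 1..10; must sum to 1.
#' @param nonsynaptic_fraction probability that a spine carries no synapse.
#' @param neck_synapse_fraction probability that a synapse sits on the neck.
#' @param noise_sd additive Gaussian noise scale applied by
#'   [apply_acquisition_artifacts()].
#' @param slice_jitter_px maximal per-slice integer translation (pixels).
#' @param intensity_drift half-range of the per-slice multiplicative drift.
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL,
                         spacing = c(3.7, 3.7, 25),
                         n_spines_per_type = c(thin = 1, filopodial = 1,
                                               stubby = 1, mushroom = 1,
                                               branched = 1),
                         geometry_ranges = default_geometry_ranges(),
                         sbi_distribution = default_sbi_distribution(),
                         nonsynaptic_fraction = 0.02,
                         neck_synapse_fraction = 0.03,
                         noise_sd = 0.02,
                         slice_jitter_px = 3L,
                         intensity_drift = 0.1,
                         rng_seed = 1L) {
  spacing <- check_spacing(spacing)
  counts <- setNames(rep(0L, length(spine_types())), spine_types())
  if (length(n_spines_per_type)) {
    if (is.null(names(n_spines_per_type)))
      stop("`n_spines_per_type` must be named")
    bad <- setdiff(names(n_spines_per_type), spine_types())
    if (length(bad)) stop("unknown spine type(s): ", toString(bad))
    counts[names(n_spines_per_type)] <- as.integer(n_spines_per_type)
  }
  if (any(counts < 0)) stop("spine counts must be >= 0")
  p <- as.numeric(sbi_distribution)
  if (length(p) != 10L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("`sbi_distribution` must be 10 probabilities over SBi 1..10 summing to 1")
  for (frac in c(nonsynaptic_fraction, neck_synapse_fraction))
    if (frac < 0 || frac > 1) stop("fractions must lie in [0, 1]")
  for (ty in names(geometry_ranges))
    for (fld in names(geometry_ranges[[ty]])) {
      rg <- geometry_ranges[[ty]][[fld]]
      if (length(rg) != 2L || rg[1] > rg[2])
        stop("geometry range ", ty, "$", fld, " must be c(min, max)")
    }
  if (noise_sd < 0 || slice_jitter_px < 0 || intensity_drift < 0)
    stop("noise, jitter and drift parameters must be >= 0")
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stop("`grid_shape` must be three positive voxel counts (x, y, z)")
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 n_spines_per_type = counts,
                 geometry_ranges = geometry_ranges,
                 sbi_distribution = p,
                 nonsynaptic_fraction = nonsynaptic_fraction,
                 neck_synapse_fraction = neck_synapse_fraction,
                 noise_sd = noise_sd,
                 slice_jitter_px = as.integer(slice_jitter_px),
                 intensity_drift = intensity_drift,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
spine_types <- function() {
  c("thin", "filopodial", "stubby", "mushroom", "branched")
}

#' @rdname phantom_spec
#' @export
default_geometry_ranges <- function() {
  list(
    thin       = list(neck_length = c(600, 1100), neck_radius = c(50, 75),
                      head_radius = c(110, 150), branch_count = c(1, 1)),
    filopodial = list(neck_length = c(1100, 1800), neck_radius = c(55, 75),
                      head_radius = c(58, 80), branch_count = c(1, 1)),
    stubby     = list(neck_length = c(0, 0), neck_radius = c(130, 190),
                      head_radius = c(130, 190), branch_count = c(1, 1)),
    mushroom   = list(neck_length = c(400, 700), neck_radius = c(80, 115),
                      head_radius = c(200, 290), branch_count = c(1, 1)),
    branched   = list(neck_length = c(500, 800), neck_radius = c(60, 85),
                      head_radius = c(110, 160), branch_count = c(2, 3))
  )
}

#' @rdname phantom_spec
#' @export
default_sbi_distribution <- function() {
  c(0.28, 0.24, 0.14, 0.10, 0.08, 0.06, 0.04, 0.03, 0.02, 0.01)
}

# fixed intensity lookup (fractions of full scale); DAB-labeled structures
# are dark under backscattered-electron contrast, synaptic densities
# darkest, vesicle-filled boutons bright, unlabeled elements near neuropil.
phantom_intensities <- function() {
  c(background = 0.55, dendrite = 0.15, synapse = 0.05,
    bouton = 0.75, element = 0.45)
}

shaft_radius_nm <- 250
synapse_thickness_nm <- 50
synapse_overlap_nm <- 15

# ---- geometry sampling ----------------------------------------------------

runif_range <- function(rg) if (rg[1] == rg[2]) rg[1] else runif(1, rg[1], rg[2])

sample_one_geometry <- function(type, ranges) {
  g <- ranges[[type]]
  bc <- if (type == "branched") {
    sample(seq.int(g$branch_count[1], g$branch_count[2]), 1L)
  } else 1L
  neck_r <- runif_range(g$neck_radius)
  head_r <- if (type == "stubby") neck_r
    else if (type == "filopodial") neck_r * runif(1, 1.0, 1.1)
    else runif_range(g$head_radius)
  list(type = type,
       neck_len = runif_range(g$neck_length),
       neck_r = neck_r,
       head_r = head_r,
       branch_count = bc)
}

#' Sample the phantom's per-spine statistical model
#'
#' Draws `n` spines from the generator's type mixture and geometry ranges
#' without rasterizing anything, returning model (analytic) volumes and
#' synapse sizes.  This is the fast path for statistical simulations that
#' need realistic per-spine measurement distributions.
#'
#' @param spec a [phantom_spec]; type mixture is proportional to
#'   `n_spines_per_type`.
#' @param n number of spines to draw.
#' @return A data.frame with columns `type`, `neck_len`, `neck_r`,
#'   `head_r`, `branch_count`, `volume_nm3`, `synapse_size_nm3`.
#' @export
sample_spine_population <- function(spec, n) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1)
  w <- spec$n_spines_per_type
  if (sum(w) == 0) stop("spec requests no spines")
  types <- sample(names(w), n, replace = TRUE, prob = w / sum(w))
  rows <- lapply(types, sample_one_geometry, ranges = spec$geometry_ranges)
  df <- do.call(rbind, lapply(rows, function(r) {
    vol <- r$branch_count *
      (pi * r$neck_r^2 * r$neck_len / max(1, r$branch_count) +
       4 / 3 * pi * r$head_r^3)
    syn_r <- max(80, 0.5 * r$head_r * runif(1, 0.9, 1.1))
    data.frame(type = r$type, neck_len = r$neck_len, neck_r = r$neck_r,
               head_r = r$head_r, branch_count = r$branch_count,
               volume_nm3 = vol,
               synapse_size_nm3 = pi * syn_r^2 * synapse_thickness_nm)
  }))
  df
}

# ---- shape primitives -----------------------------------------------------

sh_sphere <- function(center, r, label, value) {
  list(kind = "sphere", center = center, r = r, label = label, value = value)
}
sh_capsule <- function(p0, p1, r, label, value) {
  list(kind = "capsule", p0 = p0, p1 = p1, r = r, label = label,
       value = value)
}
sh_disc <- function(center, normal, r, half, label, value) {
  list(kind = "disc", center = center, normal = normal / sqrt(sum(normal^2)),
       r = r, half = half, label = label, value = value)
}

shape_bbox <- function(sh) {
  switch(sh$kind,
    sphere = rbind(sh$center - sh$r, sh$center + sh$r),
    capsule = rbind(pmin(sh$p0, sh$p1) - sh$r, pmax(sh$p0, sh$p1) + sh$r),
    disc = {
      ext <- sqrt(sh$r^2 * (1 - sh$normal^2) + sh$half^2 * sh$normal^2) +
        1e-9
      rbind(sh$center - ext, sh$center + ext)
    })
}

shift_shape <- function(sh, o) {
  for (f in c("center", "p0", "p1")) if (!is.null(sh[[f]]))
    sh[[f]] <- sh[[f]] + o
  sh
}

# membership of grid points in the shape; PX/PY/PZ are coordinate arrays
shape_inside <- function(sh, PX, PY, PZ) {
  if (sh$kind == "sphere") {
    (PX - sh$center[1])^2 + (PY - sh$center[2])^2 +
      (PZ - sh$center[3])^2 <= sh$r^2
  } else if (sh$kind == "capsule") {
    d <- sh$p1 - sh$p0
    dd <- sum(d^2)
    wx <- PX - sh$p0[1]; wy <- PY - sh$p0[2]; wz <- PZ - sh$p0[3]
    t <- if (dd > 0) pmin(pmax((wx * d[1] + wy * d[2] + wz * d[3]) / dd, 0), 1)
         else 0
    (wx - t * d[1])^2 + (wy - t * d[2])^2 + (wz - t * d[3])^2 <= sh$r^2
  } else { # disc
    n <- sh$normal
    wx <- PX - sh$center[1]; wy <- PY - sh$center[2]; wz <- PZ - sh$center[3]
    a <- wx * n[1] + wy * n[2] + wz * n[3]
    abs(a) <= sh$half &
      (wx^2 + wy^2 + wz^2 - a^2) <= sh$r^2
  }
}

# rasterize shapes into a label grid and (optionally) an intensity grid.
# Non-synapse shapes only claim unlabeled voxels; synaptic discs overwrite,
# which carves them into both partners and guarantees 26-adjacency.
rasterize_scene <- function(shapes, dims, spacing, render_intensity = TRUE) {
  vals <- phantom_intensities()
  labels <- array(0L, dims)
  intensity <- if (render_intensity) array(vals[["background"]], dims)
               else NULL
  for (sh in shapes) {
    bb <- shape_bbox(sh)
    yr <- seq.int(max(1L, floor(bb[1, 2] / spacing["y"]) + 1L),
                  min(dims[1L], ceiling(bb[2, 2] / spacing["y"]) + 1L))
    xr <- seq.int(max(1L, floor(bb[1, 1] / spacing["x"]) + 1L),
                  min(dims[2L], ceiling(bb[2, 1] / spacing["x"]) + 1L))
    zr <- seq.int(max(1L, floor(bb[1, 3] / spacing["z"]) + 1L),
                  min(dims[3L], ceiling(bb[2, 3] / spacing["z"]) + 1L))
    if (!length(yr) || !length(xr) || !length(zr)) next
    ly <- length(yr); lx <- length(xr); lz <- length(zr)
    PY <- array((yr - 1) * spacing["y"], c(ly, lx, lz))
    PX <- array(rep((xr - 1) * spacing["x"], each = ly), c(ly, lx, lz))
    PZ <- array(rep((zr - 1) * spacing["z"], each = ly * lx), c(ly, lx, lz))
    inside <- shape_inside(sh, PX, PY, PZ)
    sub <- labels[yr, xr, zr, drop = FALSE]
    dim(sub) <- c(ly, lx, lz)
    if (sh$kind == "disc") sel <- inside else sel <- inside & sub == 0L
    sub[sel] <- sh$label
    labels[yr, xr, zr] <- sub
    if (render_intensity) {
      isub <- intensity[yr, xr, zr, drop = FALSE]
      dim(isub) <- c(ly, lx, lz)
      v <- vals[[sh$value]]
      if (sh$value == "bouton") {
        # coarse vesicle-like texture
        isub[sel] <- pmin(1, pmax(0, v + rnorm(sum(sel), 0, 0.05)))
      } else {
        isub[sel] <- v
      }
      intensity[yr, xr, zr] <- isub
    }
  }
  list(labels = labels, intensity = intensity)
}

# ---- scene construction ---------------------------------------------------

unitv <- function(v) v / sqrt(sum(v^2))

# perpendicular to n lying in the (y, z) plane when n does, so satellite
# fans never extend the scene along the dendrite (x) axis
perp_yz <- function(n) unitv(c(0, n[3], -n[2])) # cross(n, ex), n in (y,z)

new_id <- function(env) {
  env$id <- env$id + 1L
  env$id
}

add_row <- function(env, ...) {
  env$rows[[length(env$rows) + 1L]] <- list(...)
}

# bouton + synaptic junction + SBi-1 unlabeled elements, contacting `post_id`
# at `contact` along outward direction `n`
add_bouton_complex <- function(env, contact, n, post_id, location,
                               syn_r, sbi) {
  t <- synapse_thickness_nm
  dlt <- synapse_overlap_nm
  bouton_r <- runif(1, 280, 360)
  b_id <- new_id(env)
  env$shapes[[length(env$shapes) + 1L]] <-
    sh_sphere(contact + n * (t + bouton_r), bouton_r, b_id, "bouton")
  add_row(env, id = b_id, category = "bouton", labeled = FALSE,
          spine_type = NA_character_, parent_id = NA_integer_,
          bouton_id = NA_integer_, post_id = NA_integer_,
          location = NA_character_, sbi = sbi)
  s_id <- new_id(env)
  env$shapes[[length(env$shapes) + 1L]] <-
    sh_disc(contact + n * (t / 2), n, syn_r, t / 2 + dlt, s_id, "synapse")
  add_row(env, id = s_id, category = "synaptic_junction", labeled = FALSE,
          spine_type = NA_character_, parent_id = post_id,
          bouton_id = b_id, post_id = post_id, location = location,
          sbi = NA_integer_)
  bc <- contact + n * (t + bouton_r)
  m <- sbi - 1L
  if (m > 0) {
    q <- perp_yz(n)
    th <- (-100 + (seq_len(m) - 0.5) * 200 / m) * pi / 180
    for (j in seq_len(m)) {
      v <- cos(th[j]) * n + sin(th[j]) * q
      sat_r <- runif(1, 140, 200)
      e_id <- new_id(env)
      csat <- bc + v * bouton_r
      env$shapes[[length(env$shapes) + 1L]] <-
        sh_sphere(csat + v * (t + sat_r), sat_r, e_id, "element")
      add_row(env, id = e_id, category = "spine", labeled = FALSE,
              spine_type = NA_character_, parent_id = NA_integer_,
              bouton_id = NA_integer_, post_id = NA_integer_,
              location = NA_character_, sbi = NA_integer_)
      sj_id <- new_id(env)
      env$shapes[[length(env$shapes) + 1L]] <-
        sh_disc(csat + v * (t / 2), v, max(80, 0.5 * sat_r),
                t / 2 + dlt, sj_id, "synapse")
      add_row(env, id = sj_id, category = "synaptic_junction",
              labeled = FALSE, spine_type = NA_character_,
              parent_id = e_id, bouton_id = b_id, post_id = e_id,
              location = "head", sbi = NA_integer_)
    }
  }
  invisible(b_id)
}

sample_sbi <- function(spec) {
  sample.int(10L, 1L, prob = spec$sbi_distribution)
}

# builds the shape list and ground-truth rows for one spine rooted at axis
# point `a` growing along u = +y
add_spine <- function(env, spec, geo, a) {
  u <- c(0, 1, 0)
  ez <- c(0, 0, 1)
  sp_id <- new_id(env)
  base <- a + u * shaft_radius_nm
  heads <- list()
  if (geo$type == "branched") {
    shared <- 0.5 * geo$neck_len
    blen <- 0.7 * geo$neck_len
    B <- a + u * (shaft_radius_nm + shared)
    env$shapes[[length(env$shapes) + 1L]] <-
      sh_capsule(a + u * (shaft_radius_nm - 20), B, geo$neck_r, sp_id,
                 "dendrite")
    # wide divergence keeps each head's bouton complex clear of its sibling
    ang <- if (geo$branch_count == 2L) c(-45, 45) else c(-60, 0, 60)
    for (i in seq_len(geo$branch_count)) {
      v <- cos(ang[i] * pi / 180) * u + sin(ang[i] * pi / 180) * ez
      hc <- B + v * (blen + 0.9 * geo$head_r)
      env$shapes[[length(env$shapes) + 1L]] <-
        sh_capsule(B, B + v * blen, 0.85 * geo$neck_r, sp_id, "dendrite")
      env$shapes[[length(env$shapes) + 1L]] <-
        sh_sphere(hc, geo$head_r, sp_id, "dendrite")
      heads[[i]] <- list(center = hc, r = geo$head_r, dir = v)
    }
  } else if (geo$type == "stubby") {
    hc <- a + u * (shaft_radius_nm + 0.55 * geo$head_r)
    env$shapes[[length(env$shapes) + 1L]] <-
      sh_sphere(hc, geo$head_r, sp_id, "dendrite")
    heads[[1]] <- list(center = hc, r = geo$head_r, dir = u)
  } else {
    p1 <- a + u * (shaft_radius_nm + geo$neck_len)
    hc <- p1 + u * (0.9 * geo$head_r)
    env$shapes[[length(env$shapes) + 1L]] <-
      sh_capsule(a + u * (shaft_radius_nm - 20), p1, geo$neck_r, sp_id,
                 "dendrite")
    env$shapes[[length(env$shapes) + 1L]] <-
      sh_sphere(hc, geo$head_r, sp_id, "dendrite")
    heads[[1]] <- list(center = hc, r = geo$head_r, dir = u)
  }
  vol_model <- geo$branch_count *
    (pi * geo$neck_r^2 * geo$neck_len / geo$branch_count +
     4 / 3 * pi * geo$head_r^3)
  add_row(env, id = sp_id, category = "spine", labeled = TRUE,
          spine_type = geo$type, parent_id = 1L,
          bouton_id = NA_integer_, post_id = NA_integer_,
          location = NA_character_, sbi = NA_integer_)
  env$bases[[length(env$bases) + 1L]] <-
    list(spine_id = sp_id, x = base[1], y = base[2], z = base[3],
         type = geo$type)
  for (i in seq_along(heads))
    env$heads[[length(env$heads) + 1L]] <-
      list(spine_id = sp_id, head = i, x = heads[[i]]$center[1],
           y = heads[[i]]$center[2], z = heads[[i]]$center[3],
           r = heads[[i]]$r)

  nonsyn <- runif(1) < spec$nonsynaptic_fraction
  if (!nonsyn) {
    for (i in seq_along(heads)) {
      h <- heads[[i]]
      on_neck <- geo$type %in% c("thin", "filopodial", "mushroom") &&
        runif(1) < spec$neck_synapse_fraction
      if (on_neck) {
        mid <- a + u * (shaft_radius_nm + 0.5 * geo$neck_len)
        contact <- mid + ez * geo$neck_r
        add_bouton_complex(env, contact, ez, sp_id, "neck",
                           max(70, 0.8 * geo$neck_r), sample_sbi(spec))
      } else {
        contact <- h$center + h$dir * h$r
        add_bouton_complex(env, contact, h$dir, sp_id, "head",
                           max(80, 0.5 * h$r), sample_sbi(spec))
      }
    }
  }
  invisible(list(id = sp_id, volume_model = vol_model,
                 nonsynaptic = nonsyn))
}

#' Build a synthetic FIB/SEM phantom
#'
#' Renders the scene described by a [phantom_spec] onto an anisotropic voxel
#' grid: objects are defined in nm and sampled on the grid directly (no
#' post-hoc scaling).  Returns the clean intensity stack, the exact label
#' grid as a [voxel_segmentation], and a ground-truth table consistent with
#' the rendered geometry.  Identical spec + seed yields bit-identical
#' output; acquisition artifacts (jitter, drift, noise) are applied
#' separately by [apply_acquisition_artifacts()].
#'
#' @param spec a [phantom_spec].
#' @param render_intensity render the grayscale stack (set `FALSE` to
#'   generate labels and ground truth only, halving memory).
#' @return An object of class `phantom`: a list with `stack`
#'   ([image_stack] or `NULL`), `segmentation` ([voxel_segmentation]),
#'   `truth` (data.frame; head centroids and neck-base attachment points in
#'   the `heads`/`bases` attributes), and `spec`.
#' @export
build_phantom <- function(spec, render_intensity = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_spines_per_type["branched"] > 0 &&
      spec$geometry_ranges$branched$branch_count[1] < 2)
    stop("impossible spec: branched spines need at least 2 heads")
  with_seed(spec$rng_seed, build_phantom_impl(spec, render_intensity))
}

build_phantom_impl <- function(spec, render_intensity) {
  counts <- spec$n_spines_per_type
  n_total <- sum(counts)
  spacing <- spec$spacing

  env <- new.env()
  env$id <- 0L
  env$shapes <- list()
  env$rows <- list()
  env$heads <- list()
  env$bases <- list()

  if (n_total > 0) {
    pitch <- 900
    margin_x <- 500
    Lx <- n_total * pitch + 2 * margin_x
    shaft_id <- new_id(env) # id 1
    env$shapes[[1L]] <- sh_capsule(c(0, 0, 0), c(Lx, 0, 0),
                                   shaft_radius_nm, shaft_id, "dendrite")
    add_row(env, id = shaft_id, category = "dendrite_shaft", labeled = TRUE,
            spine_type = NA_character_, parent_id = NA_integer_,
            bouton_id = NA_integer_, post_id = NA_integer_,
            location = NA_character_, sbi = NA_integer_)
    types <- rep(names(counts), counts)
    for (i in seq_along(types)) {
      geo <- sample_one_geometry(types[i], spec$geometry_ranges)
      a <- c(margin_x + (i - 0.5) * pitch, 0, 0)
      add_spine(env, spec, geo, a)
    }
  }

  # fit the scene into the grid
  if (length(env$shapes)) {
    bbs <- lapply(env$shapes, shape_bbox)
    lo <- do.call(pmin, lapply(bbs, function(b) b[1, ]))
    hi <- do.call(pmax, lapply(bbs, function(b) b[2, ]))
    margin <- 100
    offset <- margin - lo
    env$shapes <- lapply(env$shapes, shift_shape, o = offset)
    extent <- hi - lo + 2 * margin
    need <- ceiling(extent / spacing) + 1 # voxels (x, y, z)
    # shift recorded truth coordinates too
    env$heads <- lapply(env$heads, function(h) {
      h$x <- h$x + offset[1]; h$y <- h$y + offset[2]; h$z <- h$z + offset[3]
      h
    })
    env$bases <- lapply(env$bases, function(b) {
      b$x <- b$x + offset[1]; b$y <- b$y + offset[2]; b$z <- b$z + offset[3]
      b
    })
  } else {
    need <- c(32, 32, 8)
  }
  if (is.null(spec$grid_shape)) {
    gs <- as.integer(need)
  } else {
    gs <- spec$grid_shape
    if (any(need > gs))
      stop(sprintf(
        "geometry overflow: scene needs %d x %d x %d voxels but grid_shape is %d x %d x %d",
        need[1], need[2], need[3], gs[1], gs[2], gs[3]))
  }
  dims <- c(gs[2L], gs[1L], gs[3L]) # (y, x, z) array layout

  ras <- rasterize_scene(env$shapes, dims, spacing, render_intensity)
  if (render_intensity) {
    # smooth neuropil-like texture so every slice carries registrable
    # content, as membranous neuropil does in real block-face images
    tex <- array(cpp_smooth3d(rnorm(prod(dims)), dims, 2), dims)
    tex <- tex * (0.03 / sd(tex))
    ras$intensity <- pmin(pmax(ras$intensity + tex, 0), 1)
  }

  truth <- do.call(rbind, lapply(env$rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(truth))
    truth <- data.frame(id = integer(), category = character(),
                        labeled = logical(), spine_type = character(),
                        parent_id = integer(), bouton_id = integer(),
                        post_id = integer(), location = character(),
                        sbi = integer())
  nv <- if (nrow(truth)) tabulate(ras$labels, nbins = max(truth$id))
        else integer()
  truth$n_voxels <- if (nrow(truth)) nv[truth$id] else integer()
  truth$volume_nm3 <- truth$n_voxels * voxel_volume(spacing)
  attr(truth, "heads") <- if (length(env$heads))
    do.call(rbind, lapply(env$heads, as.data.frame)) else NULL
  attr(truth, "bases") <- if (length(env$bases))
    do.call(rbind, lapply(env$bases, as.data.frame)) else NULL

  objects <- if (nrow(truth))
    data.frame(id = truth$id, category = truth$category,
               seed = NA_integer_, threshold = NA_real_)
  else data.frame(id = integer(), category = character(),
                  seed = integer(), threshold = numeric())
  seg <- voxel_segmentation(ras$labels, objects, spacing)

  stack <- if (render_intensity)
    image_stack(ras$intensity, spacing,
                provenance = list(list(step = "build_phantom",
                                       rng_seed = spec$rng_seed)))
  else NULL
  structure(list(stack = stack, segmentation = seg, truth = truth,
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d objects, grid %s, %d labeled spines\n",
              nrow(x$truth),
              paste(dim(x$segmentation$labels), collapse = " x "),
              sum(x$truth$category == "spine" & x$truth$labeled)))
  invisible(x)
}

#' Apply acquisition artifacts to a stack
#'
#' Emulates the imperfections of serial block-face acquisition: an integer
#' per-slice translation (jitter, at most `slice_jitter_px`; the first
#' slice is the reference and is never shifted), a per-slice multiplicative
#' intensity drift, and additive Gaussian noise.  The applied jitters and
#' drifts are returned so alignment and normalization can be validated
#' against them.
#'
#' @param stack an [image_stack].
#' @param spec the [phantom_spec] carrying `slice_jitter_px`,
#'   `intensity_drift`, `noise_sd` and the seed.
#' @return A list with `stack` (corrupted [image_stack]), `jitter`
#'   (n x 2 integer matrix of applied `(dy, dx)` per slice) and `drift`
#'   (per-slice gain factors).
#' @export
apply_acquisition_artifacts <- function(stack, spec) {
  stopifnot(inherits(stack, "image_stack"), inherits(spec, "phantom_spec"))
  d <- dim(stack$grid)
  n <- d[3L]
  J <- spec$slice_jitter_px
  if (2L * J >= min(d[1L], d[2L]))
    stop("slice jitter exceeds the slice extent")
  with_seed(spec$rng_seed + 1L, {
    jitter <- matrix(0L, n, 2L, dimnames = list(NULL, c("dy", "dx")))
    if (J > 0 && n > 1L)
      jitter[2:n, ] <- matrix(sample(seq.int(-J, J), 2L * (n - 1L),
                                     replace = TRUE), ncol = 2L)
    drift <- if (spec$intensity_drift > 0)
      runif(n, 1 - spec$intensity_drift, 1 + spec$intensity_drift)
    else rep(1, n)
    out <- stack$grid
    for (k in seq_len(n)) {
      sl <- stack$grid[, , k]
      if (any(jitter[k, ] != 0L))
        sl <- shift_matrix(sl, jitter[k, 1L], jitter[k, 2L])
      out[, , k] <- sl * drift[k]
    }
    if (spec$noise_sd > 0)
      out <- out + array(rnorm(length(out), 0, spec$noise_sd), d)
    res <- image_stack(out, stack$spacing, stack$provenance)
    res <- log_step(res, "apply_acquisition_artifacts",
                    slice_jitter_px = J, intensity_drift =
                      spec$intensity_drift, noise_sd = spec$noise_sd)
    list(stack = res, jitter = jitter, drift = drift)
  })
}

#' Write phantom artifacts to disk
#'
#' Writes the intensity stack and label grid as multi-page TIFFs, the
#' ground truth as CSV and the spec echo as YAML.
#'
#' @param phantom a `phantom` from [build_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(phantom$stack))
    write_stack(phantom$stack, file.path(dir, "stack.tif"))
  write_labels(phantom$segmentation$labels, file.path(dir, "labels.tif"))
  write.csv(phantom$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  write.csv(phantom$segmentation$objects, file.path(dir, "objects.csv"),
            row.names = FALSE)
  sp <- phantom$spec
  sp$n_spines_per_type <- as.list(sp$n_spines_per_type)
  yaml::write_yaml(unclass(sp), file.path(dir, "spec.yaml"))
  invisible(dir)
}
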