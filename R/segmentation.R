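#' Voxel segmentations
#'
#' A `voxel_segmentation` couples an integer label grid (0 = background)
#' with an object table giving each label's category
#' (`dendrite_shaft`, `spine`, `synaptic_junction`, `bouton`), and
#' optionally the seed voxel and threshold used to grow it.
#'
#' @param labels integer 3D array `(ny, nx, nz)`.
#' @param objects data.frame with at least `id` and `category`.
#' @param spacing voxel spacing in nm, `c(x, y, z)`.
#' @return An object of class `voxel_segmentation`.
#' @export
voxel_segmentation <- function(labels, objects, spacing) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  spacing <- check_spacing(spacing)
  if (!all(c("id", "category") %in% names(objects)))
    stop("`objects` needs columns id and category")
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(present, objects$id)
  if (length(missing))
    stop("labels present in grid but absent from the object table: ",
         toString(missing))
  structure(list(labels = labels, objects = objects, spacing = spacing),
            class = "voxel_segmentation")
}

#' @export
print.voxel_segmentation <- function(x, ...) {
  cat(sprintf("<voxel_segmentation> %d objects in %s grid\n",
              nrow(x$objects), paste(dim(x$labels), collapse = " x ")))
  print(table(x$objects$category))
  invisible(x)
}

#' Extract one object as a voxel mask
#'
#' @param seg a [voxel_segmentation].
#' @param id object id.
#' @return A [voxel_mask].
#' @export
object_mask <- function(seg, id) {
  stopifnot(inherits(seg, "voxel_segmentation"))
  voxel_mask(which(seg$labels == id), dim(seg$labels), seg$spacing)
}

#' Otsu threshold of a stack
#'
#' Global two-class threshold of the pooled intensity histogram, used as the
#' default when no absolute threshold is supplied for seed growing.
#'
#' @param stack an [image_stack].
#' @param levels number of histogram levels.
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(stack, levels = 256L) {
  stopifnot(inherits(stack, "image_stack"))
  v <- as.numeric(stack$grid)
  rg <- range(v)
  if (rg[1] == rg[2]) return(rg[1])
  img <- EBImage::Image((v - rg[1]) / (rg[2] - rg[1]),
                        dim = c(length(v), 1L))
  th <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  rg[1] + th * (rg[2] - rg[1])
}

#' Seed-based region growing
#'
#' Grows the 26-connected component of the absolute-intensity threshold set
#' containing the seed, on the blurred companion stack: for dark (DAB)
#' objects the set is `intensity <= threshold`; with `bright_objects =
#' TRUE` the predicate is inverted.  No morphological smoothing is applied
#' before or after.
#'
#' @param blurred an [image_stack] (normally the output of [blur_stack()]).
#' @param seed voxel index `c(x, y, z)`, 1-based.
#' @param threshold absolute intensity threshold; defaults to
#'   [otsu_threshold()] of the stack.
#' @param bright_objects grow bright instead of dark objects.
#' @return A [voxel_mask] with attributes `seed` and `threshold`.
#' @export
seed_grow <- function(blurred, seed, threshold = NULL,
                      bright_objects = FALSE) {
  stopifnot(inherits(blurred, "image_stack"), length(seed) == 3L)
  d <- dim(blurred$grid)
  seed <- as.integer(seed)
  if (seed[1] < 1L || seed[1] > d[2L] || seed[2] < 1L || seed[2] > d[1L] ||
      seed[3] < 1L || seed[3] > d[3L])
    stop("seed voxel outside the grid")
  if (is.null(threshold)) threshold <- otsu_threshold(blurred)
  sel <- if (bright_objects) blurred$grid >= threshold
         else blurred$grid <= threshold
  lin <- vox_linear(seed[2], seed[1], seed[3], d)
  if (!sel[lin])
    stop(sprintf("seed intensity %.4g fails the threshold predicate (%.4g)",
                 blurred$grid[lin], threshold))
  grown <- cpp_flood_fill(as.logical(sel), d, lin - 1L, 26L)
  m <- voxel_mask(which(grown), d, blurred$spacing)
  attr(m, "seed") <- seed
  attr(m, "threshold") <- threshold
  m
}

#' Import painted label volumes
#'
#' Reads a label TIFF plus a sidecar CSV mapping each label id to a
#' category, mirroring manually traced objects (synaptic junctions traced
#' contour by contour).  Labels are taken as-is: touching objects with
#' different ids are never merged.
#'
#' @param path multi-page integer label TIFF (see [write_labels()]), or an
#'   integer 3D array.
#' @param sidecar CSV path or data.frame with columns `id`, `category`.
#' @param spacing voxel spacing in nm, `c(x, y, z)`.
#' @param reference_dim expected grid dimensions `(ny, nx, nz)` to validate
#'   against, or `NULL`.
#' @return A [voxel_segmentation].
#' @export
import_labels <- function(path, sidecar, spacing = c(3.7, 3.7, 25),
                          reference_dim = NULL) {
  labels <- if (is.character(path)) read_labels(path) else path
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!is.null(reference_dim) &&
      !identical(dim(labels), as.integer(reference_dim)))
    stop("label grid shape does not match the reference stack")
  tab <- if (is.character(sidecar)) read.csv(sidecar) else sidecar
  voxel_segmentation(labels, tab, spacing)
}

#' Isolate spines from the parent dendritic shaft
#'
#' Splits a connected dendrite mask into the shaft and one mask per spine,
#' cutting each spine through the base of its neck in a 3D-optimal
#' orientation.  The shaft is identified as the maximal inscribed tube
#' around the dendrite's central skeleton path (extracted by a
#' centrality-weighted geodesic between the two extremes of the principal
#' axis); every protrusion left outside the tube becomes a candidate spine,
#' and its cut is refined to the point of minimal cross-sectional area
#' within the first `cut_search_frac` of the branch length.  Branched
#' spines are returned as a single mask (their heads are individualized
#' later by [split_branched()]).
#'
#' @param mask a connected [voxel_mask] of the dendrite (shaft + spines).
#' @param shaft_factor multiplier on the estimated shaft surface radius
#'   (a one-voxel margin is always added on top).
#' @param cut_search_frac fraction of the branch length searched for the
#'   minimal cross-section.
#' @param min_spine_voxels protrusions smaller than this are merged back
#'   into the shaft and logged.
#' @return A list with `shaft` ([voxel_mask]), `spines` (list of
#'   [voxel_mask]s, each carrying attributes `base_nm` and `cut_nm`), and
#'   `log` (data.frame of merged-back protrusions).
#' @export
split_dendrite <- function(mask, shaft_factor = 1.0,
                           cut_search_frac = 0.3,
                           min_spine_voxels = 8L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!length(mask$idx)) stop("empty dendrite mask")
  cr <- mask_crop(mask, pad = 1L)
  d <- cr$dim
  arr <- cr$arr
  sp_dim <- spacing_dim_order(mask$spacing)
  edt <- cpp_edt(as.logical(arr), d, sp_dim)

  # principal axis endpoints (central voxels of the extreme slabs)
  idx_loc <- which(arr)
  co <- vox_coords(idx_loc, d)
  w <- cbind(co[, 2L] * mask$spacing["x"], co[, 1L] * mask$spacing["y"],
             co[, 3L] * mask$spacing["z"])
  ctr <- colMeans(w)
  wc <- sweep(w, 2L, ctr)
  keep <- if (nrow(wc) > 20000L) seq(1L, nrow(wc), length.out = 20000L)
          else seq_len(nrow(wc))
  pc1 <- eigen(crossprod(wc[keep, , drop = FALSE]),
               symmetric = TRUE)$vectors[, 1L]
  proj <- wc %*% pc1
  pick_end <- function(side) {
    q <- if (side > 0) proj >= max(proj) - 2 * max(mask$spacing)
         else proj <= min(proj) + 2 * max(mask$spacing)
    cand <- idx_loc[q]
    cand[which.max(edt[cand])]
  }
  e1 <- pick_end(1)
  e2 <- pick_end(-1)

  # central skeleton path between the endpoints
  cw <- 1 / (edt + 0.5 * min(mask$spacing))
  g1 <- cpp_geodesic(as.logical(arr), d, sp_dim, e1 - 1L, cw)
  path <- integer(0)
  v <- e2
  repeat {
    path <- c(path, v)
    if (v == e1) break
    p <- g1$pred[v] + 1L
    if (p <= 0L) break
    v <- p
  }
# maximal inscribed tube around the path (exact anisotropic Euclidean
  # distance to the skeleton path).  The tube radius is read off the radial
  # shell-count profile of the mask around the path: shell populations grow
  # ~linearly with radius inside the tube and collapse at its surface to
  # the small cross-sections of the protrusions, so the last radius whose
  # shell holds at least a quarter of the densest shell marks the shaft
  # surface robustly even when the segmented surface is rough.
  not_path <- array(TRUE, d)
  not_path[path] <- FALSE
  dist2path <- cpp_edt(as.logical(not_path), d, sp_dim, FALSE)
  dp <- dist2path[idx_loc]
  step <- min(mask$spacing)
  br <- seq(0, max(dp) + step, by = step)
  shell <- tabulate(findInterval(dp, br), nbins = length(br))
  dense <- which(shell >= 0.25 * max(shell))
  r_shaft <- br[max(dense)] + step
  tube <- shaft_factor * r_shaft + max(mask$spacing)
  shaft_loc <- arr & array(dist2path <= tube, d)

  # protrusions
  prot <- arr & !shaft_loc
  lab <- array(cpp_label_components(as.logical(prot), d, 26L), d)
  n_prot <- max(lab)
  spines <- list()
  log <- list()
  shaft_idx <- which(shaft_loc)
  for (p in seq_len(n_prot)) {
    pid <- which(lab == p)
    # interface: protrusion voxels 26-adjacent to the shaft
    sub <- array(FALSE, d)
    sub[pid] <- TRUE
    iface <- pid[adjacent_to(pid, shaft_loc, d)]
    if (!length(iface)) { # floating fragment: merge back
      shaft_idx <- c(shaft_idx, pid)
      log[[length(log) + 1L]] <- data.frame(protrusion = p,
                                            n_voxels = length(pid),
                                            action = "merged_no_interface")
      next
    }
    gg <- cpp_geodesic(as.logical(sub), d, sp_dim, iface - 1L, numeric(0))
    gd <- gg$dist[pid]
    L <- max(gd)
    if (length(pid) < min_spine_voxels || L < 2 * min(mask$spacing)) {
      shaft_idx <- c(shaft_idx, pid)
      log[[length(log) + 1L]] <- data.frame(protrusion = p,
                                            n_voxels = length(pid),
                                            action = "merged_short")
      next
    }
    # refine the cut: minimal cross-section within the proximal fraction
    step <- max(mask$spacing)
    lim <- cut_search_frac * L
    br <- seq(0, lim + step, by = step)
    area <- vapply(seq_len(length(br) - 1L), function(i)
      sum(gd >= br[i] & gd < br[i + 1L]), numeric(1))
    area <- area * voxel_volume(mask$spacing) / step
    ok <- which(area > 0 & br[-length(br)] <= lim)
    # earliest point within 20% of the minimal cross-section: shell counts
    # on anisotropic grids fluctuate by ~10%, so only a pronounced
    # constriction moves the cut away from the neck base
    cut_d <- if (length(ok)) {
      amin <- min(area[ok])
      br[ok[which(area[ok] <= 1.2 * amin)[1L]]]
    } else 0
    move <- pid[gd < cut_d | !is.finite(gd)]
    keep_idx <- setdiff(pid, move)
    if (length(keep_idx)) {
      # the cut can disconnect satellite fragments; keep the main component
      sub2 <- array(FALSE, d)
      sub2[keep_idx] <- TRUE
      cl <- cpp_label_components(as.logical(sub2), d, 26L)
      main <- as.integer(names(which.max(table(cl[keep_idx]))))
      frag <- keep_idx[cl[keep_idx] != main]
      if (length(frag)) {
        move <- c(move, frag)
        keep_idx <- setdiff(keep_idx, frag)
      }
    }
    if (length(keep_idx) < min_spine_voxels) {
      shaft_idx <- c(shaft_idx, pid)
      log[[length(log) + 1L]] <- data.frame(protrusion = p,
                                            n_voxels = length(pid),
                                            action = "merged_after_cut")
      next
    }
    shaft_idx <- c(shaft_idx, move)
    sp_mask <- mask_like(mask, uncrop_idx(keep_idx, cr, mask$dim))
    base_w <- colMeans(vox_world(uncrop_idx(iface, cr, mask$dim),
                                 mask$dim, mask$spacing))
    attr(sp_mask, "base_nm") <- base_w
    attr(sp_mask, "cut_nm") <- cut_d
    spines[[length(spines) + 1L]] <- sp_mask
  }
  shaft <- mask_like(mask, uncrop_idx(shaft_idx, cr, mask$dim))
  list(shaft = shaft, spines = spines,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(protrusion = integer(), n_voxels = integer(),
                             action = character()))
}

# which of the (local) indices `idx` touch TRUE voxels of `target` (26-conn)
adjacent_to <- function(idx, target, d) {
  co <- vox_coords(idx, d)
  out <- logical(length(idx))
  for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    iy <- co[, 1L] + dy; ix <- co[, 2L] + dx; iz <- co[, 3L] + dz
    okb <- iy >= 1L & iy <= d[1L] & ix >= 1L & ix <= d[2L] &
      iz >= 1L & iz <= d[3L]
    hit <- logical(length(idx))
    hit[okb] <- target[vox_linear(iy[okb], ix[okb], iz[okb], d)]
    out <- out | hit
  }
  out
}
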