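#' Sparse voxel masks
#'
#' A `voxel_mask` is the sparse representation of one segmented object: the
#' sorted linear indices of its voxels inside a reference grid, together
#' with the grid dimensions (y, x, z) and the physical voxel spacing
#' (x, y, z, nm).  All measurement and feature-extraction functions operate
#' on voxel masks.
#'
#' @param idx integer vector of 1-based linear indices into the grid.
#' @param dim integer vector of grid dimensions `(ny, nx, nz)`.
#' @param spacing voxel spacing in nm, `c(x, y, z)` (a single value is
#'   recycled to all three axes).
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(idx, dim, spacing) {
  spacing <- check_spacing(spacing)
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop("`dim` must be three positive integers (ny, nx, nz)")
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) && (idx[1L] < 1L || idx[length(idx)] > prod(dim)))
    stop("mask indices outside the grid")
  structure(list(idx = idx, dim = dim, spacing = spacing),
            class = "voxel_mask")
}

#' @rdname voxel_mask
#' @param x a logical 3D array (`mask_from_array`) or a `voxel_mask`.
#' @export
mask_from_array <- function(x, spacing) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  voxel_mask(which(x != 0), dim(x), spacing)
}

#' @rdname voxel_mask
#' @export
mask_to_array <- function(x) {
  stopifnot(inherits(x, "voxel_mask"))
  arr <- array(FALSE, x$dim)
  arr[x$idx] <- TRUE
  arr
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d voxels in %d x %d x %d grid, %.4g nm^3/voxel\n",
              length(x$idx), x$dim[1], x$dim[2], x$dim[3],
              voxel_volume(x$spacing)))
  invisible(x)
}

#' @export
length.voxel_mask <- function(x) length(x$idx)

# Crop a mask to its bounding box (with `pad` voxels of margin).  Returns the
# cropped logical array plus the 0-based offset of its origin in the parent
# grid, so indices can be mapped back.
mask_crop <- function(mask, pad = 1L) {
  co <- vox_coords(mask$idx, mask$dim)
  lo <- pmax(apply(co, 2L, min) - pad, 1L)
  hi <- pmin(apply(co, 2L, max) + pad, mask$dim)
  d <- hi - lo + 1L
  arr <- array(FALSE, d)
  arr[cbind(co[, 1L] - lo[1L] + 1L,
            co[, 2L] - lo[2L] + 1L,
            co[, 3L] - lo[3L] + 1L)] <- TRUE
  list(arr = arr, offset = as.integer(lo - 1L), dim = d)
}

# map linear indices in a cropped array back to the parent grid
uncrop_idx <- function(idx_local, crop, dim) {
  co <- vox_coords(idx_local, crop$dim)
  vox_linear(co[, 1L] + crop$offset[1L],
             co[, 2L] + crop$offset[2L],
             co[, 3L] + crop$offset[3L], dim)
}

mask_like <- function(mask, idx) {
  voxel_mask(idx, mask$dim, mask$spacing)
}

# world coordinates (nm) of the mask voxels
mask_world <- function(mask) {
  vox_world(mask$idx, mask$dim, mask$spacing)
}

#' Digitize an analytic ball on a voxel grid
#'
#' Rasterizes a sphere of the given radius, centred on the grid, by voxel
#' centre inclusion.  Used for convergence checks of the voxel-counting
#' volume and surface estimators against the analytic sphere.
#'
#' @param radius_nm sphere radius in nm.
#' @param spacing voxel spacing in nm, `c(x, y, z)`.
#' @param margin_vox background margin around the ball, in voxels.
#' @return A [voxel_mask].
#' @export
digitize_ball <- function(radius_nm, spacing, margin_vox = 2L) {
  spacing <- check_spacing(spacing)
  half <- ceiling(radius_nm / spacing) + margin_vox
  d <- as.integer(c(2 * half["y"] + 1, 2 * half["x"] + 1, 2 * half["z"] + 1))
  cx <- (half["x"]) * spacing["x"]
  cy <- (half["y"]) * spacing["y"]
  cz <- (half["z"]) * spacing["z"]
  ys <- ((seq_len(d[1L]) - 1) * spacing["y"] - cy)^2
  xs <- ((seq_len(d[2L]) - 1) * spacing["x"] - cx)^2
  zs <- ((seq_len(d[3L]) - 1) * spacing["z"] - cz)^2
  arr <- outer(outer(ys, xs, `+`), zs, `+`) <= radius_nm^2
  mask_from_array(arr, spacing)
}
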