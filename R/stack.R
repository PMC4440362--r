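#' Image stacks
#'
#' An `image_stack` holds a 3D scalar intensity grid together with its
#' physical voxel spacing and a processing log.  The grid is stored as an
#' array with dimensions `(y, x, z)`: each z-slice is a matrix in the usual
#' R row/column (y/x) layout, matching the page layout of a multi-page
#' TIFF.  World coordinates are voxel centres at `index * spacing` with
#' 0-based indices.
#'
#' @param grid numeric 3D array `(ny, nx, nz)` of finite intensities.
#' @param spacing voxel spacing in nm, `c(x, y, z)`; the FIB/SEM default
#'   used throughout is `c(3.7, 3.7, 25)`.
#' @param provenance list of processing-log entries.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(grid, spacing = c(3.7, 3.7, 25),
                        provenance = list()) {
  if (is.matrix(grid)) grid <- array(grid, c(dim(grid), 1L))
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  if (dim(grid)[3L] < 1L) stop("stack must contain at least one slice")
  if (!all(is.finite(grid))) stop("stack intensities must be finite")
  spacing <- check_spacing(spacing)
  structure(list(grid = grid, spacing = spacing, provenance = provenance),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<image_stack> %d x %d px, %d slices; spacing %.4g x %.4g x %.4g nm\n",
    d[2], d[1], d[3], x$spacing["x"], x$spacing["y"], x$spacing["z"]))
  for (p in x$provenance) cat("  - ", p$step, "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$grid)

n_slices <- function(stack) dim(stack$grid)[3L]

log_step <- function(stack, step, ...) {
  stack$provenance <- c(stack$provenance, list(c(list(step = step),
                                                 list(...))))
  stack
}

#' Read and write multi-page TIFF stacks
#'
#' Stacks are stored one z-slice per TIFF page.  Intensities are written as
#' 16-bit samples spanning `[0, 1]` with 65535 levels (the native depth of
#' most electron-microscope acquisitions); `write_stack()` therefore
#' quantizes to that grid (values are clamped to `[0, 1]` with a warning if
#' needed), after which write/read round trips are exact.  Label grids use
#' [write_labels()]/[read_labels()] (16-bit, exact for ids up to 65535).
#'
#' @param path file path of a multi-page TIFF.
#' @param spacing voxel spacing in nm, `c(x, y, z)`, recorded in the result.
#' @return `read_stack()` returns an [image_stack]; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path, spacing = c(3.7, 3.7, 25)) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!length(pages)) stop("empty TIFF: ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p  # drop extra channels
  })
  d1 <- dim(pages[[1L]])
  ok <- vapply(pages, function(p) identical(dim(p), d1), logical(1))
  if (!all(ok))
    stop("TIFF page sizes are inconsistent across slices: ", path)
  grid <- array(unlist(pages, use.names = FALSE),
                c(d1[1L], d1[2L], length(pages)))
  image_stack(grid, spacing,
              provenance = list(list(step = "read_stack", source = path)))
}

#' @rdname read_stack
#' @param stack an [image_stack].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  g <- stack$grid
  if (min(g) < 0 || max(g) > 1) {
    warning("intensities clamped to [0, 1] for TIFF storage")
    g[g < 0] <- 0
    g[g > 1] <- 1
  }
  g <- quantize_intensity(g)
  pages <- lapply(seq_len(dim(g)[3L]), function(k) g[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname read_stack
#' @param x numeric values in `[0, 1]`.
#' @export
quantize_intensity <- function(x) {
  round(x * 65535) / 65535
}

#' @rdname read_stack
#' @param labels integer 3D array of object labels (0 = background).
#' @export
write_labels <- function(labels, path) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (max(labels) > 65535L) stop("label ids above 65535 are not storable")
  pages <- lapply(seq_len(dim(labels)[3L]),
                  function(k) labels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname read_stack
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d1 <- dim(pages[[1L]])
  ok <- vapply(pages, function(p) identical(dim(p), d1), logical(1))
  if (!all(ok)) stop("TIFF page sizes are inconsistent across slices: ", path)
  arr <- array(as.integer(round(unlist(pages, use.names = FALSE) * 65535)),
               c(d1[1L], d1[2L], length(pages)))
  arr
}

# shift a matrix by (dy, dx), replicating edge values into the vacated strip
shift_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  src_r <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  src_c <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[src_r, src_c, drop = FALSE]
}

#' Translation-only slice alignment
#'
#' Rigid registration without rotation: each slice is aligned to its
#' predecessor by the integer translation maximizing normalized
#' cross-correlation over an exhaustive shift window, mirroring the
#' block-face acquisition setting where consecutive images are almost
#' aligned already.  The returned stack is cropped to the window that stays
#' inside the field of view for every slice.
#'
#' @param stack an [image_stack] with at least 2 slices.
#' @param max_shift_px half-width of the exhaustive integer search window.
#' @return A list with `stack` (aligned, cropped [image_stack]) and
#'   `alignment`, an `alignment_result` carrying the per-slice relative and
#'   cumulative `(dy, dx)` shifts, flags for flat (zero-variance) slices and
#'   boundary-limited searches, and the crop window applied.
#' @export
align_translation <- function(stack, max_shift_px = 20L) {
  stopifnot(inherits(stack, "image_stack"))
  n <- n_slices(stack)
  if (n < 2L) stop("alignment needs at least 2 slices")
  d <- dim(stack$grid)
  if (2L * max_shift_px >= min(d[1L], d[2L]))
    stop("`max_shift_px` must be below half the slice extent")

  rel <- matrix(0L, n, 2L, dimnames = list(NULL, c("dy", "dx")))
  flat <- logical(n)
  boundary <- logical(n)
  for (k in 2L:n) {
    ref <- stack$grid[, , k - 1L]
    mov <- stack$grid[, , k]
    if (sd(ref) == 0 || sd(mov) == 0) {
      flat[k] <- TRUE
      next
    }
    r <- cpp_align_pair(ref, mov, as.integer(max_shift_px))
    rel[k, ] <- as.integer(r[1:2])
    boundary[k] <- r[4] == 1
  }
  cum <- apply(rel, 2L, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)

  out <- stack$grid
  for (k in 2L:n)
    if (any(cum[k, ] != 0L))
      out[, , k] <- shift_matrix(stack$grid[, , k], cum[k, 1L], cum[k, 2L])
  crop <- common_window(cum, d)
  out <- out[crop[1L]:crop[2L], crop[3L]:crop[4L], , drop = FALSE]

  shifts <- data.frame(slice = seq_len(n), dy = rel[, 1L], dx = rel[, 2L],
                       cum_dy = cum[, 1L], cum_dx = cum[, 2L],
                       flat = flat, boundary_limited = boundary)
  alignment <- structure(list(shifts = shifts, crop = crop, dim = d),
                         class = "alignment_result")
  aligned <- image_stack(out, stack$spacing, stack$provenance)
  aligned <- log_step(aligned, "align_translation",
                      max_shift_px = max_shift_px)
  if (any(flat)) warning("flat slice(s) ", toString(which(flat)),
                         ": shift undefined, (0,0) used")
  list(stack = aligned, alignment = alignment)
}

# the window of (row, col) positions valid in every shifted slice
common_window <- function(cum, d) {
  r0 <- 1L + max(0L, max(cum[, 1L]))
  r1 <- d[1L] + min(0L, min(cum[, 1L]))
  c0 <- 1L + max(0L, max(cum[, 2L]))
  c1 <- d[2L] + min(0L, min(cum[, 2L]))
  if (r0 > r1 || c0 > c1) stop("alignment crop window is empty")
  c(r0, r1, c0, c1)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d slices, crop [%d:%d, %d:%d]\n",
              nrow(x$shifts), x$crop[1], x$crop[2], x$crop[3], x$crop[4]))
  invisible(x)
}

#' Apply recovered shifts to a co-registered grid
#'
#' Shifts every slice of `x` by the cumulative alignment shifts and crops to
#' the same common window, so that label grids (or any companion volume)
#' stay co-registered with the aligned stack.
#'
#' @param x an [image_stack] or a 3D array.
#' @param alignment an `alignment_result` from [align_translation()].
#' @param crop_only only apply the crop window, not the per-slice shifts
#'   (for companion volumes that are already in the registered frame, such
#'   as ground-truth labels of a simulated acquisition).
#' @return An object of the same kind as `x`.
#' @export
apply_alignment <- function(x, alignment, crop_only = FALSE) {
  arr <- if (inherits(x, "image_stack")) x$grid else x
  stopifnot(identical(dim(arr), alignment$dim))
  cum <- as.matrix(alignment$shifts[, c("cum_dy", "cum_dx")])
  if (!crop_only)
    for (k in seq_len(dim(arr)[3L]))
      if (any(cum[k, ] != 0L))
        arr[, , k] <- shift_matrix(arr[, , k], cum[k, 1L], cum[k, 2L])
  cr <- alignment$crop
  arr <- arr[cr[1L]:cr[2L], cr[3L]:cr[4L], , drop = FALSE]
  if (inherits(x, "image_stack"))
    image_stack(arr, x$spacing, x$provenance)
  else arr
}

#' Across-slice intensity normalization
#'
#' Affinely rescales every slice so that its location and scale statistics
#' match a stack-wide reference (the median over slices), removing
#' per-slice detector gain and brightness drift.  The default `robust`
#' method matches the slice median and MAD, which track the neuropil
#' background level and texture scale and are insensitive to how much
#' dark labeled structure a slice happens to contain; `moment` matches
#' mean and SD.  Zero-scale slices are shifted in location only.  The
#' per-slice gains and offsets are recorded in the `normalization`
#' attribute.  The operation is idempotent.
#'
#' @param stack an [image_stack].
#' @param method `"robust"` (median/MAD) or `"moment"` (mean/SD).
#' @return The normalized [image_stack].
#' @export
normalize_slices <- function(stack, method = c("robust", "moment")) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  n <- n_slices(stack)
  if (method == "robust") {
    mu <- apply(stack$grid, 3L, median)
    sdev <- apply(stack$grid, 3L, mad)
  } else {
    mu <- apply(stack$grid, 3L, mean)
    sdev <- apply(stack$grid, 3L, sd)
  }
  m_ref <- median(mu)
  s_ref <- if (any(sdev > 0)) median(sdev[sdev > 0]) else 0
  gain <- ifelse(sdev > 0 & s_ref > 0, s_ref / sdev, 1)
  out <- stack$grid
  for (k in seq_len(n))
    out[, , k] <- (stack$grid[, , k] - mu[k]) * gain[k] + m_ref
  res <- image_stack(out, stack$spacing, stack$provenance)
  res <- log_step(res, "normalize_slices", method = method,
                  location_ref = m_ref, scale_ref = s_ref)
  attr(res, "normalization") <- data.frame(
    slice = seq_len(n), location = mu, scale = sdev, gain = gain,
    offset = m_ref - mu * gain)
  res
}

#' Gaussian companion blur
#'
#' Per-slice (2D) Gaussian smoothing of the stack, producing the blurred
#' companion used for seed-based segmentation.  The "radius" follows the
#' common imaging-GUI convention `sigma = radius / 2` pixels.  Boundaries
#' are handled by symmetric reflection.  The blurred stack is only ever used
#' to grow seeds; all measurements are taken on unblurred masks.
#'
#' @param stack an [image_stack].
#' @param radius_px blur radius in pixels; 0 is the identity.
#' @return The blurred [image_stack].
#' @export
blur_stack <- function(stack, radius_px = 10) {
  stopifnot(inherits(stack, "image_stack"))
  if (radius_px < 0) stop("blur radius must be >= 0")
  if (radius_px == 0) return(log_step(stack, "blur_stack", radius_px = 0))
  sigma <- radius_px / 2
  g <- cpp_blur_slices(as.numeric(stack$grid), dim(stack$grid), sigma)
  res <- image_stack(array(g, dim(stack$grid)), stack$spacing,
                     stack$provenance)
  log_step(res, "blur_stack", radius_px = radius_px, sigma_px = sigma)
}
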