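# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# spacing is user-facing as c(x, y, z) nm; arrays are stored (y, x, z), so
# kernel calls need the spacing permuted into dim order.
spacing_dim_order <- function(spacing) {
  unname(spacing[c(2L, 1L, 3L)])
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (x, y, z nm)",
         call. = FALSE)
  names(spacing) <- c("x", "y", "z")
  spacing
}

voxel_volume <- function(spacing) prod(spacing)

# linear index (1-based) of voxel (iy, ix, iz) in an array of dim d
vox_linear <- function(iy, ix, iz, d) {
  iy + d[1L] * (ix - 1L) + d[1L] * d[2L] * (iz - 1L)
}

# inverse of vox_linear: matrix with columns iy, ix, iz (1-based)
vox_coords <- function(idx, d) {
  idx0 <- idx - 1L
  iy <- idx0 %% d[1L]
  ix <- (idx0 %/% d[1L]) %% d[2L]
  iz <- idx0 %/% (d[1L] * d[2L])
  cbind(iy = iy + 1L, ix = ix + 1L, iz = iz + 1L)
}

# world coordinates (nm, x/y/z) of voxel centres; 0-based centre convention:
# voxel (1,1,1) sits at the origin.
vox_world <- function(idx, d, spacing) {
  co <- vox_coords(idx, d)
  cbind(x = (co[, "ix"] - 1) * spacing["x"],
        y = (co[, "iy"] - 1) * spacing["y"],
        z = (co[, "iz"] - 1) * spacing["z"])
}

# integer percentages by largest-remainder correction; sums to 100 exactly
largest_remainder_pct <- function(n) {
  if (sum(n) == 0) return(rep(0L, length(n)))
  p <- 100 * n / sum(n)
  fl <- floor(p)
  left <- 100L - as.integer(sum(fl))
  if (left > 0) {
    take <- order(p - fl, decreasing = TRUE)[seq_len(left)]
    fl[take] <- fl[take] + 1
  }
  as.integer(fl)
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}
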