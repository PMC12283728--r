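#' 3-D image volume in Hounsfield units
#'
#' A `ct_volume` is the package's basic image container: a 3-D numeric array of
#' CT numbers (HU) plus the physical voxel spacing and grid origin in mm. The
#' grid is axis-aligned: the physical position of 0-based voxel index
#' `(i, j, k)` is `origin + c(i, j, k) * spacing`, with the first array axis
#' varying fastest (native R column-major order).
#'
#' @param data numeric 3-D array of voxel values (HU).
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0, c(8, 8, 8)), spacing = c(0.78, 0.78, 3))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  rng <- range(x$data)
  cat(sprintf("  HU range [%.1f, %.1f]\n", rng[1], rng[2]))
  invisible(x)
}

#' Per-voxel 3-D displacement field
#'
#' A `displacement_field` stores, on a reference ("fixed") grid, a pull-back
#' displacement vector per voxel in physical mm: a transformation
#' `T(x) = x + u(x)` mapping reference positions into the moving image. Warping
#' the moving image with this field resamples it onto the reference grid.
#'
#' @param u numeric 4-D array with dim `c(nx, ny, nz, 3)`; components ordered
#'   along the fourth axis as (x, y, z) displacements in mm.
#' @param spacing,origin grid geometry, as in [ct_volume()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("`u` must be a 4-D array with dim (nx, ny, nz, 3)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  storage.mode(u) <- "double"
  structure(list(u = u, spacing = spacing, origin = as.numeric(origin)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$u)
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d, |u| mean %.2f mm, max %.2f mm\n",
              d[1], d[2], d[3], mean(mag), max(mag)))
  invisible(x)
}

#' Zero displacement field on a volume's grid
#'
#' @param volume a [ct_volume()] (or anything with `$data`, `$spacing`,
#'   `$origin`) whose grid the field should live on.
#' @return A [displacement_field()] of all-zero vectors.
#' @export
zero_dvf <- function(volume) {
  d <- dim(volume$data)
  displacement_field(array(0, c(d, 3L)), volume$spacing, volume$origin)
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "displacement_field")) dim(a$u)[1:3] else dim(a$data)
  db <- if (inherits(b, "displacement_field")) dim(b$u)[1:3] else dim(b$data)
  identical(da, db) && all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share grid shape, spacing and origin", what),
         call. = FALSE)
}

# Trilinear interpolation of a 3-D array at continuous 0-based voxel indices.
# Out-of-grid queries take `fill`, or the nearest edge value when clamp = TRUE.
interp3 <- function(a, ix, iy, iz, fill = 0, clamp = FALSE) {
  d <- dim(a)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  inside <- NULL
  if (!clamp)
    inside <- ix >= 0 & ix <= nx - 1 & iy >= 0 & iy <= ny - 1 &
      iz >= 0 & iz <= nz - 1
  ix <- pmin.int(pmax.int(ix, 0), nx - 1)
  iy <- pmin.int(pmax.int(iy, 0), ny - 1)
  iz <- pmin.int(pmax.int(iz, 0), nz - 1)
  x0 <- pmin.int(floor(ix), max(nx - 2L, 0L))
  y0 <- pmin.int(floor(iy), max(ny - 2L, 0L))
  z0 <- pmin.int(floor(iz), max(nz - 2L, 0L))
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  sx <- if (nx > 1L) 1L else 0L
  sy <- if (ny > 1L) 1L else 0L
  sz <- if (nz > 1L) 1L else 0L
  base <- 1 + x0 + nx * (y0 + ny * z0)
  oy <- nx; oz <- nx * ny
  c000 <- a[base]
  c100 <- a[base + sx]
  c010 <- a[base + sy * oy]
  c110 <- a[base + sx + sy * oy]
  c001 <- a[base + sz * oz]
  c101 <- a[base + sx + sz * oz]
  c011 <- a[base + sy * oy + sz * oz]
  c111 <- a[base + sx + sy * oy + sz * oz]
  w00 <- c000 + fx * (c100 - c000)
  w10 <- c010 + fx * (c110 - c010)
  w01 <- c001 + fx * (c101 - c001)
  w11 <- c011 + fx * (c111 - c011)
  v0 <- w00 + fy * (w10 - w00)
  v1 <- w01 + fy * (w11 - w01)
  v <- v0 + fz * (v1 - v0)
  if (!clamp && !all(inside)) v[!inside] <- fill
  v
}

# Trilinear interpolation with the exact partial derivatives of the
# interpolant with respect to the (0-based index) query coordinates.
# Coordinates are clamped to the grid; derivatives are those of the clamped
# interpolant's cell.
interp3_grad <- function(a, ix, iy, iz) {
  d <- dim(a)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  in_x <- ix > 0 & ix < nx - 1
  in_y <- iy > 0 & iy < ny - 1
  in_z <- iz > 0 & iz < nz - 1
  ix <- pmin.int(pmax.int(ix, 0), nx - 1)
  iy <- pmin.int(pmax.int(iy, 0), ny - 1)
  iz <- pmin.int(pmax.int(iz, 0), nz - 1)
  x0 <- pmin.int(floor(ix), max(nx - 2L, 0L))
  y0 <- pmin.int(floor(iy), max(ny - 2L, 0L))
  z0 <- pmin.int(floor(iz), max(nz - 2L, 0L))
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  sx <- if (nx > 1L) 1L else 0L
  sy <- if (ny > 1L) 1L else 0L
  sz <- if (nz > 1L) 1L else 0L
  base <- 1 + x0 + nx * (y0 + ny * z0)
  oy <- nx; oz <- nx * ny
  c000 <- a[base]; c100 <- a[base + sx]
  c010 <- a[base + sy * oy]; c110 <- a[base + sx + sy * oy]
  c001 <- a[base + sz * oz]; c101 <- a[base + sx + sz * oz]
  c011 <- a[base + sy * oy + sz * oz]; c111 <- a[base + sx + sy * oy + sz * oz]
  gx00 <- c100 - c000; gx10 <- c110 - c010
  gx01 <- c101 - c001; gx11 <- c111 - c011
  w00 <- c000 + fx * gx00
  w10 <- c010 + fx * gx10
  w01 <- c001 + fx * gx01
  w11 <- c011 + fx * gx11
  v0 <- w00 + fy * (w10 - w00)
  v1 <- w01 + fy * (w11 - w01)
  # a clamped query does not move with the displacement, so its derivative
  # along the clamped axis is zero
  list(
    value = v0 + fz * (v1 - v0),
    dx = ((gx00 + fy * (gx10 - gx00)) * (1 - fz) +
            (gx01 + fy * (gx11 - gx01)) * fz) * in_x,
    dy = ((w10 - w00) * (1 - fz) + (w11 - w01) * fz) * in_y,
    dz = (v1 - v0) * in_z
  )
}

# Physical coordinate arrays (mm) for every voxel of a grid.
grid_coords <- function(dim3, spacing, origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(dim3[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim3[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim3[3]) - 1) * spacing[3]
  list(
    x = array(rep(xs, times = dim3[2] * dim3[3]), dim3),
    y = array(rep(rep(ys, each = dim3[1]), times = dim3[3]), dim3),
    z = array(rep(zs, each = dim3[1] * dim3[2]), dim3)
  )
}

# Sample a displacement field (mm components) at physical positions (mm).
# Nearest-edge extrapolation outside the grid.
sample_dvf <- function(dvf, px, py, pz) {
  ix <- (px - dvf$origin[1]) / dvf$spacing[1]
  iy <- (py - dvf$origin[2]) / dvf$spacing[2]
  iz <- (pz - dvf$origin[3]) / dvf$spacing[3]
  list(
    ux = interp3(dvf$u[, , , 1L, drop = TRUE], ix, iy, iz, clamp = TRUE),
    uy = interp3(dvf$u[, , , 2L, drop = TRUE], ix, iy, iz, clamp = TRUE),
    uz = interp3(dvf$u[, , , 3L, drop = TRUE], ix, iy, iz, clamp = TRUE)
  )
}

#' Warp an image with a displacement field
#'
#' Resamples `image` through the pull-back transformation `T(x) = x + u(x)`:
#' the output voxel at reference position `x` takes the trilinearly
#' interpolated value `image(x + u(x))`. Positions falling outside the image
#' grid take `fill` (typically the background HU).
#'
#' @param image a [ct_volume()].
#' @param dvf a [displacement_field()] on the same grid.
#' @param fill value for samples outside the grid; defaults to the image
#'   minimum (air/background in CT).
#' @return A [ct_volume()] on the same grid as `image`.
#' @export
warp_volume <- function(image, dvf, fill = min(image$data)) {
  stopifnot(inherits(image, "ct_volume"), inherits(dvf, "displacement_field"))
  stop_if_grid_mismatch(image, dvf, "image and displacement field")
  d <- dim(image$data)
  g <- grid_coords(d, image$spacing, image$origin)
  px <- g$x + dvf$u[, , , 1L]
  py <- g$y + dvf$u[, , , 2L]
  pz <- g$z + dvf$u[, , , 3L]
  ix <- (px - image$origin[1]) / image$spacing[1]
  iy <- (py - image$origin[2]) / image$spacing[2]
  iz <- (pz - image$origin[3]) / image$spacing[3]
  out <- interp3(image$data, ix, iy, iz, fill = fill)
  ct_volume(array(out, d), image$spacing, image$origin)
}

#' Compose two displacement fields
#'
#' Returns the field of the composed transformation `T1 then T2` in pull-back
#' convention: `u(x) = u1(x) + u2(x + u1(x))`, with `u2` sampled trilinearly
#' and extrapolated by its nearest edge value outside the grid. Warping with
#' the composed field equals warping twice:
#' `warp(img, compose(u1, u2)) == warp(warp(img, u2), u1)` up to interpolation
#' error.
#'
#' @param first,second [displacement_field()]s on the same grid.
#' @return A [displacement_field()].
#' @export
compose_dvf <- function(first, second) {
  stopifnot(inherits(first, "displacement_field"),
            inherits(second, "displacement_field"))
  stop_if_grid_mismatch(first, second, "displacement fields")
  d <- dim(first$u)[1:3]
  g <- grid_coords(d, first$spacing, first$origin)
  s <- sample_dvf(second,
                  g$x + first$u[, , , 1L],
                  g$y + first$u[, , , 2L],
                  g$z + first$u[, , , 3L])
  u <- first$u
  u[, , , 1L] <- u[, , , 1L] + s$ux
  u[, , , 2L] <- u[, , , 2L] + s$uy
  u[, , , 3L] <- u[, , , 3L] + s$uz
  displacement_field(u, first$spacing, first$origin)
}

# Numerically invert a displacement field by fixed-point iteration:
# find v with v(y) = -u(y + v(y)). Converges for smooth, fold-free fields.
invert_dvf <- function(dvf, iters = 25L, tol = 1e-3) {
  d <- dim(dvf$u)[1:3]
  g <- grid_coords(d, dvf$spacing, dvf$origin)
  vx <- array(0, d); vy <- array(0, d); vz <- array(0, d)
  for (it in seq_len(iters)) {
    s <- sample_dvf(dvf, g$x + vx, g$y + vy, g$z + vz)
    dx <- -s$ux - vx; dy <- -s$uy - vy; dz <- -s$uz - vz
    vx <- vx + dx; vy <- vy + dy; vz <- vz + dz
    if (max(abs(dx), abs(dy), abs(dz)) < tol * min(dvf$spacing)) break
  }
  displacement_field(array(c(vx, vy, vz), c(d, 3L)), dvf$spacing, dvf$origin)
}

# Shift a 3-D array by one step along an axis. s = +1 pulls from the higher
# index (result[i] = a[i + 1]); pad = "edge" replicates the border slab,
# "zero" inserts zeros.
shift3 <- function(a, s, axis, pad = c("edge", "zero")) {
  pad <- match.arg(pad)
  if (s == 0L) return(a)
  d <- dim(a)
  n <- d[axis]
  idx <- seq_len(n) + s
  if (pad == "edge") idx <- pmin.int(pmax.int(idx, 1L), n)
  pick <- function(i) switch(axis,
    a[i, , , drop = FALSE], a[, i, , drop = FALSE], a[, , i, drop = FALSE])
  if (pad == "edge") return(pick(idx))
  keep <- idx >= 1L & idx <= n
  out <- array(0, d)
  if (!any(keep)) return(out)
  src <- pick(idx[keep])
  if (axis == 1L) out[keep, , ] <- src
  else if (axis == 2L) out[, keep, ] <- src
  else out[, , keep] <- src
  out
}

# Separable Gaussian smoothing of a 3-D array (sigma in voxels per axis),
# edge-replicated boundaries.
smooth_gauss3 <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (k in seq(-r, r))
      acc <- acc + w[k + r + 1L] * shift3(a, k, axis, pad = "edge")
    a <- acc
  }
  a
}
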