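# Spatial gradient of a 3-D array along one axis in physical units:
# central differences in the interior, one-sided at the two faces.
grad3 <- function(a, axis, h) {
  n <- dim(a)[axis]
  if (n < 3L) stop("need at least 3 voxels along each axis for derivatives",
                   call. = FALSE)
  g <- (shift3(a, +1L, axis, "edge") - shift3(a, -1L, axis, "edge")) / (2 * h)
  # fix the faces: edge padding above yields a one-sided difference over 2h
  first <- function(x) switch(axis, x[1, , ], x[, 1, ], x[, , 1])
  second <- function(x) switch(axis, x[2, , ], x[, 2, ], x[, , 2])
  last <- function(x) switch(axis, x[n, , ], x[, n, ], x[, , n])
  penult <- function(x) switch(axis, x[n - 1, , ], x[, n - 1, ], x[, , n - 1])
  lo <- (second(a) - first(a)) / h
  hi <- (last(a) - penult(a)) / h
  if (axis == 1L) { g[1, , ] <- lo; g[n, , ] <- hi }
  else if (axis == 2L) { g[, 1, ] <- lo; g[, n, ] <- hi }
  else { g[, , 1] <- lo; g[, , n] <- hi }
  g
}

# All nine partial derivatives of a displacement field, physical units (mm/mm).
dvf_gradients <- function(dvf) {
  h <- dvf$spacing
  out <- vector("list", 9L)
  k <- 1L
  for (comp in 1:3) {
    uc <- dvf$u[, , , comp, drop = TRUE]
    for (axis in 1:3) {
      out[[k]] <- grad3(uc, axis, h[axis])
      k <- k + 1L
    }
  }
  # out[[3*(c-1)+j]] = d u_c / d x_j
  out
}

det_jacobian <- function(g) {
  a11 <- 1 + g[[1]]; a12 <- g[[2]]; a13 <- g[[3]]
  a21 <- g[[4]]; a22 <- 1 + g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]]; a32 <- g[[8]]; a33 <- 1 + g[[9]]
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Jacobian-determinant ventilation map
#'
#' Converts a displacement field into a voxel-wise ventilation surrogate: the
#' determinant of the deformation Jacobian `det(I + grad u)`, with the nine
#' partials of `(u_x, u_y, u_z)` taken with respect to physical coordinates
#' (central differences in the interior, one-sided at grid faces, divided by
#' the per-axis spacing in mm). Values above 1 indicate local expansion,
#' below 1 local contraction; the map is unitless and relative.
#'
#' @param dvf a [displacement_field()] with at least 3 voxels per axis.
#' @param mask logical array marking the analysis region (e.g. the foam /
#'   lung-equivalent interior). Defaults to the full grid.
#' @return An object of class `ctvi_map`: list with `values` (3-D array),
#'   `mask`, `spacing`, `origin`.
#' @export
jacobian_map <- function(dvf, mask = NULL) {
  stopifnot(inherits(dvf, "displacement_field"))
  if (!all(is.finite(dvf$u))) {
    bad <- which(!is.finite(dvf$u), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite displacement at voxel (%d, %d, %d), component %d",
                 bad[1], bad[2], bad[3], bad[4]), call. = FALSE)
  }
  d <- dim(dvf$u)[1:3]
  if (any(d < 3L)) stop("field must be at least 3 voxels per axis",
                        call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) stop("mask must match the field grid",
                                     call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  values <- det_jacobian(dvf_gradients(dvf))
  structure(list(values = values, mask = mask, spacing = dvf$spacing,
                 origin = dvf$origin),
            class = "ctvi_map")
}

#' @export
print.ctvi_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<ctvi_map> %s voxels in mask; J in [%.3f, %.3f], mean %.3f\n",
              format(sum(x$mask), big.mark = ","), min(v), max(v), mean(v)))
  invisible(x)
}

#' Even three-way division of a reference ventilation map's range
#'
#' Thresholds for the low / middle / high ventilation categories are obtained
#' by evenly dividing the *range* of Jacobian values inside the reference
#' map's mask into three equal-width intervals (not by quantiles): with
#' `r = max - min`, the cut points are `min + r/3` and `min + 2r/3`.
#'
#' @param reference a `ctvi_map` from [jacobian_map()].
#' @return Numeric length-2 `c(t1, t2)` in Jacobian units.
#' @export
tertile_thresholds <- function(reference) {
  stopifnot(inherits(reference, "ctvi_map"))
  v <- reference$values[reference$mask]
  lo <- min(v); hi <- max(v)
  if (!(hi > lo))
    stop("reference map is constant inside the mask; category range is degenerate",
         call. = FALSE)
  r <- hi - lo
  c(lo + r / 3, lo + 2 * r / 3)
}

#' Categorize a ventilation map into low / middle / high
#'
#' Applies fixed thresholds (normally derived from the *reference* map via
#' [tertile_thresholds()]) to a ventilation map. Boundary convention:
#' intervals are left-closed/right-open, with the top interval closed, so a
#' value exactly at `t1` is `middle` and exactly at `t2` is `high`.
#'
#' @param vmap a `ctvi_map`.
#' @param thresholds numeric `c(t1, t2)` with `t1 <= t2`.
#' @return A `category_map`: list with integer `labels` (0 = outside mask,
#'   1 = low, 2 = middle, 3 = high), the `thresholds` used, `mask`, `spacing`.
#' @export
classify_ventilation <- function(vmap, thresholds) {
  stopifnot(inherits(vmap, "ctvi_map"), length(thresholds) == 2L)
  if (!(thresholds[1] <= thresholds[2]))
    stop("thresholds must satisfy t1 <= t2", call. = FALSE)
  lab <- array(0L, dim(vmap$values))
  v <- vmap$values
  lab[vmap$mask & v < thresholds[1]] <- 1L
  lab[vmap$mask & v >= thresholds[1] & v < thresholds[2]] <- 2L
  lab[vmap$mask & v >= thresholds[2]] <- 3L
  structure(list(labels = lab, thresholds = as.numeric(thresholds),
                 mask = vmap$mask, spacing = vmap$spacing),
            class = "category_map")
}

#' Foam / lung-equivalent analysis mask from an exhale image
#'
#' When phantom geometry is not available, the analysis mask is recovered from
#' the reference exhale image as the largest connected component of voxels
#' below an HU threshold (lung-equivalent foam is far less dense than the
#' acrylic wall), lightly eroded to stay clear of partial-volume edges.
#'
#' @param exhale a [ct_volume()].
#' @param threshold_hu HU cutoff; candidate foam lies strictly below it.
#' @param air_hu lower HU cutoff excluding background air.
#' @return Logical array of the same shape as `exhale$data`.
#' @export
foam_mask_from_image <- function(exhale, threshold_hu = -300, air_hu = -950) {
  stopifnot(inherits(exhale, "ct_volume"))
  cand <- exhale$data < threshold_hu & exhale$data > air_hu
  comp <- label_components3(cand)
  if (max(comp) == 0L) stop("no voxels below the foam threshold", call. = FALSE)
  sizes <- tabulate(comp[comp > 0L])
  keep <- comp == which.max(sizes)
  # one-voxel erosion to drop edge voxels
  er <- keep
  for (axis in 1:3)
    er <- er & shift3(keep + 0, 1L, axis, "zero") > 0 &
      shift3(keep + 0, -1L, axis, "zero") > 0
  if (!any(er)) keep else er
}

# 6-connected component labelling via flood fill (iterative label propagation).
label_components3 <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    for (axis in 1:3) {
      new <- pmax(new, shift3(lab, 1L, axis, "zero") * mask)
      new <- pmax(new, shift3(lab, -1L, axis, "zero") * mask)
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # relabel to 1..k
  u <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}
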