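#' Specification of the digital alveoli phantom
#'
#' Parameters of a digital analogue of a nonrigid alveoli phantom: an acrylic
#' cylinder filled with polyurethane foam (the lung-equivalent texture) whose
#' caudal face is driven by a diaphragm-like piston. The defaults describe a
#' desk-scale phantom (96 x 96 x 48 voxels at 2 x 2 x 3 mm) whose diaphragm
#' amplitude and axial decay were chosen so the mean landmark displacement
#' between the two breathing phases is about 14.6 mm.
#'
#' @param grid_shape integer length-3 voxel counts, all >= 8.
#' @param spacing voxel spacing in mm per axis, all > 0.
#' @param cylinder_radius outer cylinder radius in mm.
#' @param foam_mean_hu,foam_sd_hu mean and standard deviation (HU) of the
#'   band-limited foam texture after smoothing.
#' @param background_hu HU outside the cylinder (air).
#' @param wall_hu HU of the acrylic wall.
#' @param diaphragm_amplitude peak caudal displacement of the diaphragm face
#'   in mm (>= 0).
#' @param decay_length axial e-folding length (mm) of the motion away from the
#'   diaphragm face.
#' @param n_landmarks number of auto-placed landmarks (>= 1).
#' @param seed integer seed; the phantom is a pure function of the spec.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 48L),
                         spacing = c(2, 2, 3),
                         cylinder_radius = 80,
                         foam_mean_hu = -700,
                         foam_sd_hu = 60,
                         background_hu = -1000,
                         wall_hu = 120,
                         diaphragm_amplitude = 22,
                         decay_length = 150,
                         n_landmarks = 25L,
                         seed = 0L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be 3 integers, all >= 8", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)", call. = FALSE)
  if (diaphragm_amplitude < 0)
    stop("diaphragm_amplitude must be >= 0", call. = FALSE)
  if (decay_length <= 0) stop("decay_length must be > 0", call. = FALSE)
  if (foam_sd_hu < 0) stop("foam_sd_hu must be >= 0", call. = FALSE)
  if (n_landmarks < 1L) stop("n_landmarks must be >= 1", call. = FALSE)
  if (n_landmarks > prod(grid_shape))
    stop("n_landmarks exceeds the number of voxels", call. = FALSE)
  if (cylinder_radius <= 4 * max(spacing[1:2]))
    stop("cylinder_radius too small for the grid spacing", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 cylinder_radius = cylinder_radius,
                 foam_mean_hu = foam_mean_hu, foam_sd_hu = foam_sd_hu,
                 background_hu = background_hu, wall_hu = wall_hu,
                 diaphragm_amplitude = diaphragm_amplitude,
                 decay_length = decay_length,
                 n_landmarks = as.integer(n_landmarks),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$spacing
  cx <- (d[1] - 1) / 2 * sp[1]
  cy <- (d[2] - 1) / 2 * sp[2]
  wall_thickness <- 2.5 * max(sp[1:2])
  zmax <- (d[3] - 1) * sp[3]
  # the diaphragm face sits far enough from the caudal grid edge that the
  # fully displaced face stays inside the field of view
  face_z <- zmax - spec$diaphragm_amplitude - 2 * sp[3]
  base_z <- 2 * sp[3]
  list(cx = cx, cy = cy, r_outer = spec$cylinder_radius,
       r_inner = spec$cylinder_radius - wall_thickness,
       face_z = face_z, base_z = base_z, zmax = zmax)
}

# Analytic diaphragm-driven displacement field evaluated at physical
# coordinates (vectors, mm). Dominant caudal (+z) component
#   u_z = A * exp(-d / L) * taper(r),
# with d the axial distance cranial of the diaphragm face, and a smooth
# quartic radial taper that vanishes at the cylinder wall.
analytic_dvf_at <- function(spec, px, py, pz) {
  geo <- phantom_geometry(spec)
  r <- sqrt((px - geo$cx)^2 + (py - geo$cy)^2)
  taper <- pmax(0, 1 - (r / geo$r_outer)^4)
  dax <- pmax(0, geo$face_z - pz)
  uz <- spec$diaphragm_amplitude * exp(-dax / spec$decay_length) * taper
  list(ux = numeric(length(uz)) + 0 * uz, uy = 0 * uz, uz = uz)
}

#' Analytic ground-truth displacement field of the phantom
#'
#' Evaluates the closed-form diaphragm motion model on the phantom grid. The
#' field is smooth and fold-free by construction (its Jacobian determinant is
#' `1 + (A/L) exp(-d/L) taper(r) > 0` cranial of the face and exactly 1
#' caudal of it); a defensive check still verifies positivity voxel-by-voxel.
#' Convention: pull-back field on the exhale grid, in mm, such that warping
#' the inhale image with it reproduces the exhale image, and landmarks map as
#' `inhale = exhale + u(exhale)`.
#'
#' @param spec a [phantom_spec()].
#' @return A [displacement_field()] on the phantom grid.
#' @export
analytic_dvf <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  g <- grid_coords(d, spec$spacing)
  u <- analytic_dvf_at(spec, as.vector(g$x), as.vector(g$y), as.vector(g$z))
  dvf <- displacement_field(array(c(u$ux, u$uy, u$uz), c(d, 3L)), spec$spacing)
  jac <- det_jacobian(dvf_gradients(dvf))
  if (any(jac <= 0)) {
    bad <- which(jac <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("analytic field folds (J = %.4f <= 0) at voxel ",
                        "(%d, %d, %d); reduce diaphragm_amplitude or ",
                        "increase decay_length"),
                 jac[matrix(bad, 1)], bad[1], bad[2], bad[3]), call. = FALSE)
  }
  dvf
}

phantom_masks <- function(spec) {
  d <- spec$grid_shape
  geo <- phantom_geometry(spec)
  g <- grid_coords(d, spec$spacing)
  r <- sqrt((g$x - geo$cx)^2 + (g$y - geo$cy)^2)
  in_z <- g$z >= geo$base_z & g$z <= geo$face_z
  foam <- r < geo$r_inner & in_z
  wall <- r >= geo$r_inner & r < geo$r_outer & in_z
  list(foam = foam, wall = wall, r = r, g = g, geo = geo)
}

# Strict 26-neighbourhood local maxima of a 3-D array.
local_maxima3 <- function(a) {
  is_max <- array(TRUE, dim(a))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- shift3(shift3(shift3(a, dx, 1L, "edge"), dy, 2L, "edge"),
                 dz, 3L, "edge")
    is_max <- is_max & (a > nb)
  }
  is_max
}

place_landmarks <- function(texture, masks, spec) {
  sp <- spec$spacing
  geo <- masks$geo
  # eroded interior: clear of the wall and of both axial foam faces so that
  # landmarks and their displaced twins stay inside the foam
  ok <- masks$foam & masks$r < 0.8 * geo$r_inner &
    masks$g$z >= geo$base_z + 2 * sp[3] & masks$g$z <= geo$face_z - 2 * sp[3]
  cand <- which(local_maxima3(texture) & ok)
  if (!length(cand))
    stop("no landmark candidates inside the foam interior", call. = FALSE)
  ord <- cand[order(texture[cand], decreasing = TRUE)]
  d <- dim(texture)
  idx <- arrayInd(ord, d) - 1L
  pos <- sweep(idx, 2, sp, `*`)
  min_sep <- 12
  repeat {
    chosen <- integer(0)
    for (i in seq_len(nrow(pos))) {
      if (length(chosen) >= spec$n_landmarks) break
      if (!length(chosen)) { chosen <- i; next }
      dd <- sqrt(rowSums((pos[chosen, , drop = FALSE] -
                            matrix(pos[i, ], length(chosen), 3,
                                   byrow = TRUE))^2))
      if (all(dd >= min_sep)) chosen <- c(chosen, i)
    }
    if (length(chosen) >= spec$n_landmarks || min_sep <= 1) break
    min_sep <- min_sep / 2
  }
  if (length(chosen) < spec$n_landmarks)
    stop(sprintf("only %d landmark sites available for %d requested",
                 length(chosen), spec$n_landmarks), call. = FALSE)
  landmark_set(pos[chosen[seq_len(spec$n_landmarks)], , drop = FALSE])
}

#' Generate an exhale/inhale phantom pair with ground truth
#'
#' Builds the digital phantom deterministically from its spec: an exhale
#' volume (cylinder wall enclosing band-limited random foam texture over air
#' background), the analytic diaphragm displacement field, an inhale volume
#' synthesized by resampling the exhale volume through the numerically
#' inverted field (so that warping inhale with `true_dvf` recovers exhale, the
#' same convention a registration estimate uses), the ground-truth
#' Jacobian-determinant ventilation map over the foam, and corresponding
#' landmark sets auto-placed at local texture maxima.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_pair` with elements `exhale`, `inhale`,
#'   `true_dvf`, `true_ventilation`, `landmarks_exhale`, `landmarks_inhale`,
#'   `foam_mask`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  masks <- phantom_masks(spec)

  texture <- with_local_seed(derive_seed(spec$seed, "phantom-texture"), {
    smooth_gauss3(array(stats::rnorm(prod(d)), d), sigma = c(1.2, 1.2, 0.8))
  })
  texture <- (texture - mean(texture)) / stats::sd(texture)
  foam_hu <- spec$foam_mean_hu + spec$foam_sd_hu * texture

  vol <- array(spec$background_hu, d)
  vol[masks$wall] <- spec$wall_hu
  vol[masks$foam] <- foam_hu[masks$foam]
  exhale <- ct_volume(vol, spec$spacing)

  true_dvf <- analytic_dvf(spec)
  inhale <- if (spec$diaphragm_amplitude == 0) exhale else
    warp_volume(exhale, invert_dvf(true_dvf), fill = spec$background_hu)

  true_ventilation <- jacobian_map(true_dvf, mask = masks$foam)

  lm_ex <- place_landmarks(texture * (masks$foam + 0), masks, spec)
  u_lm <- analytic_dvf_at(spec, lm_ex$x_mm, lm_ex$y_mm, lm_ex$z_mm)
  lm_in <- landmark_set(cbind(lm_ex$x_mm + u_lm$ux,
                              lm_ex$y_mm + u_lm$uy,
                              lm_ex$z_mm + u_lm$uz), id = lm_ex$id)

  structure(list(exhale = exhale, inhale = inhale, true_dvf = true_dvf,
                 true_ventilation = true_ventilation,
                 landmarks_exhale = lm_ex, landmarks_inhale = lm_in,
                 foam_mask = masks$foam, spec = spec),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  d <- x$spec$grid_shape
  disp <- sqrt(rowSums((lm_matrix(x$landmarks_inhale) -
                          lm_matrix(x$landmarks_exhale))^2))
  cat(sprintf(paste0("<phantom_pair> %d x %d x %d @ %.3g x %.3g x %.3g mm; ",
                     "%d landmarks, mean displacement %.2f mm\n"),
              d[1], d[2], d[3], x$spec$spacing[1], x$spec$spacing[2],
              x$spec$spacing[3], nrow(x$landmarks_exhale), mean(disp)))
  invisible(x)
}

#' Write a phantom pair to disk
#'
#' Persists exhale/inhale volumes, the true displacement field and ventilation
#' map as NIfTI, and both landmark sets as CSV.
#'
#' @param pair a `phantom_pair`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(pair$exhale, file.path(dir, "exhale.nii.gz"))
  write_volume(pair$inhale, file.path(dir, "inhale.nii.gz"))
  write_volume(pair$true_dvf, file.path(dir, "true_dvf.nii.gz"))
  write_volume(ct_volume(pair$true_ventilation$values, pair$exhale$spacing),
               file.path(dir, "true_ventilation.nii.gz"))
  write_volume(ct_volume(pair$foam_mask + 0, pair$exhale$spacing),
               file.path(dir, "foam_mask.nii.gz"))
  write_landmarks(pair$landmarks_exhale, file.path(dir, "landmarks_exhale.csv"))
  write_landmarks(pair$landmarks_inhale, file.path(dir, "landmarks_inhale.csv"))
  invisible(dir)
}
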