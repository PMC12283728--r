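#' Registration configuration
#'
#' Parameters of the multi-step B-spline free-form deformable registration.
#' Each of `n_steps` cascade steps runs a coarse-to-fine optimization of a
#' cubic B-spline displacement field minimizing
#' `-similarity + bending_weight * bending_energy + jacobian_weight * mean((J-1)^2)`
#' by gradient descent with backtracking line search; each step's field is
#' composed onto the accumulated field, and a step whose field folds more than
#' `overdeform_threshold` of the voxels is omitted. No rigid pre-alignment is
#' performed.
#'
#' @param n_steps cascade steps (>= 1).
#' @param levels multi-resolution levels per step (>= 1); level `l` works on
#'   the image downsampled by `2^(levels - l)`.
#' @param max_iterations maximum descent iterations per level.
#' @param bending_weight weight of the bending-energy smoothness penalty.
#' @param jacobian_weight weight of the Jacobian volume-change penalty.
#' @param grid_spacing_mm B-spline control-point spacing per axis in mm;
#'   `NULL` means 8 voxels of the reference image.
#' @param similarity `"nmi"` (normalized mutual information, maximized) or
#'   `"ssd"` (sum of squared differences normalized by the reference dynamic
#'   range, minimized; appropriate for same-modality synthetic data).
#' @param bins histogram bins for NMI.
#' @param overdeform_threshold maximum tolerated fraction of voxels with
#'   non-positive Jacobian in a step's field before the step is discarded.
#' @param tol relative cost-improvement tolerance that ends a level early.
#' @param seed integer seed (the optimizer itself is deterministic; kept for
#'   interface stability).
#' @return A validated list of class `reg_config`.
#' @export
reg_config <- function(n_steps = 4L, levels = 3L, max_iterations = 300L,
                       bending_weight = 0.005, jacobian_weight = 0.0005,
                       grid_spacing_mm = NULL, similarity = c("nmi", "ssd"),
                       bins = 64L, overdeform_threshold = 0.001,
                       tol = 1e-6, seed = 0L) {
  similarity <- match.arg(similarity)
  if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  if (bending_weight < 0 || jacobian_weight < 0)
    stop("penalty weights must be >= 0", call. = FALSE)
  if (bins < 4L) stop("bins must be >= 4", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps), levels = as.integer(levels),
                 max_iterations = as.integer(max_iterations),
                 bending_weight = bending_weight,
                 jacobian_weight = jacobian_weight,
                 grid_spacing_mm = grid_spacing_mm, similarity = similarity,
                 bins = as.integer(bins),
                 overdeform_threshold = overdeform_threshold,
                 tol = tol, seed = as.integer(seed)),
            class = "reg_config")
}

## ---- cubic B-spline tensor machinery ----

bspline3_kernel <- function(r) {
  a <- abs(r)
  out <- numeric(length(a))
  i1 <- a < 1
  out[i1] <- 2 / 3 - a[i1]^2 + a[i1]^3 / 2
  i2 <- a >= 1 & a < 2
  out[i2] <- (2 - a[i2])^3 / 6
  out
}

bspline3_d1 <- function(r) {
  a <- abs(r)
  out <- numeric(length(a))
  i1 <- a < 1
  out[i1] <- -2 * r[i1] + 1.5 * r[i1] * a[i1]
  i2 <- a >= 1 & a < 2
  out[i2] <- -sign(r[i2]) * (2 - a[i2])^2 / 2
  out
}

bspline3_d2 <- function(r) {
  a <- abs(r)
  out <- numeric(length(a))
  i1 <- a < 1
  out[i1] <- -2 + 3 * a[i1]
  i2 <- a >= 1 & a < 2
  out[i2] <- 2 - a[i2]
  out
}

# Per-axis Gram matrices of the B-spline basis and its first two derivatives
# over the image domain [0, extent]; the continuous bending energy of the
# spline field is then a separable quadratic form in the coefficients.
spline_gram <- function(extent, delta, ncp) {
  xs <- seq(0, extent, by = delta / 20)
  dx <- delta / 20
  centers <- (seq_len(ncp) - 2) * delta
  t0 <- outer(xs / delta, centers / delta, `-`)
  B0 <- matrix(bspline3_kernel(t0), nrow(t0))
  B1 <- matrix(bspline3_d1(t0), nrow(t0)) / delta
  B2 <- matrix(bspline3_d2(t0), nrow(t0)) / delta^2
  list(S0 = crossprod(B0) * dx, S1 = crossprod(B1) * dx,
       S2 = crossprod(B2) * dx)
}

# Continuous thin-plate bending energy of the spline field, per unit volume,
# with its exact coefficient gradient.
spline_bending <- function(theta_c, gx, gy, gz, volume) {
  terms <- list(list(gx$S2, gy$S0, gz$S0, 1), list(gx$S0, gy$S2, gz$S0, 1),
                list(gx$S0, gy$S0, gz$S2, 1), list(gx$S1, gy$S1, gz$S0, 2),
                list(gx$S1, gy$S0, gz$S1, 2), list(gx$S0, gy$S1, gz$S1, 2))
  e <- 0
  grad <- array(0, dim(theta_c))
  for (tm in terms) {
    tt <- tensor3_fw(theta_c, tm[[1]], tm[[2]], tm[[3]])
    e <- e + tm[[4]] * sum(theta_c * tt)
    grad <- grad + (2 * tm[[4]]) * tt
  }
  list(value = e / volume, grad = grad / volume)
}

# Basis matrix mapping control coefficients (points at (i-2)*delta, i=1..ncp)
# to values at physical coordinates `coords`.
bspline_basis <- function(coords, delta, ncp) {
  t <- coords / delta
  outer(t, seq_len(ncp) - 2, function(tt, ii) bspline3_kernel(tt - ii))
}

ncp_for_extent <- function(extent, delta) floor(extent / delta) + 4L

# theta (c1,c2,c3) -> dense (nx,ny,nz) through separable bases.
tensor3_fw <- function(theta, Bx, By, Bz) {
  d <- dim(theta)
  a <- array(Bx %*% matrix(theta, d[1]), c(nrow(Bx), d[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- array(By %*% matrix(a, d[2]), c(nrow(By), nrow(Bx), d[3]))
  a <- aperm(a, c(2, 1, 3))                     # (nx, ny, c3)
  a2 <- aperm(a, c(3, 1, 2))
  a2 <- array(Bz %*% matrix(a2, d[3]), c(nrow(Bz), nrow(Bx), nrow(By)))
  aperm(a2, c(2, 3, 1))
}

# adjoint: dense voxel gradient -> control coefficient gradient
tensor3_adj <- function(g, Bx, By, Bz) {
  tensor3_fw(g, t(Bx), t(By), t(Bz))
}

## ---- dense-field penalties with exact adjoints ----

zero_face3 <- function(v, ax) {
  n <- dim(v)[ax]
  if (ax == 1L) { v[1, , ] <- 0; v[n, , ] <- 0 }
  else if (ax == 2L) { v[, 1, ] <- 0; v[, n, ] <- 0 }
  else { v[, , 1] <- 0; v[, , n] <- 0 }
  v
}

d2_same <- function(u, ax, h) {
  v <- (shift3(u, 1L, ax, "zero") - 2 * u + shift3(u, -1L, ax, "zero")) / h^2
  zero_face3(v, ax)
}
d2_same_adj <- function(v, ax, h) {
  (shift3(v, -1L, ax, "zero") - 2 * v + shift3(v, 1L, ax, "zero")) / h^2
}
d2_cross <- function(u, ax1, ax2, h1, h2) {
  s <- function(a, b) shift3(shift3(u, a, ax1, "zero"), b, ax2, "zero")
  v <- (s(1L, 1L) - s(1L, -1L) - s(-1L, 1L) + s(-1L, -1L)) / (4 * h1 * h2)
  zero_face3(zero_face3(v, ax1), ax2)
}
d2_cross_adj <- function(v, ax1, ax2, h1, h2) {
  s <- function(a, b) shift3(shift3(v, a, ax1, "zero"), b, ax2, "zero")
  (s(-1L, -1L) - s(-1L, 1L) - s(1L, -1L) + s(1L, 1L)) / (4 * h1 * h2)
}

# masked central difference (interior only) and its adjoint
dc_fw <- function(u, ax, h) {
  v <- (shift3(u, 1L, ax, "zero") - shift3(u, -1L, ax, "zero")) / (2 * h)
  zero_face3(v, ax)
}
dc_adj <- function(v, ax, h) {
  (shift3(v, -1L, ax, "zero") - shift3(v, 1L, ax, "zero")) / (2 * h)
}

# u_list: list of the three displacement component arrays; h: spacing.
bending_core <- function(u_list, h, want_grad = FALSE) {
  n <- length(u_list[[1]])
  total <- 0
  grads <- if (want_grad) vector("list", 3L) else NULL
  for (cc in 1:3) {
    u <- u_list[[cc]]
    dxx <- d2_same(u, 1L, h[1]); dyy <- d2_same(u, 2L, h[2])
    dzz <- d2_same(u, 3L, h[3])
    dxy <- d2_cross(u, 1L, 2L, h[1], h[2])
    dxz <- d2_cross(u, 1L, 3L, h[1], h[3])
    dyz <- d2_cross(u, 2L, 3L, h[2], h[3])
    total <- total + sum(dxx^2) + sum(dyy^2) + sum(dzz^2) +
      2 * (sum(dxy^2) + sum(dxz^2) + sum(dyz^2))
    if (want_grad)
      grads[[cc]] <- (2 / n) * (
        d2_same_adj(dxx, 1L, h[1]) + d2_same_adj(dyy, 2L, h[2]) +
          d2_same_adj(dzz, 3L, h[3]) +
          2 * d2_cross_adj(dxy, 1L, 2L, h[1], h[2]) +
          2 * d2_cross_adj(dxz, 1L, 3L, h[1], h[3]) +
          2 * d2_cross_adj(dyz, 2L, 3L, h[2], h[3]))
  }
  list(value = total / n, grads = grads)
}

#' Bending energy of a displacement field
#'
#' Thin-plate bending form: the mean over voxels of the sum of squared second
#' spatial derivatives (in physical units, cross terms counted twice) of all
#' three displacement components, approximated by finite differences on the
#' interior. Affine fields, including pure translations, have zero bending
#' energy.
#'
#' @param dvf a [displacement_field()] at least 3 voxels per axis.
#' @return A single non-negative number (mm^-2 units).
#' @export
bending_energy <- function(dvf) {
  stopifnot(inherits(dvf, "displacement_field"))
  if (any(dim(dvf$u)[1:3] < 3L))
    stop("field must be at least 3 voxels per axis", call. = FALSE)
  u_list <- lapply(1:3, function(cc) dvf$u[, , , cc, drop = TRUE])
  bending_core(u_list, dvf$spacing)$value
}

jacobian_core <- function(u_list, h, want_grad = FALSE) {
  n <- length(u_list[[1]])
  G <- vector("list", 9L)
  for (cc in 1:3) for (j in 1:3)
    G[[3 * (cc - 1) + j]] <- dc_fw(u_list[[cc]], j, h[j])
  m11 <- 1 + G[[1]]; m12 <- G[[2]]; m13 <- G[[3]]
  m21 <- G[[4]]; m22 <- 1 + G[[5]]; m23 <- G[[6]]
  m31 <- G[[7]]; m32 <- G[[8]]; m33 <- 1 + G[[9]]
  jac <- m11 * (m22 * m33 - m23 * m32) - m12 * (m21 * m33 - m23 * m31) +
    m13 * (m21 * m32 - m22 * m31)
  val <- sum((jac - 1)^2) / n
  if (!want_grad) return(list(value = val, jac = jac))
  dpdj <- 2 * (jac - 1) / n
  cof <- list(
    m22 * m33 - m23 * m32, -(m21 * m33 - m23 * m31), m21 * m32 - m22 * m31,
    -(m12 * m33 - m13 * m32), m11 * m33 - m13 * m31, -(m11 * m32 - m12 * m31),
    m12 * m23 - m13 * m22, -(m11 * m23 - m13 * m21), m11 * m22 - m12 * m21)
  grads <- vector("list", 3L)
  for (cc in 1:3) {
    g <- 0
    for (j in 1:3)
      g <- g + dc_adj(zero_face3(dpdj * cof[[3 * (cc - 1) + j]], j), j, h[j])
    grads[[cc]] <- g
  }
  list(value = val, jac = jac, grads = grads)
}

#' Fraction of folded voxels in a displacement field
#'
#' Computes the Jacobian determinant at every voxel and returns the fraction
#' with `J <= 0` (physically invalid folding / over-deformation). Used to
#' automate the per-step over-deformation check of the registration cascade.
#'
#' @param dvf a [displacement_field()].
#' @param mask optional logical analysis region.
#' @return Fraction in `[0, 1]`.
#' @export
check_over_deformation <- function(dvf, mask = NULL) {
  vm <- jacobian_map(dvf, mask = mask)
  mean(vm$values[vm$mask] <= 0)
}

## ---- similarity metrics ----

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information of two volumes
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` from a joint histogram with `bins`
#' equal-width bins spanning each image's own range. Ranges from 1
#' (independent) to 2 (deterministically related). A constant image has zero
#' entropy; by convention the result is then 2, with a warning.
#'
#' @param a,b [ct_volume()]s (or plain arrays) on the same grid.
#' @param bins number of histogram bins per image.
#' @return A single number in `[1, 2]` up to estimation error.
#' @export
nmi <- function(a, b, bins = 64L) {
  av <- if (inherits(a, "ct_volume")) a$data else a
  bv <- if (inherits(b, "ct_volume")) b$data else b
  if (length(av) != length(bv)) stop("volumes differ in size", call. = FALSE)
  ra <- range(av); rb <- range(bv)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    warning("constant image: NMI defined as 2 by convention")
    return(2)
  }
  ia <- pmin.int(floor((av - ra[1]) / (ra[2] - ra[1]) * bins), bins - 1L)
  ib <- pmin.int(floor((bv - rb[1]) / (rb[2] - rb[1]) * bins), bins - 1L)
  joint <- tabulate(1L + ia + bins * ib, nbins = bins * bins) / length(av)
  pj <- matrix(joint, bins, bins)
  ha <- entropy_nats(rowSums(pj))
  hb <- entropy_nats(colSums(pj))
  hab <- entropy_nats(joint)
  (ha + hb) / hab
}

# Soft-binned NMI (hard bins on the fixed image, linear tent bins on the
# moving values) with the per-voxel derivative of -NMI w.r.t. the moving
# intensity. Used inside the optimizer.
nmi_soft <- function(fixed_bin, mov, mov_lo, mov_h, bins, want_grad = FALSE,
                     ha = NULL) {
  n <- length(mov)
  tb <- (mov - mov_lo) / mov_h - 0.5
  b0 <- pmin.int(pmax.int(floor(tb), 0), bins - 2L)
  f <- pmin.int(pmax.int(tb - b0, 0), 1)
  k1 <- 1L + (fixed_bin - 1L) + bins * b0
  k2 <- k1 + bins
  w <- c(1 - f, f)
  kk <- c(k1, k2)
  agg <- rowsum(w, kk)
  joint <- numeric(bins * bins)
  joint[as.integer(rownames(agg))] <- agg / n
  pj <- matrix(joint, bins, bins)
  if (is.null(ha)) ha <- entropy_nats(rowSums(pj))
  qb <- colSums(pj)
  hb <- entropy_nats(qb)
  hab <- entropy_nats(joint)
  val <- (ha + hb) / hab
  if (!want_grad) return(list(nmi = val))
  tiny <- 1e-12
  logq <- log(pmax(qb, tiny))
  logp <- log(pmax(joint, tiny))
  # dNMI/dP_ab = -(1 + log q_b)/H_ab + NMI (1 + log P_ab)/H_ab
  tgrid <- (-(1 + rep(logq, each = bins)) + val * (1 + logp)) / hab
  dmdm <- (tgrid[k2] - tgrid[k1]) / (n * mov_h)
  # cost is -NMI
  list(nmi = val, dcost_dmov = -dmdm)
}

## ---- multi-resolution pyramid ----

downsample_volume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  sm <- smooth_gauss3(vol$data, sigma = rep(factor / 2, 3))
  d <- dim(sm)
  ix <- seq(1L, d[1], by = factor)
  iy <- seq(1L, d[2], by = factor)
  iz <- seq(1L, d[3], by = factor)
  ct_volume(sm[ix, iy, iz, drop = FALSE], vol$spacing * factor, vol$origin)
}

## ---- level cost/gradient ----

make_level_env <- function(reference, moving, cfg) {
  d <- dim(reference$data)
  sp <- reference$spacing
  env <- list(R = reference$data, M = moving$data, sp = sp, d = d,
              n = prod(d))
  g <- grid_coords(d, sp, reference$origin)
  env$ix0 <- as.vector((g$x - moving$origin[1]) / sp[1])
  env$iy0 <- as.vector((g$y - moving$origin[2]) / sp[2])
  env$iz0 <- as.vector((g$z - moving$origin[3]) / sp[3])
  if (cfg$similarity == "ssd") {
    rng <- diff(range(reference$data))
    env$ssd_scale <- if (rng > 0) 1 / rng^2 else 1
  } else {
    rr <- range(reference$data)
    if (rr[1] == rr[2]) rr[2] <- rr[1] + 1
    fb <- pmin.int(floor((env$R - rr[1]) / (rr[2] - rr[1]) * cfg$bins),
                   cfg$bins - 1L)
    env$fixed_bin <- as.integer(fb) + 1L
    pa <- tabulate(env$fixed_bin, nbins = cfg$bins) / env$n
    env$ha <- entropy_nats(pa)
    mr <- range(moving$data)
    if (mr[1] == mr[2]) mr[2] <- mr[1] + 1
    env$mov_lo <- mr[1]
    env$mov_h <- (mr[2] - mr[1]) / cfg$bins
  }
  env
}

level_cost <- function(theta, env, basis, cfg, want_grad = FALSE) {
  u1 <- tensor3_fw(theta[, , , 1L], basis$Bx, basis$By, basis$Bz)
  u2 <- tensor3_fw(theta[, , , 2L], basis$Bx, basis$By, basis$Bz)
  u3 <- tensor3_fw(theta[, , , 3L], basis$Bx, basis$By, basis$Bz)
  sp <- env$sp
  qx <- env$ix0 + as.vector(u1) / sp[1]
  qy <- env$iy0 + as.vector(u2) / sp[2]
  qz <- env$iz0 + as.vector(u3) / sp[3]
  ws <- if (want_grad) interp3_grad(env$M, qx, qy, qz) else
    list(value = interp3(env$M, qx, qy, qz, clamp = TRUE))
  warped <- ws$value
  if (cfg$similarity == "ssd") {
    resid <- warped - as.vector(env$R)
    sim <- env$ssd_scale * sum(resid^2) / env$n
  } else {
    sm <- nmi_soft(env$fixed_bin, warped, env$mov_lo, env$mov_h, cfg$bins,
                   want_grad = want_grad, ha = env$ha)
    sim <- -sm$nmi
  }
  be_val <- 0
  be_grads <- NULL
  if (cfg$bending_weight > 0) {
    be_grads <- vector("list", 3L)
    for (cc in 1:3) {
      sb <- spline_bending(theta[, , , cc], basis$gram$x, basis$gram$y,
                           basis$gram$z, basis$volume)
      be_val <- be_val + sb$value
      be_grads[[cc]] <- sb$grad
    }
  }
  jp <- list(value = 0, grads = NULL)
  if (cfg$jacobian_weight > 0) {
    dec <- basis$dec
    ud <- lapply(1:3, function(cc)
      tensor3_fw(theta[, , , cc], dec$Bx, dec$By, dec$Bz))
    jp <- jacobian_core(ud, dec$spacing, want_grad = want_grad)
  }
  total <- sim + cfg$bending_weight * be_val + cfg$jacobian_weight * jp$value
  if (!want_grad)
    return(list(total = total, sim = sim, bending = be_val,
                jacobian = jp$value))
  dsim_dw <- if (cfg$similarity == "ssd")
    env$ssd_scale * 2 * resid / env$n else sm$dcost_dmov
  dcd <- list(array(dsim_dw * ws$dx / sp[1], env$d),
              array(dsim_dw * ws$dy / sp[2], env$d),
              array(dsim_dw * ws$dz / sp[3], env$d))
  gtheta <- array(0, dim(theta))
  for (cc in 1:3) {
    g <- tensor3_adj(dcd[[cc]], basis$Bx, basis$By, basis$Bz)
    if (cfg$bending_weight > 0)
      g <- g + cfg$bending_weight * be_grads[[cc]]
    if (cfg$jacobian_weight > 0)
      g <- g + cfg$jacobian_weight *
        tensor3_adj(jp$grads[[cc]], basis$dec$Bx, basis$dec$By, basis$dec$Bz)
    gtheta[, , , cc] <- g
  }
  list(total = total, sim = sim, bending = be_val, jacobian = jp$value,
       grad = gtheta)
}

optimize_level <- function(theta, env, basis, cfg, trace, step, level) {
  cur <- level_cost(theta, env, basis, cfg)
  tstep <- NA_real_
  for (iter in seq_len(cfg$max_iterations)) {
    cg <- level_cost(theta, env, basis, cfg, want_grad = TRUE)
    g <- cg$grad
    gmax <- max(abs(g))
    if (!is.finite(cg$total))
      stop(sprintf("non-finite registration cost at step %d level %d iter %d",
                   step, level, iter), call. = FALSE)
    if (gmax < 1e-12) break
    gnorm2 <- sum(g^2)
    if (is.na(tstep)) tstep <- 0.4 * min(env$sp) / gmax
    accepted <- FALSE
    for (ls in 1:30) {
      theta_new <- theta - tstep * g
      cand <- level_cost(theta_new, env, basis, cfg)
      if (is.finite(cand$total) &&
          cand$total <= cg$total - 1e-4 * tstep * gnorm2) {
        accepted <- TRUE
        break
      }
      tstep <- tstep / 2
    }
    if (!accepted) break
    rel <- (cur$total - cand$total) / max(abs(cur$total), 1e-12)
    theta <- theta_new
    cur <- cand
    trace$rows[[length(trace$rows) + 1L]] <-
      data.frame(step = step, level = level, iter = iter, cost = cand$total,
                 similarity = cand$sim, bending = cand$bending,
                 jacobian = cand$jacobian)
    tstep <- tstep * 1.5
    if (rel < cfg$tol) break
  }
  theta
}

## ---- public registration ----

#' Deformable registration of a moving image onto a reference
#'
#' Estimates the pull-back displacement field aligning `moving` (typically the
#' inhale image) onto `reference` (the exhale image) with a cascade of
#' `cfg$n_steps` cubic B-spline free-form deformations. Each step runs a
#' coarse-to-fine pyramid (`cfg$levels` levels); the B-spline control grid
#' lives in physical coordinates, so the same coefficients act at every
#' resolution. After each step the estimated field is checked for folding: if
#' more than `cfg$overdeform_threshold` of its voxels have a non-positive
#' Jacobian, the step is omitted; otherwise it is composed onto the
#' accumulated field and the next step starts from the re-warped moving image.
#'
#' @param reference,moving [ct_volume()]s on the same grid.
#' @param cfg a [reg_config()].
#' @return A [displacement_field()] mapping reference positions into the
#'   moving image, with attributes `log` (per-iteration cost trace) and
#'   `steps` (per-step summary: accepted, folding fraction).
#' @export
register_ffd <- function(reference, moving, cfg = reg_config()) {
  stopifnot(inherits(reference, "ct_volume"), inherits(moving, "ct_volume"))
  stop_if_grid_mismatch(reference, moving, "reference and moving images")
  if (!all(is.finite(reference$data)) || !all(is.finite(moving$data)))
    stop("images must be finite", call. = FALSE)
  d <- dim(reference$data)
  sp <- reference$spacing
  delta <- if (is.null(cfg$grid_spacing_mm)) 8 * sp else
    rep_len(as.numeric(cfg$grid_spacing_mm), 3L)
  if (any(delta < sp))
    stop("control-point spacing must be at least the voxel spacing",
         call. = FALSE)
  extent <- (d - 1) * sp
  ncp <- mapply(ncp_for_extent, extent, delta)
  fill_m <- min(moving$data)

  accum <- zero_dvf(reference)
  trace <- new.env()
  trace$rows <- list()
  steps_log <- list()
  factors <- 2L^((cfg$levels - 1L):0L)

  gram <- list(x = spline_gram(extent[1], delta[1], ncp[1]),
               y = spline_gram(extent[2], delta[2], ncp[2]),
               z = spline_gram(extent[3], delta[3], ncp[3]))
  volume <- prod(extent)

  make_basis <- function(dl, spl) {
    b <- list(
      Bx = bspline_basis((seq_len(dl[1]) - 1) * spl[1], delta[1], ncp[1]),
      By = bspline_basis((seq_len(dl[2]) - 1) * spl[2], delta[2], ncp[2]),
      Bz = bspline_basis((seq_len(dl[3]) - 1) * spl[3], delta[3], ncp[3]))
    b$gram <- gram
    b$volume <- volume
    # the fold penalty is evaluated on a stride-2 sub-lattice of large grids
    st <- ifelse(dl > 24L, 2L, 1L)
    dix <- lapply(1:3, function(ax) seq(1L, dl[ax], by = st[ax]))
    b$dec <- list(Bx = b$Bx[dix[[1]], , drop = FALSE],
                  By = b$By[dix[[2]], , drop = FALSE],
                  Bz = b$Bz[dix[[3]], , drop = FALSE],
                  spacing = spl * st)
    b
  }

  full_basis <- make_basis(d, sp)

  for (step in seq_len(cfg$n_steps)) {
    moving_cur <- if (step == 1L) moving else
      warp_volume(moving, accum, fill = fill_m)
    theta <- array(0, c(ncp, 3L))
    for (lv in seq_len(cfg$levels)) {
      f <- factors[lv]
      refl <- downsample_volume(reference, f)
      movl <- downsample_volume(moving_cur, f)
      basis <- make_basis(dim(refl$data), refl$spacing)
      env <- make_level_env(refl, movl, cfg)
      theta <- optimize_level(theta, env, basis, cfg, trace, step, lv)
    }
    u_step <- array(0, c(d, 3L))
    for (cc in 1:3)
      u_step[, , , cc] <- tensor3_fw(theta[, , , cc], full_basis$Bx,
                                     full_basis$By, full_basis$Bz)
    step_field <- displacement_field(u_step, sp, reference$origin)
    fold <- check_over_deformation(step_field)
    accept <- fold <= cfg$overdeform_threshold
    steps_log[[step]] <- data.frame(step = step, folded_fraction = fold,
                                    accepted = accept,
                                    max_disp_mm = max(abs(u_step)))
    if (accept) accum <- compose_dvf(step_field, accum)
  }
  attr(accum, "log") <- if (length(trace$rows))
    do.call(rbind, trace$rows) else
    data.frame(step = integer(), level = integer(), iter = integer(),
               cost = numeric(), similarity = numeric(), bending = numeric(),
               jacobian = numeric())
  attr(accum, "steps") <- do.call(rbind, steps_log)
  accum
}
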