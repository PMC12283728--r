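# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# A small, fast phantom used by most unit tests (half-scale grid).
small_phantom <- function() {
  if (is.null(.fixture_env$small_ph))
    .fixture_env$small_ph <- generate_phantom(
      phantom_spec(grid_shape = c(48L, 48L, 24L), diaphragm_amplitude = 12,
                   n_landmarks = 15L, seed = 2L))
  .fixture_env$small_ph
}

# Registration settings scaled for unit tests.
tiny_reg_config <- function(...) {
  reg_config(n_steps = 1L, levels = 2L, max_iterations = 15L,
             similarity = "ssd", bending_weight = 1, jacobian_weight = 0.05,
             ...)
}

desk_reg_config <- function(...) {
  reg_config(n_steps = 2L, levels = 3L, max_iterations = 40L,
             similarity = "ssd", bending_weight = 1, jacobian_weight = 0.05,
             ...)
}

# Smooth synthetic test volume (band-limited noise, HU-like scale).
smooth_volume <- function(dim3 = c(24L, 24L, 16L), spacing = c(2, 2, 3),
                          seed = 11) {
  arr <- withr_seed(seed, array(stats::rnorm(prod(dim3)), dim3))
  sm <- ctviqa:::smooth_gauss3(arr, c(1.5, 1.5, 1))
  ct_volume(sm / stats::sd(sm) * 150 - 700, spacing)
}

# Independent finite-difference + cofactor-expansion oracle for the Jacobian
# map: builds the full 3x3 matrix per voxel and expands the determinant.
jacobian_oracle <- function(dvf) {
  d <- dim(dvf$u)[1:3]
  h <- dvf$spacing
  deriv <- function(a, ax, i, j, k) {
    n <- d[ax]
    pick <- function(off) {
      ii <- c(i, j, k)
      ii[ax] <- ii[ax] + off
      a[ii[1], ii[2], ii[3]]
    }
    pos <- c(i, j, k)[ax]
    if (pos == 1) (pick(1) - pick(0)) / h[ax]
    else if (pos == n) (pick(0) - pick(-1)) / h[ax]
    else (pick(1) - pick(-1)) / (2 * h[ax])
  }
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    m <- diag(3)
    for (cc in 1:3) for (ax in 1:3)
      m[cc, ax] <- m[cc, ax] + deriv(dvf$u[, , , cc], ax, i, j, k)
    out[i, j, k] <-
      m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
      m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
      m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
  }
  out
}

# local seed helper independent of package internals
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
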