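test_that("warping with the zero field returns the input exactly", {
  vol <- smooth_volume()
  out <- warp_volume(vol, zero_dvf(vol))
  expect_identical(out$data, vol$data)
})

test_that("integer-voxel translation moves an impulse exactly", {
  d <- c(12L, 12L, 10L)
  arr <- array(0, d)
  arr[6, 7, 5] <- 1000
  vol <- ct_volume(arr, c(2, 2, 3))
  dvf <- zero_dvf(vol)
  dvf$u[, , , 1] <- 2 * 2   # +2 voxels in x (pull-back: sample from x+4mm)
  dvf$u[, , , 3] <- -1 * 3  # -1 voxel in z
  out <- warp_volume(vol, dvf, fill = 0)
  expect_equal(out$data[4, 7, 6], 1000)
  expect_equal(sum(out$data != 0), 1L)
})

test_that("warping a smooth analytic image matches the analytic composition", {
  d <- c(24L, 24L, 16L)
  sp <- c(2, 2, 3)
  f <- function(x, y, z) sin(x / 17) * cos(y / 13) + sin(z / 11)
  g <- ctviqa:::grid_coords(d, sp)
  vol <- ct_volume(array(f(g$x, g$y, g$z), d), sp)
  ux <- 3 * sin(g$y / 29)
  uz <- 2 * cos(g$x / 31)
  dvf <- displacement_field(array(c(ux, 0 * ux, uz), c(d, 3L)), sp)
  out <- warp_volume(vol, dvf, fill = NA)
  expected <- f(g$x + ux, g$y, g$z + uz)
  interior <- array(FALSE, d)
  interior[3:22, 3:22, 3:14] <- TRUE
  err <- abs(out$data - expected)[interior & !is.na(out$data)]
  # trilinear interpolation error bound ~ h^2 * max|f''| / 8
  expect_lt(max(err), 2^2 * (1 / 11^2) / 2)
})

test_that("field composition has an identity element and adds translations", {
  vol <- smooth_volume()
  z <- zero_dvf(vol)
  u <- z
  u$u[, , , 1] <- 1.5
  u$u[, , , 2] <- -2
  expect_equal(compose_dvf(u, z)$u, u$u)
  expect_equal(compose_dvf(z, u)$u, u$u)
  v <- z
  v$u[, , , 1] <- 0.5
  v$u[, , , 3] <- 3
  w <- compose_dvf(u, v)
  expect_equal(w$u[5, 5, 5, ], c(2, -2, 3))
})

test_that("warping with a composed field matches sequential warping", {
  vol <- smooth_volume(seed = 21)
  d <- dim(vol$data)
  mk <- function(seed, scale) {
    arr <- withr_seed(seed, array(rnorm(prod(d) * 3), c(d, 3L)))
    for (k in 1:3) arr[, , , k] <- ctviqa:::smooth_gauss3(arr[, , , k],
                                                         c(3, 3, 2)) * scale
    displacement_field(arr, vol$spacing)
  }
  u1 <- mk(31, 15)
  u2 <- mk(32, 15)
  once <- warp_volume(vol, compose_dvf(u1, u2))
  twice <- warp_volume(warp_volume(vol, u2), u1)
  interior <- array(FALSE, d)
  interior[4:(d[1] - 3), 4:(d[2] - 3), 3:(d[3] - 2)] <- TRUE
  err <- abs(once$data - twice$data)[interior]
  # double interpolation differs from single by O(h^2); generous HU bound
  expect_lt(stats::median(err), 5)
  expect_lt(mean(err), 10)
})

test_that("numerical field inversion satisfies the inverse identity", {
  ph <- small_phantom()
  inv <- ctviqa:::invert_dvf(ph$true_dvf)
  comp <- compose_dvf(ph$true_dvf, inv)
  mag <- sqrt(comp$u[, , , 1]^2 + comp$u[, , , 2]^2 + comp$u[, , , 3]^2)
  expect_lt(stats::median(mag[ph$foam_mask]), 0.05)
})

test_that("grid mismatches are rejected", {
  a <- smooth_volume(c(10L, 10L, 8L))
  b <- smooth_volume(c(12L, 10L, 8L))
  expect_error(warp_volume(a, zero_dvf(b)), "grid")
  expect_error(compose_dvf(zero_dvf(a), zero_dvf(b)), "grid")
})
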