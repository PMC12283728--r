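test_that("the zero field maps to the expansion/contraction boundary J = 1", {
  z <- displacement_field(array(0, c(9L, 9L, 9L, 3L)), c(0.78, 0.78, 3))
  expect_true(all(jacobian_map(z)$values == 1))
})

test_that("isotropic linear scaling has the closed-form determinant", {
  d <- c(11L, 11L, 9L)
  sp <- c(1, 2, 1.5)
  g <- ctviqa:::grid_coords(d, sp)
  a <- 0.07
  dvf <- displacement_field(array(c(a * g$x, a * g$y, a * g$z), c(d, 3L)), sp)
  jac <- jacobian_map(dvf)$values
  expect_equal(max(abs(jac - (1 + a)^3)), 0, tolerance = 1e-12)
})

test_that("the Jacobian map matches the per-voxel cofactor oracle", {
  d <- c(9L, 9L, 9L)
  arr <- withr_seed(19, array(stats::rnorm(prod(d) * 3), c(d, 3L)))
  for (cc in 1:3) arr[, , , cc] <- ctviqa:::smooth_gauss3(arr[, , , cc],
                                                          1) * 2
  dvf <- displacement_field(arr, c(1.1, 0.9, 1.3))
  expect_lt(max(abs(jacobian_map(dvf)$values - jacobian_oracle(dvf))), 1e-9)
})

test_that("the Jacobian map is invariant under constant field offsets", {
  d <- c(9L, 9L, 9L)
  arr <- withr_seed(20, array(stats::rnorm(prod(d) * 3), c(d, 3L)))
  for (cc in 1:3) arr[, , , cc] <- ctviqa:::smooth_gauss3(arr[, , , cc], 1)
  a <- displacement_field(arr, c(1, 1, 1))
  b <- a
  b$u[, , , 1] <- b$u[, , , 1] + 12
  b$u[, , , 3] <- b$u[, , , 3] - 4
  expect_equal(jacobian_map(a)$values, jacobian_map(b)$values)
})

test_that("non-finite fields are rejected with a located error", {
  u <- array(0, c(8L, 8L, 8L, 3L))
  u[3, 4, 5, 2] <- NaN
  expect_error(jacobian_map(displacement_field(u, c(1, 1, 1))),
               "\\(3, 4, 5\\)")
})

test_that("tertile thresholds evenly divide the reference range", {
  mk <- function(vals) {
    n <- length(vals)
    structure(list(values = array(vals, c(n, 1L, 1L)),
                   mask = array(TRUE, c(n, 1L, 1L)),
                   spacing = c(1, 1, 1), origin = c(0, 0, 0)),
              class = "ctvi_map")
  }
  expect_equal(tertile_thresholds(mk(seq(0.8, 1.4, length.out = 13))),
               c(1.0, 1.2))
  expect_equal(tertile_thresholds(mk(c(0, 1.7, 3))), c(1, 2))
  expect_error(tertile_thresholds(mk(rep(1, 5))), "degenerate")
  # recompute from printed extrema of a phantom reference map
  ph <- small_phantom()
  th <- tertile_thresholds(ph$true_ventilation)
  v <- ph$true_ventilation$values[ph$true_ventilation$mask]
  expect_equal(th, min(v) + diff(range(v)) * c(1, 2) / 3)
})

test_that("classification follows the documented boundary conventions", {
  vals <- array(c(0.5, 1.0, 1.1, 1.2, 1.9), c(5L, 1L, 1L))
  vmap <- structure(list(values = vals, mask = array(TRUE, c(5L, 1L, 1L)),
                         spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                    class = "ctvi_map")
  cm <- classify_ventilation(vmap, c(1.0, 1.2))
  expect_equal(as.vector(cm$labels), c(1L, 2L, 2L, 3L, 3L))
  # all below t1
  cm2 <- classify_ventilation(vmap, c(5, 6))
  expect_true(all(cm2$labels == 1L))
  # masked-out voxels stay outside
  vmap$mask[1, 1, 1] <- FALSE
  cm3 <- classify_ventilation(vmap, c(1.0, 1.2))
  expect_equal(cm3$labels[1, 1, 1], 0L)
  # exhaustive: every masked voxel gets exactly one category
  expect_true(all(cm3$labels[vmap$mask] %in% 1:3))
})

test_that("a uniform reference classifies into exact thirds", {
  n <- 300L
  vals <- (seq_len(n) - 0.5) / n
  vmap <- structure(list(values = array(sample(vals), c(n, 1L, 1L)),
                         mask = array(TRUE, c(n, 1L, 1L)),
                         spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                    class = "ctvi_map")
  cm <- classify_ventilation(vmap, tertile_thresholds(vmap))
  counts <- tabulate(cm$labels[vmap$mask], 3L)
  expect_equal(counts, rep(n / 3, 3L))
})

test_that("the HU-threshold foam mask is a faithful conservative foam region", {
  ph <- small_phantom()
  m <- foam_mask_from_image(ph$exhale)
  # no false positives: the recovered mask stays inside the true foam
  expect_equal(sum(m & !ph$foam_mask), 0L)
  # and covers most of it (the one-voxel safety erosion trims the shell)
  expect_gt(sum(m & ph$foam_mask) / sum(ph$foam_mask), 0.75)
})
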