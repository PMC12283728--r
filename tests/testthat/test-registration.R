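test_that("NMI behaves like an information measure", {
  vol <- smooth_volume(c(24L, 24L, 16L), seed = 14)
  expect_equal(nmi(vol, vol, 32L), 2, tolerance = 1e-9)
  indep <- withr_seed(15, array(stats::runif(40^3), c(40L, 40L, 40L)))
  indep2 <- withr_seed(16, array(stats::runif(40^3), c(40L, 40L, 40L)))
  expect_lt(abs(nmi(indep, indep2, 16L) - 1), 0.02)
  shuffled <- array(withr_seed(17, sample(vol$data)), dim(vol$data))
  expect_lte(nmi(vol, shuffled, 32L), nmi(vol, vol, 32L))
  expect_warning(v <- nmi(array(1, c(8L, 8L, 8L)), indep[1:8, 1:8, 1:8]),
                 "constant")
  expect_equal(v, 2)
})

test_that("bending energy vanishes for affine fields and scales quadratically", {
  d <- c(14L, 14L, 10L)
  sp <- c(2, 2, 3)
  g <- ctviqa:::grid_coords(d, sp)
  aff <- displacement_field(array(c(0.2 * g$x + 0.1 * g$y + 3,
                                    0.3 * g$z - 1,
                                    0.05 * g$x + 0.02 * g$y), c(d, 3L)), sp)
  expect_lt(bending_energy(aff), 1e-20)
  trans <- zero_dvf(ct_volume(array(0, d), sp))
  trans$u[, , , 2] <- 7
  expect_equal(bending_energy(trans), 0)
  s1 <- displacement_field(array(c(sin(g$x / 3), 0 * g$x, 0 * g$x),
                                 c(d, 3L)), sp)
  s2 <- s1
  s2$u <- 3 * s1$u
  expect_equal(bending_energy(s2) / bending_energy(s1), 9, tolerance = 1e-9)
})

test_that("the fold detector counts exactly the folded voxels", {
  d <- c(10L, 10L, 10L)
  sp <- c(2, 2, 3)
  z <- displacement_field(array(0, c(d, 3L)), sp)
  expect_equal(check_over_deformation(z), 0)
  g <- ctviqa:::grid_coords(d, sp)
  scl <- displacement_field(array(c(0.3 * g$x, 0.3 * g$y, 0.3 * g$z),
                                  c(d, 3L)), sp)
  expect_equal(check_over_deformation(scl), 0)
  # a single spike next to the z face folds exactly the face voxel below it:
  # the one-sided derivative at k = 1 is (u[2] - u[1]) / h < -1
  spike <- z
  spike$u[5, 5, 2, 3] <- -10
  expect_equal(check_over_deformation(spike), 1 / prod(d))
})

test_that("registering an image to itself returns a negligible field", {
  ph <- small_phantom()
  dvf <- register_ffd(ph$exhale, ph$exhale, tiny_reg_config())
  expect_lt(max(abs(dvf$u)), 0.1 * min(ph$spec$spacing))
})

test_that("a known translation is recovered to sub-voxel accuracy", {
  ph <- small_phantom()
  tr <- zero_dvf(ph$exhale)
  tr$u[, , , 3] <- 6  # pull-back +6 mm: content appears shifted toward -z
  moved <- warp_volume(ph$exhale, tr, fill = -1000)
  dvf <- register_ffd(ph$exhale, moved, desk_reg_config())
  sp <- ph$exhale$spacing
  # registering exhale onto its +6 mm pull-back warp must recover the
  # inverse transformation, a uniform -6 mm axial field
  err_vox <- sqrt((dvf$u[, , , 1] / sp[1])^2 + (dvf$u[, , , 2] / sp[2])^2 +
                    ((dvf$u[, , , 3] + 6) / sp[3])^2)
  expect_lt(stats::median(err_vox[ph$foam_mask]), 0.5)
})

test_that("registration reduces landmark error on the phantom", {
  ph <- small_phantom()
  dvf <- register_ffd(ph$exhale, ph$inhale, desk_reg_config())
  tre <- target_registration_error(ph$landmarks_exhale, ph$landmarks_inhale,
                                   dvf)
  disp <- landmark_displacement(ph$landmarks_exhale, ph$landmarks_inhale)
  expect_lt(tre$mean, disp$mean)
  expect_true(tre$within_3mm_tolerance)
  # the returned field is not over-deformed
  expect_lte(check_over_deformation(dvf), 0.001)
  # cost decreases monotonically within every optimized level
  trace <- attr(dvf, "log")
  for (grp in split(trace, interaction(trace$step, trace$level, drop = TRUE)))
    expect_true(all(diff(grp$cost) <= 1e-12))
})

test_that("registration rejects mismatched or invalid inputs", {
  a <- smooth_volume(c(16L, 16L, 8L))
  b <- smooth_volume(c(16L, 16L, 10L))
  expect_error(register_ffd(a, b, tiny_reg_config()), "grid")
  expect_error(reg_config(n_steps = 0), "n_steps")
  expect_error(reg_config(bending_weight = -1), "weights")
})
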