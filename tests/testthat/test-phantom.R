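test_that("zero diaphragm amplitude gives a static identity pair", {
  spec <- phantom_spec(grid_shape = c(32L, 32L, 16L), diaphragm_amplitude = 0,
                       n_landmarks = 5L, seed = 4L)
  ph <- generate_phantom(spec)
  expect_identical(ph$inhale$data, ph$exhale$data)
  expect_true(all(ph$true_dvf$u == 0))
  expect_true(all(abs(ph$true_ventilation$values[ph$foam_mask] - 1) < 1e-12))
  expect_equal(ctviqa:::lm_matrix(ph$landmarks_inhale),
               ctviqa:::lm_matrix(ph$landmarks_exhale))
})

test_that("phantom generation is deterministic in the spec seed", {
  spec <- phantom_spec(grid_shape = c(32L, 32L, 16L), n_landmarks = 5L,
                       diaphragm_amplitude = 8, seed = 9L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$exhale$data, b$exhale$data)
  expect_identical(a$inhale$data, b$inhale$data)
  expect_identical(a$landmarks_exhale, b$landmarks_exhale)
  c_ <- generate_phantom(phantom_spec(grid_shape = c(32L, 32L, 16L),
                                      n_landmarks = 5L,
                                      diaphragm_amplitude = 8, seed = 10L))
  expect_false(identical(a$exhale$data, c_$exhale$data))
})

test_that("the analytic field is fold-free and zero at the cylinder wall", {
  ph <- small_phantom()
  jac <- jacobian_map(ph$true_dvf)
  expect_true(all(jac$values > 0))
  # displacement vanishes at and outside the wall radius
  geo <- ctviqa:::phantom_geometry(ph$spec)
  g <- ctviqa:::grid_coords(ph$spec$grid_shape, ph$spec$spacing)
  r <- sqrt((g$x - geo$cx)^2 + (g$y - geo$cy)^2)
  mag <- sqrt(ph$true_dvf$u[, , , 1]^2 + ph$true_dvf$u[, , , 2]^2 +
                ph$true_dvf$u[, , , 3]^2)
  expect_true(all(mag[r >= geo$r_outer] < 1e-9))
})

test_that("landmark pairs are consistent with the true field", {
  ph <- small_phantom()
  lm <- ph$landmarks_exhale
  s <- ctviqa:::sample_dvf(ph$true_dvf, lm$x_mm, lm$y_mm, lm$z_mm)
  pred <- cbind(lm$x_mm + s$ux, lm$y_mm + s$uy, lm$z_mm + s$uz)
  err <- sqrt(rowSums((pred - ctviqa:::lm_matrix(ph$landmarks_inhale))^2))
  expect_lt(max(err), 0.5 * min(ph$spec$spacing))
})

test_that("mean landmark displacement matches the analytic-field oracle", {
  ph <- small_phantom()
  disp <- landmark_displacement(ph$landmarks_exhale, ph$landmarks_inhale)
  lm <- ph$landmarks_exhale
  oracle <- ctviqa:::analytic_dvf_at(ph$spec, lm$x_mm, lm$y_mm, lm$z_mm)
  oracle_mean <- mean(sqrt(oracle$ux^2 + oracle$uy^2 + oracle$uz^2))
  expect_lt(abs(disp$mean - oracle_mean) / oracle_mean, 0.2)
})

test_that("the default phantom reproduces the study's breathing magnitude", {
  ph <- generate_phantom(phantom_spec(seed = 0L))
  disp <- landmark_displacement(ph$landmarks_exhale, ph$landmarks_inhale)
  expect_lt(abs(disp$mean - 14.59) / 14.59, 0.2)
  expect_equal(nrow(ph$landmarks_exhale), 25L)
})

test_that("mean Jacobian over the foam matches the deformed volume ratio", {
  ph <- small_phantom()
  mean_j <- mean(ph$true_ventilation$values[ph$foam_mask])
  # independent volume measurement: carry the foam indicator into inhale
  # space the same way the inhale image is synthesized, then count
  inv <- ctviqa:::invert_dvf(ph$true_dvf)
  ind <- ct_volume(ph$foam_mask + 0, ph$spec$spacing)
  moved <- warp_volume(ind, inv, fill = 0)
  ratio <- sum(moved$data) / sum(ph$foam_mask)
  expect_lt(abs(mean_j - ratio) / ratio, 0.02)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(grid_shape = c(4, 96, 48)), ">= 8")
  expect_error(phantom_spec(spacing = c(0, 1, 1)), "positive")
  expect_error(phantom_spec(diaphragm_amplitude = -1), ">= 0")
  expect_error(phantom_spec(n_landmarks = 0), ">= 1")
})
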