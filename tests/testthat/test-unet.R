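tiny_spec <- function() unet_spec(depth = 2L, base_filters = 4L,
                                  input_size = 32L)

tiny_slices <- function(n = 16L, side = 32L, seed = 6L) {
  vol <- smooth_volume(c(side, side, n), seed = seed)
  lapply(seq_len(n), function(k) vol$data[, , k])
}

test_that("the network maps a slice to a slice of the same size", {
  m <- build_unet(tiny_spec(), seed = 1L)
  for (side in c(32L, 64L)) {
    x <- matrix(rnorm(side * side), side)
    y <- ctviqa:::unet_fw(m$params, x)$y
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  # full-scale spec accepts its stated slice size (forward only, small model)
  big <- build_unet(unet_spec(depth = 3L, base_filters = 1L,
                              input_size = 512L), seed = 1L)
  x <- matrix(0, 512L, 512L)
  expect_identical(dim(ctviqa:::unet_fw(big$params, x)$y), c(512L, 512L))
})

test_that("spec invariants are enforced", {
  expect_error(unet_spec(depth = 3L, input_size = 100L), "divisible")
  expect_error(unet_spec(depth = 0L), "depth")
  m <- build_unet(tiny_spec(), seed = 1L)
  bad <- ct_volume(array(0, c(30L, 30L, 4L)), c(1, 1, 1))
  expect_error(denoise_cnn(m, bad), "divisible")
})

test_that("an untrained model is the identity (zero-initialized head)", {
  m <- build_unet(tiny_spec(), seed = 2L)
  vol <- smooth_volume(c(32L, 32L, 4L))
  out <- denoise_cnn(m, vol)
  expect_equal(out$data, vol$data)
  expect_equal(out$spacing, vol$spacing)
})

test_that("seeded initialization and training are deterministic", {
  s <- tiny_spec()
  m1 <- build_unet(s, seed = 5L)
  m2 <- build_unet(s, seed = 5L)
  expect_identical(m1$params, m2$params)
  cfg <- train_config(max_epochs = 1L, batch_size = 4L,
                      val_slices_per_sigma = 2L, seed = 5L)
  sl <- tiny_slices(8L)
  t1 <- train_denoiser(sl, cfg, s)
  t2 <- train_denoiser(sl, cfg, s)
  expect_identical(t1$history, t2$history)
})

test_that("the recorded validation loss is reproducible bookkeeping", {
  s <- tiny_spec()
  cfg <- train_config(max_epochs = 1L, batch_size = 4L,
                      val_slices_per_sigma = 2L, seed = 7L)
  m <- train_denoiser(tiny_slices(8L), cfg, s)
  expect_equal(m$best_val_loss, validation_loss(m, tiny_slices(8L), cfg))
  expect_equal(m$best_val_loss, min(m$history$val_l1))
  expect_equal(m$history$val_l1[m$best_epoch], m$best_val_loss)
})

test_that("training configuration invariants are enforced", {
  expect_error(train_config(train_sigmas = c(10, 40)), "disjoint")
  expect_error(train_config(val_sigmas = c(30)), "disjoint")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_denoiser(list(), train_config(max_epochs = 1L),
                              tiny_spec()),
               "empty")
})

test_that("a short training run denoises better than doing nothing", {
  s <- tiny_spec()
  cfg <- train_config(max_epochs = 25L, batch_size = 8L,
                      learning_rate = 2e-3, val_slices_per_sigma = 3L,
                      seed = 3L)
  sl <- tiny_slices(24L, seed = 8L)
  m <- train_denoiser(sl, cfg, s)
  # per-sigma comparison on the validation noise levels
  for (sigma in cfg$val_sigmas) {
    loss_model <- 0
    loss_identity <- 0
    for (i in seq_along(sl)) {
      noisy <- sl[[i]] + withr_seed(1000 + i,
                                    matrix(stats::rnorm(length(sl[[i]]),
                                                        sd = sigma), 32L))
      pred <- ctviqa:::unet_fw(m$params, noisy)$y
      loss_model <- loss_model + l1_loss(pred, sl[[i]])
      loss_identity <- loss_identity + l1_loss(noisy, sl[[i]])
    }
    expect_lt(loss_model, loss_identity)
  }
  # and on a held-out test sigma applied to a volume
  vol <- smooth_volume(c(32L, 32L, 8L), seed = 12)
  noisy <- add_gaussian_noise(vol, 150, seed = 13)
  den <- denoise_cnn(m, noisy)
  rmse <- function(a, b) sqrt(mean((a$data - b$data)^2))
  expect_lt(rmse(den, vol), rmse(noisy, vol))
})
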