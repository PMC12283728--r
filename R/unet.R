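#' U-Net denoiser architecture specification
#'
#' Describes the 2-D U-Net used for CT denoising: `depth` down/up-sampling
#' levels, `base_filters` channels at the first level doubling per level, one
#' input channel (a noisy axial slice, raw HU, no normalization) and one
#' output channel (the denoised slice). The full-scale configuration is depth
#' 3 with 32 initial filters on 512 x 512 slices; the desk-scale profile used
#' throughout the tests is depth 3 with 8 filters on 96 x 96 slices.
#'
#' @param depth number of pooling levels (>= 1).
#' @param base_filters channels at the first level (>= 1).
#' @param input_size slice side length in pixels; must be divisible by
#'   `2^depth`.
#' @return A validated list of class `unet_spec`.
#' @export
unet_spec <- function(depth = 3L, base_filters = 32L, input_size = 512L) {
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  input_size <- as.integer(input_size)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (base_filters < 1L) stop("base_filters must be >= 1", call. = FALSE)
  if (input_size %% (2L^depth) != 0L)
    stop(sprintf("input_size (%d) must be divisible by 2^depth (%d)",
                 input_size, 2L^depth), call. = FALSE)
  structure(list(depth = depth, base_filters = base_filters,
                 input_size = input_size),
            class = "unet_spec")
}

#' Training configuration for the denoiser
#'
#' Noise curriculum and optimizer settings. The three sigma lists are pairwise
#' disjoint so that tested noise levels (30/80/150 HU) are never seen in
#' training or model selection. Fresh noise is drawn every epoch at a sigma
#' sampled uniformly from `train_sigmas`; validation noise is a fixed seeded
#' realization at the `val_sigmas`; the checkpoint with minimum validation L1
#' loss is returned.
#'
#' @param train_sigmas training noise SDs in HU.
#' @param val_sigmas validation noise SDs in HU (model selection).
#' @param test_sigmas held-out noise SDs in HU (reporting only).
#' @param batch_size slices per optimizer step.
#' @param max_epochs training epochs (the full-scale study value is 500; desk
#'   runs use far fewer).
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param crop_size optional side length of random square crops used as
#'   training inputs (must be divisible by `2^depth`); `NULL` trains on full
#'   slices. Cropping reduces per-step cost so short schedules see more
#'   optimizer steps.
#' @param val_slices_per_sigma validation slices sampled per sigma (caps the
#'   per-epoch validation cost).
#' @param seed integer seed controlling init, shuffling and all noise draws.
#' @return A validated list of class `train_config`.
#' @export
train_config <- function(train_sigmas = c(10, 20, 50, 60, 70, 100, 110, 120,
                                          130, 140, 170, 180, 190, 200),
                         val_sigmas = c(40, 90, 160),
                         test_sigmas = c(30, 80, 150),
                         batch_size = 8L,
                         max_epochs = 500L,
                         optimizer = "adam",
                         learning_rate = 1e-3,
                         crop_size = NULL,
                         val_slices_per_sigma = 8L,
                         seed = 0L) {
  if (length(intersect(train_sigmas, val_sigmas)) ||
      length(intersect(train_sigmas, test_sigmas)) ||
      length(intersect(val_sigmas, test_sigmas)))
    stop("train/val/test sigma lists must be pairwise disjoint", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (max_epochs < 1L) stop("max_epochs must be >= 1", call. = FALSE)
  if (!identical(optimizer, "adam"))
    stop("only the adam optimizer is implemented", call. = FALSE)
  structure(list(train_sigmas = train_sigmas, val_sigmas = val_sigmas,
                 test_sigmas = test_sigmas, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), optimizer = optimizer,
                 learning_rate = learning_rate,
                 crop_size = if (is.null(crop_size)) NULL else
                   as.integer(crop_size),
                 val_slices_per_sigma = as.integer(val_slices_per_sigma),
                 seed = as.integer(seed)),
            class = "train_config")
}

## ---- low-level layers (single image, channels-last (H, W, C)) ----

shift2z <- function(x, dx, dy) {
  d <- dim(x)
  out <- array(0, d)
  xi <- seq_len(d[1]) + dx
  yi <- seq_len(d[2]) + dy
  kx <- xi >= 1L & xi <= d[1]
  ky <- yi >= 1L & yi <= d[2]
  if (any(kx) && any(ky))
    out[kx, ky, ] <- x[xi[kx], yi[ky], , drop = FALSE]
  out
}

# im2col: stack the 9 shifted copies of (H, W, Cin) into (H*W, 9*Cin) so a
# 3x3 convolution is one GEMM.
im2col3 <- function(x) {
  d <- dim(x); npx <- d[1] * d[2]
  cols <- vector("list", 9L)
  k <- 1L
  for (dy in -1:1) for (dx in -1:1) {
    cols[[k]] <- matrix(shift2z(x, dx, dy), npx, d[3])
    k <- k + 1L
  }
  do.call(cbind, cols)
}

# weight array (9, Cin, Cout) viewed as (9*Cin, Cout) matching im2col order
wmat3 <- function(W) {
  dW <- dim(W)
  matrix(aperm(W, c(2, 1, 3)), dW[1] * dW[2], dW[3])
}

conv3_fw <- function(x, p, s = NULL) {
  d <- dim(x); cout <- length(p$b)
  if (is.null(s)) s <- im2col3(x)
  acc <- s %*% wmat3(p$W)
  acc <- acc + matrix(p$b, nrow(acc), cout, byrow = TRUE)
  array(acc, c(d[1], d[2], cout))
}

conv3_bw <- function(dy_, d, p, s) {
  npx <- d[1] * d[2]; cin <- d[3]; cout <- length(p$b)
  dm <- matrix(dy_, npx, cout)
  dWm <- crossprod(s, dm)                       # (9*Cin, Cout)
  dW <- aperm(array(dWm, c(cin, 9L, cout)), c(2, 1, 3))
  gcols <- dm %*% t(wmat3(p$W))                 # (npx, 9*Cin)
  dx_ <- array(0, d)
  k <- 1L
  for (dyo in -1:1) for (dxo in -1:1) {
    g <- array(gcols[, ((k - 1L) * cin + 1L):(k * cin)], c(d[1], d[2], cin))
    dx_ <- dx_ + shift2z(g, -dxo, -dyo)
    k <- k + 1L
  }
  list(dx = dx_, dW = dW, db = colSums(dm))
}

conv1_fw <- function(x, p) {
  d <- dim(x); npx <- d[1] * d[2]
  y <- matrix(x, npx, d[3]) %*% p$W
  y <- sweep(y, 2L, p$b, `+`)
  array(y, c(d[1], d[2], ncol(p$W)))
}

conv1_bw <- function(dy_, x, p) {
  d <- dim(x); npx <- d[1] * d[2]
  dm <- matrix(dy_, npx, ncol(p$W))
  xm <- matrix(x, npx, d[3])
  list(dx = array(dm %*% t(p$W), d), dW = crossprod(xm, dm),
       db = colSums(dm))
}

pool2_fw <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  q1 <- x[i1, j1, , drop = FALSE]; q2 <- x[i1 + 1L, j1, , drop = FALSE]
  q3 <- x[i1, j1 + 1L, , drop = FALSE]; q4 <- x[i1 + 1L, j1 + 1L, , drop = FALSE]
  y <- pmax(q1, q2, q3, q4)
  m1 <- q1 == y
  m2 <- (q2 == y) & !m1
  m3 <- (q3 == y) & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(y = y, masks = list(m1, m2, m3, m4), dim_in = d)
}

pool2_bw <- function(dy_, cache) {
  d <- cache$dim_in
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dx_ <- array(0, d)
  dx_[i1, j1, ] <- dy_ * cache$masks[[1]]
  dx_[i1 + 1L, j1, ] <- dy_ * cache$masks[[2]]
  dx_[i1, j1 + 1L, ] <- dy_ * cache$masks[[3]]
  dx_[i1 + 1L, j1 + 1L, ] <- dy_ * cache$masks[[4]]
  dx_
}

up2_fw <- function(x) {
  d <- dim(x)
  out <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  i1 <- seq(1L, 2L * d[1], 2L); j1 <- seq(1L, 2L * d[2], 2L)
  out[i1, j1, ] <- x; out[i1 + 1L, j1, ] <- x
  out[i1, j1 + 1L, ] <- x; out[i1 + 1L, j1 + 1L, ] <- x
  out
}

up2_bw <- function(dy_) {
  d <- dim(dy_)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dy_[i1, j1, , drop = FALSE] + dy_[i1 + 1L, j1, , drop = FALSE] +
    dy_[i1, j1 + 1L, , drop = FALSE] + dy_[i1 + 1L, j1 + 1L, , drop = FALSE]
}

## ---- parameter plumbing ----

init_conv3 <- function(cin, cout) {
  sd <- sqrt(2 / (9 * cin))
  list(W = array(stats::rnorm(9 * cin * cout, sd = sd), c(9L, cin, cout)),
       b = numeric(cout))
}

init_conv1 <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  list(W = matrix(stats::rnorm(cin * cout, sd = sd), cin, cout),
       b = numeric(cout))
}

params_map <- function(p, f) {
  if (is.list(p) && !is.null(p$W)) return(list(W = f(p$W), b = f(p$b)))
  lapply(p, params_map, f = f)
}

params_map2 <- function(p, q, f) {
  if (is.list(p) && !is.null(p$W))
    return(list(W = f(p$W, q$W), b = f(p$b, q$b)))
  mapply(params_map2, p, q, MoreArgs = list(f = f), SIMPLIFY = FALSE)
}

#' Build an untrained U-Net denoiser
#'
#' Constructs the encoder-decoder network: per level, two 3 x 3
#' convolution + ReLU blocks; 2 x 2 max pooling between encoder levels;
#' nearest-neighbour upsampling and channel concatenation with the matching
#' encoder output (skip connection) in the decoder; a final 1 x 1 convolution
#' to one channel added to the input slice (global residual connection, so
#' the network learns the noise correction). Weights use He initialization
#' from the seeded generator.
#'
#' @param spec a [unet_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `unet_denoiser`.
#' @export
build_unet <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "unet_spec"))
  with_local_seed(derive_seed(seed, "unet-init"), {
    dpt <- spec$depth; f <- spec$base_filters
    enc <- vector("list", dpt)
    cin <- 1L
    for (l in seq_len(dpt)) {
      cl <- f * 2L^(l - 1L)
      enc[[l]] <- list(a = init_conv3(cin, cl), b = init_conv3(cl, cl))
      cin <- cl
    }
    cb <- f * 2L^dpt
    bott <- list(a = init_conv3(cin, cb), b = init_conv3(cb, cb))
    dec <- vector("list", dpt)
    prev <- cb
    for (l in rev(seq_len(dpt))) {
      cl <- f * 2L^(l - 1L)
      dec[[l]] <- list(a = init_conv3(prev + cl, cl), b = init_conv3(cl, cl))
      prev <- cl
    }
    # zero-initialized head: the residual correction starts at exactly zero,
    # so the untrained model is the identity and training moves away from it
    # monotonically instead of first unlearning a random correction
    final <- list(W = matrix(0, f, 1L), b = numeric(1L))
    structure(list(spec = spec,
                   params = list(enc = enc, bott = bott, dec = dec,
                                 final = final),
                   trained = FALSE, history = NULL),
              class = "unet_denoiser")
  })
}

#' @export
print.unet_denoiser <- function(x, ...) {
  n <- sum(unlist(params_map(x$params, length)))
  cat(sprintf("<unet_denoiser> depth %d, base filters %d, %s parameters%s\n",
              x$spec$depth, x$spec$base_filters, format(n, big.mark = ","),
              if (isTRUE(x$trained))
                sprintf(", best val L1 %.3f HU (epoch %d)",
                        x$best_val_loss, x$best_epoch) else " (untrained)"))
  invisible(x)
}

relu_fw <- function(z) list(y = pmax(z, 0), mask = z > 0)

# One conv3+ReLU block; caches hold the im2col matrix, input dims and the
# ReLU mask needed for the backward pass.
cblock_fw <- function(x, p, keep) {
  s <- im2col3(x)
  z <- conv3_fw(x, p, s = s)
  r <- relu_fw(z)
  list(y = r$y,
       cache = if (keep) list(s = s, d = dim(x), mask = r$mask) else NULL)
}

cblock_bw <- function(dh, p, cache) {
  g <- conv3_bw(dh * cache$mask, cache$d, p, cache$s)
  list(dx = g$dx, g = list(W = g$dW, b = g$db))
}

# Full forward pass on one slice (matrix); optionally keep caches.
unet_fw <- function(params, slice, keep = FALSE) {
  dpt <- length(params$enc)
  h <- array(slice, c(dim(slice), 1L))
  x_in <- h
  cache <- if (keep) list(enc = vector("list", dpt), pool = vector("list", dpt),
                          dec = vector("list", dpt)) else NULL
  skips <- vector("list", dpt)
  for (l in seq_len(dpt)) {
    ba <- cblock_fw(h, params$enc[[l]]$a, keep)
    bb <- cblock_fw(ba$y, params$enc[[l]]$b, keep)
    skips[[l]] <- bb$y
    pl <- pool2_fw(bb$y)
    h <- pl$y
    if (keep) {
      cache$enc[[l]] <- list(a = ba$cache, b = bb$cache)
      cache$pool[[l]] <- pl
    }
  }
  ba <- cblock_fw(h, params$bott$a, keep)
  bb <- cblock_fw(ba$y, params$bott$b, keep)
  h <- bb$y
  if (keep) cache$bott <- list(a = ba$cache, b = bb$cache)
  for (l in rev(seq_len(dpt))) {
    hu <- up2_fw(h)
    nup <- dim(hu)[3]
    xcat <- array(c(hu, skips[[l]]), c(dim(hu)[1:2], nup + dim(skips[[l]])[3]))
    ba <- cblock_fw(xcat, params$dec[[l]]$a, keep)
    bb <- cblock_fw(ba$y, params$dec[[l]]$b, keep)
    h <- bb$y
    if (keep) cache$dec[[l]] <- list(a = ba$cache, b = bb$cache, nup = nup)
  }
  out <- conv1_fw(h, params$final)
  y <- x_in + out
  if (keep) cache$final_x <- h
  list(y = y[, , 1L], cache = cache)
}

# Backward pass; dy is dLoss/dOutput (matrix). Returns gradient structure.
unet_bw <- function(params, cache, dy) {
  dpt <- length(params$enc)
  dy3 <- array(dy, c(dim(dy), 1L))
  gfinal <- conv1_bw(dy3, cache$final_x, params$final)
  dh <- gfinal$dx
  gdec <- vector("list", dpt)
  skip_grad <- vector("list", dpt)
  for (l in seq_len(dpt)) {
    cc <- cache$dec[[l]]
    gb <- cblock_bw(dh, params$dec[[l]]$b, cc$b)
    ga <- cblock_bw(gb$dx, params$dec[[l]]$a, cc$a)
    gdec[[l]] <- list(a = ga$g, b = gb$g)
    nup <- cc$nup
    skip_grad[[l]] <- ga$dx[, , (nup + 1L):dim(ga$dx)[3], drop = FALSE]
    dh <- up2_bw(ga$dx[, , seq_len(nup), drop = FALSE])
  }
  gb <- cblock_bw(dh, params$bott$b, cache$bott$b)
  ga <- cblock_bw(gb$dx, params$bott$a, cache$bott$a)
  gbott <- list(a = ga$g, b = gb$g)
  dh <- ga$dx
  genc <- vector("list", dpt)
  for (l in rev(seq_len(dpt))) {
    dlevel <- pool2_bw(dh, cache$pool[[l]]) + skip_grad[[l]]
    gb2 <- cblock_bw(dlevel, params$enc[[l]]$b, cache$enc[[l]]$b)
    ga2 <- cblock_bw(gb2$dx, params$enc[[l]]$a, cache$enc[[l]]$a)
    genc[[l]] <- list(a = ga2$g, b = gb2$g)
    dh <- ga2$dx
  }
  # the global residual connection feeds dy straight to the input, which has
  # no parameters, so nothing further accumulates
  list(enc = genc, bott = gbott, dec = gdec,
       final = list(W = gfinal$dW, b = gfinal$db))
}

## ---- training ----

slices_from_input <- function(clean_slices) {
  if (inherits(clean_slices, "ct_volume")) {
    d <- dim(clean_slices$data)
    return(lapply(seq_len(d[3]), function(k) clean_slices$data[, , k]))
  }
  if (is.array(clean_slices) && length(dim(clean_slices)) == 3L) {
    d <- dim(clean_slices)
    return(lapply(seq_len(d[3]), function(k) clean_slices[, , k]))
  }
  if (is.list(clean_slices) && all(vapply(clean_slices, is.matrix, TRUE)))
    return(clean_slices)
  stop("clean_slices must be a ct_volume, a 3-D array, or a list of matrices",
       call. = FALSE)
}

check_unet_size <- function(spec, hw) {
  div <- 2L^spec$depth
  if (any(hw %% div != 0L))
    stop(sprintf("slice size %d x %d must be divisible by 2^depth = %d",
                 hw[1], hw[2], div), call. = FALSE)
}

# Mean validation L1 loss of a parameter set over seeded noise realizations.
unet_val_loss <- function(params, slices, cfg) {
  idx <- with_local_seed(derive_seed(cfg$seed, "val-subset"), {
    n <- length(slices)
    sample(n, min(cfg$val_slices_per_sigma, n))
  })
  total <- 0; count <- 0L
  for (sigma in cfg$val_sigmas) {
    for (i in idx) {
      clean <- slices[[i]]
      eps <- with_local_seed(derive_seed(cfg$seed, "val-noise", sigma, i),
                             stats::rnorm(length(clean), sd = sigma))
      noisy <- clean + matrix(eps, nrow(clean))
      pred <- unet_fw(params, noisy)$y
      total <- total + l1_loss(pred, clean)
      count <- count + 1L
    }
  }
  total / count
}

#' Train the U-Net denoiser
#'
#' Supervised denoising on clean slices: every epoch, each slice receives
#' fresh Gaussian noise at a standard deviation drawn uniformly from
#' `cfg$train_sigmas`; the network output is compared with the clean slice
#' under the L1 loss and parameters are updated by Adam. After each epoch the
#' validation loss (fixed seeded noise at `cfg$val_sigmas` against the clean
#' ground truth) is computed, and the checkpoint with the lowest validation
#' loss is returned. Fully deterministic given `cfg$seed`.
#'
#' @param clean_slices clean training data: a [ct_volume()], a 3-D array, or
#'   a list of matrices, all slices of one size divisible by `2^depth`.
#' @param cfg a [train_config()].
#' @param spec a [unet_spec()].
#' @return A trained `unet_denoiser` carrying `history` (per-epoch training
#'   and validation loss), `best_epoch` and `best_val_loss`.
#' @export
train_denoiser <- function(clean_slices, cfg, spec) {
  stopifnot(inherits(cfg, "train_config"), inherits(spec, "unet_spec"))
  slices <- slices_from_input(clean_slices)
  if (!length(slices)) stop("clean_slices is empty", call. = FALSE)
  check_unet_size(spec, dim(slices[[1]]))
  model <- build_unet(spec, seed = cfg$seed)
  params <- model$params
  mstate <- params_map(params, function(a) a * 0)
  vstate <- params_map(params, function(a) a * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  tstep <- 0L
  n <- length(slices)
  hist_train <- numeric(cfg$max_epochs)
  hist_val <- numeric(cfg$max_epochs)
  best <- list(loss = Inf, epoch = 0L, params = params)
  for (epoch in seq_len(cfg$max_epochs)) {
    hw <- dim(slices[[1]])
    cs <- cfg$crop_size
    if (!is.null(cs)) check_unet_size(spec, c(cs, cs))
    ep <- with_local_seed(derive_seed(cfg$seed, "epoch", epoch), {
      list(order = sample.int(n),
           sigmas = sample(cfg$train_sigmas, n, replace = TRUE),
           noise_seeds = sample.int(2^30, n),
           crop_x = if (is.null(cs)) NULL else
             sample.int(hw[1] - cs + 1L, n, replace = TRUE),
           crop_y = if (is.null(cs)) NULL else
             sample.int(hw[2] - cs + 1L, n, replace = TRUE))
    })
    epoch_loss <- 0
    nbatch <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      take <- ep$order[start:min(start + cfg$batch_size - 1L, n)]
      grad <- NULL
      batch_loss <- 0
      for (i in take) {
        clean <- slices[[i]]
        if (!is.null(cs))
          clean <- clean[ep$crop_x[i]:(ep$crop_x[i] + cs - 1L),
                         ep$crop_y[i]:(ep$crop_y[i] + cs - 1L)]
        eps <- with_local_seed(ep$noise_seeds[i],
                               stats::rnorm(length(clean), sd = ep$sigmas[i]))
        noisy <- clean + matrix(eps, nrow(clean))
        fw <- unet_fw(params, noisy, keep = TRUE)
        diffv <- fw$y - clean
        batch_loss <- batch_loss + mean(abs(diffv))
        dy <- sign(diffv) / length(diffv)
        g <- unet_bw(params, fw$cache, dy)
        grad <- if (is.null(grad)) g else params_map2(grad, g, `+`)
      }
      grad <- params_map(grad, function(a) a / length(take))
      tstep <- tstep + 1L
      mstate <- params_map2(mstate, grad,
                            function(m, g) beta1 * m + (1 - beta1) * g)
      vstate <- params_map2(vstate, grad,
                            function(v, g) beta2 * v + (1 - beta2) * g^2)
      bc1 <- 1 - beta1^tstep; bc2 <- 1 - beta2^tstep
      upd <- params_map2(mstate, vstate,
                         function(m, v) cfg$learning_rate * (m / bc1) /
                           (sqrt(v / bc2) + eps_adam))
      params <- params_map2(params, upd, `-`)
      epoch_loss <- epoch_loss + batch_loss / length(take)
      nbatch <- nbatch + 1L
    }
    hist_train[epoch] <- epoch_loss / nbatch
    vl <- unet_val_loss(params, slices, cfg)
    hist_val[epoch] <- vl
    if (vl < best$loss) best <- list(loss = vl, epoch = epoch, params = params)
  }
  model$params <- best$params
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$loss
  model$history <- data.frame(epoch = seq_len(cfg$max_epochs),
                              train_l1 = hist_train, val_l1 = hist_val)
  model$train_config <- cfg
  model
}

#' Recompute a model's validation loss
#'
#' Regenerates the seeded validation noise of `cfg` and evaluates the mean L1
#' loss of the model on it; equals the `val_l1` the training loop recorded for
#' the returned checkpoint's epoch.
#'
#' @param model a `unet_denoiser`.
#' @param clean_slices the training data (see [train_denoiser()]).
#' @param cfg the [train_config()] used in training.
#' @return Mean validation L1 loss in HU.
#' @export
validation_loss <- function(model, clean_slices, cfg) {
  unet_val_loss(model$params, slices_from_input(clean_slices), cfg)
}

#' Denoise a volume with a trained U-Net
#'
#' Each axial slice is passed through the network independently and the
#' volume is reassembled with its original spacing and origin.
#'
#' @param model a `unet_denoiser` from [train_denoiser()] (an untrained model
#'   from [build_unet()] is accepted and acts near-identity).
#' @param image a [ct_volume()] whose in-plane extent is divisible by
#'   `2^depth`.
#' @return A [ct_volume()].
#' @export
denoise_cnn <- function(model, image) {
  stopifnot(inherits(model, "unet_denoiser"), inherits(image, "ct_volume"))
  d <- dim(image$data)
  check_unet_size(model$spec, d[1:2])
  out <- array(0, d)
  for (k in seq_len(d[3]))
    out[, , k] <- unet_fw(model$params, image$data[, , k])$y
  ct_volume(out, image$spacing, image$origin)
}
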