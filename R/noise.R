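#' Simulate quantum noise with additive Gaussian noise
#'
#' CT quantum (photon) noise is approximated, in a deliberately simplified
#' way, as spatially white additive Gaussian noise in HU: every voxel receives
#' an independent zero-mean normal deviate with standard deviation `sigma_hu`.
#' No spatial correlation (noise power spectrum) is modelled and values are
#' not clipped afterwards, so the injected SD is unbiased. The study's
#' exercised range is 0-150 HU (registration destabilises well above that), so
#' sigmas up to 200 HU are accepted and larger values rejected.
#'
#' @param image a [ct_volume()] with finite voxels.
#' @param sigma_hu noise standard deviation in HU, in `[0, 200]`.
#' @param seed integer seed; the same seed reproduces the same realization,
#'   and different seeds (e.g. exhale vs inhale of one pair) give independent
#'   draws.
#' @return A [ct_volume()] of the same geometry.
#' @export
add_gaussian_noise <- function(image, sigma_hu, seed = 0L) {
  stopifnot(inherits(image, "ct_volume"))
  if (!is.numeric(sigma_hu) || length(sigma_hu) != 1L || !is.finite(sigma_hu) ||
      sigma_hu < 0 || sigma_hu > 200)
    stop("sigma_hu must be a single value in [0, 200] HU", call. = FALSE)
  if (!all(is.finite(image$data)))
    stop("image contains non-finite voxels", call. = FALSE)
  if (sigma_hu == 0) return(image)
  d <- dim(image$data)
  eps <- with_local_seed(seed, stats::rnorm(prod(d), sd = sigma_hu))
  ct_volume(image$data + array(eps, d), image$spacing, image$origin)
}

#' Default noise levels of the study design
#'
#' The pipeline's test conditions: Gaussian noise standard deviations of 30,
#' 80 and 150 HU added to each exhale/inhale pair.
#'
#' @return Numeric vector `c(30, 80, 150)`.
#' @export
study_noise_levels <- function() c(30, 80, 150)
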