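mk_map <- function(vals, mask = NULL) {
  n <- length(vals)
  if (is.null(mask)) mask <- array(TRUE, c(n, 1L, 1L))
  structure(list(values = array(vals, c(n, 1L, 1L)), mask = mask,
                 spacing = c(1, 1, 1), origin = c(0, 0, 0)),
            class = "ctvi_map")
}

mk_cat <- function(labels, thresholds = c(0, 0)) {
  n <- length(labels)
  structure(list(labels = array(as.integer(labels), c(n, 1L, 1L)),
                 thresholds = thresholds,
                 mask = array(labels > 0L, c(n, 1L, 1L)),
                 spacing = c(1, 1, 1)),
            class = "category_map")
}

test_that("Euclidean distance matches hand-computed cases", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(4, 6, 15)), 13)
  expect_error(euclidean_distance(c(NA, 0, 0), c(0, 0, 0)), "finite")
})

test_that("landmark displacement summarizes per-pair distances", {
  a <- landmark_set(matrix(c(0, 0, 0, 10, 10, 10), 2L, byrow = TRUE))
  expect_equal(landmark_displacement(a, a)$per_landmark, c(0, 0))
  b <- landmark_set(matrix(c(3, 4, 0, 10, 10, 10), 2L, byrow = TRUE))
  d <- landmark_displacement(a, b)
  expect_equal(d$per_landmark, c(5, 0))
  expect_equal(d$mean, 2.5)
  expect_equal(d$max, 5)
  one <- landmark_set(matrix(c(0, 0, 0), 1L))
  oneb <- landmark_set(matrix(c(0, 0, 7), 1L))
  d1 <- landmark_displacement(one, oneb)
  expect_equal(d1$mean, 7)
  expect_equal(d1$max, 7)
  expect_error(landmark_displacement(a, one), "length")
})

test_that("TRE is zero for a perfect match and d for a pure offset", {
  vol <- ct_volume(array(0, c(20L, 20L, 20L)), c(2, 2, 2))
  z <- zero_dvf(vol)
  pts <- withr_seed(23, matrix(stats::runif(75, 5, 30), 25L))
  lm <- landmark_set(pts)
  tre0 <- target_registration_error(lm, lm, z)
  expect_equal(tre0$per_landmark, rep(0, 25))
  expect_equal(tre0$mean, 0)
  shifted <- landmark_set(sweep(pts, 2, c(0, 0, 4.5), `+`))
  tre <- target_registration_error(lm, shifted, z)
  expect_equal(tre$per_landmark, rep(4.5, 25))
})

test_that("the true phantom field yields near-zero TRE, below the zero field", {
  ph <- small_phantom()
  tre_true <- target_registration_error(ph$landmarks_exhale,
                                        ph$landmarks_inhale, ph$true_dvf)
  expect_lt(tre_true$mean, 0.5 * min(ph$spec$spacing))
  tre_zero <- target_registration_error(ph$landmarks_exhale,
                                        ph$landmarks_inhale,
                                        zero_dvf(ph$exhale))
  expect_lt(tre_true$mean, tre_zero$mean)
})

test_that("confusion proportions capture agreement structure", {
  ref <- mk_cat(rep(1:3, each = 100L))
  expect_equal(diag(confusion_proportions(ref, ref)), rep(1 / 3, 3),
               ignore_attr = TRUE)
  # all reference low, all test high: one off-diagonal cell
  lo <- mk_cat(rep(1L, 50L))
  hi <- mk_cat(rep(3L, 50L))
  hi$mask <- lo$mask
  cp <- confusion_proportions(lo, hi)
  expect_equal(cp["low", "high"], 1, ignore_attr = TRUE)
  expect_equal(sum(cp), 1)
  # random shuffling approaches the product of marginals
  n <- 30000L
  rl <- withr_seed(24, sample(1:3, n, replace = TRUE, prob = c(.5, .3, .2)))
  tl <- withr_seed(25, sample(1:3, n, replace = TRUE, prob = c(.2, .5, .3)))
  cp2 <- confusion_proportions(mk_cat(rl), {
    tc <- mk_cat(tl); tc$mask <- array(TRUE, c(n, 1L, 1L)); tc
  })
  expected <- outer(tabulate(rl, 3) / n, tabulate(tl, 3) / n)
  expect_lt(max(abs(cp2 - expected)), 0.01)
})

test_that("Cohen's kappa matches arithmetic oracles and edge cases", {
  perfect <- diag(3) / 3
  expect_equal(cohens_kappa(perfect, 300)$kappa, 1)
  indep <- outer(c(.5, .3, .2), c(.5, .3, .2))
  expect_equal(cohens_kappa(indep, 1000)$kappa, 0, tolerance = 1e-12)
  conf <- rbind(c(0.25, 0.05, 0.03), c(0.05, 0.20, 0.05),
                c(0.02, 0.05, 0.30))
  k <- cohens_kappa(conf, 500)
  po <- 0.25 + 0.20 + 0.30
  pe <- sum(rowSums(conf) * colSums(conf))
  expect_equal(k$kappa, (po - pe) / (1 - pe))
  expect_equal(k$p_observed, 0.75)
  # invariance under simultaneous permutation of categories
  perm <- c(3, 1, 2)
  expect_equal(cohens_kappa(conf[perm, perm], 500)$kappa, k$kappa)
  # kappa = 1 iff the table is diagonal
  expect_lt(cohens_kappa(conf, 500)$kappa, 1)
  expect_error(cohens_kappa(diag(c(1, 0, 0)), 100), "degenerate")
})

test_that("asymptotic and permutation kappa p-values broadly agree", {
  conf <- rbind(c(0.30, 0.03, 0.01), c(0.03, 0.28, 0.03),
                c(0.01, 0.03, 0.28))
  pa <- cohens_kappa(conf, 200, method = "asymptotic")$p_value
  pp <- cohens_kappa(conf, 200, method = "permutation", n_perm = 199L,
                     seed = 1L)$p_value
  expect_lt(pa, 0.001)
  expect_lt(pp, 0.02)
})

test_that("2-D histograms tally pairs and conserve voxel counts", {
  ref_v <- c(0.1, 0.2, 0.35, 0.5, 0.55, 0.7, 0.8, 0.85, 0.9, 1.0)
  test_v <- c(0.15, 0.8, 0.3, 0.5, 0.9, 0.75, 0.2, 0.8, 0.95, 0.4)
  h <- histogram2d(mk_map(ref_v), mk_map(test_v), bins = 3L)
  expect_equal(sum(h), 10L)
  # hand tally: pooled range [0.1, 1.0], bin width 0.3
  bin <- function(v) pmin(floor((v - 0.1) / 0.3), 2) + 1
  oracle <- matrix(0L, 3L, 3L)
  for (i in seq_along(ref_v))
    oracle[bin(ref_v[i]), bin(test_v[i])] <-
      oracle[bin(ref_v[i]), bin(test_v[i])] + 1L
  expect_equal(unclass(h), oracle, ignore_attr = TRUE)
  # identical maps put all mass on the diagonal
  hd <- histogram2d(mk_map(ref_v), mk_map(ref_v), bins = 5L)
  expect_equal(sum(diag(hd)), 10L)
})

test_that("Spearman correlation matches rank oracles and cor.test", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 7.1, 6.3, 8.0)
  y <- x^3 - 2 * x           # strictly monotone transform
  expect_equal(spearman_correlation(mk_map(x), mk_map(y))$rho, 1)
  expect_equal(spearman_correlation(mk_map(x), mk_map(-x))$rho, -1)
  y2 <- c(2.1, 1.0, 4.4, 3.3, 6.6, 5.1, 8.8, 7.2)
  sp <- spearman_correlation(mk_map(x), mk_map(y2))
  oracle <- stats::cor.test(x, y2, method = "spearman", exact = FALSE)
  expect_equal(sp$rho, unname(oracle$estimate))
  # rho invariant under monotone transform of either side
  expect_equal(spearman_correlation(mk_map(exp(x)), mk_map(y2))$rho, sp$rho)
  expect_error(spearman_correlation(mk_map(rep(1, 5)), mk_map(x[1:5])),
               "constant")
})

test_that("consistency reports bundle the agreement statistics coherently", {
  ph <- small_phantom()
  ref <- ph$true_ventilation
  rep_self <- consistency_report(ref, ref, bins = 32L)
  expect_equal(rep_self$kappa, 1)
  expect_equal(rep_self$rho, 1)
  expect_equal(sum(rep_self$confusion), 1)
  expect_equal(sum(rep_self$hist2d), rep_self$n_voxels)
  # self-comparison is purely diagonal (range division need not be ~1/3
  # per category for a non-uniform value distribution)
  expect_equal(sum(diag(rep_self$confusion)), 1)
  off <- rep_self$confusion
  diag(off) <- 0
  expect_true(all(off == 0))
})
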