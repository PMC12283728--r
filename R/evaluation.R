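#' Euclidean distance between two points (mm)
#'
#' `sqrt((x_r - x_t)^2 + (y_r - y_t)^2 + (z_r - z_t)^2)`, the basic distance
#' used both for landmark displacement and for target registration error.
#'
#' @param p,q numeric length-3 points in mm.
#' @return Non-negative distance in mm.
#' @export
euclidean_distance <- function(p, q) {
  if (!all(is.finite(p)) || !all(is.finite(q)))
    stop("coordinates must be finite", call. = FALSE)
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

summarize_distances <- function(d) {
  list(per_landmark = d, mean = mean(d), sd = stats::sd(d), max = max(d),
       n = length(d))
}

#' Landmark displacement between breathing phases
#'
#' Per-landmark Euclidean distances between corresponding exhale and inhale
#' landmarks (the respiratory motion each landmark undergoes), with mean, SD
#' and maximum.
#'
#' @param exhale,inhale `landmark_set`s of equal length; correspondence by
#'   row order.
#' @return List with `per_landmark`, `mean`, `sd`, `max`, `n` (mm).
#' @export
landmark_displacement <- function(exhale, inhale) {
  a <- lm_matrix(exhale); b <- lm_matrix(inhale)
  if (nrow(a) != nrow(b))
    stop("landmark sets differ in length; correspondence is by order",
         call. = FALSE)
  summarize_distances(sqrt(rowSums((a - b)^2)))
}

# Map a target-space point into reference space through a pull-back field:
# solve p + u(p) = target by fixed-point iteration (damped restart on failure
# is handled by the caller).
pullback_point <- function(dvf, target, iters = 20L, tol_mm = NULL) {
  if (is.null(tol_mm)) tol_mm <- 1e-3 * min(dvf$spacing)
  p <- target
  converged <- FALSE
  for (it in seq_len(iters)) {
    s <- sample_dvf(dvf, p[1], p[2], p[3])
    pn <- target - c(s$ux, s$uy, s$uz)
    if (sqrt(sum((pn - p)^2)) < tol_mm) {
      p <- pn
      converged <- TRUE
      break
    }
    p <- pn
  }
  list(p = p, converged = converged)
}

#' Target registration error of a recovered deformation
#'
#' Each target-phase landmark is mapped through the recovered deformation
#' back into reference space (the position `p` with `p + u(p) = target`,
#' solved by fixed-point iteration with trilinear field sampling), and the
#' Euclidean distance to the corresponding reference landmark is the TRE. If
#' a landmark's fixed-point iteration does not converge, the forward mapping
#' of the reference landmark is used instead and the landmark is flagged.
#' When the deformation perfectly matches, TRE is zero. The summary reports
#' whether all TREs are within the 3 mm image-registration tolerance
#' (TG-132).
#'
#' @param reference reference-phase (exhale) `landmark_set`.
#' @param target target-phase (inhale) `landmark_set`.
#' @param dvf recovered [displacement_field()] on the reference grid.
#' @return List with `per_landmark`, `mean`, `sd`, `max`, `n`,
#'   `within_3mm_tolerance`, `fallback` (logical per landmark).
#' @export
target_registration_error <- function(reference, target, dvf) {
  a <- lm_matrix(reference); b <- lm_matrix(target)
  if (nrow(a) != nrow(b))
    stop("landmark sets differ in length; correspondence is by order",
         call. = FALSE)
  stopifnot(inherits(dvf, "displacement_field"))
  n <- nrow(a)
  tre <- numeric(n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    fp <- pullback_point(dvf, b[i, ])
    if (fp$converged) {
      tre[i] <- euclidean_distance(fp$p, a[i, ])
    } else {
      fallback[i] <- TRUE
      s <- sample_dvf(dvf, a[i, 1], a[i, 2], a[i, 3])
      tre[i] <- euclidean_distance(a[i, ] + c(s$ux, s$uy, s$uz), b[i, ])
    }
  }
  out <- summarize_distances(tre)
  out$within_3mm_tolerance <- all(tre <= 3)
  out$fallback <- fallback
  out
}

category_levels <- c("low", "middle", "high")

masked_labels <- function(cat_map) {
  factor(category_levels[cat_map$labels[cat_map$mask]],
         levels = category_levels)
}

#' Category agreement proportions between two ventilation maps
#'
#' The 3 x 3 table whose cell (i, j) is the fraction of masked voxels labelled
#' category i in the reference map and j in the test map; cells sum to 1 and
#' the diagonal sum is the overall agreement proportion.
#'
#' @param ref_cat,test_cat `category_map`s on identical masks.
#' @return Matrix (reference x test) of proportions with an
#'   `overall_agreement` attribute.
#' @export
confusion_proportions <- function(ref_cat, test_cat) {
  stopifnot(inherits(ref_cat, "category_map"), inherits(test_cat, "category_map"))
  if (!identical(ref_cat$mask, test_cat$mask))
    stop("category maps must share the same analysis mask", call. = FALSE)
  tab <- table(reference = masked_labels(ref_cat), test = masked_labels(test_cat))
  prop <- as.matrix(tab) / sum(tab)
  attr(prop, "overall_agreement") <- sum(diag(prop))
  prop
}

#' Cohen's kappa from a 3 x 3 proportion table
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o`
#' the diagonal sum and chance agreement `p_e` the product-marginal sum. The
#' p-value tests kappa = 0 with the asymptotic z-test using the large-sample
#' null standard error; a seeded permutation test is available for small
#' masks.
#'
#' @param confusion square matrix of proportions summing to 1 (e.g. from
#'   [confusion_proportions()]).
#' @param n number of voxels behind the table (>= 2).
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm,seed permutation count and seed for the permutation test.
#' @return List with `kappa`, `p_value`, `p_observed`, `p_expected`.
#' @export
cohens_kappa <- function(confusion, n, method = c("asymptotic", "permutation"),
                         n_perm = 999L, seed = 0L) {
  method <- match.arg(method)
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion must be square", call. = FALSE)
  if (abs(sum(confusion) - 1) > 1e-6)
    stop("confusion cells must sum to 1", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  po <- sum(diag(confusion))
  rowm <- rowSums(confusion); colm <- colSums(confusion)
  pe <- sum(rowm * colm)
  if (1 - pe < 1e-12)
    stop("degenerate marginals: chance agreement is 1, kappa undefined",
         call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  if (method == "asymptotic") {
    se0 <- sqrt(pe + pe^2 - sum(rowm * colm * (rowm + colm))) /
      ((1 - pe) * sqrt(n))
    z <- kappa / se0
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    counts <- round(confusion * n)
    ref <- rep(seq_len(nrow(confusion)), times = rowSums(counts))
    test <- unlist(lapply(seq_len(nrow(counts)), function(i)
      rep(seq_len(ncol(counts)), times = counts[i, ])))
    obs <- kappa
    perm <- with_local_seed(derive_seed(seed, "kappa-perm"), {
      vapply(seq_len(n_perm), function(b) {
        tp <- sample(test)
        tab <- table(factor(ref, seq_len(nrow(counts))),
                     factor(tp, seq_len(ncol(counts)))) / length(ref)
        poi <- sum(diag(tab)); pei <- sum(rowSums(tab) * colSums(tab))
        (poi - pei) / (1 - pei)
      }, numeric(1))
    })
    p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  }
  list(kappa = kappa, p_value = p, p_observed = po, p_expected = pe)
}

#' Joint 2-D histogram of two ventilation maps
#'
#' Counts voxel pairs (reference value, test value) on a `bins` x `bins` grid
#' of equal-width bins spanning the pooled value range of both maps. Perfect
#' agreement concentrates all mass on the y = x diagonal; total counts equal
#' the number of masked voxels.
#'
#' @param ref,test `ctvi_map`s on identical masks.
#' @param bins number of bins per axis (>= 2).
#' @return Integer matrix of counts with attributes `breaks` (bin edges) and
#'   `n` (total count).
#' @export
histogram2d <- function(ref, test, bins = 100L) {
  stopifnot(inherits(ref, "ctvi_map"), inherits(test, "ctvi_map"))
  if (!identical(ref$mask, test$mask))
    stop("maps must share the same analysis mask", call. = FALSE)
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  x <- ref$values[ref$mask]; y <- test$values[test$mask]
  if (!length(x)) stop("mask is empty", call. = FALSE)
  rng <- range(c(x, y))
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1e-9
  w <- (rng[2] - rng[1]) / bins
  bx <- pmin.int(floor((x - rng[1]) / w), bins - 1L)
  by <- pmin.int(floor((y - rng[1]) / w), bins - 1L)
  counts <- matrix(tabulate(1L + bx + bins * by, nbins = bins * bins),
                   bins, bins)
  structure(counts, breaks = seq(rng[1], rng[2], length.out = bins + 1L),
            n = length(x))
}

#' Spearman rank correlation of two ventilation maps
#'
#' Rank correlation on the raw voxel pairs inside the shared mask (mid-ranks
#' for ties), with the two-sided p-value from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param ref,test `ctvi_map`s on identical masks (or plain numeric vectors).
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(ref, test) {
  if (inherits(ref, "ctvi_map")) {
    if (!identical(ref$mask, test$mask))
      stop("maps must share the same analysis mask", call. = FALSE)
    x <- ref$values[ref$mask]; y <- test$values[test$mask]
  } else {
    x <- as.numeric(ref); y <- as.numeric(test)
    if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 voxel pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant map: rank correlation undefined", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  rho_c <- min(max(rho, -1 + 1e-15), 1 - 1e-15)
  tval <- rho_c * sqrt((n - 2) / (1 - rho_c^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(rho = rho, p_value = p, n = n)
}

#' Full consistency report between a test and reference ventilation map
#'
#' Bundles the agreement analyses applied to each test CTVI against the
#' reference: the 3 x 3 category-agreement proportions (categories from the
#' reference map's even range division, applied to both maps), Cohen's kappa
#' with p-value, Spearman rho with p-value, and the joint 2-D histogram.
#'
#' @param ref_map,test_map `ctvi_map`s on identical masks.
#' @param thresholds category thresholds, normally
#'   `tertile_thresholds(ref_map)`.
#' @param bins 2-D histogram bins.
#' @return List of class `consistency_report`: `confusion`, `kappa`,
#'   `kappa_p`, `rho`, `rho_p`, `hist2d`, `n_voxels`, `thresholds`.
#' @export
consistency_report <- function(ref_map, test_map,
                               thresholds = tertile_thresholds(ref_map),
                               bins = 100L) {
  ref_cat <- classify_ventilation(ref_map, thresholds)
  test_cat <- classify_ventilation(test_map, thresholds)
  confusion <- confusion_proportions(ref_cat, test_cat)
  n <- sum(ref_map$mask)
  kap <- cohens_kappa(confusion, n)
  sp <- spearman_correlation(ref_map, test_map)
  structure(list(confusion = confusion, kappa = kap$kappa,
                 kappa_p = kap$p_value, rho = sp$rho, rho_p = sp$p_value,
                 hist2d = histogram2d(ref_map, test_map, bins = bins),
                 n_voxels = n, thresholds = thresholds),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> n = %s voxels\n",
              format(x$n_voxels, big.mark = ",")))
  cat(sprintf("  kappa = %.3f (p = %.3g); Spearman rho = %.3f (p = %.3g)\n",
              x$kappa, x$kappa_p, x$rho, x$rho_p))
  cat(sprintf("  overall category agreement = %.1f%%\n",
              100 * sum(diag(x$confusion))))
  invisible(x)
}

#' Plot a 2-D ventilation histogram
#'
#' Log-scaled image of the joint histogram with the y = x diagonal overlaid;
#' mass along the diagonal indicates voxel-level agreement with the
#' reference.
#'
#' @param counts matrix from [histogram2d()].
#' @param main plot title.
#' @return Invisibly, `counts`.
#' @export
plot_hist2d <- function(counts, main = "CTVI joint histogram") {
  br <- attr(counts, "breaks")
  graphics::image(br, br, log1p(counts),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "reference Jacobian", ylab = "test Jacobian",
                  main = main, useRaster = TRUE)
  graphics::abline(0, 1, lty = 2)
  invisible(counts)
}
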