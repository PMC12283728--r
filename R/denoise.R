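#' Slice-wise 3 x 3 median filter
#'
#' Filters every axial (x-y) slice of a volume independently with a 3 x 3
#' median window; the kernel is strictly 2-D, so slices never mix. Borders use
#' reflect padding (edge row/column mirrored), which avoids darkening at the
#' image rim on HU data. The median of the nine neighbours is computed with a
#' vectorised exchange (min/max) selection network.
#'
#' @param image a [ct_volume()] with in-plane extent of at least 3 x 3.
#' @return A [ct_volume()] of the same geometry.
#' @export
median_filter <- function(image) {
  stopifnot(inherits(image, "ct_volume"))
  d <- dim(image$data)
  if (d[1] < 3L || d[2] < 3L)
    stop("in-plane extent must be at least 3 x 3 for a 3 x 3 median",
         call. = FALSE)
  out <- apply(image$data, 3L, median3x3)
  ct_volume(array(out, d), image$spacing, image$origin)
}

# 3x3 median of one 2-D slice, reflect (edge-replicated) padding.
median3x3 <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  shifts <- vector("list", 9L)
  k <- 1L
  for (dy in -1:1) for (dx in -1:1) {
    s <- m
    if (dx != 0) {
      idx <- pmin.int(pmax.int(seq_len(nrow(m)) + dx, 1L), nrow(m))
      s <- s[idx, , drop = FALSE]
    }
    if (dy != 0) {
      idy <- pmin.int(pmax.int(seq_len(ncol(m)) + dy, 1L), ncol(m))
      s <- s[, idy, drop = FALSE]
    }
    shifts[[k]] <- s
    k <- k + 1L
  }
  median_of_9(shifts)
}

# Paeth's optimal 19-exchange median-of-9 network, vectorised over arrays.
median_of_9 <- function(p) {
  swap <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8)
  swap(2, 3); swap(5, 6); swap(8, 9)
  p[[4]] <- pmax(p[[1]], p[[4]])
  p[[6]] <- pmin(p[[6]], p[[9]])
  swap(5, 8)
  p[[7]] <- pmax(p[[4]], p[[7]])
  p[[5]] <- pmax(p[[2]], p[[5]])
  p[[3]] <- pmin(p[[3]], p[[6]])
  p[[5]] <- pmin(p[[5]], p[[8]])
  swap(5, 3)
  p[[5]] <- pmax(p[[7]], p[[5]])
  pmin(p[[5]], p[[3]])
}

#' Mean absolute error (L1) loss
#'
#' `l1_loss(x, y) = mean(|x - y|)` over all elements: the training loss of the
#' denoising network, where `x` is the prediction and `y` the clean ground
#' truth.
#'
#' @param x,y numeric arrays of identical shape.
#' @return A single non-negative number.
#' @export
l1_loss <- function(x, y) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("l1_loss: shapes differ", call. = FALSE)
  mean(abs(x - y))
}
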