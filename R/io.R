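#' Read a NIfTI volume or displacement field
#'
#' Reads a scalar NIfTI-1 file into a [ct_volume()], or a 4-D three-component
#' NIfTI into a [displacement_field()]. The pipeline works on axis-aligned
#' grids only: files whose stored orientation matrix has off-axis (oblique)
#' terms or axis flips are rejected.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [ct_volume()] (3-D file) or [displacement_field()] (4-D file with
#'   three volumes).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))  # drop niftiImage attributes
  d <- dim(arr)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  diag_part <- diag(rot)
  if (max(abs(rot - diag(diag_part))) > 1e-4 * max(abs(diag_part)) ||
      any(diag_part <= 0))
    stop("oblique or flipped orientation matrix: this pipeline assumes ",
         "axis-aligned grids with positive voxel steps (file: ", path, ")",
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  if (length(d) == 3L) return(ct_volume(arr, spacing, origin))
  if (length(d) == 4L && d[4] == 3L)
    return(displacement_field(arr, spacing, origin))
  stop("expected a 3-D scalar volume or a 4-D 3-component field, got dim ",
       paste(d, collapse = "x"), call. = FALSE)
}

as_nifti_image <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  m <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  m <- structure(m, code = 2L)
  RNifti::sform(img) <- m
  RNifti::qform(img) <- m
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4L) c(spacing, 1) else spacing
  img
}

#' Write a volume or displacement field as NIfTI-1
#'
#' Voxel data are stored as float64 so values round-trip bit-exactly; spacing
#' and origin are stored in the sform/qform (axis-aligned, code 2).
#'
#' @param x a [ct_volume()] or [displacement_field()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "displacement_field")) x$u
         else if (inherits(x, "ct_volume")) x$data
         else stop("`x` must be a ct_volume or displacement_field",
                   call. = FALSE)
  RNifti::writeNifti(as_nifti_image(arr, x$spacing, x$origin), path,
                     datatype = "double")
  invisible(path)
}

#' Landmark set in physical coordinates
#'
#' Builds an ordered landmark table. Correspondence between two sets is by
#' row order; coordinates are physical mm.
#'
#' @param xyz numeric matrix (n x 3) or data.frame of coordinates in mm.
#' @param id optional landmark identifiers (default `1:n`).
#' @return A data.frame of class `landmark_set` with columns
#'   `id, x_mm, y_mm, z_mm`.
#' @export
landmark_set <- function(xyz, id = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("`xyz` must have 3 columns (x, y, z in mm)",
                            call. = FALSE)
  if (!all(is.finite(xyz))) stop("landmark coordinates must be finite",
                                 call. = FALSE)
  if (is.null(id)) id <- seq_len(nrow(xyz))
  if (anyDuplicated(id)) stop("landmark ids must be unique", call. = FALSE)
  out <- data.frame(id = id, x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3])
  class(out) <- c("landmark_set", "data.frame")
  out
}

lm_matrix <- function(lm) {
  stopifnot(all(c("x_mm", "y_mm", "z_mm") %in% names(lm)))
  as.matrix(lm[, c("x_mm", "y_mm", "z_mm")])
}

#' Read / write landmarks as CSV
#'
#' The on-disk format is a CSV with header `id,x_mm,y_mm,z_mm`; row order is
#' the correspondence and is preserved.
#'
#' @param path CSV path.
#' @return [read_landmarks()] returns a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("id", "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("landmark file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("landmark file ", path, " contains no landmarks", call. = FALSE)
  dup <- which(duplicated(df$id))
  if (length(dup))
    stop("duplicate landmark id '", df$id[dup[1]], "' at data line ",
         dup[1] + 1L, " of ", path, call. = FALSE)
  bad <- which(!stats::complete.cases(df[, c("x_mm", "y_mm", "z_mm")]) |
                 !apply(is.finite(as.matrix(df[, c("x_mm", "y_mm", "z_mm")])),
                        1, all))
  if (length(bad))
    stop("non-finite landmark coordinates at data line ", bad[1] + 1L, " of ",
         path, call. = FALSE)
  landmark_set(df[, c("x_mm", "y_mm", "z_mm")], id = df$id)
}

#' @param lm a `landmark_set` (or data.frame with the same columns).
#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(all(c("id", "x_mm", "y_mm", "z_mm") %in% names(lm)))
  utils::write.csv(as.data.frame(lm)[, c("id", "x_mm", "y_mm", "z_mm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
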