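#' Construct a 3-D intensity volume
#'
#' Light container for a scalar 3-D image: an intensity array, the voxel
#' spacing in millimetres, and a voxel-to-world affine.  This is the
#' in-memory form of a T1-weighted structural volume.
#'
#' @param data Numeric 3-D array of intensities; all values must be finite.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm
#'   (all strictly positive).
#' @param affine 4x4 voxel-to-world matrix; default is a RAS-aligned
#'   diagonal affine built from `voxel_size` with the origin at the first
#'   voxel.
#' @return An object of class `volume_image` with elements `data`,
#'   `voxel_size`, `affine`.
#' @export
#' @examples
#' v <- volume_image(array(0, c(4, 4, 4)))
#' dim(v$data)
volume_image <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("intensities must all be finite", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive lengths in mm",
         call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "volume_image")
}

#' Construct an anatomical label map
#'
#' Integer label volume in the style of FreeSurfer's `aparc+aseg`, paired
#' with a code table naming the structures.  The code table must contain
#' the six ventricular-system codes used to seed the segmentation (see
#' [aseg_codes()]); their voxel counts may be zero.
#'
#' @param data Integer 3-D array of label codes.
#' @param codes Named integer vector mapping structure names to codes;
#'   defaults to [aseg_codes()].
#' @param voxel_size Voxel spacing in mm, as for [volume_image()].
#' @return An object of class `label_map` with elements `data`, `codes`,
#'   `voxel_size`.
#' @export
label_map <- function(data, codes = aseg_codes(), voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "integer"
  codes <- vapply(codes, as.integer, integer(1))
  missing <- setdiff(names(ASEG_CODES), names(codes))
  if (length(missing))
    stop("code table lacks required structures: ",
         paste(missing, collapse = ", "), call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(list(data = data, codes = codes, voxel_size = voxel_size),
            class = "label_map")
}

check_aligned <- function(image, labels) {
  if (!identical(dim(image$data), dim(labels$data)))
    stop("image and label map have mismatched grid shapes (",
         paste(dim(image$data), collapse = "x"), " vs ",
         paste(dim(labels$data), collapse = "x"), ")", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 3), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range: [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$data), collapse = " x "), " voxels\n",
      sep = "")
  tab <- table(x$data[x$data != 0L])
  for (nm in names(x$codes)) {
    cnt <- tab[as.character(x$codes[[nm]])]
    cat(sprintf("  %-28s code %3d  %8d voxels\n", nm, x$codes[[nm]],
                ifelse(is.na(cnt), 0L, as.integer(cnt))))
  }
  invisible(x)
}
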