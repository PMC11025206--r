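#' Read a 3-D NIfTI volume
#'
#' Loads a NIfTI-1 file (`.nii` or `.nii.gz`) as a [volume_image()],
#' preserving the voxel spacing and the voxel-to-world affine.  Inputs
#' with more than three dimensions are rejected.
#'
#' @param path Path to the NIfTI file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- arr[, , , 1L]
    d <- dim(arr)
  }
  if (length(d) != 3L)
    stop("format error: expected a 3-D volume, got ",
         length(d), "-D in ", path, call. = FALSE)
  storage.mode(arr) <- "double"
  attributes(arr) <- list(dim = d)
  volume_image(arr, voxel_size = RNifti::pixdim(img)[1:3],
               affine = unclass(RNifti::xform(img)))
}

#' Read a 3-D NIfTI label volume
#'
#' As [read_volume()] but returning a [label_map()] with integer codes.
#'
#' @param path Path to the NIfTI file.
#' @param codes Structure code table, defaulting to [aseg_codes()].
#' @return A [label_map()].
#' @export
read_label_map <- function(path, codes = aseg_codes()) {
  v <- read_volume(path)
  arr <- v$data
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("format error: label volume contains non-integer values",
         call. = FALSE)
  label_map(array(as.integer(round(arr)), dim = dim(arr)), codes = codes,
            voxel_size = v$voxel_size)
}

#' Write a volume, label map, or mask as NIfTI-1
#'
#' Intensity volumes are stored as float64 (bit-exact round trip), label
#' maps as int16 and boolean masks as uint8.  Both `.nii` and `.nii.gz`
#' paths are supported.
#'
#' @param x A [volume_image()], [label_map()], or logical array.
#' @param path Output path.
#' @param voxel_size Voxel spacing for bare mask arrays (ignored for the
#'   container classes, which carry their own).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  if (inherits(x, "volume_image")) {
    arr <- x$data; vs <- x$voxel_size; dt <- "double"
  } else if (inherits(x, "label_map")) {
    arr <- x$data; vs <- x$voxel_size; dt <- "int16"
  } else if (is.logical(x) && length(dim(x)) == 3L) {
    arr <- array(as.integer(x), dim = dim(x)); vs <- voxel_size
    dt <- "uint8"
  } else stop("cannot write object of class ", paste(class(x),
              collapse = "/"), " as NIfTI", call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
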