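# Volumetric containers: plain 3D arrays carrying a 4x4 RAS affine in the
# "affine" attribute. Voxel indices are 0-based in world-coordinate math;
# array subscripting stays 1-based as usual in R.

#' Attach an affine to a 3D array
#'
#' @param data A 3D numeric/integer/logical array.
#' @param affine A 4x4 voxel-to-world (RAS, mm) matrix.
#' @return The array with an `affine` attribute.
#' @export
as_volume <- function(data, affine) {
  stopifnot(length(dim(data)) == 3L, is.matrix(affine),
            all(dim(affine) == c(4L, 4L)))
  attr(data, "affine") <- affine
  data
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into a plain array with the stored voxel-to-world
#' affine attached as the `affine` attribute (RAS millimetres).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A 3D array with an `affine` attribute.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("volume file does not exist: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  as_volume(arr, aff)
}

#' Write a NIfTI volume
#'
#' @param vol A 3D array; its `affine` attribute is used unless `affine`
#'   is given.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine Optional 4x4 affine overriding the attribute.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, affine = NULL) {
  aff <- affine %||% attr(vol, "affine")
  if (is.null(aff)) stop("no affine supplied for ", path, call. = FALSE)
  arr <- vol
  attributes(arr) <- list(dim = dim(vol))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel-to-world coordinate transform
#'
#' @param vox An n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @param affine A 4x4 voxel-to-world matrix.
#' @return An n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(vox, affine) {
  if (is.null(dim(vox))) vox <- matrix(vox, nrow = 1L)
  hom <- cbind(vox, 1)
  out <- hom %*% t(affine)
  out[, 1:3, drop = FALSE]
}

# Check that a list of volumes share grid shape and affine; names are used
# in the error message.
check_same_grid <- function(volumes, tol = 1e-6) {
  stopifnot(length(volumes) >= 1L)
  ref_dim <- dim(volumes[[1L]])
  ref_aff <- attr(volumes[[1L]], "affine")
  nms <- names(volumes) %||% as.character(seq_along(volumes))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!identical(dim(v), ref_dim)) {
      stop("grid shape mismatch in volume '", nms[i], "'", call. = FALSE)
    }
    aff <- attr(v, "affine")
    if (!is.null(ref_aff) && !is.null(aff) &&
        max(abs(aff - ref_aff)) > tol) {
      stop("affine mismatch in volume '", nms[i], "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Volume of one voxel in mm^3 from the affine.
voxel_volume_mm3 <- function(affine) {
  abs(det(affine[1:3, 1:3]))
}
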