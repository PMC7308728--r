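## NIfTI-1 volume I/O, built on RNifti.  All volumes live in scanner RAS
## (mm); the sform carries the affine.  Invalid voxels are stored as NaN.

#' Read a single-frame NIfTI volume
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @param expectedKind parameter kind to stamp on the result
#'   (\code{"T1"}, \code{"T2"}, \code{"T2star"}, \code{"PD"}, \code{"B1"},
#'   \code{"SIGNAL"}, \code{"R"}, \code{"Q"}, \code{"LABEL"}, \code{"MASK"}).
#' @return A \code{\linkS4class{QuantitativeVolume}}; non-finite voxels are
#'   marked invalid.
#' @export
readVolume <- function(path, expectedKind = "SIGNAL") {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected 3-D volume, got %d-D: %s", length(d), path),
         call. = FALSE)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))[1:4, 1:4]
  if (!is.finite(det(aff)) || abs(det(aff)) < .Machine$double.eps)
    stop(sprintf("non-invertible affine in %s", path), call. = FALSE)
  QuantitativeVolume(array(as.double(img), d), aff, expectedKind)
}

#' Write a volume as NIfTI-1
#'
#' Invalid voxels are stored as NaN; data are written in double precision so
#' that \code{readVolume(writeVolume(v))} reproduces finite data exactly.
#'
#' @param vol a \code{\linkS4class{QuantitativeVolume}}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("parent directory does not exist: %s", dir), call. = FALSE)
  dat <- vol@data
  dat[!vol@validMask] <- NaN
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Resample a volume onto a reference grid
#'
#' Trilinear resampling onto the grid of \code{ref}; both volumes must map
#' into the same world frame.  A target voxel is invalid if any contributing
#' source voxel is invalid, or if its centre falls outside the source grid
#' (no clamping at the edge).
#'
#' @param vol volume to resample.
#' @param ref volume whose grid and affine define the output.
#' @return A \code{QuantitativeVolume} on the grid of \code{ref}, with the
#'   kind of \code{vol}.
#' @export
resampleToReference <- function(vol, ref) {
  d <- dim(ref@data)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  world <- .voxelToWorld(ref@affine, idx)
  s <- sampleVolume(vol, world, rule = "strict")
  out <- array(s$values, d)
  QuantitativeVolume(out, ref@affine, vol@kind,
                     validMask = array(s$valid, d))
}
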