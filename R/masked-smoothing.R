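## Compartmental edge-preserving smoothing of qMRI maps: split into WM and
## non-WM compartments (with CSF partial-volume exclusions on the non-WM
## side), smooth each compartment as G(map*mask)/G(mask), recombine.

## Separable 3-D Gaussian convolution.  The 1-D kernel is the sampled,
## truncated (radius 4 sigma) Gaussian normalized to unit sum; each axis is
## applied as a dense band-matrix product (zero padding outside the grid).
## A sigma below ~0.2 voxels collapses to the identity (delta kernel).
.gaussianKernel1d <- function(sigmaVox) {
  if (sigmaVox < 0.2) return(1)
  r <- max(1L, ceiling(4 * sigmaVox))
  k <- exp(-((-r):r)^2 / (2 * sigmaVox^2))
  k / sum(k)
}

.kernelMatrix <- function(n, sigmaVox) {
  k <- .gaussianKernel1d(sigmaVox)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in (-r):r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[off + r + 1L]
  }
  K
}

#' Separable 3-D Gaussian smoothing of an array
#'
#' Zero padding outside the grid; the kernel is truncated at four standard
#' deviations and normalized to unit sum, so an isolated unit voxel spreads
#' into a blob of total mass one (away from the grid edge).
#'
#' @param arr 3-D numeric array.
#' @param sigmaMm kernel standard deviation in mm (scalar).
#' @param voxelMm voxel sizes per axis (mm); the sigma is converted to
#'   voxels per axis, so anisotropic grids smooth isotropically in mm.
#' @return smoothed array.
#' @export
gaussianSmooth3d <- function(arr, sigmaMm, voxelMm = c(1, 1, 1)) {
  d <- dim(arr)
  sig <- sigmaMm / voxelMm
  x <- matrix(arr, d[1])
  if (sig[1] >= 0.2) x <- .kernelMatrix(d[1], sig[1]) %*% x
  x <- array(x, d)
  if (sig[2] >= 0.2) {
    x <- aperm(x, c(2, 1, 3))
    x <- array(.kernelMatrix(d[2], sig[2]) %*% matrix(x, d[2]),
               d[c(2, 1, 3)])
    x <- aperm(x, c(2, 1, 3))
  }
  if (sig[3] >= 0.2) {
    x <- aperm(x, c(3, 1, 2))
    x <- array(.kernelMatrix(d[3], sig[3]) %*% matrix(x, d[3]),
               d[c(3, 1, 2)])
    x <- aperm(x, c(2, 3, 1))
  }
  x
}

#' CompartmentPair: a qMRI map split into WM and non-WM parts
#'
#' @slot wmMap,nonwmMap \code{\linkS4class{QuantitativeVolume}}s carrying
#'   the compartment values (invalid outside their masks).
#' @slot wmMask,nonwmMask disjoint logical arrays.
#' @exportClass CompartmentPair
setClass("CompartmentPair",
         slots = c(wmMap = "QuantitativeVolume",
                   nonwmMap = "QuantitativeVolume",
                   wmMask = "array", nonwmMask = "array"))

setValidity("CompartmentPair", function(object) {
  msgs <- character()
  if (any(object@wmMask & object@nonwmMask))
    msgs <- c(msgs, "WM and non-WM masks must be disjoint")
  if (!identical(dim(object@wmMask), dim(object@wmMap@data)))
    msgs <- c(msgs, "masks must share the map grid")
  if (length(msgs)) msgs else TRUE
})

#' Split a qMRI map into WM and non-WM compartments
#'
#' The non-WM compartment is the logical negation of the WM mask, further
#' cleaned of CSF partial-volume voxels: for T1 and PD maps, non-WM voxels
#' with T1 above \code{t1Max} (default 2000 ms) are excluded; for T2 maps,
#' non-WM voxels with T2 above \code{t2Max} (default 300 ms).  Comparisons
#' are strict.  The WM compartment is not filtered.
#'
#' @param map a T1, T2 or PD \code{\linkS4class{QuantitativeVolume}}.
#' @param wmMask logical array on the map's grid.
#' @param t1 the T1 map, required to filter a PD map (the exclusion is
#'   defined on T1 values); ignored for T1 and T2 maps.
#' @param t1Max,t2Max CSF exclusion thresholds (ms).
#' @return A \code{\linkS4class{CompartmentPair}}.
#' @export
splitWmNonwm <- function(map, wmMask, t1 = NULL, t1Max = 2000, t2Max = 300) {
  d <- dim(map@data)
  wmMask <- array(as.logical(wmMask), d)
  if (!identical(dim(wmMask), d))
    stop("grid mismatch between map and WM mask", call. = FALSE)
  nonwm <- !wmMask
  excl <- array(FALSE, d)
  if (map@kind == "T1") {
    excl <- is.finite(map@data) & map@data > t1Max
  } else if (map@kind == "T2") {
    excl <- is.finite(map@data) & map@data > t2Max
  } else if (map@kind == "PD") {
    if (is.null(t1))
      stop("a T1 map is required to filter the non-WM PD compartment",
           call. = FALSE)
    .stopIfGridMismatch(map, t1, "PD and T1 maps")
    excl <- is.finite(t1@data) & t1@data > t1Max
  }
  nonwmKeep <- nonwm & !excl & map@validMask
  wmKeep <- wmMask & map@validMask
  mk <- function(keep) {
    dat <- map@data
    dat[!keep] <- NA_real_
    QuantitativeVolume(dat, map@affine, map@kind, validMask = keep)
  }
  new("CompartmentPair", wmMap = mk(wmKeep), nonwmMap = mk(nonwmKeep),
      wmMask = wmKeep, nonwmMask = nonwmKeep)
}

#' Edge-preserving (quotient) smoothing within a mask
#'
#' Smooths the map and its binary mask with the same Gaussian kernel and
#' takes the quotient \code{G(map*mask) / G(mask)} inside the mask, which
#' prevents values outside the mask (zeros, CSF) from bleeding across the
#' compartment edge.  Voxels outside the mask are invalid in the output.
#'
#' @param map a \code{\linkS4class{QuantitativeVolume}}.
#' @param mask logical array; defaults to the map's validity mask.
#' @param fwhmMm kernel full width at half maximum in mm (default 1.5);
#'   sigma = fwhm / (2 sqrt(2 ln 2)), converted to voxels per axis.
#' @return smoothed \code{QuantitativeVolume}, valid only inside the mask.
#' @export
smoothEdgePreserving <- function(map, mask = NULL, fwhmMm = 1.5) {
  if (fwhmMm <= 0) stop("fwhmMm must be positive", call. = FALSE)
  d <- dim(map@data)
  if (is.null(mask)) mask <- map@validMask
  mask <- array(as.logical(mask), d) & map@validMask
  if (!any(mask)) stop("empty mask", call. = FALSE)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2)))
  vox <- voxelSizes(map@affine)
  dat <- map@data
  dat[!mask] <- 0
  num <- gaussianSmooth3d(dat, sigma, vox)
  den <- gaussianSmooth3d(mask + 0, sigma, vox)
  out <- ifelse(mask, num / pmax(den, .Machine$double.eps), NA_real_)
  QuantitativeVolume(array(out, d), map@affine, map@kind,
                     validMask = mask)
}

#' Recombine smoothed WM and non-WM compartments
#'
#' Union of the two (disjoint) compartments.  Voxels excluded by the CSF
#' thresholds at the split remain invalid in the output.
#'
#' @param pair a \code{\linkS4class{CompartmentPair}} whose maps have been
#'   smoothed (or not) on one grid.
#' @return the recombined \code{\linkS4class{QuantitativeVolume}}.
#' @export
recombine <- function(pair) {
  if (any(pair@wmMap@validMask & pair@nonwmMap@validMask))
    stop("overlapping compartment masks", call. = FALSE)
  .stopIfGridMismatch(pair@wmMap, pair@nonwmMap, "compartments")
  d <- dim(pair@wmMap@data)
  out <- array(NA_real_, d)
  out[pair@wmMap@validMask] <- pair@wmMap@data[pair@wmMap@validMask]
  out[pair@nonwmMap@validMask] <- pair@nonwmMap@data[pair@nonwmMap@validMask]
  valid <- pair@wmMap@validMask | pair@nonwmMap@validMask
  QuantitativeVolume(out, pair@wmMap@affine, pair@wmMap@kind,
                     validMask = valid)
}

#' Full compartmental smoothing of one qMRI map
#'
#' Convenience chain: split into WM / non-WM (with the CSF exclusions),
#' smooth each compartment edge-preservingly, recombine.
#'
#' @inheritParams splitWmNonwm
#' @inheritParams smoothEdgePreserving
#' @return smoothed, recombined \code{\linkS4class{QuantitativeVolume}}.
#' @export
smoothCompartments <- function(map, wmMask, t1 = NULL, fwhmMm = 1.5,
                               t1Max = 2000, t2Max = 300) {
  pair <- splitWmNonwm(map, wmMask, t1 = t1, t1Max = t1Max, t2Max = t2Max)
  sm <- function(m) if (any(m@validMask))
    smoothEdgePreserving(m, fwhmMm = fwhmMm) else m
  recombine(new("CompartmentPair", wmMap = sm(pair@wmMap),
                nonwmMap = sm(pair@nonwmMap), wmMask = pair@wmMask,
                nonwmMask = pair@nonwmMask))
}
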