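## Trilinear interpolation of a QuantitativeVolume at arbitrary world points.
##
## Two validity rules are used in the package:
##  - "strict": a sample is invalid if any corner voxel with non-negligible
##    weight is invalid (used by resampleToReference);
##  - "renormalize": weights of invalid corners are dropped and the remainder
##    renormalized; the sample is invalid only when the valid-corner weight
##    falls below `minWeight` (used by surface depth sampling, where the
##    CSF-exclusion step deliberately punches holes next to the pial surface).
## Points outside the voxel-centre domain [0, n-1] are invalid, never clamped.

#' Sample a volume at world-space points by trilinear interpolation
#'
#' @param vol a \code{\linkS4class{QuantitativeVolume}}.
#' @param points N x 3 matrix of world coordinates (mm).
#' @param rule \code{"strict"} or \code{"renormalize"} (see Details).
#' @param minWeight minimum total valid-corner weight for a renormalized
#'   sample to count as valid.
#' @return list with \code{values} (numeric, NA where invalid) and
#'   \code{valid} (logical).
#' @details Under the strict rule a sample is invalid as soon as any corner
#'   voxel contributing weight is invalid; under the renormalized rule the
#'   valid corners are reweighted to sum to one, and the sample is invalid
#'   only if the valid weight is below \code{minWeight}.  Positions outside
#'   the grid (beyond the outermost voxel centres) are always invalid.
#' @export
sampleVolume <- function(vol, points,
                         rule = c("strict", "renormalize"),
                         minWeight = 0.5) {
  rule <- match.arg(rule)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be N x 3")
  d <- dim(vol@data)
  vox <- .worldToVoxel(vol@affine, points)
  n <- nrow(vox)
  values <- rep(NA_real_, n)
  inside <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  inside[is.na(inside)] <- FALSE
  if (!any(inside)) return(list(values = values, valid = inside))

  v <- vox[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(v), 0), rep(d - 2L, each = nrow(v)))
  f <- v - i0
  dat <- vol@data
  msk <- vol@validMask
  acc <- numeric(nrow(v))
  wvalid <- numeric(nrow(v))
  anyBad <- logical(nrow(v))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
      (if (dy == 1) f[, 2] else 1 - f[, 2]) *
      (if (dz == 1) f[, 3] else 1 - f[, 3])
    lin <- (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) + d[2] * (i0[, 3] + dz)) + 1
    ok <- msk[lin] & is.finite(dat[lin])
    contrib <- w > 1e-12
    anyBad <- anyBad | (contrib & !ok)
    wv <- ifelse(ok, w, 0)
    acc <- acc + wv * ifelse(ok, dat[lin], 0)
    wvalid <- wvalid + wv
  }
  if (rule == "strict") {
    good <- !anyBad
    out <- ifelse(good, acc / pmax(wvalid, .Machine$double.eps), NA_real_)
  } else {
    good <- wvalid >= minWeight
    out <- ifelse(good, acc / ifelse(good, wvalid, 1), NA_real_)
  }
  values[inside] <- out
  inside[inside] <- good
  list(values = values, valid = inside)
}
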