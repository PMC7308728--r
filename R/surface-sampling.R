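## Depth-resolved cortical sampling.  The cortex is parameterized per
## vertex by the depth fraction f along the white->pial vector: f = 0 at
## the WM/cortex junction, f = 1 at the pial surface, negative f extends
## the same vector into WM (the mirror convention for positions (iii) and
## (iv)).  Four bands straddle the junction: 20-40% and 60-80% of the
## thickness inside the cortex and their WM mirrors.

.DEFAULT_BANDS <- list(cortexDeep = c(0.2, 0.4),
                       cortexSuperficial = c(0.6, 0.8),
                       wmShallow = c(-0.4, -0.2),
                       wmDeep = c(-0.8, -0.6))

#' World position at a cortical depth fraction
#'
#' \code{white[v] + fraction * (pial[v] - white[v])}; fraction 0 is the
#' WM/cortex junction, 1 the pial surface, negative fractions mirror into
#' WM along the same per-vertex vector.
#'
#' @param model a \code{\linkS4class{CorticalSurfaceModel}}.
#' @param vertex vertex index (1-based), may be a vector.
#' @param fraction depth fraction in [-1, 1].
#' @return N x 3 matrix of world coordinates (mm).
#' @export
depthPoint <- function(model, vertex, fraction) {
  if (any(fraction < -1 | fraction > 1))
    stop("fraction must lie in [-1, 1]", call. = FALSE)
  w <- model@whiteVertices[vertex, , drop = FALSE]
  p <- model@pialVertices[vertex, , drop = FALSE]
  w + fraction * (p - w)
}

#' Average a volume over a cortical depth band
#'
#' Samples the volume by trilinear interpolation at depth fractions
#' \code{fLo, fLo+step, ..., fHi} (endpoints inclusive; 21 layers for a
#' 20-percentage-point band at the default 1% resolution) along each
#' vertex's white->pial vector and averages them.  A vertex is invalid if
#' it is off-cortex (medial wall), or if any of its layer samples is
#' invalid or leaves the grid.
#'
#' @param vol a \code{\linkS4class{QuantitativeVolume}} on the reference
#'   grid.
#' @param model a \code{\linkS4class{CorticalSurfaceModel}}.
#' @param fLo,fHi band limits as depth fractions (\code{fLo < fHi}).
#' @param step layer resolution as a depth fraction (default 0.01).
#' @param rule interpolation validity rule passed to
#'   \code{\link{sampleVolume}} (default \code{"renormalize"}, see there).
#' @return A \code{\linkS4class{VertexOverlay}} of band means.
#' @export
sampleBand <- function(vol, model, fLo, fHi, step = 0.01,
                       rule = "renormalize") {
  if (fLo >= fHi) stop("fLo must be below fHi", call. = FALSE)
  nLayers <- round((fHi - fLo) / step) + 1L
  fractions <- seq(fLo, fHi, length.out = nLayers)
  n <- nVertices(model)
  acc <- numeric(n)
  ok <- model@cortexLabel
  u <- model@pialVertices - model@whiteVertices
  for (f in fractions) {
    pts <- model@whiteVertices + f * u
    s <- sampleVolume(vol, pts, rule = rule)
    ok <- ok & s$valid
    acc <- acc + ifelse(s$valid, s$values, 0)
  }
  vals <- ifelse(ok, acc / nLayers, NA_real_)
  VertexOverlay(vals, ok, name = sprintf("band[%g,%g]", fLo, fHi))
}

#' FourPositionSample: per-vertex values at the four junction bands
#'
#' @slot values N x 4 matrix with columns cortexDeep (20-40%),
#'   cortexSuperficial (60-80%), wmShallow (-40..-20%), wmDeep (-80..-60%).
#' @slot valid length-N logical; TRUE only if all four band means are
#'   computed from in-grid, valid voxels.
#' @slot parameter name of the sampled map (e.g. \code{"T1"}).
#' @exportClass FourPositionSample
setClass("FourPositionSample",
         slots = c(values = "matrix", valid = "logical",
                   parameter = "character"))

setValidity("FourPositionSample", function(object) {
  if (ncol(object@values) != 4L) return("values must have four columns")
  if (nrow(object@values) != length(object@valid))
    return("valid must have one entry per vertex")
  TRUE
})

setMethod("show", "FourPositionSample", function(object) {
  cat(sprintf("FourPositionSample (%s): %d vertices, %d valid\n",
              object@parameter, nrow(object@values), sum(object@valid)))
  invisible(object)
})

#' Sample a qMRI map at the four junction-straddling positions
#'
#' Band means at 20-40% and 60-80% of the cortical thickness and at the
#' WM positions mirrored at the WM/cortex boundary (-40..-20%, -80..-60%).
#' Validity is the conjunction over the four bands.
#'
#' @param vol a qMRI map on the reference grid.
#' @param model a \code{\linkS4class{CorticalSurfaceModel}}.
#' @param bands list of four length-2 fraction ranges (defaults above).
#' @param step layer resolution (default 0.01).
#' @param rule interpolation validity rule (see \code{\link{sampleBand}}).
#' @return A \code{\linkS4class{FourPositionSample}}.
#' @export
fourPositionValues <- function(vol, model, bands = .DEFAULT_BANDS,
                               step = 0.01, rule = "renormalize") {
  stopifnot(length(bands) == 4L)
  overlays <- lapply(bands, function(b)
    sampleBand(vol, model, b[1], b[2], step = step, rule = rule))
  vals <- do.call(cbind, lapply(overlays, overlayValues))
  colnames(vals) <- names(bands)
  valid <- Reduce(`&`, lapply(overlays, overlayValid))
  new("FourPositionSample", values = vals, valid = valid,
      parameter = vol@kind)
}

#' Per-vertex standard deviation of the four band values
#'
#' Population convention (divisor 4): a step junction with two values a and
#' two values b gives SD = |a - b| / 2.  Low SD flags a blurred junction.
#'
#' @param sample a \code{\linkS4class{FourPositionSample}}.
#' @return A \code{\linkS4class{VertexOverlay}} named \code{SD_<parameter>}.
#' @export
vertexSd <- function(sample) {
  m <- rowMeans(sample@values)
  sd <- sqrt(rowMeans((sample@values - m)^2))
  sd[!sample@valid] <- NA_real_
  VertexOverlay(sd, sample@valid,
                name = paste0("SD_", sample@parameter))
}

#' Junction-spread overlays for a triplet of qMRI maps
#'
#' Convenience wrapper: four-position sampling followed by the vertex SD,
#' for each of the supplied maps.
#'
#' @param maps named list of \code{\linkS4class{QuantitativeVolume}}s
#'   (typically \code{t1}, \code{t2}, \code{pd}).
#' @inheritParams fourPositionValues
#' @return named list of SD \code{\linkS4class{VertexOverlay}}s.
#' @export
sdOverlays <- function(maps, model, bands = .DEFAULT_BANDS, step = 0.01,
                       rule = "renormalize") {
  lapply(maps, function(m)
    vertexSd(fourPositionValues(m, model, bands = bands, step = step,
                                rule = rule)))
}
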