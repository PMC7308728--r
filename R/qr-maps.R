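## The Q statistic and the volumetric enhancement factor R.
## Q[v] = SD(T1) * SD(T2) * SD(PD) / T  (+ a minimal offset), low where the
## junction is blurred or the cortex thickened.  Q is projected into the
## volume, inverted as Q0/Q, capped, smoothed and offset by +1 into R.

#' QRConfig: constants of the Q -> R chain
#'
#' @slot qOffset minimal constant added to Q to avoid zero values before
#'   the division (default 0.0001).
#' @slot q0 quotient threshold: the filter computes Q0/Q, high where
#'   Q < Q0 (default 500, empirically chosen in the source protocol).
#' @slot quotientCap quotient values above this are excluded, i.e. set to
#'   zero (default 1000), suppressing artifacts where cortical values
#'   cannot be read.
#' @slot smoothSigmaMm Gaussian sigma of the volumetric smoothing (mm,
#'   default 3).
#' @slot rOffset constant added after smoothing (default 1.0), making
#'   R ~ 1 in normal tissue.
#' @exportClass QRConfig
setClass("QRConfig",
         slots = c(qOffset = "numeric", q0 = "numeric",
                   quotientCap = "numeric", smoothSigmaMm = "numeric",
                   rOffset = "numeric"))

setValidity("QRConfig", function(object) {
  v <- c(object@qOffset, object@q0, object@quotientCap,
         object@smoothSigmaMm, object@rOffset)
  if (any(v <= 0)) "all QRConfig values must be strictly positive" else TRUE
})

#' @rdname QRConfig-class
#' @param qOffset,q0,quotientCap,smoothSigmaMm,rOffset see the class slots.
#' @return A \code{QRConfig}.
#' @export
qrConfig <- function(qOffset = 1e-4, q0 = 500, quotientCap = 1000,
                     smoothSigmaMm = 3, rOffset = 1)
  new("QRConfig", qOffset = qOffset, q0 = q0, quotientCap = quotientCap,
      smoothSigmaMm = smoothSigmaMm, rOffset = rOffset)

#' Combine SD overlays and thickness into the vertex-wise Q statistic
#'
#' \code{Q[v] = SD_T1[v] * SD_T2[v] * SD_PD[v] / T[v] + qOffset}.  A vertex
#' is invalid if any input overlay is invalid there; a zero thickness at a
#' valid vertex is an error.
#'
#' @param sdT1,sdT2,sdPd SD \code{\linkS4class{VertexOverlay}}s on one
#'   surface.
#' @param thickness per-vertex cortical thickness: a
#'   \code{\linkS4class{VertexOverlay}} or numeric vector (mm).
#' @param cfg a \code{\linkS4class{QRConfig}}.
#' @return A \code{\linkS4class{VertexOverlay}} named \code{"Q"}.
#' @export
computeQ <- function(sdT1, sdT2, sdPd, thickness, cfg = qrConfig()) {
  if (is(thickness, "VertexOverlay")) {
    thickValid <- thickness@valid
    thickness <- thickness@values
  } else thickValid <- is.finite(thickness)
  n <- length(sdT1@values)
  if (length(sdT2@values) != n || length(sdPd@values) != n ||
      length(thickness) != n)
    stop("overlays must share one surface (equal lengths)", call. = FALSE)
  valid <- sdT1@valid & sdT2@valid & sdPd@valid & thickValid
  if (any(valid & !(thickness > 0)))
    stop("zero thickness at a valid vertex", call. = FALSE)
  q <- sdT1@values * sdT2@values * sdPd@values / thickness + cfg@qOffset
  q[!valid] <- NA_real_
  VertexOverlay(q, valid, name = "Q")
}

## mean triangle edge length of the white surface (used as the default
## lateral reach of the ribbon fill)
.meanEdgeLength <- function(model) {
  f <- model@faces
  v <- model@whiteVertices
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  mean(sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2)))
}

#' Project a vertex overlay into the cortical-ribbon volume
#'
#' Re-implementation of a surface-to-volume projection: every voxel whose
#' centre lies inside the cortical ribbon receives the value of the
#' nearest valid vertex; all other voxels are 0.  "Nearest" is by
#' point-to-segment distance to the vertex's white->pial segment; a voxel
#' is inside the ribbon if the depth coordinate t of that segment lies in
#' [0, 1] and the lateral (perpendicular) distance is at most
#' \code{lateralMaxMm}.  Voxels equidistant to two vertices take the lower
#' vertex index (deterministic tie-break).
#'
#' @param overlay a \code{\linkS4class{VertexOverlay}} (e.g. Q); invalid
#'   vertices contribute nothing.
#' @param model a \code{\linkS4class{CorticalSurfaceModel}} in the same
#'   world frame as \code{ref}.
#' @param ref a \code{\linkS4class{QuantitativeVolume}} defining the output
#'   grid.
#' @param lateralMaxMm maximum lateral distance from a segment for a voxel
#'   to be claimed (mm); default the mean white-mesh edge length.
#' @return A \code{\linkS4class{QuantitativeVolume}} of the overlay's kind
#'   \code{"Q"} semantics: overlay values inside the ribbon, 0 elsewhere.
#' @export
projectOverlayToVolume <- function(overlay, model, ref,
                                   lateralMaxMm = NULL) {
  d <- dim(ref@data)
  if (is.null(lateralMaxMm)) lateralMaxMm <- .meanEdgeLength(model)
  use <- which(overlay@valid)
  out <- array(0, d)
  if (!length(use))
    return(QuantitativeVolume(out, ref@affine, "Q"))

  ## candidate voxels: bounding box of both surfaces plus one voxel margin
  allv <- rbind(model@whiteVertices[use, , drop = FALSE],
                model@pialVertices[use, , drop = FALSE])
  vox <- .worldToVoxel(ref@affine, allv)
  pad <- 1 + ceiling(lateralMaxMm / min(voxelSizes(ref@affine)))
  lo <- pmax(floor(apply(vox, 2, min)) - pad, 0)
  hi <- pmin(ceiling(apply(vox, 2, max)) + pad, d - 1)
  if (any(hi < lo))
    return(QuantitativeVolume(out, ref@affine, "Q"))
  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  X <- .voxelToWorld(ref@affine, idx)
  nv <- nrow(X)
  bestD2 <- rep(Inf, nv)
  bestT <- rep(NA_real_, nv)
  bestVal <- rep(0, nv)
  for (v in use) {
    w <- model@whiteVertices[v, ]
    u <- model@pialVertices[v, ] - w
    uu <- sum(u^2)
    dx <- X[, 1] - w[1]; dy <- X[, 2] - w[2]; dz <- X[, 3] - w[3]
    t <- (dx * u[1] + dy * u[2] + dz * u[3]) / uu
    tc <- pmin(pmax(t, 0), 1)
    d2 <- (dx - tc * u[1])^2 + (dy - tc * u[2])^2 + (dz - tc * u[3])^2
    better <- d2 < bestD2          # strict: ties keep the lower index
    bestD2[better] <- d2[better]
    bestT[better] <- t[better]
    bestVal[better] <- overlay@values[v]
  }
  inRibbon <- is.finite(bestD2) & bestT >= 0 & bestT <= 1 &
    sqrt(bestD2) <= lateralMaxMm
  lin <- idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3]) + 1
  out[lin[inRibbon]] <- bestVal[inRibbon]
  QuantitativeVolume(out, ref@affine, "Q")
}

#' Quotient filter of a projected Q volume
#'
#' Ribbon voxels (Q > 0) become \code{Q0 / Q}, high where Q is below the
#' threshold Q0; quotient values above the cap (very low Q, typically
#' medial-wall/offset-only vertices) are excluded, i.e. set to 0.
#' Non-ribbon voxels stay 0.
#'
#' @param qvol projected Q volume (non-negative; 0 outside the ribbon).
#' @param cfg a \code{\linkS4class{QRConfig}}.
#' @return filtered \code{\linkS4class{QuantitativeVolume}} (kind
#'   \code{"Q"}).
#' @export
quotientFilter <- function(qvol, cfg = qrConfig()) {
  q <- qvol@data
  out <- ifelse(q > 0, cfg@q0 / q, 0)
  out[out > cfg@quotientCap] <- 0
  QuantitativeVolume(array(out, dim(q)), qvol@affine, "Q")
}

#' Smooth and offset the filtered quotient into the R map
#'
#' \code{R = G_sigma(filtered) + rOffset} with a volumetric Gaussian in mm
#' (sigma 3 mm by default); R >= 1 everywhere and approximately 1 in
#' normal tissue.
#'
#' @param filtered output of \code{\link{quotientFilter}}.
#' @param cfg a \code{\linkS4class{QRConfig}}.
#' @return An R \code{\linkS4class{QuantitativeVolume}}.
#' @export
makeRMap <- function(filtered, cfg = qrConfig()) {
  sm <- gaussianSmooth3d(filtered@data, cfg@smoothSigmaMm,
                         voxelSizes(filtered@affine))
  QuantitativeVolume(sm + cfg@rOffset, filtered@affine, "R")
}

#' Run the full Q -> R chain for the unsmoothed and smoothed map triplets
#'
#' Executes four-position sampling, vertex SDs, Q, projection, quotient
#' filtering and R-map smoothing once per input triplet: the original qMRI
#' maps give R_u, the compartmentally smoothed maps give R_s.
#'
#' @param mapsOriginal,mapsSmoothed named lists with elements \code{t1},
#'   \code{t2}, \code{pd} on one grid.
#' @param model a \code{\linkS4class{CorticalSurfaceModel}}.
#' @param thickness per-vertex thickness overlay or vector (mm); defaults
#'   to the model's thickness.
#' @param ref reference grid volume; defaults to \code{mapsOriginal$t1}.
#' @param cfg a \code{\linkS4class{QRConfig}}.
#' @param bands,step sampling bands and layer resolution (see
#'   \code{\link{fourPositionValues}}).
#' @return list with \code{rU}, \code{rS} (R maps), \code{qU}, \code{qS}
#'   (Q overlays) and \code{filteredU}, \code{filteredS} (quotient
#'   volumes).
#' @export
computeRPair <- function(mapsOriginal, mapsSmoothed, model,
                         thickness = NULL, ref = NULL, cfg = qrConfig(),
                         bands = .DEFAULT_BANDS, step = 0.01) {
  if (is.null(thickness)) thickness <- model@thickness
  if (is.null(ref)) ref <- mapsOriginal$t1
  chain <- function(maps) {
    sds <- sdOverlays(maps[c("t1", "t2", "pd")], model, bands = bands,
                      step = step)
    q <- computeQ(sds$t1, sds$t2, sds$pd, thickness, cfg)
    qvol <- projectOverlayToVolume(q, model, ref)
    filt <- quotientFilter(qvol, cfg)
    list(q = q, filtered = filt, r = makeRMap(filt, cfg))
  }
  u <- chain(mapsOriginal)
  s <- chain(mapsSmoothed)
  list(rU = u$r, rS = s$r, qU = u$q, qS = s$q,
       filteredU = u$filtered, filteredS = s$filtered)
}
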