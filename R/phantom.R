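## Digital cortical phantom: analytic ground-truth parameter volumes,
## tissue labels and white/pial surfaces for a flat cortical slab or a
## spherical-shell cortex, with an optional focal lesion (junction
## blurring, cortical thickening, subcortical T2 increase) and simulated
## raw acquisitions with Rician noise.  Everything is derived from a small
## analytic geometry description, so re-generation with the same
## specification and seed is bit-identical.

#' TissueParams: per-class relaxation times and proton density
#'
#' @slot table data.frame with rows \code{wm}, \code{gm}, \code{csf} and
#'   columns \code{t1}, \code{t2}, \code{t2star} (ms) and \code{pd} (pu).
#' @exportClass TissueParams
setClass("TissueParams", slots = c(table = "data.frame"))

setValidity("TissueParams", function(object) {
  msgs <- character()
  if (!all(c("wm", "gm", "csf") %in% rownames(object@table)))
    msgs <- c(msgs, "table must have rows wm, gm, csf")
  if (!all(c("t1", "t2", "t2star", "pd") %in% colnames(object@table)))
    msgs <- c(msgs, "table must have columns t1, t2, t2star, pd")
  else if (any(as.matrix(object@table[, c("t1", "t2", "t2star", "pd")]) <= 0))
    msgs <- c(msgs, "tissue parameters must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TissueParams-class
#' @param wm,gm,csf named vectors with entries \code{t1}, \code{t2},
#'   \code{t2star} (ms) and \code{pd} (pu).  Defaults are
#'   literature-plausible 3 T values; note GM T1 sits inside the
#'   1200-1600 ms range that motivates the 2000 ms CSF-exclusion
#'   threshold, and CSF T2 far exceeds the 300 ms threshold.
#' @return A \code{TissueParams}.
#' @export
tissueParams <- function(wm = c(t1 = 900, t2 = 70, t2star = 50, pd = 69),
                         gm = c(t1 = 1400, t2 = 90, t2star = 60, pd = 83),
                         csf = c(t1 = 4000, t2 = 2000, t2star = 200,
                                 pd = 100)) {
  tab <- as.data.frame(rbind(wm = wm, gm = gm, csf = csf))
  new("TissueParams", table = tab)
}

#' LesionSpec: a focal cortical dysplasia model
#'
#' Models the three imaging hallmarks inside a tapered circular footprint:
#' the sharp WM/cortex parameter transition is replaced by a sigmoid of
#' width \code{blurWidth} (junction blurring), the pial surface is
#' displaced outward by \code{thickeningDelta} (cortical thickening), and
#' subcortical WM T2 is raised by \code{subcorticalT2Delta}.  All three
#' effects taper smoothly to zero at the footprint rim.
#'
#' @slot center world coordinates (mm) of the lesion centre on the
#'   WM/cortex junction surface.
#' @slot radius footprint radius (mm).
#' @slot blurWidth logistic scale (mm) of the blurred junction at the
#'   lesion centre; 0 keeps the sharp step.
#' @slot thickeningDelta added cortical thickness at the centre (mm).
#' @slot subcorticalT2Delta added subcortical WM T2 at the junction (ms),
#'   decaying into depth.
#' @slot side hemisphere (\code{"left"}/\code{"right"}).
#' @exportClass LesionSpec
setClass("LesionSpec",
         slots = c(center = "numeric", radius = "numeric",
                   blurWidth = "numeric", thickeningDelta = "numeric",
                   subcorticalT2Delta = "numeric", side = "character"))

setValidity("LesionSpec", function(object) {
  msgs <- character()
  if (object@radius <= 0) msgs <- c(msgs, "radius must be positive")
  if (object@blurWidth < 0) msgs <- c(msgs, "blurWidth must be >= 0")
  if (object@thickeningDelta < 0)
    msgs <- c(msgs, "thickeningDelta must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname LesionSpec-class
#' @param center,radius,blurWidth,thickeningDelta,subcorticalT2Delta,side
#'   see the class slots; defaults give a moderate lesion in the right
#'   hemisphere.
#' @return A \code{LesionSpec}.
#' @export
lesionSpec <- function(center = c(8, 0, 0), radius = 8, blurWidth = 2,
                       thickeningDelta = 1.5, subcorticalT2Delta = 30,
                       side = NULL) {
  if (is.null(side)) side <- if (center[1] >= 0) "right" else "left"
  new("LesionSpec", center = as.double(center), radius = radius,
      blurWidth = blurWidth, thickeningDelta = thickeningDelta,
      subcorticalT2Delta = subcorticalT2Delta, side = side)
}

#' PhantomDataset: ground truth, geometry and simulated acquisitions
#'
#' @slot truth named list of ground-truth
#'   \code{\linkS4class{QuantitativeVolume}}s (\code{t1}, \code{t2},
#'   \code{t2star}, \code{pd}).
#' @slot labels integer array: 1 = WM, 2 = GM, 3 = CSF.
#' @slot surface the analytic \code{\linkS4class{CorticalSurfaceModel}}.
#' @slot wmMask logical array (labels == WM).
#' @slot affine the common 4x4 voxel-to-world affine.
#' @slot tissue a \code{\linkS4class{TissueParams}}.
#' @slot lesion \code{NULL} or a \code{\linkS4class{LesionSpec}}.
#' @slot roi \code{NULL} or the ground-truth lesion
#'   \code{\linkS4class{RoiSpec}} at the lesion centre.
#' @slot fields list of true bias fields (\code{b1}, \code{rcp}) once
#'   acquisitions are simulated.
#' @slot acquisitions list of simulated raw volumes (see
#'   \code{\link{simulateAcquisitions}}).
#' @slot seed RNG seed of the simulated acquisitions (NA before
#'   simulation).
#' @slot geometry internal analytic geometry description.
#' @exportClass PhantomDataset
setClass("PhantomDataset",
         slots = c(truth = "list", labels = "array", surface =
                     "CorticalSurfaceModel", wmMask = "array",
                   affine = "matrix", tissue = "TissueParams",
                   lesion = "ANY", roi = "ANY", fields = "list",
                   acquisitions = "list", seed = "numeric",
                   geometry = "list"))

setMethod("show", "PhantomDataset", function(object) {
  d <- dim(object@labels)
  cat(sprintf("PhantomDataset (%s): %d x %d x %d grid, %d vertices\n",
              object@geometry$type, d[1], d[2], d[3],
              nVertices(object@surface)))
  cat(sprintf("  lesion: %s\n",
              if (is.null(object@lesion)) "none"
              else sprintf("r %g mm, blur %g mm, thickening %g mm, T2 +%g ms",
                           object@lesion@radius, object@lesion@blurWidth,
                           object@lesion@thickeningDelta,
                           object@lesion@subcorticalT2Delta)))
  cat(sprintf("  acquisitions: %s\n",
              if (length(object@acquisitions))
                sprintf("simulated (seed %g)", object@seed) else "none"))
  invisible(object)
})

## lesion taper: 1 at the centre, smoothly 0 at the rim
.lesionTaper <- function(d, radius) {
  tau <- 0.5 * (1 + cos(pi * pmin(d / radius, 1)))
  tau[d >= radius] <- 0
  tau
}

## Evaluate signed junction depth s (mm), lesion taper tau and local
## thickness at arbitrary world points, for either geometry.
.phantomCoords <- function(geometry, lesion, pts) {
  if (geometry$type == "slab") {
    s <- pts[, 3] - geometry$junctionZ
    if (is.null(lesion)) tau <- numeric(nrow(pts))
    else {
      d <- sqrt((pts[, 1] - lesion@center[1])^2 +
                  (pts[, 2] - lesion@center[2])^2)
      tau <- .lesionTaper(d, lesion@radius)
    }
  } else {
    r <- sqrt(rowSums(pts^2))
    s <- r - geometry$rWhite
    if (is.null(lesion)) tau <- numeric(nrow(pts))
    else {
      dir <- lesion@center / sqrt(sum(lesion@center^2))
      cosang <- pmin(pmax((pts %*% dir) / pmax(r, 1e-9), -1), 1)
      d <- geometry$rWhite * acos(cosang)
      tau <- .lesionTaper(as.numeric(d), lesion@radius)
    }
  }
  thLocal <- geometry$thickness +
    (if (is.null(lesion)) 0 else lesion@thickeningDelta) * tau
  list(s = as.numeric(s), tau = as.numeric(tau), thLocal = thLocal)
}

## Ground-truth parameter value at depth s for one parameter, with the
## WM->GM transition blurred by the lesion where tau > 0.
.phantomParam <- function(co, wmv, gmv, csfv, lesion, isT2 = FALSE) {
  sEff <- if (is.null(lesion)) numeric(length(co$s))
  else lesion@blurWidth * co$tau
  h <- ifelse(sEff > 1e-9, stats::plogis(co$s / pmax(sEff, 1e-9)),
              as.numeric(co$s >= 0))
  v <- wmv + (gmv - wmv) * h
  if (isT2 && !is.null(lesion) && lesion@subcorticalT2Delta != 0) {
    sub <- co$s < 0
    v[sub] <- v[sub] + lesion@subcorticalT2Delta * co$tau[sub] *
      exp(co$s[sub] / 3)
  }
  v[co$s >= co$thLocal] <- csfv
  v
}

.phantomTruth <- function(geometry, tissue, lesion, affine, gridShape) {
  idx <- as.matrix(expand.grid(i = 0:(gridShape[1] - 1),
                               j = 0:(gridShape[2] - 1),
                               k = 0:(gridShape[3] - 1)))
  pts <- .voxelToWorld(affine, idx)
  co <- .phantomCoords(geometry, lesion, pts)
  tab <- tissue@table
  mk <- function(param, kind) {
    v <- .phantomParam(co, tab["wm", param], tab["gm", param],
                       tab["csf", param], lesion, isT2 = param == "t2")
    QuantitativeVolume(array(v, gridShape), affine, kind)
  }
  labels <- ifelse(co$s < 0, 1L, ifelse(co$s < co$thLocal, 2L, 3L))
  list(truth = list(t1 = mk("t1", "T1"), t2 = mk("t2", "T2"),
                    t2star = mk("t2star", "T2star"), pd = mk("pd", "PD")),
       labels = array(labels, gridShape))
}

.phantomSurface <- function(geometry, lesion) {
  if (geometry$type == "slab") {
    g <- expand.grid(x = geometry$meshX, y = geometry$meshY)
    base <- cbind(g$x, g$y, geometry$junctionZ)
    co <- .phantomCoords(geometry, lesion, base)
    white <- base
    pial <- cbind(g$x, g$y, geometry$junctionZ + co$thLocal)
    nx <- length(geometry$meshX)
    ny <- length(geometry$meshY)
    vid <- function(ix, iy) (iy - 1L) * nx + ix
    faces <- NULL
    ix <- rep(seq_len(nx - 1L), ny - 1L)
    iy <- rep(seq_len(ny - 1L), each = nx - 1L)
    a <- vid(ix, iy); b <- vid(ix + 1L, iy)
    cc <- vid(ix + 1L, iy + 1L); dd <- vid(ix, iy + 1L)
    faces <- rbind(cbind(a, b, cc), cbind(a, cc, dd))
    border <- g$x == min(geometry$meshX) | g$x == max(geometry$meshX) |
      g$y == min(geometry$meshY) | g$y == max(geometry$meshY)
    CorticalSurfaceModel(white, pial, faces, co$thLocal, !border)
  } else {
    ico <- .icosphere(geometry$subdivisions)
    base <- ico$vertices * geometry$rWhite
    co <- .phantomCoords(geometry, lesion, base)
    white <- base
    pial <- ico$vertices * (geometry$rWhite + co$thLocal)
    CorticalSurfaceModel(white, pial, ico$faces, co$thLocal,
                         rep(TRUE, nrow(base)))
  }
}

## icosphere: subdivided icosahedron projected to the unit sphere
.icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  list(vertices = v, faces = f)
}

#' Build a flat-slab cortical phantom
#'
#' A flat cortical sheet: WM below the junction plane, a GM ribbon of the
#' stated thickness, CSF above.  The white and pial surfaces are flat
#' triangulated planes with exact vertex correspondence; the thickness
#' overlay is constant.  The world origin sits at the grid centre, so
#' \code{x = 0} is the midsagittal plane for contralateral mirroring.
#'
#' @param gridShape grid dimensions (voxels).
#' @param voxelMm voxel sizes (mm).
#' @param cortexThicknessMm ribbon thickness (mm); must be at least one
#'   voxel.
#' @param tissue a \code{\linkS4class{TissueParams}}.
#' @param meshSpacingMm lateral vertex spacing of the surface mesh (mm).
#' @param junctionZ z-position (mm) of the WM/cortex junction plane.
#' @param meshMarginMm lateral margin between the mesh and the grid edge
#'   (mm), keeping all depth bands inside the grid.
#' @return A \code{\linkS4class{PhantomDataset}} (acquisitions empty).
#' @export
buildSlabPhantom <- function(gridShape = c(44, 44, 40),
                             voxelMm = c(1, 1, 1),
                             cortexThicknessMm = 2.5,
                             tissue = tissueParams(),
                             meshSpacingMm = 2, junctionZ = 0,
                             meshMarginMm = 4) {
  if (cortexThicknessMm < max(voxelMm))
    stop("cortical ribbon thinner than one voxel", call. = FALSE)
  affine <- .centeredAffine(gridShape, voxelMm)
  halfX <- (gridShape[1] - 1) / 2 * voxelMm[1]
  halfY <- (gridShape[2] - 1) / 2 * voxelMm[2]
  meshX <- seq(-(halfX - meshMarginMm), halfX - meshMarginMm,
               by = meshSpacingMm)
  meshY <- seq(-(halfY - meshMarginMm), halfY - meshMarginMm,
               by = meshSpacingMm)
  geometry <- list(type = "slab", junctionZ = junctionZ,
                   thickness = cortexThicknessMm, meshX = meshX,
                   meshY = meshY, gridShape = gridShape,
                   voxelMm = voxelMm)
  tr <- .phantomTruth(geometry, tissue, NULL, affine, gridShape)
  new("PhantomDataset", truth = tr$truth, labels = tr$labels,
      surface = .phantomSurface(geometry, NULL),
      wmMask = tr$labels == 1L, affine = affine, tissue = tissue,
      lesion = NULL, roi = NULL, fields = list(), acquisitions = list(),
      seed = NA_real_, geometry = geometry)
}

#' Build a spherical-shell cortical phantom
#'
#' A spherical cortex: white sphere inside pial sphere, icosphere meshes
#' with exact radial vertex correspondence, thickness = rPial - rWhite.
#' The curved geometry exercises the mirror/normal handling and the
#' x-reflection of contralateral ROIs (the phantom is symmetric about
#' \code{x = 0}).
#'
#' @param gridShape grid dimensions (voxels).
#' @param voxelMm voxel sizes (mm).
#' @param radii named vector \code{c(white = ..., pial = ...)} (mm),
#'   \code{white < pial}, pial fitting inside the grid.
#' @param tissue a \code{\linkS4class{TissueParams}}.
#' @param subdivisions icosphere subdivision level (default 3, 642
#'   vertices).
#' @return A \code{\linkS4class{PhantomDataset}}.
#' @export
buildShellPhantom <- function(gridShape = c(56, 56, 56),
                              voxelMm = c(1, 1, 1),
                              radii = c(white = 15, pial = 17.5),
                              tissue = tissueParams(),
                              subdivisions = 3L) {
  if (radii["pial"] <= radii["white"])
    stop("radii inverted: pial radius must exceed white radius",
         call. = FALSE)
  if (radii["pial"] >= min((gridShape - 1) / 2 * voxelMm))
    stop("outer radius does not fit in the grid", call. = FALSE)
  affine <- .centeredAffine(gridShape, voxelMm)
  geometry <- list(type = "shell", rWhite = unname(radii["white"]),
                   thickness = unname(radii["pial"] - radii["white"]),
                   subdivisions = as.integer(subdivisions),
                   gridShape = gridShape, voxelMm = voxelMm)
  tr <- .phantomTruth(geometry, tissue, NULL, affine, gridShape)
  new("PhantomDataset", truth = tr$truth, labels = tr$labels,
      surface = .phantomSurface(geometry, NULL),
      wmMask = tr$labels == 1L, affine = affine, tissue = tissue,
      lesion = NULL, roi = NULL, fields = list(), acquisitions = list(),
      seed = NA_real_, geometry = geometry)
}

#' Insert a focal lesion into a phantom
#'
#' Rebuilds the ground-truth volumes, labels and surfaces with the lesion
#' applied: sigmoid junction blurring, tapered pial displacement (the
#' thickness overlay is updated consistently) and a subcortical T2
#' increase.  The ground-truth lesion ROI (2 x 2 x 1 mm at the lesion
#' centre) is recorded.  Simulated acquisitions are cleared and must be
#' re-simulated.
#'
#' @param ph a \code{\linkS4class{PhantomDataset}}.
#' @param lesion a \code{\linkS4class{LesionSpec}}; for the slab geometry
#'   the centre z is snapped to the junction plane, for the shell the
#'   centre is projected onto the white sphere.
#' @return the modified \code{PhantomDataset}.
#' @export
insertLesion <- function(ph, lesion) {
  geometry <- ph@geometry
  if (geometry$type == "slab") {
    lesion@center[3] <- geometry$junctionZ
    if (abs(lesion@center[1]) > max(abs(geometry$meshX)) ||
        abs(lesion@center[2]) > max(abs(geometry$meshY)))
      stop("lesion footprint outside the cortical mesh", call. = FALSE)
  } else {
    lesion@center <- lesion@center / sqrt(sum(lesion@center^2)) *
      geometry$rWhite
  }
  gridShape <- geometry$gridShape
  tr <- .phantomTruth(geometry, ph@tissue, lesion, ph@affine, gridShape)
  ph@truth <- tr$truth
  ph@labels <- tr$labels
  ph@wmMask <- tr$labels == 1L
  ph@surface <- .phantomSurface(geometry, lesion)
  ph@lesion <- lesion
  ph@roi <- RoiSpec(lesion@center, side = lesion@side)
  ph@fields <- list()
  ph@acquisitions <- list()
  ph@seed <- NA_real_
  ph
}

## smooth multiplicative/bias ground-truth fields on the phantom grid
.phantomFields <- function(ph) {
  d <- dim(ph@labels)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  pts <- .voxelToWorld(ph@affine, idx)
  ext <- apply(abs(pts), 2, max)
  r2 <- (pts[, 1] / ext[1])^2 + (pts[, 2] / ext[2])^2 +
    (pts[, 3] / ext[3])^2
  b1 <- 1 + 0.05 * (0.5 - r2 / 1.5)          # mild transmit-field dome
  rcp <- 1 + 0.10 * pts[, 1] / ext[1] +      # tilted receive profile
    0.06 * pts[, 2] / ext[2] - 0.04 * pts[, 3] / ext[3]
  list(b1 = QuantitativeVolume(array(b1, d), ph@affine, "B1"),
       rcp = QuantitativeVolume(array(rcp, d), ph@affine, "SIGNAL"))
}

#' Simulate the raw acquisitions of a phantom
#'
#' Deterministic forward signals of every mapped sequence plus a FLAIR
#' anatomy, with Rician noise: the VFA SPGR pair (4/24 degrees, including
#' the B1-scaled true angles and T2* decay at the echo time), the B1
#' reference/prepared pair, the four-echo spin-echo T2 series, the
#' two-echo T2* pair, and the inversion-recovery FLAIR.  Receive-signal
#' volumes are modulated by the smooth receive-coil profile; the FLAIR is
#' assumed bias-corrected.  Per-volume noise sigma is the mean WM signal
#' of that volume divided by \code{snr} (so \code{snr} is the WM
#' signal-to-noise ratio of each acquisition); \code{noiseSigma} overrides
#' it with one absolute sigma for all volumes.  \code{snr = Inf} (or
#' sigma 0) gives exact forward signals.
#'
#' @param ph a \code{\linkS4class{PhantomDataset}}.
#' @param snr white-matter signal-to-noise ratio per volume (default 50).
#' @param seed RNG seed; the same phantom, seed and noise settings
#'   reproduce the acquisitions bit-identically.
#' @param noiseSigma optional absolute channel sigma applied to every
#'   volume (signal units), overriding \code{snr}.
#' @param noiseType \code{"rician"} (magnitude data) or \code{"gaussian"}.
#' @param flairScale overall FLAIR intensity scale (arbitrary units).
#' @return the \code{PhantomDataset} with \code{acquisitions} and
#'   \code{fields} filled.
#' @export
simulateAcquisitions <- function(ph, snr = 50, seed = 1,
                                 noiseSigma = NULL,
                                 noiseType = "rician",
                                 flairScale = 100) {
  fields <- .phantomFields(ph)
  b1 <- fields$b1@data
  rcp <- fields$rcp@data
  t1 <- ph@truth$t1@data
  t2 <- ph@truth$t2@data
  t2s <- ph@truth$t2star@data
  pd <- ph@truth$pd@data
  vfa <- vfaParams()
  b1p <- b1Params()
  t2p <- t2SeriesParams()
  t2sp <- t2starParams()
  wm <- ph@wmMask

  noisy <- function(signal) {
    sigma <- if (!is.null(noiseSigma)) noiseSigma
    else if (is.infinite(snr)) 0 else mean(signal[wm]) / snr
    addNoise(signal, sigma, noiseType)
  }
  vol <- function(dat, kind = "SIGNAL")
    QuantitativeVolume(array(dat, dim(t1)), ph@affine, kind)

  set.seed(seed)
  spgr <- function(alpha)
    rcp * spgrSignal(pd, t1, alpha * b1, vfa@tr) * exp(-vfa@te / t2s)
  acq <- list()
  acq$spgrLow <- vol(noisy(spgr(vfa@flipAngle[1])))
  acq$spgrHigh <- vol(noisy(spgr(vfa@flipAngle[2])))
  b1ref <- rcp * pd
  acq$b1Reference <- vol(noisy(b1ref))
  acq$b1Prepared <- vol(noisy(b1ref * cos(.deg2rad(b1p@nominalBeta0 * b1))))
  acq$t2Echoes <- lapply(t2p@te, function(te)
    vol(noisy(rcp * seSignal(pd, t2, te))))
  acq$t2starEcho1 <- vol(noisy(rcp * pd * exp(-t2sp@te[1] / t2s)))
  acq$t2starEcho2 <- vol(noisy(rcp * pd * exp(-t2sp@te[2] / t2s)))
  acq$flair <- vol(noisy(flairScale * flairSignal(pd, t1, t2)))
  acq$params <- list(vfa = vfa, b1 = b1p, t2 = t2p, t2star = t2sp,
                     flair = flairParams())

  ph@acquisitions <- acq
  ph@fields <- fields
  ph@seed <- seed
  ph
}

#' Fit the full qMRI map set from simulated (or real) raw acquisitions
#'
#' Runs the complete mapping chain: B1 from the prepared/reference pair,
#' T1/M0 from the VFA pair with B1 correction, T2 from the multi-echo
#' series, T2* from the two-echo pair, the receive-coil profile from the
#' low-angle SPGR against a model signal built from the fitted maps and
#' the Fatouros pseudo-PD, and finally the PD map scaled to 100 pu over
#' the CSF reference region.
#'
#' @param acq acquisitions list as produced by
#'   \code{\link{simulateAcquisitions}}.
#' @param csfMask logical array: the PD reference region.
#' @param brainMask logical array for the RCP fit; defaults to all voxels
#'   with a valid T1 fit.
#' @param rcp optional known receive-profile volume (e.g. phantom ground
#'   truth); if supplied, estimation is skipped.
#' @param constants Fatouros constants for the RCP model signal.
#' @param b1SmoothFwhmMm FWHM (mm) of the quotient smoothing applied to
#'   the fitted B1 map before it corrects the other fits (default 8).
#'   The transmit field is spatially smooth (the mapping protocol acquires
#'   it at 4 mm resolution), so smoothing suppresses voxel noise that
#'   would otherwise dominate the T1 error; 0 disables it (e.g. for
#'   noiseless consistency checks).
#' @return named list of \code{\linkS4class{QuantitativeVolume}}s:
#'   \code{t1}, \code{t2}, \code{t2star}, \code{b1}, \code{pd}, \code{m0},
#'   \code{rcp}.
#' @export
fitQmriMaps <- function(acq, csfMask, brainMask = NULL, rcp = NULL,
                        constants = fatourosConstants(),
                        b1SmoothFwhmMm = 8) {
  b1 <- fitB1Map(acq$b1Reference, acq$b1Prepared, acq$params$b1)
  if (b1SmoothFwhmMm > 0)
    b1 <- smoothEdgePreserving(b1, fwhmMm = b1SmoothFwhmMm)
  vfa <- acq$params$vfa
  t1fit <- fitT1Vfa(acq$spgrLow, acq$spgrHigh, vfa, b1 = b1)
  t2fit <- fitT2MultiEcho(acq$t2Echoes, acq$params$t2@te)
  t2star <- fitT2StarTwoEcho(acq$t2starEcho1, acq$t2starEcho2,
                             acq$params$t2star@te)
  if (is.null(brainMask))
    brainMask <- t1fit$t1@validMask & t2star@validMask
  if (is.null(rcp)) {
    pseudo <- fatourosPseudoPd(t1fit$t1, constants)
    aTrue <- .deg2rad(vfa@flipAngle[1]) * b1@data
    e1 <- exp(-vfa@tr / t1fit$t1@data)
    model <- pseudo@data * sin(aTrue) * (1 - e1) / (1 - cos(aTrue) * e1) *
      exp(-vfa@te / t2star@data)
    modelVol <- QuantitativeVolume(array(model, dim(b1@data)),
                                   acq$spgrLow@affine, "SIGNAL")
    rcp <- estimateRcp(acq$spgrLow, modelVol, brainMask)
  }
  pd <- computePd(acq$spgrLow, t1fit$t1, t2star, b1, rcp, vfa,
                  refMask = csfMask)
  list(t1 = t1fit$t1, t2 = t2fit$t2, t2star = t2star, b1 = b1, pd = pd,
       m0 = t1fit$m0, rcp = rcp)
}
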