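#' @import methods
#' @importFrom stats rnorm sd median quantile lm.fit setNames
#' @importFrom utils write.table read.table head tail
NULL

## Recognised parameter kinds and their units
.VOL_KINDS <- c(T1 = "ms", T2 = "ms", T2star = "ms", PD = "pu",
                B1 = "dimensionless", SIGNAL = "au",
                R = "dimensionless", Q = "dimensionless",
                LABEL = "dimensionless", MASK = "dimensionless")

#' QuantitativeVolume: a 3-D scalar map with world geometry
#'
#' Container for one quantitative parameter map (T1, T2, T2*, PD, B1) or a
#' signal/derived volume (SIGNAL, Q, R).  Carries the 4x4 voxel-to-world
#' (RAS, mm) affine and a validity mask; voxels where the mask is
#' \code{FALSE} are ignored by every downstream operation.  Voxel indexing
#' is 0-based with the world position of a voxel being its centre.
#'
#' @slot data 3-D numeric array.
#' @slot affine 4x4 voxel-to-world transform (RAS, mm), invertible.
#' @slot kind one of \code{"T1"}, \code{"T2"}, \code{"T2star"}, \code{"PD"},
#'   \code{"B1"}, \code{"SIGNAL"}, \code{"R"}, \code{"Q"}, \code{"LABEL"},
#'   \code{"MASK"}.
#' @slot units unit string derived from the kind (ms, pu, au, dimensionless).
#' @slot validMask 3-D logical array, same shape as \code{data}.
#' @exportClass QuantitativeVolume
setClass("QuantitativeVolume",
         slots = c(data = "array", affine = "matrix", kind = "character",
                   units = "character", validMask = "array"))

setValidity("QuantitativeVolume", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3-D array")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msgs <- c(msgs, "affine must be 4x4")
  det <- tryCatch(det(object@affine), error = function(e) 0)
  if (!is.finite(det) || abs(det) < .Machine$double.eps)
    msgs <- c(msgs, "affine must be invertible")
  else if (any(voxelSizes(object@affine) <= 0))
    msgs <- c(msgs, "voxel sizes derived from the affine must be positive")
  if (!object@kind %in% names(.VOL_KINDS))
    msgs <- c(msgs, sprintf("unknown kind '%s'", object@kind))
  if (!identical(dim(object@validMask), dim(object@data)))
    msgs <- c(msgs, "validMask must have the shape of data")
  if (!is.logical(object@validMask))
    msgs <- c(msgs, "validMask must be logical")
  if (object@kind %in% c("T1", "T2", "T2star")) {
    v <- object@data[object@validMask]
    if (length(v) && any(v < 0, na.rm = TRUE))
      msgs <- c(msgs, sprintf("%s values must be non-negative where valid",
                              object@kind))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a QuantitativeVolume
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world (RAS, mm) affine; voxel index 0 maps to
#'   the centre of the first voxel.
#' @param kind parameter kind (see \code{\linkS4class{QuantitativeVolume}}).
#' @param validMask optional logical array; defaults to \code{is.finite(data)}.
#' @return A \code{QuantitativeVolume}.
#' @examples
#' v <- QuantitativeVolume(array(1000, c(4, 4, 4)), diag(4), "T1")
#' volKind(v)
#' @export
QuantitativeVolume <- function(data, affine, kind,
                               validMask = NULL) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (is.null(validMask)) validMask <- is.finite(data)
  validMask <- array(as.logical(validMask), dim(data))
  new("QuantitativeVolume", data = data, affine = affine, kind = kind,
      units = unname(.VOL_KINDS[kind]), validMask = validMask)
}

#' @describeIn QuantitativeVolume raw data array accessor
#' @param x,vol a \code{QuantitativeVolume}
#' @export
volData <- function(x) x@data

#' @describeIn QuantitativeVolume affine accessor
#' @export
volAffine <- function(x) x@affine

#' @describeIn QuantitativeVolume kind accessor
#' @export
volKind <- function(x) x@kind

#' @describeIn QuantitativeVolume units accessor
#' @export
volUnits <- function(x) x@units

#' @describeIn QuantitativeVolume validity-mask accessor
#' @export
validMask <- function(x) x@validMask

#' @describeIn QuantitativeVolume replace the data array (mask re-derived
#'   unless given)
#' @param value replacement array
#' @export
`volData<-` <- function(x, value) {
  x@data <- array(as.double(value), dim(x@data))
  x@validMask <- x@validMask & is.finite(x@data)
  validObject(x)
  x
}

#' Voxel sizes implied by an affine
#'
#' Column norms of the 3x3 rotation/scaling block, in mm.
#' @param affine 4x4 affine or a \code{QuantitativeVolume}.
#' @return length-3 numeric vector (mm).
#' @export
voxelSizes <- function(affine) {
  if (is(affine, "QuantitativeVolume")) affine <- affine@affine
  sqrt(colSums(affine[1:3, 1:3]^2))
}

setMethod("show", "QuantitativeVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("QuantitativeVolume [%s, %s]\n", object@kind, object@units))
  cat(sprintf("  grid: %d x %d x %d, voxels %s mm\n", d[1], d[2], d[3],
              paste(signif(voxelSizes(object@affine), 4), collapse = " x ")))
  cat(sprintf("  valid voxels: %d / %d\n", sum(object@validMask), prod(d)))
  v <- object@data[object@validMask]
  if (length(v))
    cat(sprintf("  range (valid): [%g, %g]\n", min(v), max(v)))
  invisible(object)
})

setMethod("dim", "QuantitativeVolume", function(x) dim(x@data))

#' CorticalSurfaceModel: paired white/pial meshes with per-vertex measures
#'
#' White and pial triangle meshes with 1:1 vertex correspondence (shared
#' faces), a per-vertex cortical thickness (mm) and a cortex-label flag
#' which is \code{FALSE} on the medial wall or wherever cortical values
#' cannot be read.  Coordinates are world RAS in mm, the same frame as
#' \code{\linkS4class{QuantitativeVolume}}.
#'
#' @slot whiteVertices N x 3 matrix, white (WM/cortex junction) surface.
#' @slot pialVertices N x 3 matrix, pial surface.
#' @slot faces M x 3 integer matrix of 1-based vertex indices, shared.
#' @slot thickness length-N numeric, cortical thickness (mm).
#' @slot cortexLabel length-N logical.
#' @exportClass CorticalSurfaceModel
setClass("CorticalSurfaceModel",
         slots = c(whiteVertices = "matrix", pialVertices = "matrix",
                   faces = "matrix", thickness = "numeric",
                   cortexLabel = "logical"))

setValidity("CorticalSurfaceModel", function(object) {
  msgs <- character()
  n <- nrow(object@whiteVertices)
  if (ncol(object@whiteVertices) != 3L || ncol(object@pialVertices) != 3L)
    msgs <- c(msgs, "vertex matrices must be N x 3")
  if (nrow(object@pialVertices) != n)
    msgs <- c(msgs, "white and pial vertex counts differ")
  if (length(object@thickness) != n || length(object@cortexLabel) != n)
    msgs <- c(msgs, "thickness and cortexLabel must have one entry per vertex")
  if (ncol(object@faces) != 3L)
    msgs <- c(msgs, "faces must be M x 3")
  if (nrow(object@faces) &&
      (min(object@faces) < 1L || max(object@faces) > n))
    msgs <- c(msgs, "face indices out of range")
  if (any(object@thickness < 0, na.rm = TRUE))
    msgs <- c(msgs, "thickness must be non-negative")
  if (any(object@cortexLabel & !(object@thickness > 0), na.rm = TRUE))
    msgs <- c(msgs, "thickness must be positive wherever cortexLabel is TRUE")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CorticalSurfaceModel
#'
#' @param whiteVertices,pialVertices N x 3 world coordinates (mm).
#' @param faces M x 3 matrix of 1-based triangle vertex indices.
#' @param thickness per-vertex cortical thickness (mm).
#' @param cortexLabel per-vertex logical; \code{FALSE} marks the medial wall.
#' @return A \code{CorticalSurfaceModel}.
#' @export
CorticalSurfaceModel <- function(whiteVertices, pialVertices, faces,
                                 thickness, cortexLabel = NULL) {
  whiteVertices <- as.matrix(whiteVertices)
  pialVertices <- as.matrix(pialVertices)
  storage.mode(whiteVertices) <- "double"
  storage.mode(pialVertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(whiteVertices) <- NULL
  dimnames(pialVertices) <- NULL
  dimnames(faces) <- NULL
  thickness <- unname(thickness)
  if (!is.null(cortexLabel)) cortexLabel <- unname(cortexLabel)
  if (is.null(cortexLabel)) cortexLabel <- rep(TRUE, nrow(whiteVertices))
  new("CorticalSurfaceModel", whiteVertices = whiteVertices,
      pialVertices = pialVertices, faces = faces,
      thickness = as.double(thickness), cortexLabel = as.logical(cortexLabel))
}

#' @describeIn CorticalSurfaceModel number of vertices
#' @param x a \code{CorticalSurfaceModel}
#' @export
nVertices <- function(x) nrow(x@whiteVertices)

#' @describeIn CorticalSurfaceModel white-surface coordinates
#' @export
whiteVertices <- function(x) x@whiteVertices

#' @describeIn CorticalSurfaceModel pial-surface coordinates
#' @export
pialVertices <- function(x) x@pialVertices

#' @describeIn CorticalSurfaceModel shared triangle faces (1-based)
#' @export
surfaceFaces <- function(x) x@faces

#' @describeIn CorticalSurfaceModel per-vertex thickness (mm)
#' @export
thicknessValues <- function(x) x@thickness

#' @describeIn CorticalSurfaceModel per-vertex cortex flag
#' @export
cortexLabel <- function(x) x@cortexLabel

setMethod("show", "CorticalSurfaceModel", function(object) {
  cat(sprintf("CorticalSurfaceModel: %d vertices, %d faces\n",
              nVertices(object), nrow(object@faces)))
  cat(sprintf("  cortex vertices: %d (%.1f%%)\n", sum(object@cortexLabel),
              100 * mean(object@cortexLabel)))
  th <- object@thickness[object@cortexLabel]
  if (length(th))
    cat(sprintf("  thickness (cortex): median %.2f mm, range [%.2f, %.2f]\n",
                median(th), min(th), max(th)))
  invisible(object)
})

#' VertexOverlay: a per-vertex scalar field
#'
#' Scalar values aligned to the vertices of one surface model, with a
#' per-vertex validity flag.  Invalid vertices are excluded from all
#' statistics and from surface-to-volume projection.
#'
#' @slot values numeric vector, one entry per vertex.
#' @slot valid logical vector, same length.
#' @slot name short field name (e.g. \code{"SD_T1"}, \code{"Q"}).
#' @exportClass VertexOverlay
setClass("VertexOverlay",
         slots = c(values = "numeric", valid = "logical", name = "character"))

setValidity("VertexOverlay", function(object) {
  if (length(object@values) != length(object@valid))
    "values and valid must have equal length" else TRUE
})

#' Construct a VertexOverlay
#' @param values per-vertex scalars.
#' @param valid per-vertex validity; defaults to \code{is.finite(values)}.
#' @param name field name.
#' @return A \code{VertexOverlay}.
#' @export
VertexOverlay <- function(values, valid = NULL, name = "overlay") {
  values <- as.double(values)
  if (is.null(valid)) valid <- is.finite(values)
  new("VertexOverlay", values = values, valid = as.logical(valid),
      name = name)
}

#' @describeIn VertexOverlay values accessor
#' @param x a \code{VertexOverlay}
#' @export
overlayValues <- function(x) x@values

#' @describeIn VertexOverlay validity accessor
#' @export
overlayValid <- function(x) x@valid

setMethod("show", "VertexOverlay", function(object) {
  cat(sprintf("VertexOverlay '%s': %d vertices, %d valid\n", object@name,
              length(object@values), sum(object@valid)))
  v <- object@values[object@valid]
  if (length(v))
    cat(sprintf("  range (valid): [%g, %g], median %g\n",
                min(v), max(v), median(v)))
  invisible(object)
})

setMethod("length", "VertexOverlay", function(x) length(x@values))

#' RoiSpec: an axis-aligned box region of interest
#'
#' World-space ROI used for signal readout, by default 2 x 2 x 1 mm.
#' Membership is by voxel centre with half-open bounds
#' \code{[centre - dim/2, centre + dim/2)}.
#'
#' @slot center length-3 world coordinates (mm).
#' @slot dims length-3 box extents (mm), strictly positive.
#' @slot side \code{"left"} or \code{"right"}.
#' @exportClass RoiSpec
setClass("RoiSpec",
         slots = c(center = "numeric", dims = "numeric", side = "character"))

setValidity("RoiSpec", function(object) {
  msgs <- character()
  if (length(object@center) != 3L) msgs <- c(msgs, "center must be length 3")
  if (length(object@dims) != 3L || any(object@dims <= 0))
    msgs <- c(msgs, "dims must be 3 strictly positive extents")
  if (!object@side %in% c("left", "right"))
    msgs <- c(msgs, "side must be 'left' or 'right'")
  if (length(msgs)) msgs else TRUE
})

#' Construct an RoiSpec
#' @param center world coordinates (mm).
#' @param dims box extents (mm); default the 2 x 2 x 1 mm readout box.
#' @param side hemisphere label.
#' @return An \code{RoiSpec}.
#' @export
RoiSpec <- function(center, dims = c(2, 2, 1), side = "right") {
  new("RoiSpec", center = as.double(center), dims = as.double(dims),
      side = side)
}

setMethod("show", "RoiSpec", function(object) {
  cat(sprintf("RoiSpec (%s): centre (%g, %g, %g) mm, dims %g x %g x %g mm\n",
              object@side, object@center[1], object@center[2],
              object@center[3], object@dims[1], object@dims[2],
              object@dims[3]))
  invisible(object)
})

## ---- internal grid helpers -------------------------------------------------

## world -> continuous 0-based voxel coordinates (points as N x 3)
.worldToVoxel <- function(affine, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  v <- solve(affine) %*% pts
  t(v[1:3, , drop = FALSE])
}

## 0-based voxel coordinates -> world
.voxelToWorld <- function(affine, vox) {
  vox <- rbind(t(as.matrix(vox)), 1)
  w <- affine %*% vox
  t(w[1:3, , drop = FALSE])
}

## default centred affine used by the phantom: world origin mid-grid
.centeredAffine <- function(gridShape, voxelMm) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(voxelMm, 3)
  a[1:3, 4] <- -(gridShape - 1) / 2 * voxelMm
  a
}

.sameGrid <- function(a, b, tol = 1e-6) {
  identical(dim(a@data), dim(b@data)) &&
    max(abs(a@affine - b@affine)) < tol
}

.stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!.sameGrid(a, b))
    stop(sprintf("grid mismatch: %s must share grid and affine", what),
         call. = FALSE)
  invisible(TRUE)
}
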