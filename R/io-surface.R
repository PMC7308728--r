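## Surface and overlay I/O: FreeSurfer binary surface/curv/label files and
## GIFTI (.surf.gii / .func.gii / .shape.gii).  Minimal, self-contained
## readers/writers for the subset of each format the pipeline touches.
## FreeSurfer binaries are big-endian; GIFTI data arrays are written
## little-endian, base64-encoded, row-major.

.FS_TRIANGLE_MAGIC <- 16777214L  # int24 -2
.FS_CURV_MAGIC <- 16777215L      # int24 -1

.readInt24 <- function(con) {
  b <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  b[1] * 65536L + b[2] * 256L + b[3]
}

.writeInt24 <- function(con, value) {
  writeBin(as.integer(c(value %/% 65536, (value %/% 256) %% 256,
                        value %% 256)), con, size = 1)
}

#' Read a FreeSurfer binary triangle surface
#'
#' @param path path to a surface file (e.g. \code{lh.white}).
#' @param crasOffset length-3 translation (mm) added to the stored
#'   coordinates to move them into scanner RAS.  FreeSurfer stores surfaces
#'   in a volume-centred ("tkrRAS") frame; pass the volume's centre offset
#'   to recover world coordinates.  Phantom-written surfaces use offset 0.
#' @return list with \code{vertices} (N x 3) and \code{faces}
#'   (M x 3, 1-based).
#' @export
readFsSurface <- function(path, crasOffset = c(0, 0, 0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .readInt24(con)
  if (magic != .FS_TRIANGLE_MAGIC)
    stop(sprintf("unknown format magic in %s", path), call. = FALSE)
  ## comment terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (length(ch) == 0) stop("truncated surface file", call. = FALSE)
    if (ch == as.raw(10) && prev == as.raw(10)) break
    prev <- ch
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  verts <- matrix(readBin(con, "numeric", nv * 3, size = 4, endian = "big"),
                  ncol = 3, byrow = TRUE)
  faces <- matrix(readBin(con, "integer", nf * 3, size = 4, endian = "big"),
                  ncol = 3, byrow = TRUE) + 1L
  verts <- sweep(verts, 2, as.double(crasOffset), "+")
  list(vertices = verts, faces = faces)
}

#' Write a FreeSurfer binary triangle surface
#' @param vertices N x 3 coordinates (mm).
#' @param faces M x 3 1-based triangle indices.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFsSurface <- function(vertices, faces, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  .writeInt24(con, .FS_TRIANGLE_MAGIC)
  writeBin(charToRaw("created by fcdenhance\n\n"), con)
  writeBin(as.integer(nrow(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer curvature/overlay file (new binary format)
#' @param path path to a curv-format file (e.g. \code{lh.thickness}).
#' @return numeric vector of per-vertex values.
#' @export
readFsCurv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .readInt24(con)
  if (magic != .FS_CURV_MAGIC)
    stop(sprintf("unknown format magic in %s", path), call. = FALSE)
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 1, size = 4, endian = "big")  # nfaces, unused
  vpv <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (vpv != 1L) stop("only one value per vertex is supported", call. = FALSE)
  readBin(con, "numeric", nv, size = 4, endian = "big")
}

#' Write a FreeSurfer curvature/overlay file
#' @param values per-vertex values.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFsCurv <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  .writeInt24(con, .FS_CURV_MAGIC)
  writeBin(as.integer(length(values)), con, size = 4, endian = "big")
  writeBin(0L, con, size = 4, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer ASCII label file as a logical per-vertex flag
#' @param path label file path.
#' @param nVertices total vertex count of the surface.
#' @return logical vector, \code{TRUE} for listed vertices.
#' @export
readFsLabel <- function(path, nVertices) {
  lines <- readLines(path)
  if (!grepl("^#!ascii", lines[1]))
    stop(sprintf("unknown format magic in %s", path), call. = FALSE)
  n <- as.integer(lines[2])
  flag <- rep(FALSE, nVertices)
  if (n > 0) {
    tab <- read.table(text = lines[3:(2 + n)])
    flag[tab[[1]] + 1L] <- TRUE
  }
  flag
}

#' Write a FreeSurfer ASCII label file
#' @param flag logical per-vertex flag.
#' @param vertices N x 3 coordinates (written alongside indices).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFsLabel <- function(flag, vertices, path) {
  idx <- which(flag) - 1L
  lines <- c("#!ascii label, written by fcdenhance",
             sprintf("%d", length(idx)),
             sprintf("%d  %.6f  %.6f  %.6f  0.000000", idx,
                     vertices[idx + 1L, 1], vertices[idx + 1L, 2],
                     vertices[idx + 1L, 3]))
  writeLines(lines, path)
  invisible(path)
}

## ---- GIFTI -----------------------------------------------------------------

.giftiTypeInfo <- list(
  NIFTI_TYPE_FLOAT32 = list(what = "numeric", size = 4L),
  NIFTI_TYPE_FLOAT64 = list(what = "numeric", size = 8L),
  NIFTI_TYPE_INT32 = list(what = "integer", size = 4L))

.giftiDataArrayXml <- function(values, intent, dataType, dims) {
  info <- .giftiTypeInfo[[dataType]]
  con <- rawConnection(raw(0), "wb")
  writeBin(if (info$what == "integer") as.integer(values)
           else as.numeric(values),
           con, size = info$size, endian = "little")
  raw <- rawConnectionValue(con)
  close(con)
  b64 <- jsonlite::base64_enc(raw)
  dimAttrs <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                    collapse = " ")
  sprintf(paste0(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" ',
    'Dimensionality="%d" %s Encoding="Base64Binary" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset="">\n<Data>%s</Data>\n</DataArray>'),
    intent, dataType, length(dims), dimAttrs, b64)
}

.giftiWrite <- function(arrays, path) {
  body <- vapply(arrays, function(a)
    .giftiDataArrayXml(a$values, a$intent, a$dataType, a$dims), character(1))
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">\n',
                        length(arrays)),
                paste(body, collapse = "\n"), "\n</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

.giftiRead <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "GIFTI")
    stop(sprintf("unknown format magic in %s", path), call. = FALSE)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(arrays, function(a) {
    dataType <- xml2::xml_attr(a, "DataType")
    info <- .giftiTypeInfo[[dataType]]
    if (is.null(info))
      stop(sprintf("unsupported GIFTI DataType %s", dataType), call. = FALSE)
    ndim <- as.integer(xml2::xml_attr(a, "Dimensionality"))
    dims <- vapply(seq_len(ndim) - 1L, function(i)
      as.integer(xml2::xml_attr(a, sprintf("Dim%d", i))), integer(1))
    enc <- xml2::xml_attr(a, "Encoding")
    txt <- xml2::xml_text(xml2::xml_find_first(a, ".//Data"))
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (identical(enc, "GZipBase64Binary"))
      raw <- memDecompress(raw, type = "gzip")
    else if (!identical(enc, "Base64Binary"))
      stop(sprintf("unsupported GIFTI encoding %s", enc), call. = FALSE)
    vals <- readBin(raw, info$what, n = prod(dims), size = info$size,
                    endian = "little")
    list(intent = xml2::xml_attr(a, "Intent"), values = vals, dims = dims)
  })
}

#' Write a surface mesh as GIFTI (.surf.gii)
#' @param vertices N x 3 coordinates (mm).
#' @param faces M x 3 1-based triangle indices.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGiftiSurface <- function(vertices, faces, path) {
  .giftiWrite(list(
    list(values = as.numeric(t(vertices)), intent = "NIFTI_INTENT_POINTSET",
         dataType = "NIFTI_TYPE_FLOAT64", dims = c(nrow(vertices), 3L)),
    list(values = as.integer(t(faces) - 1L),
         intent = "NIFTI_INTENT_TRIANGLE",
         dataType = "NIFTI_TYPE_INT32", dims = c(nrow(faces), 3L))), path)
}

#' Read a GIFTI surface mesh
#' @param path path to a .surf.gii file.
#' @return list with \code{vertices} (N x 3) and \code{faces}
#'   (M x 3, 1-based).
#' @export
readGiftiSurface <- function(path) {
  arrays <- .giftiRead(path)
  intents <- vapply(arrays, `[[`, character(1), "intent")
  pi_ <- match("NIFTI_INTENT_POINTSET", intents)
  ti <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(pi_) || is.na(ti))
    stop(sprintf("not a surface GIFTI: %s", path), call. = FALSE)
  verts <- matrix(arrays[[pi_]]$values, ncol = 3, byrow = TRUE)
  faces <- matrix(arrays[[ti]]$values, ncol = 3, byrow = TRUE) + 1L
  list(vertices = verts, faces = faces)
}

#' Write a per-vertex overlay as GIFTI (.func.gii / .shape.gii)
#' @param values per-vertex values (NA allowed; stored as NaN).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGiftiOverlay <- function(values, path) {
  v <- as.numeric(values)
  v[is.na(v)] <- NaN
  .giftiWrite(list(list(values = v, intent = "NIFTI_INTENT_NONE",
                        dataType = "NIFTI_TYPE_FLOAT64",
                        dims = length(v))), path)
}

#' Read a per-vertex overlay from GIFTI
#' @param path path to a functional/shape GIFTI file.
#' @return numeric vector of per-vertex values.
#' @export
readGiftiOverlay <- function(path) {
  arrays <- .giftiRead(path)
  v <- as.numeric(arrays[[1]]$values)
  v[is.nan(v)] <- NA_real_
  v
}

## ---- model-level I/O -------------------------------------------------------

.isGifti <- function(path) grepl("\\.gii$", path, ignore.case = TRUE)

.readAnySurface <- function(path, crasOffset) {
  if (.isGifti(path)) readGiftiSurface(path)
  else readFsSurface(path, crasOffset = crasOffset)
}

.readAnyOverlay <- function(path) {
  if (.isGifti(path)) readGiftiOverlay(path) else readFsCurv(path)
}

#' Read a cortical surface model from white/pial/thickness/label files
#'
#' Accepts FreeSurfer binary surface, curv and ASCII label files, or their
#' GIFTI equivalents (.surf.gii / .func.gii), mixed freely.  White and pial
#' surfaces must have identical vertex counts (1:1 correspondence).
#'
#' @param whitePath,pialPath surface files.
#' @param thicknessPath per-vertex thickness overlay (curv or GIFTI).
#' @param labelPath cortex label: FreeSurfer ASCII label or a GIFTI overlay
#'   interpreted as non-zero = cortex.  \code{NULL} marks every vertex as
#'   cortex.
#' @param crasOffset translation (mm) applied to FreeSurfer binary surface
#'   coordinates to move them into scanner RAS (see
#'   \code{\link{readFsSurface}}).
#' @return A \code{\linkS4class{CorticalSurfaceModel}}.
#' @export
readSurfaceModel <- function(whitePath, pialPath, thicknessPath,
                             labelPath = NULL, crasOffset = c(0, 0, 0)) {
  white <- .readAnySurface(whitePath, crasOffset)
  pial <- .readAnySurface(pialPath, crasOffset)
  if (nrow(white$vertices) != nrow(pial$vertices))
    stop("vertex count mismatch between white and pial surfaces",
         call. = FALSE)
  if (!identical(dim(white$faces), dim(pial$faces)))
    stop("face count mismatch between white and pial surfaces", call. = FALSE)
  thickness <- .readAnyOverlay(thicknessPath)
  if (length(thickness) != nrow(white$vertices))
    stop("vertex count mismatch between surface and thickness overlay",
         call. = FALSE)
  label <- if (is.null(labelPath)) rep(TRUE, nrow(white$vertices))
  else if (.isGifti(labelPath))
    readGiftiOverlay(labelPath) != 0
  else readFsLabel(labelPath, nrow(white$vertices))
  CorticalSurfaceModel(white$vertices, pial$vertices, white$faces,
                       thickness, label)
}

#' Write a cortical surface model to disk
#'
#' @param model a \code{\linkS4class{CorticalSurfaceModel}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (e.g. \code{"lh"}).
#' @param format \code{"gifti"} or \code{"freesurfer"}.
#' @return named character vector of the written paths.
#' @export
writeSurfaceModel <- function(model, dir, prefix = "hemi",
                              format = c("gifti", "freesurfer")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  if (format == "gifti") {
    paths <- c(white = p(".white.surf.gii"), pial = p(".pial.surf.gii"),
               thickness = p(".thickness.func.gii"),
               label = p(".cortexlabel.func.gii"))
    writeGiftiSurface(model@whiteVertices, model@faces, paths["white"])
    writeGiftiSurface(model@pialVertices, model@faces, paths["pial"])
    writeGiftiOverlay(model@thickness, paths["thickness"])
    writeGiftiOverlay(as.numeric(model@cortexLabel), paths["label"])
  } else {
    paths <- c(white = p(".white"), pial = p(".pial"),
               thickness = p(".thickness"), label = p(".cortex.label"))
    writeFsSurface(model@whiteVertices, model@faces, paths["white"])
    writeFsSurface(model@pialVertices, model@faces, paths["pial"])
    writeFsCurv(model@thickness, paths["thickness"])
    writeFsLabel(model@cortexLabel, model@whiteVertices, paths["label"])
  }
  paths
}

#' Write a VertexOverlay to a GIFTI functional or FreeSurfer curv file
#' @param overlay a \code{\linkS4class{VertexOverlay}}; invalid vertices are
#'   stored as NaN (GIFTI) or 0 (curv, which cannot encode NaN portably).
#' @param path output path; format chosen by extension (.gii = GIFTI).
#' @return \code{path}, invisibly.
#' @export
writeOverlay <- function(overlay, path) {
  v <- overlay@values
  v[!overlay@valid] <- NA_real_
  if (.isGifti(path)) writeGiftiOverlay(v, path)
  else {
    v[is.na(v)] <- 0
    writeFsCurv(v, path)
  }
  invisible(path)
}
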