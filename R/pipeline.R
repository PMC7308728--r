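## End-to-end orchestration: in-memory per-subject chain, phantom cohort
## helpers, and the file-based pipeline with stage-labelled errors and
## provenance metadata.

#' Run the enhancement chain for one subject (in memory)
#'
#' Builds the compartmentally smoothed map triplet, computes the R-map
#' pair (from the original and the smoothed maps), and enhances the FLAIR
#' with the averaged R maps.
#'
#' @param maps named list of fitted maps (\code{t1}, \code{t2}, \code{pd})
#'   on the reference grid.
#' @param model a \code{\linkS4class{CorticalSurfaceModel}}.
#' @param wmMask logical array (WM segmentation) on the reference grid.
#' @param flair conventional FLAIR volume on the reference grid.
#' @param cfg a \code{\linkS4class{QRConfig}}.
#' @param smoothFwhmMm edge-preserving smoothing FWHM (mm, default 1.5).
#' @param t1CsfMax,t2CsfMax CSF exclusion thresholds (ms, defaults
#'   2000/300).
#' @param bands,step depth-sampling bands and layer resolution.
#' @return list with \code{smoothedMaps}, \code{rU}, \code{rS}, \code{qU},
#'   \code{qS}, \code{filteredU}, \code{filteredS}, \code{enhanced}.
#' @export
runSubjectPipeline <- function(maps, model, wmMask, flair,
                               cfg = qrConfig(), smoothFwhmMm = 1.5,
                               t1CsfMax = 2000, t2CsfMax = 300,
                               bands = .DEFAULT_BANDS, step = 0.01) {
  smoothed <- list(
    t1 = smoothCompartments(maps$t1, wmMask, fwhmMm = smoothFwhmMm,
                            t1Max = t1CsfMax, t2Max = t2CsfMax),
    t2 = smoothCompartments(maps$t2, wmMask, fwhmMm = smoothFwhmMm,
                            t1Max = t1CsfMax, t2Max = t2CsfMax),
    pd = smoothCompartments(maps$pd, wmMask, t1 = maps$t1,
                            fwhmMm = smoothFwhmMm, t1Max = t1CsfMax,
                            t2Max = t2CsfMax))
  pair <- computeRPair(maps, smoothed, model, ref = maps$t1, cfg = cfg,
                       bands = bands, step = step)
  enhanced <- enhanceFlair(flair, pair$rS, pair$rU)
  c(list(smoothedMaps = smoothed, enhanced = enhanced), pair)
}

#' Simulate and process one phantom subject
#'
#' Builds a slab phantom (optionally with a lesion), simulates the raw
#' acquisitions at the given SNR and seed, fits the qMRI maps, and runs
#' the full enhancement chain.
#'
#' @param seed RNG seed for the acquisition noise.
#' @param lesion a \code{\linkS4class{LesionSpec}} or \code{NULL} for a
#'   lesion-free subject.
#' @param snr white-matter SNR of each simulated volume (default 50).
#' @param gridShape,cortexThicknessMm,tissue phantom geometry (see
#'   \code{\link{buildSlabPhantom}}).
#' @param cfg a \code{\linkS4class{QRConfig}}.
#' @param roi readout ROI; defaults to the phantom's ground-truth lesion
#'   ROI, or the nominal lesion-site ROI for lesion-free subjects.
#' @return list with the phantom (\code{ph}), fitted \code{maps}, the
#'   pipeline outputs (see \code{\link{runSubjectPipeline}}), and
#'   \code{conventional} / \code{enhanced} / \code{roi} ready for
#'   \code{\link{buildReport}}.
#' @export
runPhantomSubject <- function(seed, lesion = lesionSpec(), snr = 50,
                              gridShape = c(44, 44, 40),
                              cortexThicknessMm = 2.5,
                              tissue = tissueParams(), cfg = qrConfig(),
                              roi = NULL) {
  ph <- buildSlabPhantom(gridShape = gridShape,
                         cortexThicknessMm = cortexThicknessMm,
                         tissue = tissue)
  if (!is.null(lesion)) ph <- insertLesion(ph, lesion)
  ph <- simulateAcquisitions(ph, snr = snr, seed = seed)
  maps <- fitQmriMaps(ph@acquisitions, csfMask = ph@labels == 3L)
  out <- runSubjectPipeline(maps, ph@surface, ph@wmMask,
                            ph@acquisitions$flair, cfg = cfg)
  if (is.null(roi))
    roi <- if (!is.null(ph@roi)) ph@roi
  else RoiSpec(lesionSpec()@center, side = "right")
  c(list(ph = ph, maps = maps, conventional = ph@acquisitions$flair,
         roi = roi), out)
}

#' Run a phantom cohort and build the group enhancement report
#'
#' One subject per seed, identical lesion specification (or lesion-free
#' with \code{lesion = NULL}), full pipeline each, ROI analysis across the
#' group.
#'
#' @inheritParams runPhantomSubject
#' @param seeds one RNG seed per subject (default 1:10).
#' @return list with \code{report} (an
#'   \code{\linkS4class{EnhancementReport}}) and \code{subjects} (the
#'   per-subject pipeline outputs).
#' @export
runPhantomCohort <- function(seeds = 1:10, lesion = lesionSpec(),
                             snr = 50, gridShape = c(44, 44, 40),
                             cortexThicknessMm = 2.5,
                             tissue = tissueParams(), cfg = qrConfig()) {
  subjects <- lapply(seeds, function(s)
    runPhantomSubject(s, lesion = lesion, snr = snr,
                      gridShape = gridShape,
                      cortexThicknessMm = cortexThicknessMm,
                      tissue = tissue, cfg = cfg))
  report <- buildReport(lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    list(conventional = s$conventional, enhanced = s$enhanced,
         roi = s$roi, id = sprintf("phantom%02d", seeds[i]))
  }))
  list(report = report, subjects = subjects)
}

#' Write a phantom subject directory
#'
#' Emits the ground-truth and simulated volumes as NIfTI, the surfaces and
#' overlays as GIFTI, the lesion ROI as TSV and a JSON sidecar recording
#' the phantom specification and seed.
#'
#' @param ph a simulated \code{\linkS4class{PhantomDataset}}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
writePhantomSubject <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wv <- function(vol, name) writeVolume(vol, file.path(dir, name))
  for (nm in names(ph@truth))
    wv(ph@truth[[nm]], sprintf("truth_%s.nii.gz", nm))
  wv(QuantitativeVolume(ph@labels + 0, ph@affine, "LABEL"),
     "labels.nii.gz")
  wv(QuantitativeVolume(ph@wmMask + 0, ph@affine, "MASK"),
     "wm_mask.nii.gz")
  acq <- ph@acquisitions
  if (length(acq)) {
    for (nm in setdiff(names(acq), c("t2Echoes", "params")))
      wv(acq[[nm]], sprintf("raw_%s.nii.gz", nm))
    for (i in seq_along(acq$t2Echoes))
      wv(acq$t2Echoes[[i]], sprintf("raw_t2Echo%d.nii.gz", i))
  }
  writeSurfaceModel(ph@surface, dir, prefix = "cortex", format = "gifti")
  if (!is.null(ph@roi)) {
    roi <- ph@roi
    write.table(data.frame(subject_id = basename(dir),
                           x = roi@center[1], y = roi@center[2],
                           z = roi@center[3], dx = roi@dims[1],
                           dy = roi@dims[2], dz = roi@dims[3],
                           side = roi@side),
                file.path(dir, "lesion_roi.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  sidecar <- list(
    geometry = ph@geometry[setdiff(names(ph@geometry),
                                   c("meshX", "meshY"))],
    tissue = as.list(as.data.frame(t(ph@tissue@table))),
    lesion = if (is.null(ph@lesion)) NULL else list(
      center = ph@lesion@center, radius = ph@lesion@radius,
      blurWidth = ph@lesion@blurWidth,
      thickeningDelta = ph@lesion@thickeningDelta,
      subcorticalT2Delta = ph@lesion@subcorticalT2Delta,
      side = ph@lesion@side),
    seed = ph@seed)
  jsonlite::write_json(sidecar, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.requirePaths <- function(stage, paths) {
  missing <- names(paths)[!vapply(paths, function(p)
    is.character(p) && length(p) == 1 && file.exists(p), logical(1))]
  if (length(missing))
    stop(sprintf("stage %s failed: missing input(s): %s", stage,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Run the full file-based pipeline from a configuration
#'
#' Reads fitted qMRI maps (or raw acquisitions to fit), the surface model,
#' the WM mask and the FLAIR, runs the enhancement chain and writes every
#' intermediate (smoothed maps, SD overlays, Q overlay, filtered quotient
#' volume, R_u, R_s, enhanced FLAIR) plus a provenance JSON into the
#' output directory.  The run is deterministic: no stage consumes
#' unseeded randomness, and re-running on identical inputs reproduces the
#' outputs bit-identically.
#'
#' @param config a named list or the path of a YAML file with entries:
#'   \code{maps} (paths \code{t1}, \code{t2}, \code{pd}) or \code{raw}
#'   (paths \code{spgr_low}, \code{spgr_high}, \code{b1_reference},
#'   \code{b1_prepared}, \code{t2_echo_1..4}, \code{t2star_echo1},
#'   \code{t2star_echo2}, \code{csf_mask}); \code{surfaces} (paths
#'   \code{white}, \code{pial}, \code{thickness}, optional \code{label});
#'   \code{wm_mask}; \code{flair}; \code{out_dir}; optional constants
#'   \code{smooth_fwhm} (1.5), \code{t1_csf_max} (2000), \code{t2_csf_max}
#'   (300), \code{q_offset} (0.0001), \code{q0} (500), \code{quotient_cap}
#'   (1000), \code{smooth_sigma} (3), \code{r_offset} (1); optional
#'   \code{roi_table} (TSV with columns subject_id, x, y, z, dx, dy, dz,
#'   side).
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outDir <- config$out_dir
  if (is.null(outDir)) stop("config must name out_dir", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- qrConfig(qOffset = config$q_offset %||% 1e-4,
                  q0 = config$q0 %||% 500,
                  quotientCap = config$quotient_cap %||% 1000,
                  smoothSigmaMm = config$smooth_sigma %||% 3,
                  rOffset = config$r_offset %||% 1)

  maps <- .stage("qmri_mapping", {
    if (!is.null(config$maps)) {
      .requirePaths("qmri_mapping", config$maps[c("t1", "t2", "pd")])
      list(t1 = readVolume(config$maps$t1, "T1"),
           t2 = readVolume(config$maps$t2, "T2"),
           pd = readVolume(config$maps$pd, "PD"))
    } else {
      raw <- config$raw
      .requirePaths("qmri_mapping",
                    raw[c("spgr_low", "spgr_high", "b1_reference",
                          "b1_prepared", "t2star_echo1", "t2star_echo2",
                          "csf_mask")])
      echoes <- lapply(grep("^t2_echo_", names(raw), value = TRUE),
                       function(k) readVolume(raw[[k]], "SIGNAL"))
      acq <- list(spgrLow = readVolume(raw$spgr_low, "SIGNAL"),
                  spgrHigh = readVolume(raw$spgr_high, "SIGNAL"),
                  b1Reference = readVolume(raw$b1_reference, "SIGNAL"),
                  b1Prepared = readVolume(raw$b1_prepared, "SIGNAL"),
                  t2Echoes = echoes,
                  t2starEcho1 = readVolume(raw$t2star_echo1, "SIGNAL"),
                  t2starEcho2 = readVolume(raw$t2star_echo2, "SIGNAL"),
                  params = list(vfa = vfaParams(), b1 = b1Params(),
                                t2 = t2SeriesParams(),
                                t2star = t2starParams()))
      csf <- readVolume(raw$csf_mask, "MASK")
      fit <- fitQmriMaps(acq, csfMask = csf@data > 0)
      fit[c("t1", "t2", "pd")]
    }
  })
  ref <- maps$t1

  inputs <- .stage("io_model", {
    .requirePaths("io_model", list(wm_mask = config$wm_mask,
                                   flair = config$flair))
    wm <- readVolume(config$wm_mask, "MASK")
    flair <- readVolume(config$flair, "SIGNAL")
    if (!.sameGrid(flair, ref)) flair <- resampleToReference(flair, ref)
    list(wmMask = wm@data > 0, flair = flair)
  })

  model <- .stage("surface_sampling", {
    s <- config$surfaces
    .requirePaths("surface_sampling",
                  list(white = s$white, pial = s$pial,
                       thickness = s$thickness))
    readSurfaceModel(s$white, s$pial, s$thickness, s$label)
  })

  res <- .stage("q_r_maps",
                runSubjectPipeline(maps, model, inputs$wmMask,
                                   inputs$flair, cfg = cfg,
                                   smoothFwhmMm = config$smooth_fwhm %||% 1.5,
                                   t1CsfMax = config$t1_csf_max %||% 2000,
                                   t2CsfMax = config$t2_csf_max %||% 300))

  .stage("io_model", {
    for (nm in names(res$smoothedMaps))
      writeVolume(res$smoothedMaps[[nm]],
                  file.path(outDir, sprintf("smoothed_%s.nii.gz", nm)))
    writeOverlay(res$qU, file.path(outDir, "Q_unsmoothed.func.gii"))
    writeOverlay(res$qS, file.path(outDir, "Q_smoothed.func.gii"))
    writeVolume(res$filteredU, file.path(outDir, "quotient_u.nii.gz"))
    writeVolume(res$filteredS, file.path(outDir, "quotient_s.nii.gz"))
    writeVolume(res$rU, file.path(outDir, "R_u.nii.gz"))
    writeVolume(res$rS, file.path(outDir, "R_s.nii.gz"))
    writeVolume(res$enhanced, file.path(outDir, "enhanced_flair.nii.gz"))
  })

  if (!is.null(config$roi_table)) {
    .stage("enhancement", {
      rois <- read.table(config$roi_table, header = TRUE, sep = "\t")
      means <- lapply(seq_len(nrow(rois)), function(i) {
        roi <- RoiSpec(c(rois$x[i], rois$y[i], rois$z[i]),
                       c(rois$dx[i], rois$dy[i], rois$dz[i]),
                       side = as.character(rois$side[i]))
        data.frame(subject_id = rois$subject_id[i],
                   conventional = roiMean(inputs$flair, roi),
                   enhanced = roiMean(res$enhanced, roi),
                   contralateral_enhanced =
                     roiMean(res$enhanced, mirrorRoi(roi)))
      })
      write.table(do.call(rbind, means),
                  file.path(outDir, "roi_means.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    })
  }

  prov <- list(package = "fcdenhance",
               version = as.character(utils::packageVersion("fcdenhance")),
               rVersion = R.version.string,
               config = config[setdiff(names(config), "out_dir")],
               constants = list(qOffset = cfg@qOffset, q0 = cfg@q0,
                                quotientCap = cfg@quotientCap,
                                smoothSigmaMm = cfg@smoothSigmaMm,
                                rOffset = cfg@rOffset),
               validVertices = sum(res$qU@valid))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}
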