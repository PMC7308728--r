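## Quantitative map fitting: B1, VFA T1, multi-echo T2, two-echo T2*, the
## receive-coil profile and PD, plus the Fatouros pseudo-PD and the
## synthetic MP-RAGE anatomy.  All fits are closed-form/voxel-wise
## vectorized inversions of the forward models in signal-models.R.

#' AcquisitionParams: sequence timing and angles
#'
#' Holder for the acquisition parameters of one sequence: repetition time,
#' echo time(s), inversion time, flip angle(s), echo spacing, the nominal
#' preparation angle of the B1 measurement, and the MP-RAGE readout-train
#' geometry.  Preset constructors carry the protocol defaults:
#' \code{vfaParams()} (TE 6.7 ms, TR 16.4 ms, angles 4/24 deg),
#' \code{t2SeriesParams()} (TEs 13/67/93/106 ms),
#' \code{t2starParams()} (TEs 4.3/11 ms),
#' \code{b1Params()} (nominal preparation angle 45 deg),
#' \code{mprageParams()} (TR 1900 ms, TI 900 ms, 9 deg, echo spacing
#' 8.1 ms, 176-excitation train, centre at excitation 88) and
#' \code{flairParams()} (TR 5000 ms, TI 1800 ms, TE 353 ms).
#'
#' @slot tr,ti,echoSpacing times (ms).
#' @slot te echo time(s) (ms).
#' @slot flipAngle flip angle(s) (degrees).
#' @slot nominalBeta0 nominal preparation angle (degrees).
#' @slot nTrain,centerIndex MP-RAGE readout-train length and k-space-centre
#'   excitation index (1-based).
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
         slots = c(tr = "numeric", te = "numeric", ti = "numeric",
                   flipAngle = "numeric", echoSpacing = "numeric",
                   nominalBeta0 = "numeric", nTrain = "integer",
                   centerIndex = "integer"))

setValidity("AcquisitionParams", function(object) {
  msgs <- character()
  times <- c(object@tr, object@te, object@ti, object@echoSpacing)
  if (any(times <= 0)) msgs <- c(msgs, "all times must be strictly positive")
  angles <- c(object@flipAngle, object@nominalBeta0)
  if (length(angles) && any(angles <= 0 | angles >= 180))
    msgs <- c(msgs, "angles must lie in (0, 180) degrees")
  if (length(msgs)) msgs else TRUE
})

#' @rdname AcquisitionParams-class
#' @param tr,te,ti,flipAngle,echoSpacing,nominalBeta0,nTrain,centerIndex
#'   see the class slots; unused entries may be left empty.
#' @return An \code{AcquisitionParams}.
#' @export
acquisitionParams <- function(tr = numeric(), te = numeric(),
                              ti = numeric(), flipAngle = numeric(),
                              echoSpacing = numeric(),
                              nominalBeta0 = numeric(),
                              nTrain = integer(),
                              centerIndex = integer()) {
  new("AcquisitionParams", tr = as.double(tr), te = as.double(te),
      ti = as.double(ti), flipAngle = as.double(flipAngle),
      echoSpacing = as.double(echoSpacing),
      nominalBeta0 = as.double(nominalBeta0),
      nTrain = as.integer(nTrain), centerIndex = as.integer(centerIndex))
}

#' @rdname AcquisitionParams-class
#' @export
vfaParams <- function(tr = 16.4, te = 6.7, flipAngle = c(4, 24))
  acquisitionParams(tr = tr, te = te, flipAngle = flipAngle)

#' @rdname AcquisitionParams-class
#' @export
t2SeriesParams <- function(te = c(13, 67, 93, 106), tr = 10000)
  acquisitionParams(tr = tr, te = te)

#' @rdname AcquisitionParams-class
#' @export
t2starParams <- function(te = c(4.3, 11), tr = 1336, flipAngle = 50)
  acquisitionParams(tr = tr, te = te, flipAngle = flipAngle)

#' @rdname AcquisitionParams-class
#' @export
b1Params <- function(nominalBeta0 = 45, tr = 11, te = 5, flipAngle = 11)
  acquisitionParams(tr = tr, te = te, flipAngle = flipAngle,
                    nominalBeta0 = nominalBeta0)

#' @rdname AcquisitionParams-class
#' @export
mprageParams <- function(tr = 1900, ti = 900, flipAngle = 9,
                         echoSpacing = 8.1, nTrain = 176L,
                         centerIndex = 88L)
  acquisitionParams(tr = tr, ti = ti, flipAngle = flipAngle,
                    echoSpacing = echoSpacing, nTrain = nTrain,
                    centerIndex = centerIndex)

#' @rdname AcquisitionParams-class
#' @export
flairParams <- function(tr = 5000, ti = 1800, te = 353)
  acquisitionParams(tr = tr, ti = ti, te = te)

#' FatourosConstants: the empirical PD(T1) relation
#'
#' Constants of the empirical relation \code{1/PD = A + B/T1} linking water
#' content and T1 in brain tissue, used to derive pseudo-PD maps from T1.
#' The defaults (A = 0.916, B = 436 ms) are literature-derived
#' configuration values, never hard-coded into logic.
#'
#' @slot a dimensionless offset (> 0).
#' @slot b slope in ms (> 0).
#' @exportClass FatourosConstants
setClass("FatourosConstants", slots = c(a = "numeric", b = "numeric"))

setValidity("FatourosConstants", function(object) {
  if (object@a <= 0 || object@b <= 0) "A and B must be positive" else TRUE
})

#' @rdname FatourosConstants-class
#' @param a,b constants of \code{1/PD = a + b/T1}.
#' @return A \code{FatourosConstants}.
#' @export
fatourosConstants <- function(a = 0.916, b = 436)
  new("FatourosConstants", a = a, b = b)

.newMap <- function(template, data, kind, valid) {
  data[!valid] <- NA_real_
  QuantitativeVolume(array(data, dim(template@data)), template@affine, kind,
                     validMask = array(valid, dim(template@data)))
}

#' Fit a B1 map from a reference / magnetization-prepared image pair
#'
#' The preparation pulse rotates the longitudinal magnetization by an angle
#' beta (nominal value beta0); the ratio of prepared to reference signal
#' equals cos(beta), so \code{beta = acos(clamp(prepared/reference, 0, 1))}
#' and \code{B1 = beta/beta0}.  Voxels with non-positive reference signal
#' are invalid.
#'
#' @param reference,prepared signal volumes on one grid.
#' @param params an \code{\linkS4class{AcquisitionParams}} carrying the
#'   nominal preparation angle (default 45 degrees).
#' @return A B1 \code{\linkS4class{QuantitativeVolume}} (ratio of actual to
#'   nominal flip angle).
#' @export
fitB1Map <- function(reference, prepared, params = b1Params()) {
  .stopIfGridMismatch(reference, prepared, "reference and prepared")
  refd <- reference@data
  ratio <- pmin(pmax(prepared@data / refd, 0), 1)
  beta <- acos(ratio) * 180 / pi
  b1 <- beta / params@nominalBeta0
  valid <- reference@validMask & prepared@validMask &
    is.finite(refd) & refd > 0 & is.finite(b1)
  .newMap(reference, b1, "B1", valid)
}

#' Fit T1 by the variable flip angle (VFA) method
#'
#' Linearizes the SPGR equation by plotting \code{SI/tan(a)} against
#' \code{SI/sin(a)} for the two acquisitions: the slope of the two-point
#' line equals \code{E1 = exp(-TR/T1)}.  Local true angles are the nominal
#' angles multiplied by the B1 map.  Voxels with slope outside (0, 1) or
#' non-positive signal in either acquisition are invalid.
#'
#' @param spgrLow,spgrHigh SPGR signal volumes at the lower/higher nominal
#'   flip angle, on one grid.
#' @param params sequence parameters (default \code{vfaParams()}: TE 6.7,
#'   TR 16.4 ms, angles 4/24 degrees).
#' @param b1 optional B1 map on the same grid; if missing, B1 = 1 is
#'   assumed with a warning.
#' @return list with \code{t1} (T1 map, ms) and \code{m0} (companion
#'   equilibrium-signal volume, absorbing PD and T2* decay at the TE).
#' @export
fitT1Vfa <- function(spgrLow, spgrHigh, params = vfaParams(), b1 = NULL) {
  .stopIfGridMismatch(spgrLow, spgrHigh, "the two SPGR volumes")
  if (is.null(b1)) {
    warning("no B1 map supplied; assuming B1 = 1 everywhere")
    b1d <- 1
    b1ok <- TRUE
  } else {
    .stopIfGridMismatch(spgrLow, b1, "SPGR and B1 volumes")
    b1d <- b1@data
    b1ok <- b1@validMask
  }
  a1 <- .deg2rad(params@flipAngle[1]) * b1d
  a2 <- .deg2rad(params@flipAngle[2]) * b1d
  s1 <- spgrLow@data
  s2 <- spgrHigh@data
  ## SPGR linearization: S/sin(a) = E1 * S/tan(a) + M0 (1 - E1)
  u1 <- s1 / tan(a1); v1 <- s1 / sin(a1)
  u2 <- s2 / tan(a2); v2 <- s2 / sin(a2)
  m <- (v2 - v1) / (u2 - u1)
  t1 <- -params@tr / log(m)
  m0 <- (v1 - m * u1) / (1 - m)
  valid <- spgrLow@validMask & spgrHigh@validMask & b1ok &
    is.finite(m) & m > 0 & m < 1 & s1 > 0 & s2 > 0 & is.finite(t1)
  list(t1 = .newMap(spgrLow, t1, "T1", valid),
       m0 = .newMap(spgrLow, m0, "SIGNAL", valid & is.finite(m0)))
}

#' Fit T2 from a multi-echo spin-echo series
#'
#' Unweighted log-linear least squares of \code{ln S = ln S0 - TE/T2} over
#' the echoes, per voxel.  Voxels with any non-positive signal are invalid.
#'
#' @param echoes list of signal volumes, one per echo, on one grid.
#' @param tes echo times (ms), strictly increasing, one per echo
#'   (default the protocol echoes 13, 67, 93, 106 ms).
#' @return list with \code{t2} (T2 map, ms) and \code{s0} (extrapolated
#'   TE = 0 signal volume).
#' @export
fitT2MultiEcho <- function(echoes, tes = c(13, 67, 93, 106)) {
  if (length(echoes) != length(tes))
    stop("TE count mismatch: need one echo time per echo volume",
         call. = FALSE)
  if (length(echoes) < 2) stop("need at least two echoes", call. = FALSE)
  if (any(diff(tes) <= 0))
    stop("echo times must be strictly increasing", call. = FALSE)
  for (e in echoes[-1]) .stopIfGridMismatch(echoes[[1]], e, "echo volumes")
  k <- length(tes)
  valid <- Reduce(`&`, lapply(echoes, function(e)
    e@validMask & is.finite(e@data) & e@data > 0))
  logs <- lapply(echoes, function(e) log(pmax(e@data, .Machine$double.xmin)))
  teBar <- mean(tes)
  sxx <- sum((tes - teBar)^2)
  sxy <- 0
  ybar <- 0
  for (i in seq_len(k)) ybar <- ybar + logs[[i]] / k
  for (i in seq_len(k)) sxy <- sxy + (tes[i] - teBar) * (logs[[i]] - ybar)
  slope <- sxy / sxx
  t2 <- -1 / slope
  s0 <- exp(ybar - slope * teBar)
  valid <- valid & is.finite(t2) & t2 > 0
  list(t2 = .newMap(echoes[[1]], t2, "T2", valid),
       s0 = .newMap(echoes[[1]], s0, "SIGNAL", valid))
}

#' Fit T2* from a two-echo gradient-echo pair
#'
#' Closed form \code{T2* = (TE2 - TE1) / ln(S1/S2)}.  Voxels with
#' non-positive signal or \code{S1 <= S2} (unphysical, infinite or negative
#' T2*) are invalid.
#'
#' @param echo1,echo2 signal volumes at the shorter/longer echo time.
#' @param tes the two echo times (ms), \code{tes[2] > tes[1]} (default
#'   4.3 and 11 ms).
#' @return A T2* \code{\linkS4class{QuantitativeVolume}}.
#' @export
fitT2StarTwoEcho <- function(echo1, echo2, tes = c(4.3, 11)) {
  .stopIfGridMismatch(echo1, echo2, "the two echoes")
  if (tes[2] <= tes[1])
    stop("second echo time must exceed the first", call. = FALSE)
  s1 <- echo1@data
  s2 <- echo2@data
  t2star <- (tes[2] - tes[1]) / log(s1 / s2)
  valid <- echo1@validMask & echo2@validMask &
    is.finite(s1) & is.finite(s2) & s1 > 0 & s2 > 0 & s1 > s2 &
    is.finite(t2star)
  .newMap(echo1, t2star, "T2star", valid)
}

.polyDesign <- function(d, order) {
  ## polynomial basis in grid coordinates normalized to [-1, 1]
  ax <- lapply(d, function(n) seq(-1, 1, length.out = n))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
    cols[[length(cols) + 1L]] <- g$x^i * g$y^j * g$z^k
  do.call(cbind, cols)
}

#' Estimate the receive-coil profile (RCP)
#'
#' Fits a low-order 3-D polynomial to the ratio of the measured PD-weighted
#' signal to a model signal predicted from the fitted maps without the
#' receive profile, over a brain mask.  The fitted field is normalized to
#' mean 1 over the mask and represents the smooth multiplicative
#' sensitivity of the receive coil.
#'
#' @param pdwSignal measured PD-weighted signal volume.
#' @param modelSignal predicted signal (same grid) without receive-profile
#'   effects.
#' @param brainMask logical array selecting the voxels entering the fit.
#' @param order polynomial order (default 3).
#' @return A dimensionless \code{\linkS4class{QuantitativeVolume}}
#'   (kind \code{"SIGNAL"}), strictly positive over the mask.
#' @export
estimateRcp <- function(pdwSignal, modelSignal, brainMask, order = 3L) {
  .stopIfGridMismatch(pdwSignal, modelSignal, "signal and model")
  d <- dim(pdwSignal@data)
  brainMask <- array(as.logical(brainMask), d)
  ratio <- pdwSignal@data / modelSignal@data
  use <- brainMask & is.finite(ratio) & pdwSignal@validMask &
    modelSignal@validMask & modelSignal@data > 0
  if (!any(use)) stop("empty mask", call. = FALSE)
  X <- .polyDesign(d, order)
  fit <- lm.fit(X[use, , drop = FALSE], ratio[use])
  field <- array(X %*% fit$coefficients, d)
  field <- field / mean(field[use])
  if (any(field[use] <= 0))
    warning("fitted receive profile non-positive inside the mask")
  QuantitativeVolume(field, pdwSignal@affine, "SIGNAL")
}

#' Compute a proton-density map from the low-angle SPGR acquisition
#'
#' Corrects the PD-weighted (low flip angle) SPGR signal for T1 saturation,
#' T2* decay during the echo time, B1 deviations of the flip angle and the
#' receive-coil profile:
#' \code{PD = SI / (RCP sin(aB1) (1-E1)/(1-cos(aB1) E1) exp(-TE/T2*))}.
#' The result is scaled so that its mean over a reference region equals
#' 100 pu.
#'
#' @param spgrLow low-flip-angle SPGR signal volume.
#' @param t1,t2star,b1 fitted maps on the same grid.
#' @param rcp receive-coil profile volume (see \code{\link{estimateRcp}}).
#' @param params sequence parameters (default \code{vfaParams()}; the first
#'   flip angle is used).
#' @param refMask logical array defining the 100-pu reference region
#'   (e.g. ventricular CSF).
#' @return A PD \code{\linkS4class{QuantitativeVolume}} in percent units.
#' @export
computePd <- function(spgrLow, t1, t2star, b1, rcp,
                      params = vfaParams(), refMask) {
  for (m in list(t1, t2star, b1, rcp))
    .stopIfGridMismatch(spgrLow, m, "signal and parameter maps")
  aTrue <- .deg2rad(params@flipAngle[1]) * b1@data
  e1 <- exp(-params@tr / t1@data)
  sat <- sin(aTrue) * (1 - e1) / (1 - cos(aTrue) * e1)
  decay <- exp(-params@te[1] / t2star@data)
  pd <- spgrLow@data / (rcp@data * sat * decay)
  valid <- spgrLow@validMask & t1@validMask & t2star@validMask &
    b1@validMask & rcp@validMask & is.finite(pd) & pd > 0
  refMask <- array(as.logical(refMask), dim(spgrLow@data)) & valid
  if (!any(refMask)) stop("empty PD reference region", call. = FALSE)
  pd <- pd * 100 / mean(pd[refMask])
  .newMap(spgrLow, pd, "PD", valid)
}

#' Pseudo-PD from T1 via the Fatouros relation
#'
#' Evaluates \code{PD = 1 / (A + B/T1)} per voxel; monotonically increasing
#' in T1 with limit \code{1/A}.  Voxels with non-positive T1 are invalid.
#'
#' @param t1 a T1 map (ms).
#' @param constants a \code{\linkS4class{FatourosConstants}}.
#' @return A PD \code{\linkS4class{QuantitativeVolume}} on the water-fraction
#'   scale (0..1/A).
#' @export
fatourosPseudoPd <- function(t1, constants = fatourosConstants()) {
  pd <- 1 / (constants@a + constants@b / t1@data)
  valid <- t1@validMask & is.finite(t1@data) & t1@data > 0
  .newMap(t1, pd, "PD", valid)
}

#' Synthesize an MP-RAGE anatomy from T1 and PD maps
#'
#' Voxel-wise steady-state MP-RAGE signal via the recursive Bloch
#' simulation of \code{\link{mprageSignal}} at the virtual acquisition
#' parameters (defaults TR 1900 ms, TI 900 ms, 9 degrees, echo spacing
#' 8.1 ms).
#'
#' @param t1 a T1 map (ms).
#' @param pd a PD map on the same grid.
#' @param params virtual acquisition parameters.
#' @return A \code{\linkS4class{QuantitativeVolume}} of kind
#'   \code{"SIGNAL"}.
#' @export
synthesizeMprage <- function(t1, pd, params = mprageParams()) {
  .stopIfGridMismatch(t1, pd, "T1 and PD maps")
  valid <- t1@validMask & pd@validMask & t1@data > 0
  t1d <- ifelse(valid, t1@data, 1000)   # placeholder, masked out below
  sig <- mprageSignal(t1d, pd@data, params)
  .newMap(t1, sig, "SIGNAL", valid & is.finite(sig))
}
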