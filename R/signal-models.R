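## Forward signal models.  These are the ideal-spoiling / mono-exponential
## equations that the fitting routines invert; the phantom simulator uses
## the same models, which keeps forward/inverse consistency exactly
## testable.  All times in ms, angles in degrees, signals in arbitrary
## units proportional to effective proton density.

.deg2rad <- function(x) x * pi / 180

#' Spoiled gradient-echo (SPGR/FLASH) steady-state signal
#'
#' \code{S = m0 sin(a) (1 - E1) / (1 - cos(a) E1)} with
#' \code{E1 = exp(-TR/T1)}.  Ideal spoiling is assumed.
#'
#' @param m0 equilibrium signal (absorbs PD, T2* decay at the echo time,
#'   and receive-profile effects).
#' @param t1 longitudinal relaxation time (ms).
#' @param alphaDeg excitation flip angle (degrees); the local true angle,
#'   i.e. already multiplied by B1 where relevant.
#' @param tr repetition time (ms).
#' @return signal, same shape as the inputs.
#' @export
spgrSignal <- function(m0, t1, alphaDeg, tr) {
  e1 <- exp(-tr / t1)
  a <- .deg2rad(alphaDeg)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Spin-echo signal with mono-exponential T2 decay
#'
#' \code{S = pd exp(-TE/T2)}; the repetition time is assumed long enough
#' for full longitudinal recovery (the mapping protocol uses TR = 10 s).
#'
#' @param pd proton density (arbitrary units).
#' @param t2 transverse relaxation time (ms).
#' @param te echo time (ms).
#' @return signal.
#' @export
seSignal <- function(pd, t2, te) pd * exp(-te / t2)

#' Inversion-recovery FLAIR signal
#'
#' \code{S = pd (1 - 2 exp(-TI/T1) + exp(-TR/T1)) exp(-TE/T2)}, the
#' standard long-TE inversion-recovery form with CSF suppressed by the
#' inversion time.  Used as the phantom's FLAIR forward model; clinical
#' FLAIR contrast fidelity beyond the T1-nulling and T2-weighting terms is
#' not attempted.
#'
#' @param pd,t1,t2 tissue parameters (pu, ms, ms).
#' @param params an \code{\linkS4class{AcquisitionParams}} carrying
#'   \code{tr}, \code{ti}, \code{te}; defaults to \code{flairParams()}.
#' @return signal (absolute value of the recovery term is taken, matching
#'   magnitude images).
#' @export
flairSignal <- function(pd, t1, t2, params = flairParams()) {
  rec <- 1 - 2 * exp(-params@ti / t1) + exp(-params@tr / t1)
  pd * abs(rec) * exp(-params@te / t2)
}

#' MP-RAGE steady-state signal by recursive Bloch simulation
#'
#' Simulates the magnetization-prepared rapid gradient-echo cycle:
#' inversion, free recovery until the readout train starts, a train of
#' small-angle excitations at the echo spacing, then recovery to the end of
#' the repetition time.  The inversion time \code{ti} is the delay from the
#' inversion pulse to the k-space-centre excitation.  The cycle is iterated
#' to steady state and the transverse signal of the centre excitation is
#' returned; the result is proportional to \code{pd}.
#'
#' @param t1 longitudinal relaxation time (ms), any shape.
#' @param pd proton density, same shape.
#' @param params an \code{\linkS4class{AcquisitionParams}} with \code{tr},
#'   \code{ti}, \code{flipAngle}, \code{echoSpacing}, \code{nTrain},
#'   \code{centerIndex}; defaults to \code{mprageParams()}.
#' @param nCycles number of TR cycles simulated (steady state is reached
#'   well within the default).
#' @param m0init initial longitudinal magnetization relative to equilibrium
#'   (the steady state is independent of it).
#' @return signal, same shape as \code{t1}.
#' @export
mprageSignal <- function(t1, pd, params = mprageParams(), nCycles = 30L,
                         m0init = 1) {
  esp <- params@echoSpacing
  n <- params@nTrain
  ic <- params@centerIndex
  a <- .deg2rad(params@flipAngle[1])
  tStart <- params@ti - (ic - 1) * esp
  if (tStart < 0)
    stop("inversion time shorter than the leading half of the echo train",
         call. = FALSE)
  tEnd <- params@tr - tStart - n * esp
  if (tEnd < 0)
    stop("echo train does not fit into the repetition time", call. = FALSE)
  relax <- function(mz, dt) 1 + (mz - 1) * exp(-dt / t1)
  eEsp <- exp(-esp / t1)
  cosA <- cos(a)
  mz <- m0init + 0 * t1
  centreMz <- NULL
  for (cyc in seq_len(nCycles)) {
    mz <- -mz                      # adiabatic inversion
    mz <- relax(mz, tStart)        # recovery before the train
    for (e in seq_len(n)) {
      if (e == ic) centreMz <- mz
      mz <- mz * cosA              # excitation
      mz <- 1 + (mz - 1) * eEsp    # recovery over one echo spacing
    }
    mz <- relax(mz, tEnd)          # recovery to the end of TR
  }
  pd * centreMz * sin(a)
}

#' Add Rician (or Gaussian) acquisition noise to a magnitude signal
#'
#' Rician noise is the magnitude of the complex signal plus independent
#' Gaussian noise in both channels, the noise model of magnitude MR images.
#'
#' @param signal noiseless signal array.
#' @param sigma Gaussian channel noise standard deviation (signal units);
#'   0 returns the input unchanged.
#' @param type \code{"rician"} or \code{"gaussian"}.
#' @return noisy signal, same shape.
#' @export
addNoise <- function(signal, sigma, type = c("rician", "gaussian")) {
  type <- match.arg(type)
  if (sigma == 0) return(signal)
  n <- length(signal)
  if (type == "rician") {
    out <- sqrt((signal + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
  } else {
    out <- signal + rnorm(n, sd = sigma)
  }
  array(out, dim(signal) %||% n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
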