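#' @import methods
NULL

P_REF <- 20e-6  # reference pressure, Pa (0 dB SPL)

#' Swept-tone stimulus specification
#'
#' Describes a linear frequency sweep: start/end frequency, duration, level,
#' raised-cosine ramp duration and sampling rate. The instantaneous frequency
#' is `f(t) = fStart + (fEnd - fStart) * t / duration`.
#'
#' @slot fStart,fEnd sweep endpoint frequencies (Hz)
#' @slot duration sweep duration (s)
#' @slot level stimulus level (dB SPL, i.e. RMS re 20 uPa)
#' @slot ramp raised-cosine onset/offset ramp duration (s)
#' @slot fs sampling rate (Hz)
#' @export
setClass("SweepSpec",
  representation(fStart = "numeric", fEnd = "numeric", duration = "numeric",
                 level = "numeric", ramp = "numeric", fs = "numeric"))

setValidity("SweepSpec", function(object) {
  msg <- character()
  if (!(object@fStart > 0 && object@fEnd > object@fStart))
    msg <- c(msg, "need 0 < fStart < fEnd")
  if (object@fEnd > object@fs / 2)
    msg <- c(msg, "fEnd exceeds the Nyquist frequency fs/2")
  if (object@duration <= 2 * object@ramp)
    msg <- c(msg, "duration must exceed twice the ramp length")
  if (length(msg)) msg else TRUE
})

#' Construct a SweepSpec
#'
#' @param fStart,fEnd sweep endpoints (Hz)
#' @param duration sweep duration (s)
#' @param level level (dB SPL)
#' @param ramp raised-cosine ramp (s)
#' @param fs sampling rate (Hz)
#' @return a [SweepSpec-class] object
#' @examples
#' probeSweep()            # the default 40-dB probe, 0.5 -> 8 kHz in 2.05 s
#' sweepSpec(1000, 2000, duration = 0.5, level = 30)
#' @export
sweepSpec <- function(fStart, fEnd, duration, level, ramp = 0.025, fs = 50e3) {
  new("SweepSpec", fStart = fStart, fEnd = fEnd, duration = duration,
      level = level, ramp = ramp, fs = fs)
}

#' @rdname sweepSpec
#' @export
probeSweep <- function(fs = 50e3)
  sweepSpec(500, 8000, duration = 2.05, level = 40, ramp = 0.025, fs = fs)

#' @rdname sweepSpec
#' @export
suppressorSweep <- function(fs = 50e3)
  sweepSpec(540, 8040, duration = 2.05, level = 55, ramp = 0.025, fs = fs)

#' Parametric emission model for the synthetic ear
#'
#' Describes the emission embedded in a synthetic recording: a frequency-
#' dependent level profile (dB SPL), a frequency-dependent group-delay profile
#' (s), spectral notches (Gaussian dips in dB on a log2-frequency axis), and
#' the fraction of the emission removed when the suppressor is present.
#'
#' @slot levelProfile function(freq Hz) -> emission level (dB SPL)
#' @slot delayProfile function(freq Hz) -> group delay (s), non-negative
#' @slot notches data.frame with columns `center_hz`, `depth_db`,
#'   `width_octaves` (Gaussian sigma on the log2-frequency axis)
#' @slot suppressionFraction fraction of the emission suppressed in the
#'   combined probe+suppressor condition, in `[0, 1]`
#' @export
setClass("EmissionModel",
  representation(levelProfile = "function", delayProfile = "function",
                 notches = "data.frame", suppressionFraction = "numeric"))

setValidity("EmissionModel", function(object) {
  msg <- character()
  f <- c(500, 1000, 2000, 4000, 8000)
  if (!all(is.finite(object@levelProfile(f))))
    msg <- c(msg, "levelProfile must be finite on [0.5, 8] kHz")
  if (any(object@delayProfile(f) < 0))
    msg <- c(msg, "delayProfile must be non-negative")
  sf <- object@suppressionFraction
  if (length(sf) != 1 || sf < 0 || sf > 1)
    msg <- c(msg, "suppressionFraction must be a scalar in [0, 1]")
  if (nrow(object@notches) &&
      !all(c("center_hz", "depth_db", "width_octaves") %in% names(object@notches)))
    msg <- c(msg, "notches needs columns center_hz, depth_db, width_octaves")
  if (length(msg)) msg else TRUE
})

#' Three-condition swept-tone recording session
#'
#' Holds the repetition waveforms for the probe-alone, suppressor-alone and
#' combined conditions of the suppression paradigm, plus the sweep metadata.
#' Waveform matrices are samples x repetitions, in Pa.
#'
#' @slot waveforms named list (`probe`, `suppressor`, `both`) of numeric
#'   matrices, samples x repetitions
#' @slot sweeps named list of [SweepSpec-class] per condition
#' @slot fs sampling rate (Hz), common to all conditions
#' @slot metadata list; session/ear identifiers and, for synthetic sessions,
#'   the ground truth
#' @export
setClass("RecordingSession",
  representation(waveforms = "list", sweeps = "list", fs = "numeric",
                 metadata = "list"))

setValidity("RecordingSession", function(object) {
  msg <- character()
  cond <- c("probe", "suppressor", "both")
  if (!all(cond %in% names(object@waveforms)))
    msg <- c(msg, "waveforms must have elements probe, suppressor, both")
  else {
    n <- vapply(object@waveforms[cond], nrow, 0L)
    if (length(unique(n)) != 1)
      msg <- c(msg, "all conditions must have repetitions of equal length")
  }
  if (!all(cond %in% names(object@sweeps)))
    msg <- c(msg, "sweeps must have elements probe, suppressor, both")
  if (length(msg)) msg else TRUE
})

#' SFOAE spectrum on a swept-frequency grid
#'
#' Complex emission pressure versus frequency as estimated by the windowed
#' least-squares sweep fit, with level, unwrapped phase and (optionally) the
#' odd/even-trial noise floor. `pressure` is the RMS phasor, so
#' `level = 20*log10(Mod(pressure)/20e-6)` is in dB SPL.
#'
#' @slot freq frequency grid (Hz, ascending)
#' @slot pressure complex RMS pressure (Pa)
#' @slot level emission level (dB SPL)
#' @slot phase unwrapped phase (cycles)
#' @slot noiseFloor noise-floor level (dB SPL); `NA` until estimated
#' @export
setClass("SfoaeSpectrum",
  representation(freq = "numeric", pressure = "complex", level = "numeric",
                 phase = "numeric", noiseFloor = "numeric"))

setValidity("SfoaeSpectrum", function(object) {
  msg <- character()
  n <- length(object@freq)
  if (is.unsorted(object@freq, strictly = TRUE))
    msg <- c(msg, "freq must be strictly ascending")
  if (length(object@pressure) != n || length(object@level) != n ||
      length(object@phase) != n || length(object@noiseFloor) != n)
    msg <- c(msg, "freq, pressure, level, phase, noiseFloor must be equal length")
  nz <- which(Mod(object@pressure) > 0)
  if (length(nz) && any(abs(object@level[nz] -
        20 * log10(Mod(object@pressure[nz]) / P_REF)) > 1e-6))
    msg <- c(msg, "level must equal 20*log10(|pressure|/20uPa)")
  if (length(msg)) msg else TRUE
})

#' SFOAE phase-gradient delay curve
#'
#' N_SFOAE, the emission delay in stimulus cycles, per frequency, with a
#' validity mask carrying the exclusion reason (`none`, `low_snr`, `trough`)
#' for every grid point.
#'
#' @slot freq frequency grid (Hz)
#' @slot nsfoae delay in stimulus cycles
#' @slot valid logical mask, TRUE where the point survives the exclusions
#' @slot reason character, one of "none", "low_snr", "trough" per point
#' @export
setClass("DelayCurve",
  representation(freq = "numeric", nsfoae = "numeric", valid = "logical",
                 reason = "character"))

setValidity("DelayCurve", function(object) {
  msg <- character()
  n <- length(object@freq)
  if (length(object@nsfoae) != n || length(object@valid) != n ||
      length(object@reason) != n)
    msg <- c(msg, "freq, nsfoae, valid, reason must be equal length")
  if (any(object@valid & !is.finite(object@nsfoae)))
    msg <- c(msg, "nsfoae must be finite wherever valid")
  if (!all(object@reason %in% c("none", "low_snr", "trough")))
    msg <- c(msg, "reason must be one of none, low_snr, trough")
  if (length(msg)) msg else TRUE
})

#' Auditory-nerve frequency-threshold tuning curve
#'
#' A fiber's pure-tone threshold as a function of frequency. Frequencies are
#' stored ascending regardless of acquisition order (threshold tracking
#' proceeds downward in frequency in vivo).
#'
#' @slot freq tone frequencies (Hz, strictly ascending)
#' @slot threshold thresholds (dB SPL)
#' @slot fiberId fiber identifier
#' @slot truth list; for synthetic fibers, the generating `FiberSpec` values
#' @export
setClass("TuningCurve",
  representation(freq = "numeric", threshold = "numeric", fiberId = "character",
                 truth = "list"))

setValidity("TuningCurve", function(object) {
  msg <- character()
  if (length(object@freq) < 7)
    msg <- c(msg, "a tuning curve needs at least 7 points")
  if (is.unsorted(object@freq, strictly = TRUE))
    msg <- c(msg, "freq must be strictly ascending")
  if (length(object@threshold) != length(object@freq))
    msg <- c(msg, "freq and threshold must be equal length")
  if (!all(is.finite(object@threshold)))
    msg <- c(msg, "thresholds must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a TuningCurve
#'
#' @param freq frequencies (Hz); any order, stored ascending
#' @param threshold thresholds (dB SPL)
#' @param fiberId identifier
#' @param truth optional list of ground-truth values (synthetic fibers)
#' @return a [TuningCurve-class]
#' @export
tuningCurve <- function(freq, threshold, fiberId = "fiber", truth = list()) {
  o <- order(freq)
  new("TuningCurve", freq = as.numeric(freq[o]),
      threshold = as.numeric(threshold[o]),
      fiberId = as.character(fiberId), truth = truth)
}

#' Gaussian-weighted trend with bootstrap confidence band
#'
#' A local weighted-mean trend on a log-spaced frequency grid, with optional
#' 95% percentile-bootstrap confidence limits.
#'
#' @slot freq evaluation grid (Hz, log-spaced ascending)
#' @slot mean trend value per grid point (NA where undefined)
#' @slot ciLo,ciHi 95% bootstrap bounds (NA when not computed / unreliable)
#' @slot sigmaOctaves Gaussian kernel sigma (octaves)
#' @slot nBoot bootstrap repetitions (0 when no CI)
#' @slot resampleUnit resampling unit label ("ear", "fiber", "none")
#' @export
setClass("TrendCurve",
  representation(freq = "numeric", mean = "numeric", ciLo = "numeric",
                 ciHi = "numeric", sigmaOctaves = "numeric", nBoot = "numeric",
                 resampleUnit = "character"))

setValidity("TrendCurve", function(object) {
  msg <- character()
  n <- length(object@freq)
  if (length(object@mean) != n || length(object@ciLo) != n ||
      length(object@ciHi) != n)
    msg <- c(msg, "freq, mean, ciLo, ciHi must be equal length")
  if (is.unsorted(object@freq, strictly = TRUE))
    msg <- c(msg, "freq must be strictly ascending")
  ok <- is.finite(object@ciLo) & is.finite(object@ciHi)
  if (any(object@ciLo[ok] > object@ciHi[ok]))
    msg <- c(msg, "ciLo must not exceed ciHi")
  if (length(msg)) msg else TRUE
})

#' Cross-species tuning-ratio curve
#'
#' The frequency-dependent quotient r = QERB / N_SFOAE used to convert
#' emission delays into tuning-sharpness predictions. Points built from
#' extrapolated Q10 (beyond the empirically sampled CF range) are marked in
#' `extended` and may carry a +/-1 SE band.
#'
#' @slot freq frequency grid (Hz)
#' @slot r tuning ratio per grid point
#' @slot lo,hi band edges where derived from extrapolation SE (NA elsewhere)
#' @slot extended logical, TRUE where built from extrapolated Q10
#' @slot species source species tag
#' @export
setClass("TuningRatioCurve",
  representation(freq = "numeric", r = "numeric", lo = "numeric",
                 hi = "numeric", extended = "logical", species = "character"))

setValidity("TuningRatioCurve", function(object) {
  msg <- character()
  n <- length(object@freq)
  if (length(object@r) != n || length(object@extended) != n ||
      length(object@lo) != n || length(object@hi) != n)
    msg <- c(msg, "freq, r, lo, hi, extended must be equal length")
  if (any(object@r[is.finite(object@r)] <= 0))
    msg <- c(msg, "r must be positive where defined")
  if (any(object@extended) && any(diff(which(object@extended)) != 1))
    msg <- c(msg, "extended points must be contiguous")
  if (length(msg)) msg else TRUE
})

#' SFOAE-based prediction of QERB
#'
#' @slot freq frequency grid (Hz)
#' @slot qerb predicted QERB
#' @slot lo,hi bounds propagated from the tuning ratio's SE band (NA elsewhere)
#' @export
setClass("PredictionCurve",
  representation(freq = "numeric", qerb = "numeric", lo = "numeric",
                 hi = "numeric"))

setValidity("PredictionCurve", function(object) {
  n <- length(object@freq)
  if (length(object@qerb) != n || length(object@lo) != n ||
      length(object@hi) != n)
    "freq, qerb, lo, hi must be equal length" else TRUE
})
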