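#' Accessors for cochleartune objects
#'
#' `freqHz()` returns the frequency grid; `levelDb()` the level in dB SPL;
#' `phaseCycles()` the unwrapped phase; `noiseFloorDb()` the noise-floor
#' level; `nsfoaeCycles()` the delay in stimulus cycles; `validPoints()` the
#' exclusion mask; `trendMean()`, `trendCi()` the trend and its bootstrap
#' band; `tuningR()` the tuning ratio.
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("freqHz", function(x) standardGeneric("freqHz"))
#' @rdname accessors
#' @export
setGeneric("levelDb", function(x) standardGeneric("levelDb"))
#' @rdname accessors
#' @export
setGeneric("phaseCycles", function(x) standardGeneric("phaseCycles"))
#' @rdname accessors
#' @export
setGeneric("noiseFloorDb", function(x) standardGeneric("noiseFloorDb"))
#' @rdname accessors
#' @export
setGeneric("nsfoaeCycles", function(x) standardGeneric("nsfoaeCycles"))
#' @rdname accessors
#' @export
setGeneric("validPoints", function(x) standardGeneric("validPoints"))
#' @rdname accessors
#' @export
setGeneric("trendMean", function(x) standardGeneric("trendMean"))
#' @rdname accessors
#' @export
setGeneric("trendCi", function(x) standardGeneric("trendCi"))
#' @rdname accessors
#' @export
setGeneric("tuningR", function(x) standardGeneric("tuningR"))

#' @rdname accessors
setMethod("freqHz", "SfoaeSpectrum", function(x) x@freq)
#' @rdname accessors
setMethod("freqHz", "DelayCurve", function(x) x@freq)
#' @rdname accessors
setMethod("freqHz", "TuningCurve", function(x) x@freq)
#' @rdname accessors
setMethod("freqHz", "TrendCurve", function(x) x@freq)
#' @rdname accessors
setMethod("freqHz", "TuningRatioCurve", function(x) x@freq)
#' @rdname accessors
setMethod("freqHz", "PredictionCurve", function(x) x@freq)
#' @rdname accessors
setMethod("levelDb", "SfoaeSpectrum", function(x) x@level)
#' @rdname accessors
setMethod("phaseCycles", "SfoaeSpectrum", function(x) x@phase)
#' @rdname accessors
setMethod("noiseFloorDb", "SfoaeSpectrum", function(x) x@noiseFloor)
#' @rdname accessors
setMethod("nsfoaeCycles", "DelayCurve", function(x) x@nsfoae)
#' @rdname accessors
setMethod("validPoints", "DelayCurve", function(x) x@valid)
#' @rdname accessors
setMethod("trendMean", "TrendCurve", function(x) x@mean)
#' @rdname accessors
setMethod("trendCi", "TrendCurve",
          function(x) cbind(lo = x@ciLo, hi = x@ciHi))
#' @rdname accessors
setMethod("tuningR", "TuningRatioCurve", function(x) x@r)

#' @export
setMethod("show", "SweepSpec", function(object) {
  cat(sprintf("SweepSpec: %.0f -> %.0f Hz in %.3g s at %g dB SPL (fs %g Hz, ramp %g ms)\n",
              object@fStart, object@fEnd, object@duration, object@level,
              object@fs, 1e3 * object@ramp))
})

#' @export
setMethod("show", "RecordingSession", function(object) {
  n <- ncol(object@waveforms$probe)
  cat(sprintf("RecordingSession '%s': %d reps x 3 conditions, %d samples at %g Hz\n",
              if (is.null(object@metadata$session)) "?" else object@metadata$session,
              n, nrow(object@waveforms$probe), object@fs))
})

#' @export
setMethod("show", "SfoaeSpectrum", function(object) {
  cat(sprintf("SfoaeSpectrum: %d grid points, %.0f-%.0f Hz", length(object@freq),
              min(object@freq), max(object@freq)))
  if (any(is.finite(object@noiseFloor)))
    cat(sprintf(", median noise floor %.1f dB SPL",
                stats::median(object@noiseFloor, na.rm = TRUE)))
  cat("\n")
})

#' @export
setMethod("show", "DelayCurve", function(object) {
  cat(sprintf("DelayCurve: %d points, %d valid (%d low_snr, %d trough)\n",
              length(object@freq), sum(object@valid),
              sum(object@reason == "low_snr"), sum(object@reason == "trough")))
})

#' @export
setMethod("show", "TuningCurve", function(object) {
  cat(sprintf("TuningCurve '%s': %d points, %.0f-%.0f Hz, min threshold %.1f dB SPL\n",
              object@fiberId, length(object@freq), min(object@freq),
              max(object@freq), min(object@threshold)))
})

#' @export
setMethod("show", "TrendCurve", function(object) {
  cat(sprintf("TrendCurve: sigma %.2g octaves, %d grid points (%d defined)",
              object@sigmaOctaves, length(object@freq),
              sum(is.finite(object@mean))))
  if (object@nBoot > 0)
    cat(sprintf(", 95%% CI from %d bootstrap reps over %ss",
                object@nBoot, object@resampleUnit))
  cat("\n")
})

#' @export
setMethod("show", "TuningRatioCurve", function(object) {
  cat(sprintf("TuningRatioCurve (%s): %d points, %d extended; r %.2f -> %.2f\n",
              object@species, length(object@freq), sum(object@extended),
              object@r[1], object@r[length(object@r)]))
})

#' @export
setMethod("show", "PredictionCurve", function(object) {
  cat(sprintf("PredictionCurve: %d points, %.0f-%.0f Hz\n",
              length(object@freq), min(object@freq), max(object@freq)))
})

#' Convert cochleartune curves to data frames
#'
#' @param x object to convert
#' @param row.names,optional,... ignored, for generic compatibility
#' @return a `data.frame` with one row per grid point
#' @name as.data.frame-methods
NULL

#' @rdname as.data.frame-methods
#' @export
as.data.frame.SfoaeSpectrum <- function(x, row.names = NULL, optional = FALSE, ...)
  data.frame(freq_hz = x@freq, level_db_spl = x@level, phase_cycles = x@phase,
             noise_floor_db_spl = x@noiseFloor)

#' @rdname as.data.frame-methods
#' @export
as.data.frame.DelayCurve <- function(x, row.names = NULL, optional = FALSE, ...)
  data.frame(freq_hz = x@freq, n_sfoae_cycles = x@nsfoae, valid = x@valid,
             exclusion_reason = x@reason)

#' @rdname as.data.frame-methods
#' @export
as.data.frame.TuningCurve <- function(x, row.names = NULL, optional = FALSE, ...)
  data.frame(fiber_id = x@fiberId, freq_hz = x@freq, threshold_db_spl = x@threshold)

#' @rdname as.data.frame-methods
#' @export
as.data.frame.TrendCurve <- function(x, row.names = NULL, optional = FALSE, ...)
  data.frame(freq_hz = x@freq, mean = x@mean, ci_lo = x@ciLo, ci_hi = x@ciHi)

#' @rdname as.data.frame-methods
#' @export
as.data.frame.TuningRatioCurve <- function(x, row.names = NULL, optional = FALSE, ...)
  data.frame(freq_hz = x@freq, r = x@r, lo = x@lo, hi = x@hi, extended = x@extended)

#' @rdname as.data.frame-methods
#' @export
as.data.frame.PredictionCurve <- function(x, row.names = NULL, optional = FALSE, ...)
  data.frame(freq_hz = x@freq, q_erb_predicted = x@qerb, lo = x@lo, hi = x@hi)
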