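# Tuning-curve metrics: five-point triangular smoothing, CF, Q10 by the
# 10-dB bandwidth, and QERB by the area under the inverted curve.

#' Five-point triangular smoothing of a tuning curve
#'
#' Convolves the threshold track with the kernel (1,2,3,2,1)/9. At the edges
#' the kernel is renormalized over the in-range taps, so no thresholds are
#' fabricated beyond the measured span. The frequency grid is unchanged.
#'
#' @param curve a [TuningCurve-class] with at least 5 points
#' @return the smoothed [TuningCurve-class]
#' @export
smoothTriangular <- function(curve) {
  th <- curve@threshold
  n <- length(th)
  if (n < 5) stop("triangular smoothing needs at least 5 points")
  k <- c(1, 2, 3, 2, 1)
  sm <- vapply(seq_len(n), function(i) {
    j <- (i - 2):(i + 2)
    ok <- j >= 1 & j <= n
    sum(k[ok] * th[j[ok]]) / sum(k[ok])
  }, 0)
  new("TuningCurve", freq = curve@freq, threshold = sm,
      fiberId = curve@fiberId, truth = curve@truth)
}

#' Characteristic frequency: the frequency of lowest threshold
#'
#' Exact ties are resolved to the geometric mean of the tied frequencies
#' (symmetric on the log-frequency axis). A minimum at either end of the
#' grid flags the curve as unreliable (truncated tip).
#'
#' @param curve a (smoothed) [TuningCurve-class]
#' @return list(cf, thresholdAtCf, reliable)
#' @export
findCf <- function(curve) {
  th <- curve@threshold
  tied <- which(th == min(th))
  cf <- exp(mean(log(curve@freq[tied])))
  reliable <- !(1 %in% tied || length(th) %in% tied)
  list(cf = cf, thresholdAtCf = min(th), reliable = reliable)
}

# first crossing of `target` on one flank, moving outward from the tip index;
# linear interpolation in (log f, dB). dir = -1 (low flank) or +1 (high flank)
flankCrossing <- function(freq, th, tipIdx, target, dir) {
  idx <- if (dir < 0) rev(seq_len(tipIdx)) else tipIdx:length(th)
  above <- which(th[idx] >= target)
  if (!length(above)) return(NA_real_)
  iA <- idx[above[1]]
  if (iA == tipIdx) return(freq[tipIdx])
  iB <- iA - dir  # neighbour nearer the tip, below target
  lf <- log(freq[iB]) + (target - th[iB]) * (log(freq[iA]) - log(freq[iB])) /
        (th[iA] - th[iB])
  exp(lf)
}

#' Q10: CF over the 10-dB bandwidth
#'
#' The bandwidth is measured 10 dB above the lowest threshold, with the first
#' crossings found moving outward from CF and interpolated linearly in
#' (log frequency, dB). A flank that never reaches +10 dB leaves the metric
#' undefined (`NA`), not extrapolated.
#'
#' @param curve a (smoothed) [TuningCurve-class]
#' @param cf,thrCf as from [findCf()]
#' @return list(q10, bw10, fLo, fHi)
#' @export
tuningQ10 <- function(curve, cf, thrCf) {
  tipIdx <- which.min(abs(log(curve@freq / cf)))
  target <- thrCf + 10
  fLo <- flankCrossing(curve@freq, curve@threshold, tipIdx, target, -1)
  fHi <- flankCrossing(curve@freq, curve@threshold, tipIdx, target, +1)
  if (is.na(fLo) || is.na(fHi) || fHi <= fLo)
    return(list(q10 = NA_real_, bw10 = NA_real_, fLo = fLo, fHi = fHi))
  bw <- fHi - fLo
  list(q10 = cf / bw, bw10 = bw, fLo = fLo, fHi = fHi)
}

#' QERB: CF over the equivalent rectangular bandwidth
#'
#' The inverted tuning curve is weighted as linear power re the tip,
#' `W(f) = 10^((thrCf - T(f))/10)`, and the ERB is its area by trapezoidal
#' integration on the linear (Hz) frequency axis over the measured span.
#'
#' @param curve a (smoothed) [TuningCurve-class]
#' @param cf,thrCf as from [findCf()]
#' @return list(qErb, erb, truncated) where `truncated` flags a span of less
#'   than one octave around CF
#' @export
tuningQerb <- function(curve, cf, thrCf) {
  f <- curve@freq
  w <- 10^((thrCf - curve@threshold) / 10)
  erb <- sum(diff(f) * (w[-1] + w[-length(w)]) / 2)
  truncated <- log2(max(f) / cf) < 0.5 || log2(cf / min(f)) < 0.5
  list(qErb = cf / erb, erb = erb, truncated = truncated)
}

#' Compute all tuning metrics for one fiber
#'
#' Applies five-point triangular smoothing (the processing order: smoothing
#' precedes every metric), then CF, Q10 and QERB.
#'
#' @param curve a [TuningCurve-class]
#' @param smooth apply [smoothTriangular()] first (default TRUE)
#' @return one-row data.frame: `fiber_id, cf_hz, threshold_at_cf_db, q10,
#'   q_erb, erb_hz, bw10_hz, flags`
#' @export
fiberMetrics <- function(curve, smooth = TRUE) {
  sm <- if (smooth) smoothTriangular(curve) else curve
  tip <- findCf(sm)
  q <- tuningQ10(sm, tip$cf, tip$thresholdAtCf)
  e <- tuningQerb(sm, tip$cf, tip$thresholdAtCf)
  flags <- c(if (!tip$reliable) "edge_minimum",
             if (is.na(q$q10)) "q10_undefined",
             if (e$truncated) "erb_truncated")
  data.frame(fiber_id = curve@fiberId, cf_hz = tip$cf,
             threshold_at_cf_db = tip$thresholdAtCf, q10 = q$q10,
             q_erb = e$qErb, erb_hz = e$erb, bw10_hz = q$bw10,
             flags = paste(flags, collapse = ";"))
}

#' Metrics for a list of tuning curves
#'
#' @param curves list of [TuningCurve-class]
#' @param smooth apply smoothing first
#' @return data.frame, one row per fiber (see [fiberMetrics()])
#' @export
populationMetrics <- function(curves, smooth = TRUE)
  do.call(rbind, lapply(curves, fiberMetrics, smooth = smooth))

#' Median and interquartile range of QERB/Q10
#'
#' @param metrics data.frame from [populationMetrics()]
#' @return list(median, iqr = c(lo, hi), n) over fibers with both metrics
#'   defined (quartiles by the default type-7 rule)
#' @export
summarizeRatio <- function(metrics) {
  r <- metrics$q_erb / metrics$q10
  r <- r[is.finite(r)]
  if (!length(r)) stop("no fiber has both Q10 and QERB defined")
  list(median = stats::median(r),
       iqr = unname(stats::quantile(r, c(0.25, 0.75))),
       n = length(r))
}
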