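# SFOAE extraction: artifact excision, repetition averaging, suppression-
# paradigm vector subtraction, swept-tone least-squares spectral analysis,
# odd/even noise floor, phase-gradient delay and the two exclusion rules.

#' Excise transient artifacts from a repetition waveform
#'
#' Every sample whose magnitude exceeds `threshold` triggers removal of a
#' 20-ms window centered on it (overlapping windows merge). Excised samples
#' are set to `NA` so that downstream averaging ignores them rather than
#' being biased by zeros.
#'
#' @param rep numeric waveform (Pa)
#' @param threshold artifact threshold (Pa, > 0); see [artifactThreshold()]
#' @param fs sampling rate (Hz)
#' @param windowSec excision window length (s), default 20 ms
#' @return list(wave = waveform with NA at excised samples,
#'   log = data.frame(start_s, end_s) of excised intervals,
#'   dropped = TRUE if > 50% of the repetition was excised)
#' @export
rejectArtifacts <- function(rep, threshold, fs, windowSec = 0.020) {
  stopifnot(threshold > 0)
  hits <- which(abs(rep) > threshold)
  if (!length(hits))
    return(list(wave = rep, log = data.frame(start_s = numeric(), end_s = numeric()),
                dropped = FALSE))
  half <- round(windowSec * fs / 2)
  bad <- rep(FALSE, length(rep))
  lo <- pmax(hits - half, 1L)
  hi <- pmin(hits + half - 1L, length(rep))
  for (i in seq_along(hits)) bad[lo[i]:hi[i]] <- TRUE
  rep[bad] <- NA_real_
  runs <- rle(bad)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  log <- data.frame(start_s = (starts[keep] - 1) / fs, end_s = ends[keep] / fs)
  dropped <- mean(bad) > 0.5
  if (dropped)
    warning("more than 50% of the repetition excised; repetition dropped")
  list(wave = rep, log = log, dropped = dropped)
}

#' Default artifact threshold for a repetition ensemble
#'
#' Six times the median absolute deviation of the pooled samples.
#'
#' @param reps samples x repetitions matrix
#' @return threshold (Pa)
#' @export
artifactThreshold <- function(reps) 6 * stats::mad(as.vector(reps))

#' Average cleaned repetitions
#'
#' Per-sample mean over repetitions, ignoring excised (`NA`) samples. Samples
#' with no surviving repetition are interpolated linearly and reported.
#'
#' @param reps samples x repetitions matrix (NAs mark excised samples), or a
#'   list of equal-length waveforms
#' @return list(wave = mean waveform, nContrib = contributing-rep count per
#'   sample, interpolated = indices that had zero contributors)
#' @export
averageReps <- function(reps) {
  if (is.list(reps)) reps <- do.call(cbind, reps)
  if (ncol(reps) < 2) stop("need at least 2 surviving repetitions")
  nContrib <- rowSums(!is.na(reps))
  wave <- rowMeans(reps, na.rm = TRUE)
  gap <- which(nContrib == 0)
  if (length(gap)) {
    ok <- which(nContrib > 0)
    wave[gap] <- stats::approx(ok, wave[ok], xout = gap, rule = 2)$y
  }
  list(wave = wave, nContrib = nContrib, interpolated = gap)
}

#' Suppression-paradigm vector subtraction
#'
#' The emission pressure is the samplewise residual
#' `P_probe + P_suppressor - P_probe+suppressor`: stimulus components cancel
#' by linearity and the emission (absent in the suppressed condition)
#' remains.
#'
#' @param pProbe,pSupp,pBoth mean waveforms (Pa), equal length
#' @return residual waveform (Pa)
#' @export
vectorSubtract <- function(pProbe, pSupp, pBoth) {
  if (length(pProbe) != length(pSupp) || length(pProbe) != length(pBoth))
    stop("waveform lengths differ")
  pProbe + pSupp - pBoth
}

hannWindow <- function(m) 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))

#' Least-squares spectral estimate along a sweep
#'
#' At analysis times spaced by `hop`, fits a Hann-weighted cosine/sine
#' quadrature pair that follows the sweep's instantaneous phase over a short
#' window, yielding a complex amplitude assigned to the instantaneous sweep
#' frequency at the window center. `pressure` is the RMS phasor, and `phase`
#' is the unwrapped phase in cycles relative to the sweep stimulus. Samples
#' flagged `NA` (artifact excision) get zero weight; windows extending past
#' the signal edges are dropped.
#'
#' @param wave waveform (Pa); may contain NA
#' @param sweep the probe [SweepSpec-class] defining the analysis phase track
#' @param window analysis window length (s); default 20 ms
#' @param hop hop between analysis times (s); default 5 ms
#' @return an [SfoaeSpectrum-class] (noise floor unset)
#' @export
lsfSpectrum <- function(wave, sweep, window = 0.020, hop = 0.005) {
  stopifnot(hop > 0)
  fs <- sweep@fs
  n <- length(wave)
  m <- round(window * fs)
  if (m < 8 || m > n) stop("window must fit inside the signal")
  # local-cycle coverage check at the lowest analysis frequency
  if (window * sweep@fStart < 3)
    stop("window covers fewer than 3 cycles of the lowest sweep frequency")
  centers <- seq(window / 2, n / fs - window / 2, by = hop)
  if (length(centers) < 1) stop("no analysis windows fit the signal")
  t <- (seq_len(n) - 1) / fs
  phi <- sweepPhase(sweep, t)
  w0 <- hannWindow(m)
  off <- seq_len(m) - 1
  cosAll <- cos(phi); sinAll <- sin(phi)

  est <- vapply(centers, function(tc) {
    i0 <- round((tc - window / 2) * fs) + 1
    idx <- i0 + off
    x <- wave[idx]
    w <- w0
    bad <- is.na(x)
    if (any(bad)) { w[bad] <- 0; x[bad] <- 0 }
    cb <- cosAll[idx]; sb <- sinAll[idx]
    scc <- sum(w * cb * cb); sss <- sum(w * sb * sb); scs <- sum(w * cb * sb)
    det <- scc * sss - scs^2
    if (det <= 0) return(c(NA_real_, NA_real_))
    bx <- c(sum(w * cb * x), sum(w * sb * x))
    a <- (sss * bx[1] - scs * bx[2]) / det
    b <- (scc * bx[2] - scs * bx[1]) / det
    c(a, b)
  }, numeric(2))

  freq <- sweepFreq(sweep, centers)
  keep <- is.finite(est[1, ])
  pressure <- complex(real = est[1, keep], imaginary = -est[2, keep]) / sqrt(2)
  phase <- unwrapCycles(Arg(pressure) / (2 * pi))
  level <- ifelse(Mod(pressure) > 0, 20 * log10(Mod(pressure) / P_REF), -Inf)
  new("SfoaeSpectrum", freq = freq[keep], pressure = pressure, level = level,
      phase = phase, noiseFloor = rep(NA_real_, sum(keep)))
}

#' Unwrap a phase sequence in cycles
#'
#' Removes jumps larger than half a cycle between neighbouring points.
#'
#' @param p phase (cycles)
#' @return unwrapped phase (cycles)
#' @export
unwrapCycles <- function(p) {
  d <- diff(p)
  p - c(0, cumsum(round(d)))
  # round(d) removes integer-cycle jumps; equivalent to the standard
  # half-cycle jump correction since |corrected diff| <= 0.5
}

#' Odd/even-trial noise floor
#'
#' Forms the suppression-paradigm residual separately from odd- and from
#' even-indexed repetitions, analyzes half their difference with the same
#' spectral estimator as the signal, and reports its level per frequency.
#' Halving makes the estimate track the noise level of the full-average
#' residual for equal split sizes. Unequal odd/even counts are truncated to
#' the smaller count.
#'
#' @param repsProbe,repsSupp,repsBoth cleaned samples x repetitions matrices
#' @param sweep the probe [SweepSpec-class]
#' @param window,hop spectral-analysis parameters as in [lsfSpectrum()]
#' @return noise-floor level (dB SPL) per grid frequency, with the grid as
#'   attribute `freq`
#' @export
estimateNoiseFloor <- function(repsProbe, repsSupp, repsBoth, sweep,
                               window = 0.020, hop = 0.005) {
  nrep <- min(ncol(repsProbe), ncol(repsSupp), ncol(repsBoth))
  if (nrep < 4) stop("need at least 4 repetitions per condition (2 odd, 2 even)")
  odd <- seq(1, nrep, by = 2); even <- seq(2, nrep, by = 2)
  k <- min(length(odd), length(even))
  odd <- odd[seq_len(k)]; even <- even[seq_len(k)]
  res <- function(idx)
    vectorSubtract(averageReps(repsProbe[, idx])$wave,
                   averageReps(repsSupp[, idx])$wave,
                   averageReps(repsBoth[, idx])$wave)
  d <- (res(odd) - res(even)) / 2
  spec <- lsfSpectrum(d, sweep, window, hop)
  structure(spec@level, freq = spec@freq)
}

#' Phase-gradient delay in stimulus cycles
#'
#' `N_SFOAE(f) = -f * dphi/df` with phase in cycles. The gradient is
#' estimated by a local linear regression of phase on frequency over a
#' sliding window of `smoothOctaves` half-width on the octave axis, with
#' tricube distance weights optionally multiplied by the local signal power
#' `|pressure|^2`. When the spectrum carries a noise floor, points whose
#' level fails the same SNR criterion used by [applyExclusions()] (less than
#' `gateDb` above the median noise floor) get zero weight in the regression:
#' this emphasizes phase gradients near magnitude maxima, where the phase is
#' reliable, and removes the leverage of noise-dominated grid points whose
#' unwrapped phase is meaningless. With `smoothOctaves = 0` the gradient falls back
#' to plain centered differences on the grid (one-sided at the edges), which
#' is unbiased but propagates grid-point phase noise directly. Phase must be
#' unwrapped (as produced by [lsfSpectrum()]).
#'
#' @param spectrum an [SfoaeSpectrum-class]
#' @param smoothOctaves half-width of the local regression window (octaves);
#'   0 for centered differences
#' @param weightByPower weight the local regression by `|pressure|^2`
#' @param gateDb SNR gate (dB re median noise floor) for regression weights
#' @return a [DelayCurve-class] with all points marked valid
#' @export
phaseGradientDelay <- function(spectrum, smoothOctaves = 0.3,
                               weightByPower = TRUE, gateDb = 10) {
  f <- spectrum@freq; p <- spectrum@phase
  n <- length(f)
  if (n < 3) stop("need at least 3 grid points for a phase gradient")
  if (smoothOctaves <= 0) {
    dp <- numeric(n)
    dp[1] <- (p[2] - p[1]) / (f[2] - f[1])
    dp[n] <- (p[n] - p[n - 1]) / (f[n] - f[n - 1])
    mid <- 2:(n - 1)
    dp[mid] <- (p[mid + 1] - p[mid - 1]) / (f[mid + 1] - f[mid - 1])
  } else {
    lf <- log2(f)
    pw <- if (weightByPower) Mod(spectrum@pressure)^2 else rep(1, n)
    nf <- spectrum@noiseFloor
    gate <- rep(TRUE, n)
    if (any(is.finite(nf)))
      gate <- spectrum@level >= stats::median(nf, na.rm = TRUE) + gateDb
    pw <- pw * gate
    # contiguous runs of gate-passing points: the regression never crosses a
    # gated-out gap (e.g. a notch core), where the unwrapped phase offset is
    # unreliable
    runId <- cumsum(c(TRUE, diff(gate) != 0))
    dp <- vapply(seq_len(n), function(i) {
      sel <- which(abs(lf - lf[i]) <= smoothOctaves)
      if (gate[i]) sel <- sel[runId[sel] == runId[i]]
      # a regression support much narrower than the window (a short segment
      # truncated by the SNR gate) gives an unstable slope; flag it instead
      if (length(sel) < 3 || diff(range(lf[sel])) < smoothOctaves / 2)
        return(NA_real_)
      u <- abs(lf[sel] - lf[i]) / smoothOctaves
      w <- (1 - u^3)^3 * pw[sel]
      if (sum(w) <= 0) return(NA_real_)
      x <- f[sel]; y <- p[sel]
      xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
      sxx <- sum(w * (x - xm)^2)
      if (sxx <= 0) return(NA_real_)
      sum(w * (x - xm) * (y - ym)) / sxx
    }, 0)
  }
  new("DelayCurve", freq = f, nsfoae = -f * dp,
      valid = is.finite(dp), reason = ifelse(is.finite(dp), "none", "low_snr"))
}

#' White-noise RMS for a target single-repetition SNR
#'
#' Returns the white-noise RMS (Pa) at which a tone of level `levelDbSpl`
#' sits `snrDb` above the single-repetition noise floor of the
#' three-condition residual analyzed with the Hann-weighted least-squares
#' fit of [lsfSpectrum()] (noise variance per estimate approximately
#' `9 sigma^2 / M` for window length `M` samples across the three averaged
#' conditions).
#'
#' @param levelDbSpl emission level (dB SPL)
#' @param snrDb target SNR (dB)
#' @param window analysis window (s)
#' @param fs sampling rate (Hz)
#' @return noise RMS (Pa)
#' @export
noiseRmsForSnr <- function(levelDbSpl, snrDb, window = 0.020, fs = 50e3)
  P_REF * 10^((levelDbSpl - snrDb) / 20) * sqrt(window * fs / 9)

# local extrema of a level curve; returns indices
localMinima <- function(x) which(diff(sign(diff(x))) > 0) + 1
localMaxima <- function(x) which(diff(sign(diff(x))) < 0) + 1

#' Apply the SNR and magnitude-trough exclusion rules
#'
#' Points less than `snrDb` (10 dB) above the *median* of the estimated
#' noise floor are rejected (`low_snr`). Points at the base of magnitude
#' troughs are rejected (`trough`): a trough is a local minimum of SFOAE
#' level at least 10 dB below both flanking local maxima, and the exclusion
#' covers points within 1/24 octave of the minimum or within 3 dB of the
#' minimum level inside the notch.
#'
#' @param delay a [DelayCurve-class]
#' @param spectrum the matching [SfoaeSpectrum-class] (same grid, noise floor
#'   set)
#' @param snrDb SNR criterion re the median noise floor (dB)
#' @param troughDepthDb minimum trough depth re both flanking maxima (dB)
#' @param troughOctaves half-width of the around-minimum exclusion (octaves)
#' @param troughBaseDb points within this of the minimum level, inside the
#'   notch, are excluded (dB)
#' @return the [DelayCurve-class] with `valid`/`reason` updated
#' @export
applyExclusions <- function(delay, spectrum, snrDb = 10, troughDepthDb = 10,
                            troughOctaves = 1 / 24, troughBaseDb = 3) {
  stopifnot(length(delay@freq) == length(spectrum@freq))
  f <- spectrum@freq; lev <- spectrum@level
  reason <- delay@reason
  nfMed <- stats::median(spectrum@noiseFloor, na.rm = TRUE)
  lowSnr <- lev < nfMed + snrDb
  reason[lowSnr & reason == "none"] <- "low_snr"

  mins <- localMinima(lev); maxs <- localMaxima(lev)
  troughMask <- rep(FALSE, length(f))
  for (i in mins) {
    left <- maxs[maxs < i]; right <- maxs[maxs > i]
    iL <- if (length(left)) max(left) else 1L
    iR <- if (length(right)) min(right) else length(f)
    if (lev[iL] - lev[i] >= troughDepthDb && lev[iR] - lev[i] >= troughDepthDb) {
      near <- abs(log2(f / f[i])) <= troughOctaves
      inNotch <- seq_along(f) >= iL & seq_along(f) <= iR &
                 lev <= lev[i] + troughBaseDb
      troughMask <- troughMask | near | inNotch
    }
  }
  reason[troughMask] <- "trough"
  valid <- reason == "none"
  if (!any(valid)) warning("all grid points excluded")
  new("DelayCurve", freq = delay@freq, nsfoae = delay@nsfoae,
      valid = valid, reason = reason)
}

#' Run the full SFOAE extraction on a recording session
#'
#' Pipeline: per-condition artifact excision (default threshold 6 x the MAD
#' of the repetition ensemble) and averaging; suppression-paradigm vector
#' subtraction; least-squares sweep spectrum of the residual; odd/even noise
#' floor; phase-gradient delay; SNR and trough exclusions.
#'
#' @param session a [RecordingSession-class]
#' @param window,hop spectral-analysis parameters (s)
#' @param snrDb SNR exclusion criterion (dB re median noise floor)
#' @param threshold artifact threshold (Pa); default per condition from
#'   [artifactThreshold()]
#' @param smoothOctaves,weightByPower phase-gradient estimator settings, see
#'   [phaseGradientDelay()]
#' @return list with elements `spectrum` ([SfoaeSpectrum-class], noise floor
#'   set), `delay` ([DelayCurve-class], exclusions applied), `residual`
#'   (waveform), and `artifactLog`
#' @examples
#' s <- synthesizeSession(emissionModel(), nReps = 4, noiseRms = 1e-4, seed = 1)
#' ex <- extractSfoae(s)
#' ex$delay
#' @export
extractSfoae <- function(session, window = 0.020, hop = 0.005, snrDb = 10,
                         threshold = NULL, smoothOctaves = 0.3,
                         weightByPower = TRUE) {
  stopifnot(is(session, "RecordingSession"))
  conds <- c("probe", "suppressor", "both")
  cleaned <- list(); logs <- list()
  for (cond in conds) {
    reps <- session@waveforms[[cond]]
    thr <- threshold %||% artifactThreshold(reps)
    out <- lapply(seq_len(ncol(reps)), function(r)
      rejectArtifacts(reps[, r], thr, session@fs))
    keep <- !vapply(out, `[[`, TRUE, "dropped")
    cleaned[[cond]] <- do.call(cbind, lapply(out[keep], `[[`, "wave"))
    logs[[cond]] <- lapply(out, `[[`, "log")
  }
  avg <- lapply(cleaned, function(m) averageReps(m)$wave)
  residual <- vectorSubtract(avg$probe, avg$suppressor, avg$both)
  spec <- lsfSpectrum(residual, session@sweeps$probe, window, hop)
  nf <- estimateNoiseFloor(cleaned$probe, cleaned$suppressor, cleaned$both,
                           session@sweeps$probe, window, hop)
  if (length(nf) != length(spec@freq))
    stop("noise-floor grid does not match the signal grid")
  spec@noiseFloor <- as.numeric(nf)
  validObject(spec)
  delay <- applyExclusions(phaseGradientDelay(spec, smoothOctaves, weightByPower),
                           spec, snrDb = snrDb)
  list(spectrum = spec, delay = delay, residual = residual, artifactLog = logs)
}

#' Write extraction results as CSV
#'
#' Writes `sfoae_spectrum.csv` (`freq_hz, level_db_spl, phase_cycles,
#' noise_floor_db_spl`) and `delay_curve.csv` (`freq_hz, n_sfoae_cycles,
#' valid, exclusion_reason`).
#'
#' @param extraction result of [extractSfoae()]
#' @param dir output directory
#' @return the directory, invisibly
#' @export
writeExtraction <- function(extraction, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(extraction$spectrum),
                   file.path(dir, "sfoae_spectrum.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(extraction$delay),
                   file.path(dir, "delay_curve.csv"), row.names = FALSE)
  invisible(dir)
}
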