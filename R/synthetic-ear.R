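# Synthetic-ear generator: swept-tone SFOAE sessions and auditory-nerve
# tuning curves with known ground truth, emulating the budgerigar recording
# protocol (40-dB probe swept 0.5->8 kHz over 2.05 s, 55-dB suppressor offset
# by 40 Hz, 50 kHz sampling, 25-ms raised-cosine ramps).

#' Instantaneous phase / frequency of a linear sweep
#'
#' @param spec a [SweepSpec-class]
#' @param t times (s)
#' @return phase in radians (`sweepPhase`) or frequency in Hz (`sweepFreq`)
#' @keywords internal
sweepPhase <- function(spec, t) {
  k <- (spec@fEnd - spec@fStart) / spec@duration
  2 * pi * (spec@fStart * t + k * t^2 / 2)
}

#' @rdname sweepPhase
#' @keywords internal
sweepFreq <- function(spec, t)
  spec@fStart + (spec@fEnd - spec@fStart) * t / spec@duration

rampEnvelope <- function(n, fs, ramp) {
  env <- rep(1, n)
  nr <- round(ramp * fs)
  if (nr > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- r
    env[n - nr + seq_len(nr)] <- rev(r)
  }
  env
}

#' Render a swept tone as a pressure waveform
#'
#' dB SPL is RMS re 20 uPa, so the peak amplitude is `sqrt(2) * 20e-6 *
#' 10^(level/20)` Pa.
#'
#' @param spec a [SweepSpec-class]
#' @return numeric waveform (Pa)
#' @export
sweepWave <- function(spec) {
  n <- round(spec@duration * spec@fs)
  t <- (seq_len(n) - 1) / spec@fs
  amp <- sqrt(2) * P_REF * 10^(spec@level / 20)
  amp * rampEnvelope(n, spec@fs, spec@ramp) * cos(sweepPhase(spec, t))
}

#' Construct an EmissionModel
#'
#' The default emulates a budgerigar-like emission: level near 12 dB SPL below
#' 5-6 kHz rolling off steeply above, three deep spectral notches, and a
#' group-delay profile chosen so that the delay in stimulus cycles follows
#' `N(f) = 1.7 * (f/1 kHz)^0.548` (a 1.65 dB/octave increase of N with
#' frequency).
#'
#' @param levelProfile function(freq Hz) -> level (dB SPL)
#' @param delayProfile function(freq Hz) -> group delay (s)
#' @param notches data.frame(center_hz, depth_db, width_octaves)
#' @param suppressionFraction fraction of emission removed by the suppressor
#' @return an [EmissionModel-class]
#' @examples
#' m <- emissionModel()
#' nsfoaeTruth(m, c(1000, 2000, 4000))
#' @export
emissionModel <- function(levelProfile = function(f) 12 - 40 / (1 + exp(-(f - 5500) / 300)),
                          delayProfile = function(f) 1.7 * (f / 1000)^0.548 / f,
                          notches = data.frame(center_hz = c(1500, 2800, 4500),
                                               depth_db = c(25, 30, 25),
                                               width_octaves = c(0.04, 0.05, 0.04)),
                          suppressionFraction = 1.0) {
  new("EmissionModel", levelProfile = levelProfile, delayProfile = delayProfile,
      notches = notches, suppressionFraction = suppressionFraction)
}

#' Emission level at given frequencies, notches included
#'
#' Notches are Gaussian dips in dB on the log2-frequency axis.
#'
#' @param model an [EmissionModel-class]
#' @param f frequencies (Hz)
#' @return level (dB SPL)
#' @export
emissionLevel <- function(model, f) {
  L <- model@levelProfile(f)
  for (i in seq_len(nrow(model@notches))) {
    nt <- model@notches[i, ]
    L <- L - nt$depth_db *
      exp(-(log2(f / nt$center_hz))^2 / (2 * nt$width_octaves^2))
  }
  L
}

#' Ground-truth phase-gradient delay of an emission model
#'
#' The synthesized emission's phase lag re the probe is the integral of the
#' group-delay profile over frequency, so its phase gradient is `-tau(f)`
#' and the delay in stimulus cycles is exactly `N(f) = f * tau(f)`.
#'
#' @param model an [EmissionModel-class]
#' @param f frequencies (Hz)
#' @return N_SFOAE ground truth (stimulus cycles)
#' @export
nsfoaeTruth <- function(model, f) f * model@delayProfile(f)

#' Synthesize a three-condition SFOAE recording session
#'
#' Renders the probe-alone, suppressor-alone and combined conditions of the
#' suppression paradigm. The emission is rendered per-sample as the probe
#' sweep passed through a delay-and-scale operator evaluated at the
#' instantaneous sweep frequency, which makes the phase-gradient delay of the
#' embedded emission known exactly (see [nsfoaeTruth()]). The probe-alone
#' condition carries the full emission; the combined condition carries
#' `(1 - suppressionFraction)` of it; the suppressor's own emission is not
#' modeled. Independent white noise is added per repetition, and transient
#' artifacts (1-ms raised-cosine clicks) are injected at Poisson times.
#'
#' @param model an [EmissionModel-class]
#' @param probe,suppressor [SweepSpec-class] objects (defaults: the study
#'   sweeps at 40 and 55 dB SPL)
#' @param noiseRms RMS of the additive white noise (Pa) per repetition
#' @param nReps repetitions per condition; must be even (the noise floor is
#'   estimated downstream from an odd/even split)
#' @param artifactRate expected artifact count per second per repetition
#' @param artifactAmp artifact click amplitude (Pa); default 50 x `noiseRms`
#' @param seed integer seed; identical seeds give identical sessions
#' @param session session identifier stored in the metadata
#' @return a [RecordingSession-class] with ground truth in `@metadata$truth`
#' @examples
#' s <- synthesizeSession(emissionModel(), nReps = 2, noiseRms = 0,
#'                        artifactRate = 0, seed = 1)
#' s
#' @export
synthesizeSession <- function(model, probe = probeSweep(),
                              suppressor = suppressorSweep(),
                              noiseRms = 1e-3, nReps = 40, artifactRate = 0.2,
                              artifactAmp = 50 * noiseRms, seed = NULL,
                              session = "synthetic") {
  stopifnot(is(model, "EmissionModel"))
  validObject(probe); validObject(suppressor)
  if (nReps %% 2 != 0)
    stop("nReps must be even: the noise floor is estimated from an odd/even ",
         "split of repetitions")
  if (probe@fs != suppressor@fs)
    stop("probe and suppressor must share the sampling rate")
  if (!is.null(seed)) set.seed(seed)

  fs <- probe@fs
  n <- round(probe@duration * fs)
  t <- (seq_len(n) - 1) / fs
  env <- rampEnvelope(n, fs, probe@ramp)

  stimP <- sweepWave(probe)
  stimS <- sweepWave(suppressor)
  if (length(stimS) != n)
    stop("probe and suppressor conditions must have equal duration")

  # emission: delay-and-scale at the instantaneous probe frequency; the
  # phase lag is the cumulative integral of the group-delay profile over
  # frequency, so that -dphi/df = tau(f) and N = f * tau(f) exactly
  fi <- sweepFreq(probe, t)
  amp <- sqrt(2) * P_REF * 10^(emissionLevel(model, fi) / 20)
  tau <- model@delayProfile(fi)
  lagCycles <- c(0, cumsum((tau[-1] + tau[-n]) / 2 * diff(fi)))
  emis <- env * amp * cos(sweepPhase(probe, t) - 2 * pi * lagCycles)

  clean <- list(probe = stimP + emis,
                suppressor = stimS,
                both = stimP + stimS + (1 - model@suppressionFraction) * emis)

  click <- local({  # 1-ms raised-cosine transient
    m <- round(0.001 * fs)
    0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
  })

  waveforms <- lapply(clean, function(base) {
    w <- matrix(base, nrow = n, ncol = nReps)
    if (noiseRms > 0)
      w <- w + matrix(stats::rnorm(n * nReps, sd = noiseRms), n, nReps)
    if (artifactRate > 0 && artifactAmp > 0) {
      for (r in seq_len(nReps)) {
        nA <- stats::rpois(1, artifactRate * probe@duration)
        if (nA > 0) {
          at <- round(stats::runif(nA, 1, n - length(click)))
          for (a in at) {
            idx <- a + seq_along(click) - 1
            w[idx, r] <- w[idx, r] + sample(c(-1, 1), 1) * artifactAmp * click
          }
        }
      }
    }
    w
  })

  fgrid <- exp(seq(log(probe@fStart), log(probe@fEnd), length.out = 200))
  new("RecordingSession",
      waveforms = waveforms,
      sweeps = list(probe = probe, suppressor = suppressor, both = probe),
      fs = fs,
      metadata = list(
        session = session,
        truth = list(freq_hz = fgrid,
                     emission_level_db_spl = emissionLevel(model, fgrid),
                     n_sfoae_cycles = nsfoaeTruth(model, fgrid),
                     suppression_fraction = model@suppressionFraction),
        noise_rms = noiseRms, artifact_rate = artifactRate, seed = seed))
}

# solve (1 + p*g) * exp(-p*g) = w for p*g (used for roex bandwidths)
roexPg <- function(w)
  stats::uniroot(function(x) (1 + x) * exp(-x) - w, c(1e-9, 60), tol = 1e-12)$root

#' Rounded-exponential and V-shaped tuning-curve families
#'
#' `roexThreshold()` returns thresholds of a roex-filter curve
#' `W(g) = (1 + p g) exp(-p g)`, `g = |f - cf|/cf`, inverted to dB
#' attenuation re the tip. For roex, `Q10 = p / 7.7794` and `QERB = p / 4`.
#' `vThreshold()` returns a log-symmetric V with flank slopes `s` dB/octave,
#' for which `Q10 = 1 / (2^(10/s) - 2^(-10/s))`.
#'
#' @param f frequencies (Hz)
#' @param cf characteristic frequency (Hz)
#' @param thrCf threshold at CF (dB SPL)
#' @param p roex shape parameter
#' @param s V flank slope (dB/octave)
#' @return thresholds (dB SPL)
#' @export
roexThreshold <- function(f, cf, thrCf, p) {
  g <- abs(f - cf) / cf
  thrCf - 10 * log10(pmax((1 + p * g) * exp(-p * g), 1e-300))
}

#' @rdname roexThreshold
#' @export
vThreshold <- function(f, cf, thrCf, s)
  thrCf + s * abs(log2(f / cf))

# flank slope (dB/oct) of the log-symmetric V achieving a given Q10
vSlopeForQ10 <- function(q10) {
  y <- (1 / q10 + sqrt(1 / q10^2 + 4)) / 2   # y = 2^(10/s)
  10 / log2(y)
}

#' Generate a synthetic auditory-nerve fiber population
#'
#' Draws CFs log-uniformly over `cfRange` and assigns each fiber a Q10 from
#' the power law `Q10 = a * (CF/1 kHz)^b` with multiplicative log-normal
#' jitter. Tuning curves are sampled at `pointsPerOctave` points per octave
#' descending from an upper frequency limit (the in-vivo tracking direction)
#' and truncated where the threshold would exceed `maxLevel`. Defaults
#' emulate the budgerigar sample: 127 fibers, CFs 0.28-5.65 kHz, and
#' `b = 0.289`, i.e. a 0.87 dB/octave rise of Q10 with CF.
#'
#' @param n number of fibers
#' @param cfRange CF range (Hz, ascending pair)
#' @param qLaw c(a, b) of the power law `Q10 = a * (CF/1 kHz)^b`
#' @param thresholdLaw function(cf) -> threshold at CF (dB SPL)
#' @param jitterSd log-normal jitter SD of per-fiber Q10 (log units)
#' @param shape "roex" or "symmetric-V"
#' @param pointsPerOctave sampling density of the frequency grid
#' @param maxLevel highest threshold retained (dB SPL)
#' @param seed integer seed
#' @return list of [TuningCurve-class]; each carries its generating truth
#'   (`cf`, `q10`, `threshold_at_cf`, `shape`) in `@truth`
#' @examples
#' pop <- generateFiberPopulation(5, seed = 1)
#' pop[[1]]
#' @export
generateFiberPopulation <- function(n = 127, cfRange = c(280, 5650),
                                    qLaw = c(a = 3.2, b = 0.289),
                                    thresholdLaw = function(cf) 8 + 2.5 * (log2(cf / 2500))^2,
                                    jitterSd = 0.1, shape = c("roex", "symmetric-V"),
                                    pointsPerOctave = 28, maxLevel = 80,
                                    seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(n >= 1, length(cfRange) == 2, cfRange[1] > 0,
            cfRange[2] > cfRange[1], pointsPerOctave >= 4)
  a <- unname(qLaw[1]); b <- unname(qLaw[2])
  if (min(a * (cfRange / 1000)^b) <= 0)
    stop("Q10 law must be positive over the CF range")
  if (!is.null(seed)) set.seed(seed)

  cf <- exp(stats::runif(n, log(cfRange[1]), log(cfRange[2])))
  q10 <- a * (cf / 1000)^b * exp(stats::rnorm(n, sd = jitterSd))

  lapply(seq_len(n), function(i) {
    thr <- thresholdLaw(cf[i])
    span <- maxLevel - thr  # dB of flank available
    if (shape == "roex") {
      p <- 7.7794 * q10[i]
      gMax <- roexPg(10^(-span / 10)) / p
      fHi <- cf[i] * (1 + gMax)
      fLo <- cf[i] * max(1 - gMax, 2^-5)
    } else {
      s <- vSlopeForQ10(q10[i])
      w <- span / s
      fHi <- cf[i] * 2^w
      fLo <- cf[i] * 2^(-w)
    }
    fHi <- min(fHi, 8000); fLo <- max(fLo, 100)
    # grid descends from the upper limit at the configured density
    k <- 0:floor(log2(fHi / fLo) * pointsPerOctave)
    f <- fHi * 2^(-k / pointsPerOctave)
    th <- if (shape == "roex") roexThreshold(f, cf[i], thr, 7.7794 * q10[i])
          else vThreshold(f, cf[i], thr, vSlopeForQ10(q10[i]))
    keep <- th <= maxLevel + 1e-9
    f <- f[keep]; th <- th[keep]
    tuningCurve(f, th, fiberId = sprintf("fiber%03d", i),
                truth = list(cf = cf[i], q10 = q10[i], threshold_at_cf = thr,
                             shape = shape, sampling_density = pointsPerOctave))
  })
}

#' Write / read tuning-curve and ground-truth CSV files
#'
#' `writeTuningCurves()` writes the long-format curve table
#' (`fiber_id, freq_hz, threshold_db_spl`) and, when ground truth is present,
#' a companion `<stem>_truth.csv` (`fiber_id, cf_hz, q10_true, threshold_true`).
#' `readTuningCurves()` reads the long-format table back into a list of
#' [TuningCurve-class] objects.
#'
#' @param curves list of [TuningCurve-class]
#' @param path CSV path for the curve table
#' @return `readTuningCurves()`: a list of [TuningCurve-class]
#' @export
writeTuningCurves <- function(curves, path) {
  tab <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE)
  withTruth <- Filter(function(cu) length(cu@truth) > 0, curves)
  if (length(withTruth)) {
    tr <- do.call(rbind, lapply(withTruth, function(cu)
      data.frame(fiber_id = cu@fiberId, cf_hz = cu@truth$cf,
                 q10_true = cu@truth$q10,
                 threshold_true = cu@truth$threshold_at_cf)))
    utils::write.csv(tr, sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeTuningCurves
#' @export
readTuningCurves <- function(path) {
  tab <- utils::read.csv(path)
  lapply(split(tab, tab$fiber_id), function(d)
    tuningCurve(d$freq_hz, d$threshold_db_spl, fiberId = d$fiber_id[1]))
}
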