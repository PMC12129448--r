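# Shared fixtures: short, cheap sweeps for unit tests (the full study sweep
# at 50 kHz is exercised in the acceptance properties).

shortProbe <- function(fs = 20e3)
  sweepSpec(500, 6000, duration = 0.6, level = 40, ramp = 0.01, fs = fs)

shortSupp <- function(fs = 20e3)
  sweepSpec(540, 6040, duration = 0.6, level = 55, ramp = 0.01, fs = fs)

flatModel <- function(tau = 1e-3, level = 10, sf = 1)
  emissionModel(levelProfile = function(f) rep(level, length(f)),
                delayProfile = function(f) rep(tau, length(f)),
                notches = data.frame(center_hz = numeric(), depth_db = numeric(),
                                     width_octaves = numeric()),
                suppressionFraction = sf)

shortSession <- function(model = flatModel(), noiseRms = 0, nReps = 4,
                         artifactRate = 0, seed = 1, ...)
  synthesizeSession(model, shortProbe(), shortSupp(), noiseRms = noiseRms,
                    nReps = nReps, artifactRate = artifactRate, seed = seed, ...)

# analytic tuning-curve on a grid of the given density (points/octave),
# spanning each flank up to `span` dB above the tip
sampledCurve <- function(shape, cf, thrCf, sharp, perOct = 100, span = 60) {
  thrF <- if (shape == "roex") function(f) roexThreshold(f, cf, thrCf, sharp)
          else function(f) vThreshold(f, cf, thrCf, sharp)
  f <- 2^seq(log2(cf) - 3, log2(cf) + 3, by = 1 / perOct)
  th <- thrF(f)
  keep <- th <= thrCf + span
  tuningCurve(f[keep], th[keep])
}

# independent dense-grid brute-force Q metrics (no interpolation; direct
# crossing scan and trapezoid on a 2000-points/octave grid)
bruteMetrics <- function(shape, cf, thrCf, sharp, span = 60) {
  thrF <- if (shape == "roex") function(f) roexThreshold(f, cf, thrCf, sharp)
          else function(f) vThreshold(f, cf, thrCf, sharp)
  f <- 2^seq(log2(cf) - 3, log2(cf) + 3, by = 1 / 2000)
  th <- thrF(f)
  keep <- th <= thrCf + span
  f <- f[keep]; th <- th[keep]
  tip <- which.min(th)
  target <- th[tip] + 10
  iHi <- tip + which(th[(tip + 1):length(th)] >= target)[1]
  iLo <- tip - which(rev(th[1:(tip - 1)]) >= target)[1]
  bw <- f[iHi] - f[iLo]
  w <- 10^((th[tip] - th) / 10)
  erb <- sum(diff(f) * (w[-1] + w[-length(w)]) / 2)
  list(q10 = f[tip] / bw, qErb = f[tip] / erb)
}
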