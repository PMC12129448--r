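test_that("artifact excision removes 20-ms windows and merges overlaps", {
  fs <- 50e3
  x <- rep(0.001, 2 * fs)
  out <- rejectArtifacts(x, threshold = 0.01, fs = fs)
  expect_identical(out$wave, x)
  expect_equal(nrow(out$log), 0)

  x[fs + 1] <- 0.5  # single spike at t = 1.0 s
  out <- rejectArtifacts(x, threshold = 0.01, fs = fs)
  expect_equal(sum(is.na(out$wave)), 1000)  # exactly 20 ms at 50 kHz
  expect_equal(out$log$start_s, 0.99, tolerance = 1e-4)
  expect_equal(out$log$end_s, 1.01, tolerance = 1e-4)

  x2 <- rep(0.001, 2 * fs)
  x2[fs + 1] <- 0.5
  x2[fs + 1 + 0.005 * fs] <- 0.5  # second spike 5 ms later
  out2 <- rejectArtifacts(x2, threshold = 0.01, fs = fs)
  expect_equal(sum(is.na(out2$wave)), 1250)  # merged 25 ms
  expect_equal(nrow(out2$log), 1)

  xall <- rep(0.5, 1000)
  expect_warning(out3 <- rejectArtifacts(xall, 0.01, fs), "50%")
  expect_true(out3$dropped)
})

test_that("averaging ignores excised samples and fills dead samples", {
  expect_equal(averageReps(cbind(1:5, 1:5, 1:5))$wave, as.numeric(1:5))
  v <- sin(1:100)
  expect_equal(averageReps(cbind(v, -v))$wave, rep(0, 100))
  # 3 reps, one with an excised window: average over the remaining two there
  r1 <- rep(1, 10); r2 <- rep(2, 10); r3 <- rep(6, 10)
  r3[4:6] <- NA
  out <- averageReps(cbind(r1, r2, r3))
  expect_equal(out$wave, c(rep(3, 3), rep(1.5, 3), rep(3, 4)))
  expect_equal(out$nContrib[5], 2)
  # a sample dead in all reps is interpolated and reported
  r1[7] <- r2[7] <- r3[7] <- NA
  out2 <- averageReps(cbind(r1, r2, r3))
  expect_equal(out2$interpolated, 7)
  expect_true(is.finite(out2$wave[7]))
  expect_error(averageReps(cbind(r1)), "2")
})

test_that("vector subtraction is linear and checks lengths", {
  a <- rnorm(50); b <- rnorm(50); e <- rnorm(50)
  expect_equal(vectorSubtract(a, b, a + b), rep(0, 50))
  expect_equal(vectorSubtract(a + e, b, a + b), e)
  expect_equal(vectorSubtract(3 * a, 3 * b, 3 * (a + b) - 3 * e), 3 * e)
  expect_error(vectorSubtract(a, b, rnorm(10)), "length")
})

test_that("least-squares sweep fit recovers amplitude and delay phase slope", {
  sw <- shortProbe()
  x <- sweepWave(sw)
  sp <- lsfSpectrum(x, sw)
  f <- freqHz(sp)
  core <- f > 700 & f < 5500
  expect_lt(max(abs(levelDb(sp)[core] - 40)), 0.1)
  expect_lt(diff(range(phaseCycles(sp)[core])), 0.02)

  # delay the sweep by tau: fitted phase is -f*tau + const within 1%
  tau <- 1e-3
  lag <- round(tau * sw@fs)
  xd <- c(rep(0, lag), x[1:(length(x) - lag)])
  spd <- lsfSpectrum(xd, sw)
  ph <- phaseCycles(spd)[core] + f[core] * tau
  expect_lt(diff(range(ph)) / (tau * diff(range(f[core]))), 0.01)

  sp0 <- lsfSpectrum(numeric(length(x)), sw)
  expect_true(all(Mod(sp0@pressure) == 0))
})

test_that("phase unwrapping removes integer-cycle jumps", {
  truePhase <- seq(0, -6, length.out = 200)
  wrapped <- truePhase - round(truePhase)
  expect_equal(diff(unwrapCycles(wrapped)), diff(truePhase), tolerance = 1e-12)
})

test_that("phase gradients: linear phase, constant phase, spline oracle", {
  f <- 2^seq(log2(500), log2(6000), length.out = 250)
  mkSpec <- function(ph) new("SfoaeSpectrum", freq = f,
    pressure = complex(modulus = 1e-3, argument = 2 * pi * (ph %% 1)),
    level = rep(20 * log10(1e-3 / 20e-6), length(f)), phase = ph,
    noiseFloor = rep(NA_real_, length(f)))

  tau <- 1e-3
  d <- phaseGradientDelay(mkSpec(-f * tau), smoothOctaves = 0)
  expect_equal(nsfoaeCycles(d), f * tau, tolerance = 1e-9)
  expect_equal(approx(f, nsfoaeCycles(d), xout = 2000)$y, 2.0,
               tolerance = 1e-6)

  d0 <- phaseGradientDelay(mkSpec(rep(1.23, length(f))), smoothOctaves = 0)
  expect_equal(nsfoaeCycles(d0), rep(0, length(f)))

  # smoothing by local regression leaves a pure-latency phase exact too
  dS <- phaseGradientDelay(mkSpec(-f * tau), smoothOctaves = 0.3)
  expect_equal(nsfoaeCycles(dS), f * tau, tolerance = 1e-9)

  # random smooth phase: centered differences vs analytic spline derivative
  set.seed(7)
  nTrue <- 2 + (f / 1000)^0.6 + 0.4 * sin(2 * pi * log2(f / 500) / 1.7)
  ph <- -cumsum(c(0, (nTrue / f)[-1] * diff(f)))
  d2 <- phaseGradientDelay(mkSpec(ph), smoothOctaves = 0)
  oracle <- -f * splinefun(f, ph)(f, deriv = 1)
  rel <- (nsfoaeCycles(d2) - oracle) / oracle
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("fewer than 3 grid points is an explicit error", {
  sp <- new("SfoaeSpectrum", freq = c(1000, 2000),
            pressure = complex(real = c(1, 1) * 1e-3, imaginary = c(0, 0)),
            level = 20 * log10(c(1e-3, 1e-3) / 20e-6), phase = c(0, 0),
            noiseFloor = c(NA_real_, NA_real_))
  expect_error(phaseGradientDelay(sp), "3 grid points")
})

test_that("SNR and trough exclusion rules", {
  f <- 2^seq(log2(1000), log2(5000), by = 1 / 48)
  n <- length(f)
  mkSpec <- function(lev) {
    pr <- complex(modulus = 20e-6 * 10^(lev / 20), argument = 0)
    new("SfoaeSpectrum", freq = f, pressure = pr, level = lev,
        phase = rep(0, n), noiseFloor = rep(0, n))  # median floor 0 dB SPL
  }
  mkDelay <- function() new("DelayCurve", freq = f, nsfoae = rep(1, n),
                            valid = rep(TRUE, n), reason = rep("none", n))

  # 9 dB above the median floor -> excluded; 15 dB -> retained
  expect_warning(d9 <- applyExclusions(mkDelay(), mkSpec(rep(9, n))),
                 "excluded")
  expect_true(all(!validPoints(d9)))
  expect_true(all(d9@reason == "low_snr"))
  d15 <- applyExclusions(mkDelay(), mkSpec(rep(15, n)))
  expect_true(all(validPoints(d15)))

  # 30-dB notch at 3 kHz: trough exclusions near the minimum
  lev <- 20 - 30 * exp(-(log2(f / 3000))^2 / (2 * 0.05^2))
  dN <- applyExclusions(mkDelay(), mkSpec(lev))
  at3k <- which.min(abs(f - 3000))
  expect_equal(dN@reason[at3k], "trough")
  nearby <- abs(log2(f / 3000)) <= 1 / 24
  expect_true(all(dN@reason[nearby] == "trough"))
  far <- abs(log2(f / 3000)) > 0.5
  expect_true(all(validPoints(dN)[far]))
})

test_that("noise-only sessions are excluded nearly everywhere", {
  s <- shortSession(flatModel(level = -300), noiseRms = 5e-4, nReps = 8,
                    artifactRate = 0, seed = 21)
  ex <- suppressWarnings(extractSfoae(s))
  expect_gte(mean(!validPoints(ex$delay)), 0.95)
})

test_that("noise floor tracks the averaged-residual noise level within 3 dB", {
  diffs <- vapply(1:30, function(seed) {
    s <- shortSession(flatModel(level = -300), noiseRms = 1e-3, nReps = 8,
                      artifactRate = 0, seed = 300 + seed)
    w <- s@waveforms
    floorLev <- estimateNoiseFloor(w$probe, w$suppressor, w$both,
                                   s@sweeps$probe)
    res <- vectorSubtract(rowMeans(w$probe), rowMeans(w$suppressor),
                          rowMeans(w$both))
    actual <- lsfSpectrum(res, s@sweeps$probe)
    median(floorLev) - median(levelDb(actual))
  }, 0)
  expect_lt(abs(mean(diffs)), 3)
})

test_that("doubling the repetitions lowers the noise floor by about 3 dB", {
  med <- function(nReps, seed) {
    s <- shortSession(flatModel(level = -300), noiseRms = 1e-3, nReps = nReps,
                      artifactRate = 0, seed = seed)
    w <- s@waveforms
    median(estimateNoiseFloor(w$probe, w$suppressor, w$both, s@sweeps$probe))
  }
  drop <- mean(vapply(1:8, function(s) med(8, 500 + s) - med(16, 600 + s), 0))
  expect_gt(drop, 1.5)
  expect_lt(drop, 4.5)
})

test_that("recovered delay is insensitive to doubling the analysis window", {
  m <- emissionModel(notches = data.frame(center_hz = numeric(),
                                          depth_db = numeric(),
                                          width_octaves = numeric()))
  s <- shortSession(m, noiseRms = 0, nReps = 2)
  avg <- lapply(s@waveforms, rowMeans)
  res <- vectorSubtract(avg$probe, avg$suppressor, avg$both)
  n1 <- phaseGradientDelay(lsfSpectrum(res, s@sweeps$probe, window = 0.020))
  n2 <- phaseGradientDelay(lsfSpectrum(res, s@sweeps$probe, window = 0.040))
  f1 <- freqHz(n1)
  sel <- f1 > 1000 & f1 < 5000
  interp <- approx(log2(freqHz(n2)), nsfoaeCycles(n2), xout = log2(f1[sel]))$y
  expect_lt(max(abs(interp / nsfoaeCycles(n1)[sel] - 1), na.rm = TRUE), 0.02)
})

test_that("unwrapped SFOAE phase decreases monotonically for a delayed emission", {
  s <- shortSession(flatModel(tau = 1.5e-3), noiseRms = 0)
  ex <- extractSfoae(s)
  ph <- phaseCycles(ex$spectrum)[validPoints(ex$delay)]
  expect_true(all(diff(ph) < 1e-6))
})

test_that("extraction writes the documented CSV layout", {
  dir <- file.path(tempdir(), "extr")
  s <- shortSession(noiseRms = 2e-4, nReps = 4, seed = 4)
  writeExtraction(extractSfoae(s), dir)
  spec <- read.csv(file.path(dir, "sfoae_spectrum.csv"))
  expect_named(spec, c("freq_hz", "level_db_spl", "phase_cycles",
                       "noise_floor_db_spl"))
  del <- read.csv(file.path(dir, "delay_curve.csv"))
  expect_named(del, c("freq_hz", "n_sfoae_cycles", "valid", "exclusion_reason"))
  expect_equal(nrow(spec), nrow(del))
  unlink(dir, recursive = TRUE)
})
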