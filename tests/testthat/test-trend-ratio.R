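mkPts <- function(f, v, unit = "u1") data.frame(freq = f, value = v, unit = unit)

test_that("Gaussian trend: constants, single points, boundedness", {
  f <- 2^seq(10, 12.5, by = 0.05)
  tr <- gaussianTrend(mkPts(f, rep(4.2, length(f))), 0.5)
  expect_equal(trendMean(tr)[is.finite(trendMean(tr))],
               rep(4.2, sum(is.finite(trendMean(tr)))))

  one <- gaussianTrend(mkPts(2000, 3.3), 0.5, grid = c(1500, 2000, 2500))
  expect_equal(trendMean(one), rep(3.3, 3))

  set.seed(2)
  v <- runif(length(f), 1, 9)
  trb <- gaussianTrend(mkPts(f, v), 0.25)
  ok <- is.finite(trendMean(trb))
  expect_true(all(trendMean(trb)[ok] >= min(v) & trendMean(trb)[ok] <= max(v)))
})

test_that("group-delay mode matches a direct weighted-mean oracle", {
  set.seed(3)
  f <- 2^runif(300, log2(700), log2(5000))
  tau <- 1.2e-3
  v <- f * tau * exp(rnorm(300, sd = 0.05))
  grid <- c(1000, 2000, 4000)
  tr <- gaussianTrend(mkPts(f, v), 0.25, grid = grid, mode = "group_delay")
  oracle <- vapply(grid, function(f0) {
    w <- exp(-(log2(f / f0))^2 / (2 * 0.25^2))
    sum(w * v * f) / sum(w) / f0
  }, 0)
  expect_equal(trendMean(tr), oracle, tolerance = 1e-12)
  # noiseless f*tau data: the group-delay weighted mean agrees with the
  # direct-summation oracle (group delay f^2*tau is not affine in log f,
  # so the oracle, not f0*tau, is the reference)
  tr2 <- gaussianTrend(mkPts(f, f * tau), 0.25, grid = grid,
                       mode = "group_delay")
  oracle2 <- vapply(grid, function(f0) {
    w <- exp(-(log2(f / f0))^2 / (2 * 0.25^2))
    sum(w * f^2 * tau) / sum(w) / f0
  }, 0)
  expect_equal(trendMean(tr2), oracle2, tolerance = 1e-9)
  expect_lt(max(abs(trendMean(tr2) / (grid * tau) - 1)), 0.10)
})

test_that("grid points with an empty 3-sigma neighborhood are undefined", {
  tr <- gaussianTrend(mkPts(c(1000, 1100), c(1, 2)), 0.1,
                      grid = c(1000, 4000))
  expect_true(is.finite(trendMean(tr)[1]))
  expect_true(is.na(trendMean(tr)[2]))
})

test_that("bootstrap CIs are reproducible and collapse for identical units", {
  f <- 2^seq(log2(800), log2(4000), length.out = 25)
  pts <- do.call(rbind, lapply(1:6, function(u) mkPts(f, 2 + log2(f / 1000),
                                                      paste0("u", u))))
  a <- bootstrapCi(pts, 0.5, nBoot = 200, seed = 42)
  b <- bootstrapCi(pts, 0.5, nBoot = 200, seed = 42)
  expect_equal(trendCi(a), trendCi(b))
  ok <- is.finite(a@ciLo)
  expect_equal(a@ciLo[ok], a@ciHi[ok], tolerance = 1e-12)  # identical units
  expect_true(all(a@ciLo[ok] <= trendMean(a)[ok] + 1e-9))
  expect_true(all(trendMean(a)[ok] <= a@ciHi[ok] + 1e-9))
  expect_error(bootstrapCi(mkPts(f, f, "only"), 0.5), "2 distinct")
})

test_that("bootstrap CI equals naive unit resampling in law", {
  # the sufficient-statistic implementation must reproduce a literal
  # resample-and-refit bootstrap with the same resampled unit multiset
  f <- 2^seq(log2(900), log2(3600), length.out = 12)
  set.seed(5)
  pts <- do.call(rbind, lapply(1:5, function(u)
    mkPts(f, 3 + rnorm(1) + rnorm(12, sd = 0.2), paste0("u", u))))
  grid <- c(1200, 2400)
  units <- unique(pts$unit)
  set.seed(9); counts <- as.vector(rmultinom(1, 5, rep(0.2, 5)))
  naive <- do.call(rbind, lapply(seq_along(units), function(i)
    if (counts[i] > 0)
      do.call(rbind, replicate(counts[i],
        pts[pts$unit == units[i], ], simplify = FALSE))))
  direct <- gaussianTrend(naive, 0.5, grid = grid)
  # same counts via the matrix path
  ss <- cochleartune:::trendSuffStats(pts, 0.5, grid, "direct")
  m <- as.vector((ss$num %*% counts) / (ss$den %*% counts))
  expect_equal(m, trendMean(direct), tolerance = 1e-12)
})

test_that("tuning ratio is 1 for identical trends and refines stably", {
  grid <- 2^seq(log2(700), log2(5000), by = 1 / 48)
  tr <- function(g, v) new("TrendCurve", freq = g, mean = v,
                           ciLo = rep(NA_real_, length(g)),
                           ciHi = rep(NA_real_, length(g)),
                           sigmaOctaves = 0.5, nBoot = 0, resampleUnit = "none")
  n <- tr(grid, 1.5 * (grid / 1000)^0.5)
  expect_equal(tuningR(tuningRatio(n, n)), rep(1, length(grid)))

  q <- tr(grid, 6 * (grid / 1000)^0.2)
  r1 <- tuningRatio(q, n)
  grid2 <- 2^seq(log2(700), log2(5000), by = 1 / 96)
  n2 <- tr(grid2, 1.5 * (grid2 / 1000)^0.5)
  r2 <- tuningRatio(q, n2)
  common <- approx(log2(freqHz(r2)), tuningR(r2), xout = log2(freqHz(r1)))$y
  ok <- is.finite(common)
  expect_lt(max(abs(common[ok] / tuningR(r1)[ok] - 1)), 0.005)
})

test_that("ratio times delay closes the identity on a single species", {
  grid <- 2^seq(log2(700), log2(5000), by = 1 / 48)
  mk <- function(v) new("TrendCurve", freq = grid, mean = v,
                        ciLo = rep(NA_real_, length(grid)),
                        ciHi = rep(NA_real_, length(grid)),
                        sigmaOctaves = 0.5, nBoot = 0, resampleUnit = "none")
  n <- mk(1.4 * (grid / 1000)^0.55)
  q <- mk(5.5 * (grid / 1000)^0.25)
  pred <- predictQerb(n, tuningRatio(q, n))
  expect_equal(pred@qerb, trendMean(q), tolerance = 1e-9)
})

test_that("constant ratio and cross-species prediction with shared r", {
  grid <- 2^seq(log2(700), log2(4500), by = 1 / 48)
  mk <- function(v) new("TrendCurve", freq = grid, mean = v,
                        ciLo = rep(NA_real_, length(grid)),
                        ciHi = rep(NA_real_, length(grid)),
                        sigmaOctaves = 0.5, nBoot = 0, resampleUnit = "none")
  rConst <- tuningRatio(mk(rep(6, length(grid))), mk(rep(3, length(grid))))
  expect_equal(tuningR(rConst), rep(2, length(grid)))
  pred <- predictQerb(mk(rep(3, length(grid))), rConst)
  expect_equal(pred@qerb, rep(6, length(grid)))

  # two species share r(f); r from A predicts B's QERB
  rShared <- function(f) 4 * (f / 1000)^-0.3
  nA <- mk(1.5 * (grid / 1000)^0.5); qA <- mk(rShared(grid) * 1.5 * (grid / 1000)^0.5)
  nB <- mk(2.2 * (grid / 1000)^0.55)
  predB <- predictQerb(nB, tuningRatio(qA, nA, species = "A"))
  truthB <- rShared(predB@freq) * 2.2 * (predB@freq / 1000)^0.55
  expect_lt(max(abs(predB@qerb / truthB - 1)), 0.05)
})

test_that("Q10 extrapolation continues a line with a textbook SE band", {
  cf <- seq(1800, 3300, by = 50)
  exact <- extrapolateQ10(data.frame(cf = cf, q10 = 1 + 0.8 * log2(cf / 1000)))
  expect_equal(exact$trend$mean, 1 + 0.8 * log2(exact$trend$freq / 1000),
               tolerance = 1e-9)
  expect_lt(max(exact$trend$se), 1e-9)

  flat <- extrapolateQ10(data.frame(cf = cf,
                                    q10 = 3 + rep_len(c(0.01, -0.01),
                                                      length(cf))))
  expect_equal(flat$trend$mean, rep(3, nrow(flat$trend)), tolerance = 0.01)

  expect_error(extrapolateQ10(data.frame(cf = rep(2000, 5), q10 = 1:5)),
               "singular|CFs")
  expect_error(extrapolateQ10(data.frame(cf = c(1800, 1900), q10 = c(1, 2))),
               "3 fibers")

  # SE of the mean prediction vs a brute-force residual bootstrap of the
  # regression (fixed design, resampled residuals)
  set.seed(12)
  n <- 250
  d <- data.frame(cf = exp(runif(n, log(1750), log(3350))))
  d$q10 <- 2 + 0.7 * log2(d$cf / 1000) + rnorm(n, sd = 0.25)
  ext <- extrapolateQ10(d, grid = c(3800, 4400))
  fit0 <- lm(q10 ~ log2(cf), data = d)
  fitted0 <- fitted(fit0); resid0 <- resid(fit0)
  boot <- replicate(4000, {
    d2 <- d
    d2$q10 <- fitted0 + sample(resid0, replace = TRUE)
    predict(lm(q10 ~ log2(cf), data = d2),
            newdata = data.frame(cf = c(3800, 4400)))
  })
  expect_equal(ext$trend$se, unname(apply(boot, 1, sd)), tolerance = 0.05)
})

test_that("dB/octave slopes: doubling, constants, power laws", {
  f <- 2^seq(9, 13, by = 0.1)
  expect_equal(dbPerOctave(f, 2^(log2(f))), 10 * log10(2), tolerance = 1e-9)
  expect_equal(dbPerOctave(f, rep(5, length(f))), 0, tolerance = 1e-12)
  b <- 0.55
  expect_equal(dbPerOctave(f, 3 * (f / 1000)^b), 10 * b * log10(2),
               tolerance = 1e-9)
  expect_error(dbPerOctave(f, rep(-1, length(f))), "positive")
  expect_error(dbPerOctave(f[1], 5), "2 frequencies")
})

test_that("LOESS trend: exactness on linear data and a textbook oracle", {
  f <- 2^seq(log2(600), log2(5000), length.out = 40)
  expect_equal(loessTrend(f, rep(2, 40), grid = f)$fit, rep(2, 40),
               tolerance = 1e-9)
  lin <- 1 + 0.5 * log2(f / 1000)
  expect_equal(loessTrend(f, lin, grid = f)$fit, lin, tolerance = 1e-9)

  set.seed(8)
  y <- 3 + 0.6 * log2(f / 1000) + 0.3 * sin(2 * pi * log2(f / 600) / 3) +
    rnorm(40, sd = 0.1)
  got <- loessTrend(f, y, span = 0.65, grid = f)$fit
  # independent textbook tricube local-linear regression
  x <- log2(f)
  k <- ceiling(0.65 * length(x))
  oracle <- vapply(x, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[k]
    w <- pmax(1 - (d / h)^3, 0)^3
    coef(lm(y ~ I(x - x0), weights = w))[1]
  }, 0)
  expect_lt(sqrt(mean((got - oracle)^2)) / diff(range(y)), 0.02)

  expect_error(loessTrend(f[1:4], y[1:4]), "5 points")
  expect_error(loessTrend(f, y, span = 0.05), "3 points")
})

test_that("behavioral Q10 scaling", {
  expect_equal(scaleBehavioral(2), 3.52)
  expect_equal(scaleBehavioral(c(1, 4), factor = 1), c(1, 4))
  pop <- generateFiberPopulation(30, shape = "roex", pointsPerOctave = 200,
                                 jitterSd = 0, seed = 13)
  fac <- summarizeRatio(populationMetrics(pop, smooth = FALSE))$median
  expect_equal(scaleBehavioral(1, factor = fac), 1.9449, tolerance = 0.01)
  expect_error(scaleBehavioral(-2))
})

test_that("extended ratio carries a contiguous high-frequency SE band", {
  ck <- syntheticChickenReference(seed = 4)
  nTrend <- gaussianTrend(ck$nsfoae, 0.5)
  r <- ratioFromQ10(ck$q10, nTrend, extendTo = 4600)
  expect_s4_class(r, "TuningRatioCurve")
  expect_true(any(r@extended))
  ext <- which(r@extended)
  expect_true(all(diff(ext) == 1))
  expect_true(max(freqHz(r)[!r@extended]) <= min(freqHz(r)[r@extended]))
  expect_true(all(is.finite(r@lo[ext]) & r@lo[ext] <= r@r[ext] &
                    r@r[ext] <= r@hi[ext]))
  # ratio follows the designed r law within the empirical range
  mid <- !r@extended & freqHz(r) > 600 & freqHz(r) < 3000
  expect_lt(median(abs(tuningR(r)[mid] / ck$design$rLaw(freqHz(r)[mid]) - 1)),
            0.15)
})
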