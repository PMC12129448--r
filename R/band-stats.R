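# Banded mixed-effects analysis of SFOAE level and N_SFOAE vs frequency:
# five log-spaced bands (1-5 kHz centers), per-ear robust first-degree
# polynomials evaluated at the band center, then a linear mixed model with
# ear random intercepts and a Satterthwaite F test of the band effect.

#' Log-spaced band centers
#'
#' Geometrically spaced center frequencies, default five from 1 to 5 kHz:
#' 1000, 1495, 2236, 3344, 5000 Hz.
#'
#' @param nBands number of bands
#' @param lo,hi first and last center (Hz)
#' @return centers (Hz)
#' @export
bandCenters <- function(nBands = 5, lo = 1000, hi = 5000)
  10^seq(log10(lo), log10(hi), length.out = nBands)

#' Pool curve points into per-ear band values
#'
#' Band edges are the geometric midpoints between adjacent centers (mirrored
#' at the outer edges, i.e. constant width in log frequency). Within each
#' ear x band cell a robust first-degree polynomial in log2(f) is fit by
#' bisquare IRLS (tuning constant 4.685) and evaluated at the band center;
#' cells with fewer than 2 points are missing.
#'
#' @param points data.frame with columns `freq` (Hz), `value`, `ear`
#' @param nBands,lo,hi see [bandCenters()]
#' @return data.frame(ear_id, band_center_hz, value); one row per non-missing
#'   ear x band cell
#' @export
bandPool <- function(points, nBands = 5, lo = 1000, hi = 5000) {
  centers <- bandCenters(nBands, lo, hi)
  step <- sqrt(centers[2] / centers[1])
  edges <- c(centers[1] / step, centers * step)
  out <- list()
  for (ear in unique(points$ear)) {
    pe <- points[points$ear == ear, ]
    for (b in seq_along(centers)) {
      d <- pe[pe$freq >= edges[b] & pe$freq < edges[b + 1] &
                is.finite(pe$value), ]
      if (nrow(d) < 2) next
      x <- log2(d$freq)
      val <- tryCatch({
        fit <- MASS::rlm(d$value ~ x, psi = MASS::psi.bisquare, c = 4.685,
                         maxit = 50)
        unname(stats::predict(fit, newdata = data.frame(x = log2(centers[b]))))
      }, error = function(e) {
        unname(stats::predict(stats::lm(d$value ~ x),
                              newdata = data.frame(x = log2(centers[b]))))
      })
      out[[length(out) + 1]] <- data.frame(ear_id = ear,
                                           band_center_hz = centers[b],
                                           value = val)
    }
  }
  if (!length(out)) stop("no ear x band cell has at least 2 points")
  do.call(rbind, out)
}

#' Mixed-model F test of the band effect
#'
#' Fits `value ~ band + (1 | ear)` by REML with band as a categorical fixed
#' effect and ear as a random intercept, and tests the band effect with a
#' Satterthwaite-approximated F test. If the mixed fit fails or does not
#' converge, the model is refit with ear as fixed blocks (two-way ANOVA
#' without interaction) and the result is flagged `fallback`.
#'
#' @param obs data.frame from [bandPool()] (`ear_id, band_center_hz, value`)
#' @param alpha significance level (default 0.01)
#' @return list: `f_stat`, `df_num`, `df_den`, `p_value`, `alpha`,
#'   `significant`, `variance_components` (ear intercept and residual
#'   variances; NA under the fallback), `method` ("satterthwaite" or
#'   "fallback")
#' @export
mixedModelF <- function(obs, alpha = 0.01) {
  stopifnot(all(c("ear_id", "band_center_hz", "value") %in% names(obs)))
  d <- data.frame(value = obs$value,
                  band = factor(obs$band_center_hz),
                  ear = factor(obs$ear_id))
  if (nlevels(d$ear) < 2 || nlevels(d$band) < 2)
    stop("need at least 2 ears and 2 bands")
  res <- tryCatch({
    fit <- lmerTest::lmer(value ~ band + (1 | ear), data = d, REML = TRUE)
    a <- stats::anova(fit, ddf = "Satterthwaite")
    vc <- as.data.frame(lme4::VarCorr(fit))
    list(f_stat = a[["F value"]][1], df_num = a[["NumDF"]][1],
         df_den = a[["DenDF"]][1], p_value = a[["Pr(>F)"]][1],
         variance_components = c(ear = vc$vcov[vc$grp == "ear"],
                                 residual = vc$vcov[vc$grp == "Residual"]),
         method = "satterthwaite")
  }, error = function(e) NULL)
  if (is.null(res)) {
    a <- stats::anova(stats::lm(value ~ band + ear, data = d))
    res <- list(f_stat = a["band", "F value"], df_num = a["band", "Df"],
                df_den = a["Residuals", "Df"],
                p_value = a["band", "Pr(>F)"],
                variance_components = c(ear = NA_real_, residual = NA_real_),
                method = "fallback")
  }
  # an exactly constant response has no variance to test against
  if (stats::var(d$value) < 1e-24) {
    res$f_stat <- 0; res$p_value <- 1
  }
  res$alpha <- alpha
  res$significant <- res$p_value < alpha
  res
}
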