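# Synthetic stand-in for the published chicken reference data (two
# auditory-nerve Q10 studies pooled, n = 289 fibers with CFs below 3.35 kHz,
# and a 9-animal N_SFOAE data set spanning 0.5-4.6 kHz). The real reference
# values are literature data that are not redistributed here; this generator
# is *synthetic* and is designed only to reproduce the qualitative reference
# behaviour: monotonically rising Q10 and N_SFOAE, and a tuning ratio near 7
# at 500 Hz falling to 3-4 over 1-3.35 kHz.

#' Synthetic chicken reference data set
#'
#' Returns synthetic stand-ins for the chicken reference inputs of the
#' tuning-ratio construction: pooled auditory-nerve Q10 points (`q10`:
#' columns `cf`, `q10`, `study`) and per-animal N_SFOAE points (`nsfoae`:
#' columns `freq`, `value`, `unit`). The design laws are a monotone Q10
#' `Q10(f) = 1.55 (f/1 kHz)^0.35`, a tuning ratio
#' `r(f) = 3.1 + 3.9 (f/500 Hz)^-2.2` (about 7 at 500 Hz, 3-4 over
#' 1-3.35 kHz), and the N_SFOAE law implied by the two,
#' `N(f) = 1.76 Q10(f) / r(f)`, which rises monotonically from ~0.3 cycles
#' at 500 Hz. Points are drawn with log-normal scatter.
#'
#' @param nFibers number of Q10 points (reference sample: 289)
#' @param nAnimals number of N_SFOAE animals (reference sample: 9)
#' @param seed integer seed
#' @return list(q10, nsfoae, design = list(qLaw, nLaw, rLaw))
#' @export
syntheticChickenReference <- function(nFibers = 289, nAnimals = 9, seed = 1) {
  set.seed(seed)
  qLaw <- function(f) 1.55 * (f / 1000)^0.35
  rLaw <- function(f) 3.1 + 3.9 * (f / 500)^-2.2
  nLaw <- function(f) 1.76 * qLaw(f) / rLaw(f)
  cf <- exp(stats::runif(nFibers, log(250), log(3350)))
  q10 <- qLaw(cf) * exp(stats::rnorm(nFibers, sd = 0.15))
  q10Tab <- data.frame(cf = cf, q10 = q10,
                       study = sample(c("studyA", "studyB"), nFibers, TRUE))
  grids <- lapply(seq_len(nAnimals), function(a) {
    f <- 2^seq(log2(500), log2(4600), by = 1 / 12)
    data.frame(freq = f,
               value = nLaw(f) * exp(stats::rnorm(length(f), sd = 0.08)),
               unit = sprintf("animal%02d", a))
  })
  list(q10 = q10Tab, nsfoae = do.call(rbind, grids),
       design = list(qLaw = qLaw, nLaw = nLaw, rLaw = rLaw))
}
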