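# cochleartune

Estimating cochlear frequency tuning from stimulus-frequency otoacoustic
emissions (SFOAEs), with auditory-nerve validation.

## The problem

Cochlear filter sharpness — summarized by the quality factors
`Q10 = CF / BW10` and `QERB = CF / ERB` of auditory-nerve frequency-threshold
tuning curves — can only be measured invasively. SFOAEs offer a non-invasive
alternative: the emission's phase-gradient delay in stimulus cycles,

    N_SFOAE(f) = −f · dφ/df        (φ in cycles),

grows with tuning sharpness, and the two are linked by the slowly varying
tuning ratio

    r(f) = QERB(f) / N_SFOAE(f),

which is broadly conserved across related species. Multiplying a species'
measured `N_SFOAE` by `r` from a related species predicts its cochlear
`QERB`. This package implements the full analysis chain for a swept-tone
suppression protocol in small birds, for researchers in auditory physiology
and otoacoustic-emission methodology:

* **Synthetic ear** (`synthesizeSession`, `generateFiberPopulation`) —
  three-condition swept-tone recordings (probe 0.5→8 kHz over 2.05 s at
  40 dB SPL; suppressor offset 40 Hz at 55 dB SPL; 50 kHz sampling) with an
  embedded emission of exactly known delay, plus V-shaped/roex neural tuning
  curves with known CF and Q10 — every downstream stage is verifiable
  against analytic ground truth.
* **SFOAE extraction** (`extractSfoae`) — artifact excision (20-ms windows),
  repetition averaging, vector subtraction
  `P_probe + P_suppressor − P_both`, windowed least-squares sweep spectra,
  odd/even-trial noise floor, phase-gradient delay, and the 10-dB-SNR and
  magnitude-trough exclusion rules.
* **Tuning metrics** (`fiberMetrics`, `summarizeRatio`) — five-point
  triangular smoothing, CF, Q10, and QERB by the inverted-curve-area method.
* **Trends and prediction** (`gaussianTrend`, `bootstrapCi`, `ratioFromQ10`,
  `predictQerb`) — Gaussian-weighted trends (σ = 0.25 oct for delays, 0.5
  oct for Q), 1000-rep bootstrap confidence bands over ears or fibers, Q10
  extrapolation above 1.7 kHz, cross-species QERB prediction, dB/octave
  slopes, LOESS summaries, and behavioral Q10 × 1.76 scaling.
* **Banded statistics** (`bandPool`, `mixedModelF`) — five log-spaced bands
  (centers 1–5 kHz), per-ear robust band polynomials, and a REML mixed model
  with ear random intercepts and Satterthwaite F tests (α = 0.01).

## Worked example

```r
library(cochleartune)

# one synthetic ear under the study protocol, then full extraction
ses <- synthesizeSession(emissionModel(), noiseRms = 6e-4, nReps = 40,
                         artifactRate = 0.2, seed = 42, session = "ear01")
ex <- extractSfoae(ses)
ex$delay
#> DelayCurve: 407 points, 187 valid (80 low_snr, 140 trough)

f <- freqHz(ex$delay); ok <- validPoints(ex$delay)
approx(f[ok], nsfoaeCycles(ex$delay)[ok], xout = 2000)$y
#> [1] 2.42          # cycles at 2 kHz; generator truth is 2.49

# a 127-fiber population and its tuning metrics
met <- populationMetrics(generateFiberPopulation(127, seed = 7))
summarizeRatio(met)
#> $median 1.86   $iqr 1.83 1.87   $n 127
dbPerOctave(met$cf_hz, met$q10)
#> [1] 0.79           # dB/octave rise of Q10 with CF
```

The delay curve keeps 187 of 407 grid points: the rest fall below the
10-dB-SNR criterion (mostly above ~5 kHz, where the emission rolls into the
noise floor) or sit at the base of the three spectral notches. The recovered
delay at 2 kHz is within a few percent of the generator's analytic truth.
The fiber population's median QERB/Q10 of 1.86 sits slightly below the roex
family's analytic 1.944 because five-point tip smoothing at 28
points/octave widens the 10-dB bandwidth a little more than the ERB; the
same effect attenuates the measured Q10 slope relative to the generating
0.87 dB/octave law.

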