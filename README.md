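# flagellaR

Quantitative analysis of planar flagellar beat patterns in R.

Digitized flagellar midlines — the time series of ordered (x, y) points a
tracking pipeline extracts from videomicroscopy of swimming spermatozoa or
other flagellates — are not directly comparable between cells: each swimmer
has its own flagellum length, beating period, phase, and pose in the field
of view. flagellaR turns such captures into comparable, population-level
quantities:

* **Normalization** — body-frame alignment, beat-period detection by
  autocorrelation of a material point, rescaling of arclength by flagellum
  length *L* and of time by period *T*, truncation to a single beat, and
  phase alignment, onto a common grid of 1000 arclength points
  (*s<sub>i</sub>* = (i−1)/999) by 100 timepoints.
* **Parametrizations** — conversion between Cartesian form (x(s,t), y(s,t))
  and the tangent-angle form θ(s,t) = atan2(y<sub>s</sub>, x<sub>s</sub>),
  inverted by (x, y) = ∫₀ˢ (cos θ, sin θ) dŝ; signed curvature
  κ = θ<sub>s</sub>.
* **Population-level PCA** — one decomposition fit to all swimmers at all
  timepoints simultaneously, with unit-norm modes so the time-varying
  coefficients c<sub>i</sub> are comparable across swimmers and modes, and
  the **maximal distal curvature** (MDC): max |θ<sub>s</sub>| over the
  distal 10% of the captured flagellum and the whole beat.
* **Two-sample statistics** — the sinusoidal coefficient model
  c₁ = α + β cos(kt − φ), with (k, φ) from nonlinear least squares on the
  mean coefficient and per-swimmer (α, β) from OLS at fixed (k, φ);
  two-sample Kolmogorov–Smirnov tests on the α and β distributions with an
  overall waveform difference declared only when **both** are significant,
  plus KS/Wilcoxon rank-sum comparisons for scalar metrics (period, length,
  MDC).
* **Synthetic waveforms** — evidence-based generation
  S = μ + N<sub>s</sub><sup>−1/2</sup> Σ (θᵢ − μ) from N<sub>s</sub>
  waveforms drawn uniformly from an empirical dataset; the scaling
  preserves the dataset's pointwise mean and variance, and the output space
  (non-empty subsets) grows as 2ᴺ − 1.
* **A simulator** of flagellate populations with known ground truth
  (traveling bending wave with distally growing amplitude, per-swimmer
  lognormal parameter variation, lab-frame drift and digitization noise),
  so every stage is testable without external data.

## Worked example

Simulate a small two-sample study (sample B beats harder and more
asymmetrically), normalize, decompose, and test:

```r
library(flagellaR)

cfg <- simConfig(nSwimmers = 12, pointsPerFrame = 80, noiseSD = 0)
pop <- simulatePopulation(cfg, groupB = list(amplitude = 0.78, asymmetry = 0.2),
                          seed = 42)

beats <- lapply(pop$captures, preprocessBeat, nS = 300, nT = 50)
beats[[1]]
#> NormalizedBeat 'A001': 300 x 50 grid, L = 58 um, T = 0.06522 s, beat offset 0.555

model <- fitPopulationPCA(beats, representation = "cartesian")
model
#> PopulationModes (cartesian): 24 swimmers, 600 modes
#>   leading weights: 86.9%, 8.5%, 3.6%
```

The first mode carries 86.9% of the pooled variance — a dominant,
near-sinusoidal transverse component, as expected for a regular planar
beat. Fit the coefficient model and run the two-sample decision:

```r
fit <- fitCoefficientModel(model, mode = 1)
fit
#> SinusoidFit of c1: k = 6.1399, phi = 0.5075; 24 swimmers

inA <- pop$truth$group == "A"
fitsA <- new("SinusoidFit", k = fit@k, phi = fit@phi,
             perSwimmer = fit@perSwimmer[inA, ], mode = 1L)
fitsB <- new("SinusoidFit", k = fit@k, phi = fit@phi,
             perSwimmer = fit@perSwimmer[!inA, ], mode = 1L)
cmp <- compareWaveforms(fitsA, fitsB, level = 0.05)
cmp$alpha
#> two-sample KS: statistic = 1, p = 1.229e-05 (significant at 0.05)
cmp$beta
#> two-sample KS: statistic = 0.5833, p = 0.0337 (significant at 0.05)
cmp$reject
#> [1] TRUE
```

Both marginal tests are significant at the 5% level, so the conjunction
rule declares an overall waveform difference between the samples — the
planted amplitude/asymmetry separation is detected. The fitted wavenumber
k ≈ 6.14 ≈ 2π confirms one oscillation per normalized beat. Scalar metrics
and synthesis work from the same objects:

```r
median(vapply(beats, computeMDC, numeric(1)))
#> [1] 6.788     # maximal distal curvature, 1/(normalized arclength)

ds <- EmpiricalDataset(beats)
synthesizeBeat(ds, Ns = 5, seed = 7)
#> SyntheticBeat from 5 source waveforms: L = 53.7 um, T = 0.06353 s

countSyntheticOutputs(216)
#> [1] "105312291668557186697918027683670432318895095400549111254310977535"
```

A 216-swimmer dataset admits 2²¹⁶ − 1 ≈ 1.05 × 10⁶⁵ distinct synthetic
waveform subsets.

## Documentation

The methods vignette (`vignettes/flagellar-beat-analysis.Rmd`) describes
the model and conventions in detail: the normalization pipeline and its
invariances, the population-PCA contract, the sinusoid/KS decision
procedure and its calibration, the moment-preserving synthesis rule, the
simulator's assumptions, and the package's numerical choices and known
limitations.
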