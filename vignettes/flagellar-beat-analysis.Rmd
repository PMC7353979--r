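---
title: "Quantifying planar flagellar beat patterns with flagellaR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar flagellar beat patterns with flagellaR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagellaR)
```

## The problem

A beating flagellum traces out a time-periodic planar curve. Modern
phase-contrast imaging and tracking can digitize most of that curve — the
flagellar midline — frame by frame for hundreds of spermatozoa, but raw
digitizations are not comparable across cells: every swimmer has its own
flagellum length, beating period, phase, and position and orientation in the
field of view. flagellaR implements the normalization, decomposition and
statistical machinery needed to turn such captures into population-level
statements: which shape components dominate the beat, whether two samples of
cells beat differently, and how to generate realistic synthetic beats for
biophysical population models.

## Waveform representations

A normalized beat lives on a fixed grid of `nS` arclength points by `nT`
timepoints (defaults 1000 x 100, i.e. material points at
$s_i = (i-1)/999$ and one period split into 100 equal steps). Two
equivalent parametrizations are supported:

* **Cartesian** $(x(s,t), y(s,t))$, dimensionless after rescaling by the
  flagellum length, base at the origin, points equispaced in arclength;
* **tangent angle** $\theta(s,t) = \mathrm{atan2}(y_s, x_s)$, the angle of
  the local tangent against the body-frame x-axis.

The angle form determines the shape up to rigid motion and is the natural
space for synthesis; the Cartesian form is recovered by integrating the unit
tangent, $(x,y) = \int_0^s (\cos\theta, \sin\theta)\,d\hat{s}$. Derivatives
are second-order central differences (one-sided at the ends), integrals are
cumulative trapezoids, and angles are unwrapped along arclength before any
differentiation — the atan2 branch cut would otherwise corrupt $\theta_s$.
At 1000 material points the round trip between parametrizations is accurate
to better than $10^{-4}$ and the reconstructed curve has unit length to
about $10^{-6}$ for physiological curvatures; both bounds degrade
quadratically in $\kappa\,\Delta s$, which the tests account for when they
probe extreme bending.

## From raw capture to normalized beat

`preprocessBeat()` composes five steps, each exposed on its own:

1. **Body frame** (`toSpermFrame`): per frame, the base point moves to the
   origin and the best-fit direction of the proximal 10% of the flagellum is
   rotated onto +x. The proximal flagellum proxies the head axis; the result
   is invariant under rigid motions of the input to machine precision. The
   rotation uses the principal axis of the proximal points, oriented
   base-to-tip.
2. **Period** (`estimatePeriod`): the normalized autocorrelation of the
   mean-removed trajectory of one material point (default the midpoint; the
   per-coordinate autocovariances are summed, normalized by the overlap
   length so the finite record does not bias the peak). The first local
   maximum above 0.5 wins, with parabolic sub-frame interpolation. Taking
   the *first* qualifying peak returns the fundamental period rather than a
   multiple, and the threshold rejects aperiodic records; two-harmonic beats
   resolve to the fundamental, not the half period.
3. **Rescaling**: arclength by the flagellum length $L$ (reported as the
   median over frames of the digitized midline length; each frame's shape is
   normalized by its own length, since for an inextensible flagellum
   per-frame length differences are tracking noise), time by the period $T$.
4. **Single-beat truncation** (`findBeatStart`): the beat starts at the
   offset $t^\star$ minimizing the distance between the flagellar midpoint
   positions at $t$ and $t+1$ (smallest $t$ on ties); the record must span
   more than one rescaled period, and the pipeline requires more than two.
5. **Phase alignment** (`alignPhase`): a circular time shift placing the
   maximum of the midpoint transverse displacement $y(s_{mid}, t)$ at
   $t = 0$. Any fixed phase event would do; this one is deterministic and
   tied to the dominant transverse mode.

Time discretization interpolates linearly between frames; a final iterative
equal-chord resampling pass then restores exactly equispaced arclength
sampling, which interpolation between frames otherwise perturbs. An optional
smoothing spline (parameter `smooth`, a `smooth.spline` `spar` in (0, 1])
can be applied to each frame before resampling; it is off by default because
released waveform datasets are typically already smoothed, and because
smoothing trades distal-curvature bias against noise (see below).

## Population-level PCA

`fitPopulationPCA()` pools every swimmer at every timepoint into one
observation matrix — rows are single-timepoint waveforms, flattened as
$(x_1, y_1, \ldots, x_{1000}, y_{1000})$ or
$(\theta_1, \ldots, \theta_{1000})$ — and decomposes about the grand mean.
Fitting *one* basis for the whole population (both samples pooled, when two
are compared) is the crux: coefficients of different swimmers then refer to
the same modes and can be compared directly, which per-individual PCA does
not allow. Modes have unit Euclidean norm, so all variance lives in the
coefficients and coefficient magnitudes are comparable across modes; signs
are fixed by making each mode's largest-magnitude entry positive; weights
are variance fractions against the full spectrum. Raw normalized coordinates
enter the decomposition without per-column weighting. With all modes
retained the decomposition is exact (reconstruction to $10^{-8}$), weights
sum to one, and planted low-rank populations are recovered exactly — a
rank-1 population yields weight 1, planted 4:1 coefficient variances yield
weights 0.8/0.2.

The angle and Cartesian decompositions of the same population differ (the
map between them is nonlinear); each reconstructs its own data exactly.

## Maximal distal curvature

`computeMDC()` reports $\max |\theta_s(s,t)|$ over the distal 10% of the
captured flagellum ($s \ge 0.9$) and the whole beat, in units of inverse
normalized arclength (`physical = TRUE` divides by $L$ for 1/µm). Distal
curvature is the part of the beat that older, 70%-capture digitizations
missed, and has been linked to swimming efficiency. Note that the metric is
defined on the *captured* domain: with 90% capture it reflects roughly the
81–90% band of the true flagellum. It is also the statistic most sensitive
to digitization noise — curvature differentiates the tangent angle — so it
should be computed from smoothed captures; on noiseless simulated input the
pipeline reproduces the true MDC to a few tenths of a percent.

## Two-sample comparison

The mean first-mode coefficient $\bar c_1(t)$ of a pooled population is
near-sinusoidal, which motivates the linear model
$c_1 = \alpha + \beta\cos(kt - \phi)$. `fitMeanSinusoid()` estimates
$(k, \phi)$ by nonlinear least squares on $\bar c_1$ — for fixed $k$ the
model is linear, so the fit profiles out $(\alpha, \beta\cos\phi,
\beta\sin\phi)$ and Brent-searches over $k$ from multiple starts
($k \in \{2\pi, 4\pi, 6\pi\}$); $\beta \ge 0$ and $\phi \in [0, 2\pi)$ by
canonicalization. `fitIndividualLinear()` then fits each swimmer by ordinary
least squares with $(k, \phi)$ frozen, yielding per-swimmer $(\alpha,
\beta)$ distributions.

`compareWaveforms()` applies two-tailed two-sample Kolmogorov–Smirnov tests
to the $\alpha$ and $\beta$ samples and declares an overall waveform
difference only if *both* are significant at the level (default 5%). The
conjunction makes the overall test conservative — its simulated type-I rate
is about 2% at a nominal 5% — while amplitude separations of 1.5
between-swimmer SDs are detected essentially always at 80 swimmers per
group. Scalar metrics (period, length, MDC) are compared with
`compareScalars()`: KS for the whole distribution, Wilcoxon rank-sum for the
median (the period comparison conventionally uses the 1% level, available
via `ranksumLevel`). KS p-values are exact (permutation-distribution) for
$\min(n,m) \le 10$ and asymptotic otherwise; rank-sum p-values are exact for
$n + m \le 12$ without ties and use the tie-corrected normal approximation
otherwise, without continuity correction so identical samples give exactly
$p = 1$. No multiplicity correction is applied across the $\alpha/\beta$
pair beyond the conjunction rule, and the joint distribution of
$(\alpha, \beta)$ is deliberately not modeled — marginal tests only.
When subsamples of one population are compared, $(k, \phi)$ are refit on
the pooled set under comparison.

## Synthetic waveform generation

Given an `EmpiricalDataset` of $N$ angle-parametrized beats with mean field
$\mu(s,t)$, `synthesizeBeat()` draws $N_s$ waveforms uniformly without
replacement and forms
$$S(s,t) = \mu(s,t) + N_s^{-1/2} \sum_{i=1}^{N_s} \big[\theta_i(s,t) - \mu(s,t)\big].$$
The $N_s^{-1/2}$ scaling is what makes the generator moment-preserving:
over repeated draws $S$ has pointwise mean $\mu$ and pointwise variance
equal to the dataset variance (times the finite-population factor
$(N - N_s)/(N - 1)$ for subset draws; `replace = TRUE` removes the
correction). A plain average of sampled waveforms would shrink the variance
by $1/N_s$ and produce unrealistically mean-like beats. Boundary cases are
exact: $N_s = 1$ returns the drawn waveform itself, $N_s = N$ returns
$\mu$. A physical scale is attached by uniformly sampling a length and a
period from the empirical marginals, independently by default (`paired`
draws both from one source swimmer); `subset` restricts sampling to a
stratum. Counting distinct waveform subsets over all draw sizes gives
$2^N - 1$ possible outputs — computed exactly in arbitrary precision by
`countSyntheticOutputs()`; a 216-swimmer dataset already admits more than
$10^{60}$. The generator assumes the deviations $\theta_i - \mu$ are
approximately normal pointwise; `angleDeviationDiagnostics()` reports
per-gridpoint skewness and excess kurtosis as a screening diagnostic, and
the package makes no distributional claim beyond the two moments.

## The simulator and what passing tests do (and do not) show

`simulatePopulation()` generates captures with known ground truth from a
traveling bending wave in tangent angle,
$$\theta(s,t) = \theta_0 s + A_0(c + s)\sin\!\big(2\pi(t/T - s/\lambda) + \varphi_0\big)
  + a_2 A_0 (c+s) \sin\!\big(4\pi(t/T - s/\lambda)\big),$$
integrated to Cartesian form, scaled to the flagellum length, truncated to
the captured fraction, carried through a drifting and rotating lab frame,
sampled at the frame rate and corrupted with isotropic Gaussian point noise.
The distally growing envelope reproduces the tendency of beat amplitude to
increase toward the tip; the $\theta_0 s$ term is a static curvature offset
modeling beat asymmetry — a constant angle offset would merely rotate the
body frame and be removed by alignment, so it could never be detected
downstream. Across swimmers, length, period and amplitude vary lognormally
(positive, and at small CV nearly normal, matching unimodal coefficient
histograms), phase uniformly.

Defaults are fixed at what a population study of planar-beating bull sperm
in a viscous medium would look like: 200 swimmers, mean captured length
55 µm with 4% CV, mean period 0.07 s with 10% CV, amplitude 0.6 rad with
15% CV, envelope offset 0.5, one wavelength per flagellum, asymmetry
0.1 rad, second-harmonic fraction 0.15, 90% of the flagellum captured,
40 frames per beat for 4 beats, and 0.05 µm residual point noise (digitized
midlines are normally released after spatial/temporal smoothing; this is
the post-smoothing residual). `framesPerBeat` is even so that symmetric
beats average to zero exactly on the frame grid.

The simulator emulates the *statistical structure* of a real dataset — not
hydrodynamics, head morphology, out-of-plane motion, or the correlated,
heavy-tailed errors of real tracking. Tests passing on simulated data
therefore validate the pipeline's algebra, invariances and statistical
calibration; they do not certify performance on any particular imaging
setup.

## Numerical choices and degenerate inputs

* Equal-arclength resampling uses cubic splines against cumulative chord
  length (linear interpolation as a robust option for jagged polylines);
  the interpolation order is a free choice, made for smooth digitizations.
* Coincident adjacent points, zero-length polylines, constant trajectories,
  records shorter than one period, constant coefficient series and empty
  samples all raise descriptive errors rather than propagating NaNs.
* Ties: the beat-start offset and the phase maximum take the smallest index
  among (numerical) ties; KS/rank-sum tie handling is delegated to the exact
  permutation distributions where available.
* All stochastic routines take explicit seeds; identical seeds give
  bit-identical outputs.
* Problem sizes in the tests and the acceptance script are scaled-down
  study conditions chosen for a desk-scale run: e.g. 50 swimmers for period
  recovery, 20 + 20 swimmers on a 300 x 50 grid for the end-to-end
  two-sample study, coefficient-level replicates (1000 type-I / 500 power)
  for the decision procedure, and 10^4 synthesis draws on a 60 x 20 grid.
  The decision-procedure calibration operates where the test itself
  operates — on per-swimmer $(\alpha, \beta)$ fits — since that is the
  quantity the conjunction rule consumes.

## Known limitations

* Planar beats only; no 3-D (helical or rolling) waveforms.
* Flagellum identification from images and tracking are upstream of this
  package: input is already-digitized midline coordinates.
* The MDC depends on capture fraction and is not a tip curvature.
* Storage is plain CSV/JSON; very large collections (hundreds of swimmers
  at 1000 x 100) are better generated in memory than round-tripped through
  text files.
* The sperm-frame convention (proximal-segment alignment) and the
  phase-zero convention (midpoint maximum) are two of several admissible
  choices; either can be swapped without affecting the rest of the
  pipeline, but coefficients are only comparable within one convention.
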