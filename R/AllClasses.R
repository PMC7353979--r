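#' @import methods
NULL

#' Planar flagellar waveform in Cartesian form
#'
#' A fully normalized beating pattern \eqn{(x(s,t), y(s,t))} sampled on a
#' regular grid of normalized arclength \eqn{s \in [0,1]} (rows) by
#' normalized time \eqn{t \in [0,1)} (columns). Coordinates are dimensionless
#' (rescaled by the flagellum length), the flagellar base sits at the origin
#' in every frame, and sample points are equispaced in arclength so that the
#' shape has unit total length.
#'
#' @slot x,y numeric matrices, arclength by time.
#' @slot sGrid normalized arclength values, equispaced on \eqn{[0,1]}.
#' @slot tGrid normalized time values, equispaced on \eqn{[0,1)}.
#' @export
setClass("CartesianWaveform",
  representation(x = "matrix", y = "matrix", sGrid = "numeric", tGrid = "numeric"))

setValidity("CartesianWaveform", function(object) {
  msg <- character()
  ns <- length(object@sGrid)
  if (!all(dim(object@x) == dim(object@y))) msg <- c(msg, "x and y dimensions differ")
  if (nrow(object@x) != ns) msg <- c(msg, "nrow(x) must equal length(sGrid)")
  if (ncol(object@x) != length(object@tGrid)) msg <- c(msg, "ncol(x) must equal length(tGrid)")
  if (ns < 2L) msg <- c(msg, "need at least 2 arclength points")
  if (length(msg) == 0L) {
    ds <- diff(object@sGrid)
    if (abs(object@sGrid[1L]) > 1e-12 || abs(object@sGrid[ns] - 1) > 1e-12 ||
        any(ds <= 0) || diff(range(ds)) > 1e-9)
      msg <- c(msg, "sGrid must be equispaced, increasing, from 0 to 1")
    if (max(abs(object@x[1L, ])) > 1e-9 || max(abs(object@y[1L, ])) > 1e-9)
      msg <- c(msg, "base point x(0,t), y(0,t) must be at the origin")
    chord <- sqrt(diff(object@x)^2 + diff(object@y)^2)
    target <- 1 / (ns - 1L)
    if (max(abs(chord - target)) > 0.01 * target)
      msg <- c(msg, "points must be equispaced in arclength (chords within 1% of 1/(n-1))")
  }
  if (length(msg)) msg else TRUE
})

#' Planar flagellar waveform in tangent-angle form
#'
#' The tangent-angle parametrization \eqn{\theta(s,t)}: the angle (radians) of
#' the flagellar tangent against the body-frame x-axis, on the same
#' arclength-by-time grid as [CartesianWaveform-class]. Angles are unwrapped
#' along arclength, so the field is free of \eqn{\pm 2\pi} branch jumps.
#'
#' @slot theta numeric matrix, arclength by time, radians.
#' @slot sGrid,tGrid as in [CartesianWaveform-class].
#' @export
setClass("AngleWaveform",
  representation(theta = "matrix", sGrid = "numeric", tGrid = "numeric"))

setValidity("AngleWaveform", function(object) {
  msg <- character()
  if (nrow(object@theta) != length(object@sGrid))
    msg <- c(msg, "nrow(theta) must equal length(sGrid)")
  if (ncol(object@theta) != length(object@tGrid))
    msg <- c(msg, "ncol(theta) must equal length(tGrid)")
  if (!all(is.finite(object@theta))) msg <- c(msg, "theta must be finite everywhere")
  else if (nrow(object@theta) > 1L && max(abs(diff(object@theta))) > pi + 1e-9)
    msg <- c(msg, "theta must be unwrapped along arclength (no +-2*pi jumps)")
  if (length(msg)) msg else TRUE
})

#' Raw digitized capture of one swimmer
#'
#' Per-frame ordered flagellar midline points (micrometres) with timestamps
#' (seconds), before any normalization. The first frame is at time zero and
#' the flagellum length is the median over frames of the cumulative chord
#' length of the digitized midline.
#'
#' @slot frames list of numeric matrices (points x 2), ordered base to tip.
#' @slot timestamps numeric vector of frame times in seconds, starting at 0.
#' @slot swimmerID character label.
#' @export
setClass("RawCapture",
  representation(frames = "list", timestamps = "numeric", swimmerID = "character"))

setValidity("RawCapture", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@timestamps))
    msg <- c(msg, "one timestamp per frame required")
  if (length(object@timestamps) > 0L) {
    if (abs(object@timestamps[1L]) > 1e-12) msg <- c(msg, "first timestamp must be 0")
    if (any(diff(object@timestamps) <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
  }
  npts <- vapply(object@frames, NROW, integer(1))
  if (length(npts) && any(npts < 10L)) msg <- c(msg, "every frame needs at least 10 points")
  if (length(msg)) msg else TRUE
})

#' One normalized flagellar beat
#'
#' A single beat of one swimmer on the common normalized grid: a
#' [CartesianWaveform-class] covering exactly one period, together with the
#' physical flagellum length \code{L} (micrometres), the beating period
#' \code{T} (seconds), and the dimensionless offset \code{beatOffset} at which
#' the retained beat started within the capture.
#'
#' @export
setClass("NormalizedBeat",
  representation(waveform = "CartesianWaveform", L = "numeric", T = "numeric",
                 beatOffset = "numeric", swimmerID = "character",
                 capturedFraction = "numeric"))

setValidity("NormalizedBeat", function(object) {
  msg <- character()
  if (length(object@L) != 1L || object@L <= 0) msg <- c(msg, "L must be a positive scalar")
  if (length(object@T) != 1L || object@T <= 0) msg <- c(msg, "T must be a positive scalar")
  tg <- object@waveform@tGrid
  nt <- length(tg)
  if (nt < 2L || abs(tg[1L]) > 1e-12 || abs(tg[nt] - (nt - 1) / nt) > 1e-9)
    msg <- c(msg, "tGrid must be equispaced on [0, 1): j/n for j = 0..n-1")
  if (length(msg)) msg else TRUE
})

#' Population-level principal component decomposition
#'
#' The result of PCA fit to the pooled observations of every swimmer at every
#' timepoint: the grand-mean shape, unit-norm modes, variance-fraction
#' weights, and the per-swimmer time courses of the mode coefficients (a
#' swimmers x timepoints x modes array). One common basis is fit for the
#' whole population so coefficients are directly comparable across swimmers.
#'
#' @slot representation "cartesian" (observations x1,y1,...,xn,yn) or
#'   "angle" (observations theta1,...,thetan).
#' @slot mean grand-mean observation vector.
#' @slot modes matrix, observation dimension by number of modes; unit columns.
#' @slot weights variance fractions, non-increasing.
#' @slot coefficients array (swimmer, timepoint, mode).
#' @slot sGrid,tGrid the shared grid.
#' @export
setClass("PopulationModes",
  representation(representation = "character", mean = "numeric", modes = "matrix",
                 weights = "numeric", coefficients = "array",
                 sGrid = "numeric", tGrid = "numeric", swimmerIDs = "character"))

setValidity("PopulationModes", function(object) {
  msg <- character()
  if (!object@representation %in% c("cartesian", "angle"))
    msg <- c(msg, "representation must be 'cartesian' or 'angle'")
  if (ncol(object@modes) != length(object@weights))
    msg <- c(msg, "one weight per mode required")
  if (any(object@weights < -1e-12)) msg <- c(msg, "weights must be non-negative")
  if (is.unsorted(rev(object@weights + 1e-12))) msg <- c(msg, "weights must be non-increasing")
  if (length(dim(object@coefficients)) != 3L)
    msg <- c(msg, "coefficients must be a swimmer x time x mode array")
  if (length(msg)) msg else TRUE
})

#' Sinusoidal model fit of a PCA coefficient
#'
#' The linear model \eqn{c_1 = \alpha + \beta \cos(k t - \phi)} fitted to a
#' mode-coefficient time course: the population-level wavenumber \code{k} and
#' phase \code{phi} (from nonlinear least squares on the mean coefficient),
#' and per-swimmer \code{(alpha, beta)} from ordinary least squares with
#' \code{(k, phi)} held fixed.
#'
#' @slot k wavenumber, radians per unit normalized time; positive.
#' @slot phi phase in \eqn{[0, 2\pi)}.
#' @slot perSwimmer data.frame with columns alpha, beta, rms.
#' @slot mode which PCA coefficient was fitted.
#' @export
setClass("SinusoidFit",
  representation(k = "numeric", phi = "numeric", perSwimmer = "data.frame",
                 mode = "integer"))

setValidity("SinusoidFit", function(object) {
  msg <- character()
  if (object@k <= 0) msg <- c(msg, "k must be positive")
  if (object@phi < 0 || object@phi >= 2 * pi) msg <- c(msg, "phi must lie in [0, 2*pi)")
  if (!all(c("alpha", "beta", "rms") %in% names(object@perSwimmer)))
    msg <- c(msg, "perSwimmer needs columns alpha, beta, rms")
  if (length(msg)) msg else TRUE
})

#' Empirical waveform dataset for synthesis
#'
#' A collection of angle-parametrized beats on one common grid, with their
#' physical lengths and periods and the pointwise mean angle field
#' \eqn{\mu(s,t)}, from which synthetic beats are drawn.
#'
#' @slot theta array (arclength, time, swimmer), radians.
#' @slot lengths,periods per-swimmer L (micrometres) and T (seconds).
#' @slot mu pointwise mean of theta over swimmers.
#' @export
setClass("EmpiricalDataset",
  representation(theta = "array", lengths = "numeric", periods = "numeric",
                 mu = "matrix", sGrid = "numeric", tGrid = "numeric"))

setValidity("EmpiricalDataset", function(object) {
  msg <- character()
  n <- dim(object@theta)[3L]
  if (length(object@lengths) != n || length(object@periods) != n)
    msg <- c(msg, "lengths and periods must be index-aligned with waveforms")
  if (any(object@lengths <= 0) || any(object@periods <= 0))
    msg <- c(msg, "lengths and periods must be positive")
  mu <- rowMeans(object@theta, dims = 2L)
  if (max(abs(mu - object@mu)) > 1e-12)
    msg <- c(msg, "mu must equal the pointwise mean of the stored waveforms")
  if (length(msg)) msg else TRUE
})

#' Synthetic flagellar beat
#'
#' An angle parametrization generated from an [EmpiricalDataset-class] as the
#' dataset mean plus a rescaled sum of deviations of sampled real waveforms,
#' with a length and period drawn from the empirical marginals.
#'
#' @slot S the synthetic [AngleWaveform-class].
#' @slot L,T sampled flagellum length (micrometres) and period (seconds).
#' @slot sourceIndices indices of the waveforms drawn from the dataset.
#' @export
setClass("SyntheticBeat",
  representation(S = "AngleWaveform", L = "numeric", T = "numeric",
                 sourceIndices = "integer"))

setValidity("SyntheticBeat", function(object) {
  msg <- character()
  if (object@L <= 0 || object@T <= 0) msg <- c(msg, "L and T must be positive")
  if (length(msg)) msg else TRUE
})
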