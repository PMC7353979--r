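#' Population-level PCA of normalized beats
#'
#' Fits one principal component decomposition to the pooled observations of
#' every swimmer at every timepoint: each observation is the waveform of one
#' swimmer at one timepoint, flattened as
#' \eqn{(x_1, y_1, \ldots, x_{n_s}, y_{n_s})} (Cartesian) or
#' \eqn{(\theta_1, \ldots, \theta_{n_s})} (tangent angle). Observations are
#' centered on the grand mean; modes are normalized to unit Euclidean norm so
#' all variance is carried by the coefficients and coefficient magnitudes are
#' comparable across modes; mode signs are fixed so each mode's
#' largest-magnitude entry is positive. Weights are the fractions of total
#' pooled variance, computed against the full spectrum regardless of how many
#' modes are retained. Fitting one common basis for the whole population (for
#' two-sample comparisons: both samples pooled) is what makes coefficients
#' comparable between swimmers.
#'
#' @param beats list of [NormalizedBeat-class] objects on a common grid (or,
#'   for representation-specific analyses, bare [CartesianWaveform-class] /
#'   [AngleWaveform-class] objects).
#' @param representation "cartesian" or "angle".
#' @param nModes number of modes to retain; \code{NULL} (default) keeps the
#'   full rank, so reconstruction from all modes is exact.
#' @return a [PopulationModes-class].
#' @export
fitPopulationPCA <- function(beats, representation = c("cartesian", "angle"),
                             nModes = NULL) {
  representation <- match.arg(representation)
  if (length(beats) < 2L) stop("need at least 2 swimmers")
  sg <- sGrid(beats[[1L]]); tg <- tGrid(beats[[1L]])
  for (b in beats)
    if (length(sGrid(b)) != length(sg) || length(tGrid(b)) != length(tg))
      stop("inconsistent grids across swimmers")
  nT <- length(tg)
  obs <- do.call(rbind, lapply(beats, function(b) {
    if (representation == "cartesian") {
      x <- xCoords(b); y <- yCoords(b)
      m <- matrix(NA_real_, nT, 2L * nrow(x))
      m[, seq(1L, ncol(m), by = 2L)] <- t(x)
      m[, seq(2L, ncol(m), by = 2L)] <- t(y)
      m
    } else {
      t(thetaMatrix(b))
    }
  }))
  mu <- colMeans(obs)
  ctr <- sweep(obs, 2L, mu)
  sv <- svd(ctr)
  totVar <- sum(sv$d^2)
  if (totVar <= 0) stop("degenerate population: no variance")
  rank <- length(sv$d)
  k <- if (is.null(nModes)) rank else min(as.integer(nModes), rank)
  modes <- sv$v[, seq_len(k), drop = FALSE]
  scores <- ctr %*% modes
  # deterministic sign: largest-magnitude entry of each mode positive
  for (i in seq_len(k)) {
    j <- which.max(abs(modes[, i]))
    if (modes[j, i] < 0) {
      modes[, i] <- -modes[, i]
      scores[, i] <- -scores[, i]
    }
  }
  weights <- (sv$d^2 / totVar)[seq_len(k)]
  coef <- array(NA_real_, c(length(beats), nT, k))
  for (sw in seq_along(beats))
    coef[sw, , ] <- scores[((sw - 1L) * nT + 1L):(sw * nT), , drop = FALSE]
  ids <- vapply(beats, function(b)
    if (is(b, "NormalizedBeat")) b@swimmerID else "swimmer", character(1))
  new("PopulationModes", representation = representation, mean = mu,
      modes = modes, weights = weights, coefficients = coef,
      sGrid = sg, tGrid = tg, swimmerIDs = make.unique(ids))
}

#' Average coefficient time course over a set of swimmers
#'
#' @param model a [PopulationModes-class].
#' @param mode mode index.
#' @param swimmers indices (or logical mask) of the swimmers to average;
#'   default all.
#' @return numeric vector \eqn{\bar c_i(t_j)} over the time grid.
#' @export
meanCoefficient <- function(model, mode = 1L, swimmers = NULL) {
  stopifnot(is(model, "PopulationModes"))
  k <- dim(model@coefficients)[3L]
  if (mode < 1L || mode > k) stop("mode index out of range")
  nSw <- dim(model@coefficients)[1L]
  if (is.null(swimmers)) swimmers <- seq_len(nSw)
  if (is.logical(swimmers)) swimmers <- which(swimmers)
  if (length(swimmers) == 0L) stop("empty swimmer subset")
  m <- model@coefficients[swimmers, , mode, drop = FALSE]
  colMeans(matrix(m, nrow = length(swimmers)))
}

#' Reconstruct pooled observations from a PopulationModes fit
#'
#' Mean plus coefficient-weighted modes; with all modes retained this
#' reproduces the fitted observations exactly.
#'
#' @param model a [PopulationModes-class].
#' @return matrix of observations (swimmer-major by timepoint) by dimension.
#' @export
reconstructObservations <- function(model) {
  stopifnot(is(model, "PopulationModes"))
  d <- dim(model@coefficients)
  scores <- matrix(aperm(model@coefficients, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
  sweep(scores %*% t(model@modes), 2L, model@mean, `+`)
}

#' Maximal distal curvature of a beat
#'
#' The maximum over the distal 10% of the captured flagellum
#' (\eqn{s \ge 0.9}) and the entire beating period of the absolute signed
#' curvature \eqn{|\theta_s(s,t)|}. Reported in units of inverse normalized
#' arclength by default; set \code{physical = TRUE} to divide by the
#' flagellum length and obtain 1/micrometres.
#'
#' @param beat a [NormalizedBeat-class], or an [AngleWaveform-class]
#'   (normalized units only).
#' @param physical rescale to physical units (requires a beat with length).
#' @return scalar maximal distal curvature.
#' @export
computeMDC <- function(beat, physical = FALSE) {
  if (is(beat, "NormalizedBeat")) {
    a <- cartesianToAngle(beat@waveform)
    L <- beat@L
  } else if (is(beat, "AngleWaveform")) {
    a <- beat
    L <- NA_real_
  } else stop("beat must be a NormalizedBeat or AngleWaveform")
  kappa <- curvatureProfile(a)
  distal <- a@sGrid >= 0.9 - 1e-12
  out <- max(abs(kappa[distal, , drop = FALSE]))
  if (physical) {
    if (!is.finite(L)) stop("physical units require a NormalizedBeat")
    out <- out / L
  }
  out
}
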