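#' Construct a Cartesian waveform
#'
#' Low-level constructor with validity checking. \code{x} and \code{y} are
#' arclength-by-time matrices of normalized coordinates; grids default to
#' equispaced \eqn{s_i = (i-1)/(n_s-1)} and \eqn{t_j = (j-1)/n_t}.
#'
#' @param x,y numeric matrices (arclength by time).
#' @param sGrid,tGrid optional grids; defaults as above.
#' @return a [CartesianWaveform-class].
#' @export
CartesianWaveform <- function(x, y, sGrid = NULL, tGrid = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(sGrid)) sGrid <- seq(0, 1, length.out = nrow(x))
  if (is.null(tGrid)) tGrid <- seq(0, 1 - 1 / ncol(x), length.out = ncol(x))
  new("CartesianWaveform", x = x, y = y, sGrid = as.numeric(sGrid),
      tGrid = as.numeric(tGrid))
}

#' Construct an angle waveform
#'
#' @param theta numeric matrix of tangent angles (arclength by time), radians.
#' @inheritParams CartesianWaveform
#' @return an [AngleWaveform-class].
#' @export
AngleWaveform <- function(theta, sGrid = NULL, tGrid = NULL) {
  theta <- as.matrix(theta)
  if (is.null(sGrid)) sGrid <- seq(0, 1, length.out = nrow(theta))
  if (is.null(tGrid)) tGrid <- seq(0, 1 - 1 / ncol(theta), length.out = ncol(theta))
  new("AngleWaveform", theta = theta, sGrid = as.numeric(sGrid),
      tGrid = as.numeric(tGrid))
}

#' Tangent-angle parametrization of a Cartesian waveform
#'
#' Computes \eqn{\theta(s,t) = \mathrm{atan2}(y_s, x_s)} from numerical
#' arclength derivatives (second-order central differences in the interior,
#' one-sided at the ends), then unwraps the angle along arclength at each
#' timepoint so the field carries no branch-cut jumps.
#'
#' @param w a [CartesianWaveform-class] with at least 3 arclength points.
#' @return an [AngleWaveform-class] on the same grid.
#' @seealso [angleToCartesian()] for the inverse reconstruction.
#' @examples
#' # unit-radius circular arc: tangent angle grows linearly with arclength
#' s <- seq(0, 1, length.out = 200)
#' arc <- CartesianWaveform(x = cbind(sin(s)), y = cbind(1 - cos(s)))
#' range(thetaMatrix(cartesianToAngle(arc)) - s)
#' @export
cartesianToAngle <- function(w) {
  stopifnot(is(w, "CartesianWaveform"))
  if (length(w@sGrid) < 3L) stop("need at least 3 arclength points")
  xs <- fdDeriv(w@x, w@sGrid)
  ys <- fdDeriv(w@y, w@sGrid)
  speed <- sqrt(xs^2 + ys^2)
  if (any(speed < 1e-8))
    stop("invalid geometry: degenerate (coincident) adjacent points")
  theta <- atan2(ys, xs)
  theta <- apply(theta, 2L, unwrapAngle)
  AngleWaveform(theta, sGrid = w@sGrid, tGrid = w@tGrid)
}

#' Reconstruct Cartesian coordinates from a tangent-angle waveform
#'
#' Inverts the tangent-angle parametrization by cumulative trapezoidal
#' quadrature of the unit-speed integrand,
#' \eqn{(x, y)(s, t) = \int_0^s (\cos\theta, \sin\theta)\, d\hat s},
#' placing the flagellar base at the origin. The reconstruction has unit
#' total arclength by construction.
#'
#' @param a an [AngleWaveform-class].
#' @return a [CartesianWaveform-class] on the same grid.
#' @export
angleToCartesian <- function(a) {
  stopifnot(is(a, "AngleWaveform"))
  x <- apply(cos(a@theta), 2L, function(col) pracma::cumtrapz(a@sGrid, col))
  y <- apply(sin(a@theta), 2L, function(col) pracma::cumtrapz(a@sGrid, col))
  CartesianWaveform(x, y, sGrid = a@sGrid, tGrid = a@tGrid)
}

#' Resample an ordered polyline at equal arclength fractions
#'
#' Returns \code{n} points whose cumulative chord-length fractions are
#' \eqn{(i-1)/(n-1)}, obtained by cubic-spline interpolation of each
#' coordinate against the cumulative chord length of the input polyline. The
#' first and last input points are preserved.
#'
#' @param points numeric matrix (points x 2), ordered along the curve.
#' @param n number of output points (>= 2).
#' @param method "spline" (default; cubic, best for smooth digitizations) or
#'   "linear" (points stay on the input polyline, robust to jagged input).
#' @return an n x 2 matrix of resampled points.
#' @export
resampleArclength <- function(points, n, method = c("spline", "linear")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (nrow(points) < 2L || n < 2L) stop("need >= 2 input points and n >= 2")
  len <- chordLengths(points)
  if (len[length(len)] <= 0) stop("invalid geometry: polyline has zero total length")
  keep <- c(TRUE, diff(len) > 0)          # drop exactly coincident points
  len <- len[keep]; points <- points[keep, , drop = FALSE]
  target <- seq(0, len[length(len)], length.out = n)
  if (method == "linear" || nrow(points) < 4L)
    return(cbind(stats::approx(len, points[, 1L], xout = target)$y,
                 stats::approx(len, points[, 2L], xout = target)$y))
  cbind(stats::spline(len, points[, 1L], xout = target, method = "fmm")$y,
        stats::spline(len, points[, 2L], xout = target, method = "fmm")$y)
}

#' Signed curvature field of an angle waveform
#'
#' The signed curvature \eqn{\kappa(s,t) = \theta_s(s,t)} by second-order
#' finite differences along arclength, in units of inverse normalized length.
#'
#' @param a an [AngleWaveform-class].
#' @return a matrix of the same shape as \code{thetaMatrix(a)}.
#' @export
curvatureProfile <- function(a) {
  stopifnot(is(a, "AngleWaveform"))
  fdDeriv(a@theta, a@sGrid)
}
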