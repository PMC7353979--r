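#' Assemble an empirical dataset for waveform synthesis
#'
#' Collects angle-parametrized beats on a common grid together with their
#' physical lengths and periods, and precomputes the pointwise mean angle
#' field \eqn{\mu(s,t)}.
#'
#' @param beats list of [NormalizedBeat-class] or [AngleWaveform-class]
#'   objects on one common grid.
#' @param lengths,periods per-swimmer L (micrometres) and T (seconds);
#'   taken from the beats when they are [NormalizedBeat-class] objects.
#' @return an [EmpiricalDataset-class].
#' @export
EmpiricalDataset <- function(beats, lengths = NULL, periods = NULL) {
  if (length(beats) < 1L) stop("dataset must be non-empty")
  angles <- lapply(beats, function(b) {
    if (is(b, "NormalizedBeat")) cartesianToAngle(b@waveform)
    else if (is(b, "AngleWaveform")) b
    else stop("beats must be NormalizedBeat or AngleWaveform objects")
  })
  if (is.null(lengths))
    lengths <- vapply(beats, function(b)
      if (is(b, "NormalizedBeat")) b@L else NA_real_, numeric(1))
  if (is.null(periods))
    periods <- vapply(beats, function(b)
      if (is(b, "NormalizedBeat")) b@T else NA_real_, numeric(1))
  sg <- angles[[1L]]@sGrid; tg <- angles[[1L]]@tGrid
  th <- array(NA_real_, c(length(sg), length(tg), length(angles)))
  for (i in seq_along(angles)) {
    a <- angles[[i]]
    if (length(a@sGrid) != length(sg) || length(a@tGrid) != length(tg))
      stop("all waveforms must share one common grid (offender: ", i, ")")
    th[, , i] <- a@theta
  }
  new("EmpiricalDataset", theta = th, lengths = as.numeric(lengths),
      periods = as.numeric(periods), mu = rowMeans(th, dims = 2L),
      sGrid = sg, tGrid = tg)
}

#' Generate a synthetic flagellar beat
#'
#' Draws \code{Ns} waveforms \eqn{\theta_1, \ldots, \theta_{N_s}} uniformly
#' from the dataset (without replacement by default, so each draw is a
#' subset) and forms the synthetic angle parametrization
#' \deqn{S(s,t) = \mu(s,t) + N_s^{-1/2} \sum_i [\theta_i(s,t) - \mu(s,t)],}
#' where \eqn{\mu} is the dataset's pointwise mean. The \eqn{N_s^{-1/2}}
#' scaling of the summed deviations makes the generator moment-preserving:
#' over repeated draws \eqn{S} has pointwise mean \eqn{\mu} and pointwise
#' variance equal to the dataset variance (with the finite-population
#' correction under without-replacement draws). A physical scale is attached
#' by uniformly sampling a flagellum length and a beating period from the
#' empirical marginals (independently unless \code{paired}).
#'
#' @param ds an [EmpiricalDataset-class].
#' @param Ns number of waveforms to draw, between 1 and the dataset size.
#' @param seed optional integer seed; identical seeds give identical output.
#' @param replace draw waveforms with replacement (default \code{FALSE}).
#' @param paired draw the length and period jointly from one source swimmer
#'   instead of independently.
#' @param subset optional indices restricting sampling to a stratum of the
#'   dataset.
#' @return a [SyntheticBeat-class].
#' @export
synthesizeBeat <- function(ds, Ns, seed = NULL, replace = FALSE,
                           paired = FALSE, subset = NULL) {
  stopifnot(is(ds, "EmpiricalDataset"))
  pool <- if (is.null(subset)) seq_len(dim(ds@theta)[3L]) else as.integer(subset)
  n <- length(pool)
  Ns <- as.integer(Ns)
  if (Ns < 1L || (!replace && Ns > n)) stop("Ns out of range for this dataset")
  if (!is.null(seed)) set.seed(seed)
  idx <- pool[sample.int(n, Ns, replace = replace)]
  dev <- rowSums(ds@theta[, , idx, drop = FALSE], dims = 2L) - Ns * ds@mu
  S <- ds@mu + dev / sqrt(Ns)
  iL <- pool[sample.int(n, 1L)]
  iT <- if (paired) iL else pool[sample.int(n, 1L)]
  new("SyntheticBeat",
      S = AngleWaveform(S, sGrid = ds@sGrid, tGrid = ds@tGrid),
      L = ds@lengths[iL], T = ds@periods[iT], sourceIndices = as.integer(idx))
}

#' Exact size of the synthetic output space
#'
#' The number of distinct waveform subsets a dataset of size \code{n} can
#' yield over all draw sizes \eqn{N_s = 1, \ldots, n}: the count of
#' non-empty subsets, \eqn{2^n - 1}, computed exactly in arbitrary precision
#' and returned as a decimal string. The count grows exponentially with
#' dataset size; length and period draws are not multiplied in.
#'
#' @param n dataset size (non-negative integer).
#' @return the exact count as a decimal character string, with the number of
#'   decimal digits attached as attribute \code{nDigits}.
#' @examples
#' countSyntheticOutputs(10)   # "1023"
#' @export
countSyntheticOutputs <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  if (n == 0L) return(structure("0", nDigits = 1L))
  chunks <- 1
  for (i in seq_len(n)) chunks <- bigDouble(chunks)
  out <- bigFormat(bigDecrement(chunks))
  structure(out, nDigits = nchar(out))
}

#' Rescale a synthetic beat to physical units
#'
#' Reconstructs the Cartesian beating pattern from the synthetic angle
#' parametrization by cumulative quadrature, then rescales space by the
#' sampled flagellum length and time by the sampled period.
#'
#' @param beat a [SyntheticBeat-class].
#' @return list with matrices \code{x}, \code{y} (micrometres), vectors
#'   \code{s} (arclength, micrometres), \code{t} (seconds), and scalars
#'   \code{L}, \code{T}.
#' @export
toPhysical <- function(beat) {
  stopifnot(is(beat, "SyntheticBeat"))
  w <- angleToCartesian(beat@S)
  list(x = w@x * beat@L, y = w@y * beat@L, s = w@sGrid * beat@L,
       t = w@tGrid * beat@T, L = beat@L, T = beat@T)
}

#' Normality diagnostic for angle deviations
#'
#' Per-gridpoint skewness and excess kurtosis of the deviations of the
#' dataset's waveforms from their pointwise mean; a screening diagnostic for
#' the approximate-normality assumption behind moment-preserving synthesis.
#'
#' @param ds an [EmpiricalDataset-class].
#' @return list of matrices \code{skewness} and \code{kurtosis} on the grid.
#' @export
angleDeviationDiagnostics <- function(ds) {
  stopifnot(is(ds, "EmpiricalDataset"))
  dev <- sweep(ds@theta, c(1L, 2L), ds@mu)
  m2 <- rowMeans(dev^2, dims = 2L)
  m3 <- rowMeans(dev^3, dims = 2L)
  m4 <- rowMeans(dev^4, dims = 2L)
  list(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}
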