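#' @importFrom stats ks.test wilcox.test lm.fit
NULL

# Uniform container for a two-sample test outcome.
.testResult <- function(statistic, pValue, testName, level) {
  structure(list(statistic = unname(statistic), p.value = unname(pValue),
                 test = testName, level = level,
                 reject = unname(pValue) < level),
            class = "flagTest")
}

#' @export
print.flagTest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%ssignificant at %g)\n",
              x$test, x$statistic, x$p.value, if (x$reject) "" else "not ",
              x$level))
  invisible(x)
}

#' Sinusoid fit of a mean coefficient time course
#'
#' Nonlinear least-squares fit of \eqn{\bar c(t) = \alpha + \beta\cos(kt-\phi)}
#' to a mean mode-coefficient. For fixed wavenumber the model is linear in
#' \eqn{(\alpha, \beta\cos\phi, \beta\sin\phi)}, so the fit profiles out the
#' linear part and minimizes over \eqn{k} alone (Brent search, multi-start
#' around \eqn{k \in \{2\pi, 4\pi, 6\pi\}}, best residual wins).
#' \eqn{\beta \ge 0} is enforced by the canonicalization
#' \eqn{(\beta,\phi) \to (-\beta, \phi+\pi)} and \eqn{\phi} is reported in
#' \eqn{[0, 2\pi)}.
#'
#' @param cbar numeric vector, mean coefficient at each timepoint.
#' @param tGrid normalized times; defaults to \eqn{(j-1)/n}.
#' @return list with elements \code{k}, \code{phi}, \code{alpha}, \code{beta},
#'   \code{rms}.
#' @export
fitMeanSinusoid <- function(cbar, tGrid = NULL) {
  cbar <- as.numeric(cbar)
  n <- length(cbar)
  if (n < 5L) stop("too few timepoints")
  if (stats::sd(cbar) < 1e-12) stop("degenerate fit: constant coefficient")
  if (is.null(tGrid)) tGrid <- (seq_len(n) - 1) / n

  rssAt <- function(k) {
    X <- cbind(1, cos(k * tGrid), sin(k * tGrid))
    fit <- lm.fit(X, cbar)
    sum(fit$residuals^2)
  }
  best <- NULL
  for (k0 in c(2, 4, 6) * pi) {
    opt <- stats::optimize(rssAt, interval = c(0.4 * k0, 1.6 * k0), tol = 1e-10)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  k <- best$minimum
  X <- cbind(1, cos(k * tGrid), sin(k * tGrid))
  fit <- lm.fit(X, cbar)
  b <- fit$coefficients
  beta <- sqrt(b[2L]^2 + b[3L]^2)
  phi <- atan2(b[3L], b[2L]) %% (2 * pi)
  list(k = unname(k), phi = unname(phi), alpha = unname(b[1L]),
       beta = unname(beta), rms = sqrt(mean(fit$residuals^2)))
}

#' Per-swimmer linear sinusoid fits at fixed wavenumber and phase
#'
#' Ordinary least squares of each swimmer's coefficient time course on the
#' design \eqn{[1, \cos(kt-\phi)]}, with \eqn{(k, \phi)} held fixed at the
#' population values; returns per-swimmer \eqn{(\alpha, \beta)}.
#'
#' @param c1 matrix (swimmers x timepoints) or a single time-course vector.
#' @param k,phi fixed wavenumber and phase from [fitMeanSinusoid()].
#' @param tGrid normalized times; defaults to \eqn{(j-1)/n}.
#' @param mode coefficient index recorded in the result.
#' @return a [SinusoidFit-class].
#' @export
fitIndividualLinear <- function(c1, k, phi, tGrid = NULL, mode = 1L) {
  if (is.null(dim(c1))) c1 <- matrix(c1, nrow = 1L)
  n <- ncol(c1)
  if (is.null(tGrid)) tGrid <- (seq_len(n) - 1) / n
  X <- cbind(1, cos(k * tGrid - phi))
  fit <- lm.fit(X, t(c1))
  cf <- t(fit$coefficients)
  res <- t(c1) - X %*% fit$coefficients
  per <- data.frame(alpha = cf[, 1L], beta = cf[, 2L],
                    rms = sqrt(colMeans(res^2)))
  new("SinusoidFit", k = as.numeric(k), phi = as.numeric(phi) %% (2 * pi),
      perSwimmer = per, mode = as.integer(mode))
}

#' Fit the sinusoidal coefficient model to a population
#'
#' Convenience wrapper: fits \eqn{(k, \phi)} by nonlinear least squares on
#' the mean coefficient of the pooled fitting set, then per-swimmer
#' \eqn{(\alpha, \beta)} by linear least squares with \eqn{(k, \phi)} fixed.
#'
#' @param model a [PopulationModes-class].
#' @param mode which coefficient to model (default 1).
#' @param swimmers optional subset used for the mean fit; per-swimmer fits
#'   are returned for all swimmers.
#' @return a [SinusoidFit-class].
#' @export
fitCoefficientModel <- function(model, mode = 1L, swimmers = NULL) {
  cbar <- meanCoefficient(model, mode = mode, swimmers = swimmers)
  mf <- fitMeanSinusoid(cbar, tGrid = model@tGrid)
  c1 <- matrix(model@coefficients[, , mode],
               nrow = dim(model@coefficients)[1L])
  fitIndividualLinear(c1, k = mf$k, phi = mf$phi, tGrid = model@tGrid,
                      mode = mode)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-tailed two-sample KS test: the statistic is the supremum distance
#' between the empirical CDFs; the p-value is exact (permutation
#' distribution) when \code{min(n, m) <= 10} and asymptotic otherwise.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @param level significance level (default 0.05).
#' @return a \code{flagTest} list: statistic, p.value, reject.
#' @export
ksTwoSample <- function(a, b, level = 0.05) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  exact <- min(length(a), length(b)) <= 10L
  ht <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  .testResult(ht$statistic, ht$p.value, "two-sample KS", level)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test: exact null enumeration for
#' combined sample sizes \code{n + m <= 12} without ties, normal
#' approximation with tie correction otherwise.
#'
#' @inheritParams ksTwoSample
#' @return a \code{flagTest} list.
#' @export
wilcoxonRankSum <- function(a, b, level = 0.05) {
  if (length(a) < 1L || length(b) < 1L) stop("each sample needs >= 1 value")
  exact <- (length(a) + length(b) <= 12L) && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  .testResult(ht$statistic, ht$p.value, "Wilcoxon rank-sum", level)
}

#' Two-sample waveform comparison via sinusoid-fit parameters
#'
#' The decision procedure for an overall waveform difference between two
#' samples: two-sample KS tests on the per-swimmer \eqn{\alpha} values and on
#' the \eqn{\beta} values, with an overall significant difference declared
#' only if both tests are significant at \code{level}. The two fits must
#' share the \eqn{(k, \phi)} obtained from the pooled mean-coefficient fit.
#' The conjunction rule makes the overall test conservative (its type-I
#' error is at most the nominal level).
#'
#' @param fitsA,fitsB [SinusoidFit-class] objects for the two samples,
#'   sharing \code{k} and \code{phi}.
#' @param level significance level for each marginal KS test (default 0.05).
#' @return list with elements \code{alpha} and \code{beta} (marginal
#'   \code{flagTest}s), \code{reject} (the conjunction) and \code{level}.
#' @export
compareWaveforms <- function(fitsA, fitsB, level = 0.05) {
  stopifnot(is(fitsA, "SinusoidFit"), is(fitsB, "SinusoidFit"))
  if (abs(fitsA@k - fitsB@k) > 1e-9 || abs(fitsA@phi - fitsB@phi) > 1e-9)
    stop("fits must share (k, phi) from the pooled mean fit")
  ta <- ksTwoSample(fitsA@perSwimmer$alpha, fitsB@perSwimmer$alpha, level)
  tb <- ksTwoSample(fitsA@perSwimmer$beta, fitsB@perSwimmer$beta, level)
  list(alpha = ta, beta = tb, reject = ta$reject && tb$reject, level = level)
}

#' Two-sample comparison of a scalar beat metric
#'
#' Compares the distributions of a scalar summary (beating period, flagellum
#' length, maximal distal curvature, ...) between two samples: the full
#' distributions by a two-sample KS test and the medians by a Wilcoxon
#' rank-sum test.
#'
#' @inheritParams ksTwoSample
#' @param ranksumLevel optional separate level for the rank-sum test
#'   (defaults to \code{level}).
#' @return list with elements \code{ks} and \code{ranksum}.
#' @export
compareScalars <- function(a, b, level = 0.05, ranksumLevel = level) {
  list(ks = ksTwoSample(a, b, level),
       ranksum = wilcoxonRankSum(a, b, ranksumLevel))
}
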