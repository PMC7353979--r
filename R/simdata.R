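#' Configuration for the flagellate population simulator
#'
#' Builds and validates the parameter set for [simulateSwimmer()] and
#' [simulatePopulation()]. The simulated beat is a traveling bending wave in
#' tangent angle,
#' \deqn{\theta(s,t) = \theta_0 s + A(s)\sin(2\pi(t/T - s/\lambda) + \varphi_0)
#'       + a_2 A(s) \sin(4\pi(t/T - s/\lambda)),}
#' with a distally growing amplitude envelope \eqn{A(s) = A_0 (c + s)} and a
#' static curvature offset whose tangent angle reaches \eqn{\theta_0} radians
#' at the tip (beat asymmetry; a constant angle offset would only rotate the
#' body frame). The
#' defaults emulate a population of planar-beating bovine spermatozoa
#' digitized over about 90% of the flagellum: ~200 swimmers, flagellum-length
#' coefficient of variation below 4%, near-sinusoidal dominant-mode dynamics
#' with a subtle standing asymmetry, and mild harmonic content.
#'
#' @param nSwimmers number of swimmers per group.
#' @param meanLength mean captured flagellum length, micrometres.
#' @param lengthCV coefficient of variation of length across swimmers.
#' @param meanPeriod mean beating period, seconds.
#' @param periodCV coefficient of variation of the period.
#' @param amplitude base wave amplitude \eqn{A_0}, radians.
#' @param amplitudeCV across-swimmer amplitude CV.
#' @param envelopeOffset envelope constant \eqn{c} in \eqn{A_0(c+s)}.
#' @param wavelength normalized wavelength \eqn{\lambda} of the traveling wave.
#' @param asymmetry static curvature offset: the tangent angle it contributes
#'   at the tip, \eqn{\theta_0}, radians.
#' @param asymmetrySD across-swimmer SD of the asymmetry offset.
#' @param harmonic relative amplitude \eqn{a_2} of the second harmonic.
#' @param noiseSD isotropic Gaussian noise on digitized points, micrometres.
#' @param framesPerBeat frames recorded per beating period (even, so that
#'   symmetric beats average to zero exactly on the frame grid).
#' @param beatsRecorded number of beats in each capture.
#' @param capturedFraction fraction of the true flagellum that is digitized.
#' @param pointsPerFrame digitized midline points per frame.
#' @param driftSpeed lab-frame swimming speed, micrometres per second.
#' @param yawRate lab-frame rotation rate, radians per second.
#' @return a validated \code{SimConfig} list.
#' @export
simConfig <- function(nSwimmers = 200L, meanLength = 55, lengthCV = 0.04,
                      meanPeriod = 0.07, periodCV = 0.1,
                      amplitude = 0.6, amplitudeCV = 0.15,
                      envelopeOffset = 0.5, wavelength = 1,
                      asymmetry = 0.1, asymmetrySD = 0.02, harmonic = 0.15,
                      noiseSD = 0.05, framesPerBeat = 40L, beatsRecorded = 4L,
                      capturedFraction = 0.9, pointsPerFrame = 101L,
                      driftSpeed = 30, yawRate = 0.5) {
  cfg <- list(nSwimmers = as.integer(nSwimmers), meanLength = meanLength,
              lengthCV = lengthCV, meanPeriod = meanPeriod,
              periodCV = periodCV, amplitude = amplitude,
              amplitudeCV = amplitudeCV, envelopeOffset = envelopeOffset,
              wavelength = wavelength, asymmetry = asymmetry,
              asymmetrySD = asymmetrySD, harmonic = harmonic,
              noiseSD = noiseSD, framesPerBeat = as.integer(framesPerBeat),
              beatsRecorded = as.integer(beatsRecorded),
              capturedFraction = capturedFraction,
              pointsPerFrame = as.integer(pointsPerFrame),
              driftSpeed = driftSpeed, yawRate = yawRate)
  with(cfg, {
    stopifnot(nSwimmers >= 1L, meanLength > 0, meanPeriod > 0, amplitude >= 0,
              lengthCV >= 0, periodCV >= 0, amplitudeCV >= 0, wavelength > 0,
              noiseSD >= 0, framesPerBeat >= 4L, beatsRecorded >= 1L,
              capturedFraction > 0, capturedFraction <= 1,
              pointsPerFrame >= 10L)
  })
  structure(cfg, class = "SimConfig")
}

# Noiseless tangent-angle field of the simulated traveling wave on the
# full-length normalized arclength grid s (theta0/A0/phi0 per swimmer).
# Asymmetry enters as a static curvature offset (tangent angle ramping to
# theta0 radians at the tip): a constant angle offset would be a rigid
# rotation and vanish in the body-fixed frame.
.simTheta <- function(s, tNorm, cfg, A0, theta0, phi0) {
  A <- A0 * (cfg$envelopeOffset + s)
  ph <- outer(-s / cfg$wavelength, tNorm, `+`)
  theta0 * s + A * sin(2 * pi * ph + phi0) + cfg$harmonic * A * sin(4 * pi * ph)
}

#' Noiseless tangent-angle field of one simulated swimmer
#'
#' Evaluates the traveling-wave model of [simConfig()] over the captured
#' portion of the flagellum (arclength renormalized to \eqn{[0,1]}) on a
#' beat grid of \code{nS} arclength points by \code{nT} timepoints; this is
#' the ground-truth angle field against which pipeline output can be
#' compared, and a cheap source of model-distributed waveform datasets.
#'
#' @inheritParams simulateSwimmer
#' @param nS,nT grid sizes of the returned field.
#' @return an [AngleWaveform-class].
#' @export
simulateThetaField <- function(cfg, A0 = cfg$amplitude, theta0 = cfg$asymmetry,
                               phi0 = 0, nS = 1000L, nT = 100L) {
  stopifnot(inherits(cfg, "SimConfig"))
  sNorm <- seq(0, 1, length.out = nS) * cfg$capturedFraction
  tBeat <- (seq_len(nT) - 1L) / nT
  AngleWaveform(.simTheta(sNorm, tBeat, cfg, A0, theta0, phi0))
}

#' Simulate one swimmer's raw capture
#'
#' Generates the digitized midline of one flagellate under the traveling-wave
#' model of [simConfig()]: the tangent-angle field is integrated to Cartesian
#' coordinates (scaled to the swimmer's full flagellum length), truncated to
#' the captured fraction, moved through a rigidly drifting and rotating lab
#' frame, sampled at the configured frame rate, and corrupted with isotropic
#' Gaussian point noise.
#'
#' @param cfg a \code{SimConfig}.
#' @param L,T,A0,theta0,phi0 per-swimmer captured length (micrometres),
#'   period (seconds), amplitude, asymmetry offset and initial phase;
#'   defaults are the configured means with phase 0.
#' @param swimmerID label for the capture.
#' @return list with elements \code{capture} (a [RawCapture-class]) and
#'   \code{truth} (list of the generating parameters and the noiseless angle
#'   field \code{theta} on a 100-timepoint beat grid over the captured,
#'   renormalized arclength).
#' @export
simulateSwimmer <- function(cfg, L = cfg$meanLength, T = cfg$meanPeriod,
                            A0 = cfg$amplitude, theta0 = cfg$asymmetry,
                            phi0 = 0, swimmerID = "sim") {
  stopifnot(inherits(cfg, "SimConfig"))
  f <- cfg$capturedFraction
  Lfull <- L / f
  nFrames <- cfg$framesPerBeat * cfg$beatsRecorded
  tPhys <- (seq_len(nFrames) - 1L) * T / cfg$framesPerBeat
  sCap <- seq(0, f, length.out = cfg$pointsPerFrame)   # full-length units
  frames <- vector("list", nFrames)
  for (m in seq_len(nFrames)) {
    th <- .simTheta(sCap, tPhys[m] / T, cfg, A0, theta0, phi0)
    x <- Lfull * pracma::cumtrapz(sCap, cos(th))
    y <- Lfull * pracma::cumtrapz(sCap, sin(th))
    pts <- cbind(as.numeric(x), as.numeric(y))
    ang <- cfg$yawRate * tPhys[m]
    pts <- pts %*% rotationMatrix(ang)
    pts <- sweep(pts, 2L, -c(cfg$driftSpeed * tPhys[m], 0))
    if (cfg$noiseSD > 0)
      pts <- pts + matrix(rnorm(length(pts), sd = cfg$noiseSD), ncol = 2L)
    frames[[m]] <- pts
  }
  # ground-truth angle field over the captured, renormalized arclength
  thetaTrue <- thetaMatrix(simulateThetaField(cfg, A0, theta0, phi0))
  list(capture = RawCapture(frames, tPhys, swimmerID),
       truth = list(L = L, T = T, A0 = A0, theta0 = theta0, phi0 = phi0,
                    theta = thetaTrue))
}

#' Simulate a population (one or two groups) of swimmers
#'
#' Draws per-swimmer parameters (length, period, amplitude) lognormally
#' around the configured means with the configured coefficients of
#' variation — positive-valued and, at small CV, close to normal — plus a
#' normally jittered asymmetry offset and a uniform initial phase, then
#' simulates each swimmer's capture. A second group with modified parameters
#' is produced by supplying \code{groupB}, a named list of [simConfig()]
#' overrides.
#'
#' @param cfg a \code{SimConfig} for group A.
#' @param groupB optional named list of config overrides defining group B.
#' @param seed integer seed; the simulation is deterministic given the seed.
#' @return list with \code{captures} (list of [RawCapture-class]),
#'   \code{truth} (data.frame of per-swimmer generating parameters and group
#'   labels) and \code{thetaTrue} (list of noiseless angle fields).
#' @export
simulatePopulation <- function(cfg, groupB = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(seed)
  cfgs <- list(A = cfg)
  if (!is.null(groupB)) {
    cfgB <- unclass(cfg)
    cfgB[names(groupB)] <- groupB
    cfgs$B <- do.call(simConfig, cfgB)
  }
  captures <- list(); thetaTrue <- list(); rows <- list()
  for (g in names(cfgs)) {
    cg <- cfgs[[g]]
    for (i in seq_len(cg$nSwimmers)) {
      L <- .rlnormMeanCV(1L, cg$meanLength, cg$lengthCV)
      T <- .rlnormMeanCV(1L, cg$meanPeriod, cg$periodCV)
      A0 <- .rlnormMeanCV(1L, cg$amplitude, cg$amplitudeCV)
      th0 <- rnorm(1L, cg$asymmetry, cg$asymmetrySD)
      ph0 <- runif(1L, 0, 2 * pi)
      id <- sprintf("%s%03d", g, i)
      sw <- simulateSwimmer(cg, L = L, T = T, A0 = A0, theta0 = th0,
                            phi0 = ph0, swimmerID = id)
      captures[[id]] <- sw$capture
      thetaTrue[[id]] <- sw$truth$theta
      rows[[id]] <- data.frame(swimmerID = id, group = g, L = L, T = T,
                               A0 = A0, theta0 = th0, phi0 = ph0)
    }
  }
  list(captures = captures, truth = do.call(rbind, c(rows, make.row.names = FALSE)),
       thetaTrue = thetaTrue)
}

# Lognormal draws with a given arithmetic mean and coefficient of variation.
.rlnormMeanCV <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
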