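#' Construct a raw capture
#'
#' @param frames list of numeric matrices (points x 2), micrometres, each row
#'   ordered from flagellar base to tip.
#' @param timestamps frame times in seconds; the first must be 0.
#' @param swimmerID character label.
#' @return a [RawCapture-class].
#' @export
RawCapture <- function(frames, timestamps, swimmerID = "swimmer") {
  frames <- lapply(frames, function(f) unname(as.matrix(f)))
  new("RawCapture", frames = frames, timestamps = as.numeric(timestamps),
      swimmerID = as.character(swimmerID))
}

#' Beating period by autocorrelation of a material point
#'
#' Estimates the minimal beating period as the lag after which a material
#' point's trajectory is most self-similar: the normalized autocorrelation of
#' the mean-removed trajectory (per-coordinate autocovariances summed) is
#' scanned for its first local maximum exceeding \code{threshold}, and the
#' peak is refined to sub-frame resolution by parabolic interpolation.
#' Choosing the first qualifying maximum returns the fundamental period
#' rather than a multiple of it, and is robust to harmonic content in the
#' trajectory.
#'
#' @param track numeric matrix (frames x 2), positions of one material point.
#' @param dt constant frame interval in seconds.
#' @param threshold minimal normalized autocorrelation for a peak (default 0.5).
#' @return the period T in seconds.
#' @export
estimatePeriod <- function(track, dt, threshold = 0.5) {
  track <- as.matrix(track)
  n <- nrow(track)
  if (n < 6L) stop("track too short for period estimation")
  z <- sweep(track, 2L, colMeans(track))
  if (max(abs(z)) < 1e-12) stop("no periodicity: constant trajectory")
  maxLag <- min(n - 2L, as.integer(floor(2 * (n - 1L) / 3)))
  # unbiased autocovariance (normalized by the overlap length) so the
  # finite-record taper does not bias the peak location
  r <- vapply(0:maxLag, function(k) {
    (sum(z[1:(n - k), 1L] * z[(1L + k):n, 1L]) +
       sum(z[1:(n - k), 2L] * z[(1L + k):n, 2L])) / (n - k)
  }, numeric(1))
  r <- r / r[1L]
  # first interior local maximum above threshold (lag index k -> r[k + 1])
  for (k in 1:(maxLag - 1L)) {
    if (r[k + 1L] > threshold && r[k + 1L] >= r[k] && r[k + 1L] >= r[k + 2L]) {
      denom <- r[k] - 2 * r[k + 1L] + r[k + 2L]
      shift <- if (abs(denom) > 1e-15) 0.5 * (r[k] - r[k + 2L]) / denom else 0
      shift <- max(-0.5, min(0.5, shift))
      return((k + shift) * dt)
    }
  }
  stop("no periodicity: no autocorrelation peak above threshold")
}

# Best-fit direction (unit vector) of a point cloud by principal axis,
# oriented from the first toward the last point.
.principalDirection <- function(pts) {
  ctr <- sweep(pts, 2L, colMeans(pts))
  ev <- eigen(crossprod(ctr), symmetric = TRUE)
  v <- ev$vectors[, 1L]
  if (sum(v * (pts[nrow(pts), ] - pts[1L, ])) < 0) v <- -v
  v
}

#' Transform a capture into the sperm (body-fixed) reference frame
#'
#' Per frame, translates the flagellar base (first digitized point) to the
#' origin and rotates so the best-fit direction of the proximal 10% of the
#' flagellum lies along the +x axis. The proximal flagellum proxies the head
#' axis, yielding a body-fixed frame that removes swimming translation and
#' rotation.
#'
#' @param capture a [RawCapture-class].
#' @return a [RawCapture-class] in body-fixed coordinates.
#' @export
toSpermFrame <- function(capture) {
  stopifnot(is(capture, "RawCapture"))
  frames <- lapply(capture@frames, function(f) {
    f <- sweep(f, 2L, f[1L, ])
    len <- chordLengths(f)
    total <- len[length(len)]
    if (total <= 0) stop("invalid geometry: zero-length frame")
    prox <- f[len <= 0.1 * total, , drop = FALSE]
    if (nrow(prox) < 2L) prox <- f[1:2, , drop = FALSE]
    if (max(chordLengths(prox)) < 1e-9 * total)
      stop("invalid geometry: degenerate proximal segment")
    v <- .principalDirection(prox)
    # row-vector convention: X %*% rotationMatrix(a) rotates points by -a
    f %*% rotationMatrix(atan2(v[2L], v[1L]))
  })
  RawCapture(frames, capture@timestamps, capture@swimmerID)
}

# Linear interpolation of per-gridpoint coordinates at rescaled time tq.
# X is an (arclength x frame) matrix and tvec the frame times.
.interpFrames <- function(X, tvec, tq) {
  j <- findInterval(tq, tvec, rightmost.closed = TRUE)
  j <- max(1L, min(j, length(tvec) - 1L))
  w <- (tq - tvec[j]) / (tvec[j + 1L] - tvec[j])
  (1 - w) * X[, j] + w * X[, j + 1L]
}

#' Offset of the best single beat within a rescaled record
#'
#' Finds the dimensionless offset \eqn{t^\star} at which the retained beat
#' should start: over all valid times \eqn{t} with \eqn{t + 1} inside the
#' record, the Euclidean distance between the flagellar midpoint positions at
#' \eqn{t} and \eqn{t + 1} is minimized (ties broken by the smallest t).
#' An exactly periodic record therefore yields \eqn{t^\star = 0}.
#'
#' @param X,Y arclength-by-frame coordinate matrices (any consistent units).
#' @param tvec rescaled frame times \eqn{\tilde t / T}.
#' @param candidates optional vector of candidate offsets; defaults to all
#'   frame times at least one period before the end of the record.
#' @return the offset t* (dimensionless).
#' @export
findBeatStart <- function(X, Y, tvec, candidates = NULL) {
  tmax <- tvec[length(tvec)]
  if (tmax < 1) stop("insufficient data: record spans less than one period")
  if (is.null(candidates)) candidates <- tvec[tvec + 1 <= tmax + 1e-9]
  if (length(candidates) == 0L)
    stop("insufficient data: record spans less than one period")
  mid <- as.integer(ceiling(nrow(X) / 2))
  d <- vapply(candidates, function(t0) {
    p0 <- c(.interpFrames(X[mid, , drop = FALSE], tvec, t0),
            .interpFrames(Y[mid, , drop = FALSE], tvec, t0))
    p1 <- c(.interpFrames(X[mid, , drop = FALSE], tvec, t0 + 1),
            .interpFrames(Y[mid, , drop = FALSE], tvec, t0 + 1))
    sqrt(sum((p1 - p0)^2))
  }, numeric(1))
  # smallest candidate wins among numerical ties
  candidates[which(d <= min(d) + 1e-12)[1L]]
}

#' Phase-align a normalized beat
#'
#' Circularly shifts the time grid so that the transverse displacement of the
#' flagellar midpoint, \eqn{y(s_{mid}, t)}, attains its maximum at \eqn{t=0}
#' (ties broken by the smallest index). Applying one fixed phase convention
#' to every swimmer makes beats directly comparable in phase.
#'
#' @param beat a [NormalizedBeat-class].
#' @return the phase-aligned [NormalizedBeat-class].
#' @export
alignPhase <- function(beat) {
  stopifnot(is(beat, "NormalizedBeat"))
  w <- beat@waveform
  mid <- as.integer(ceiling(nrow(w@x) / 2))
  shift <- which.max(w@y[mid, ]) - 1L
  if (shift == 0L) return(beat)
  idx <- c((shift + 1L):ncol(w@x), 1L:shift)
  beat@waveform <- CartesianWaveform(w@x[, idx], w@y[, idx],
                                     sGrid = w@sGrid, tGrid = w@tGrid)
  beat
}

# Resample a polyline so the n output points have (iteratively) equal
# successive straight-line chords, not just equal path-length spacing; the
# two differ when digitization noise makes the polyline locally wiggly.
.equalChordResample <- function(p, n, iters = 4L) {
  u <- chordLengths(p)
  keep <- c(TRUE, diff(u) > 0)
  u <- u[keep]; p <- p[keep, , drop = FALSE]
  target <- seq(0, u[length(u)], length.out = n)
  at <- function(tg) cbind(stats::approx(u, p[, 1L], xout = tg)$y,
                           stats::approx(u, p[, 2L], xout = tg)$y)
  q <- at(target)
  for (it in seq_len(iters)) {
    cc <- chordLengths(q)
    if (diff(range(diff(cc))) < 1e-4 * cc[n] / (n - 1L)) break
    target <- stats::approx(cc, target, xout = seq(0, cc[n], length.out = n))$y
    q <- at(target)
  }
  q
}

# Optional smoothing of one frame's coordinates against cumulative chord
# length, with smooth.spline smoothing parameter `spar` in (0, 1].
.smoothFrame <- function(f, spar) {
  len <- chordLengths(f)
  keep <- c(TRUE, diff(len) > 0)
  len <- len[keep]; f <- f[keep, , drop = FALSE]
  if (nrow(f) < 8L) return(f)
  cbind(stats::smooth.spline(len, f[, 1L], spar = spar)$y,
        stats::smooth.spline(len, f[, 2L], spar = spar)$y)
}

#' Normalize a raw capture into a single phase-aligned beat
#'
#' The full preprocessing pipeline. The capture is moved to the body-fixed
#' sperm frame; each frame is resampled to \code{nS} points equispaced in
#' arclength; the flagellum length \code{L} is the median over frames of the
#' digitized midline length; the beating period \code{T} comes from
#' [estimatePeriod()] applied to a material point (default the midpoint) in
#' the body frame; space is rescaled to unit length and time by the period;
#' the record is truncated to the single beat starting at the offset from
#' [findBeatStart()], discretized into \code{nT} equispaced timepoints, and
#' phase-aligned with [alignPhase()].
#'
#' @param capture a [RawCapture-class] spanning more than two beat periods.
#' @param nS,nT output grid sizes (defaults 1000 arclength points, 100
#'   timepoints).
#' @param materialPoint arclength fraction of the point used for period
#'   detection (default 0.5, the flagellar midpoint).
#' @param threshold autocorrelation peak threshold for [estimatePeriod()].
#' @param smooth optional smoothing-spline parameter in (0, 1] applied to
#'   each frame's coordinates before resampling; \code{NULL} (default) for
#'   already-smooth input.
#' @param capturedFraction recorded metadata: fraction of the true flagellum
#'   captured by the digitization (not used to reject input).
#' @return a [NormalizedBeat-class] on the \code{nS} x \code{nT} grid.
#' @export
preprocessBeat <- function(capture, nS = 1000L, nT = 100L, materialPoint = 0.5,
                           threshold = 0.5, smooth = NULL,
                           capturedFraction = NA_real_) {
  stopifnot(is(capture, "RawCapture"))
  nFrames <- length(capture@frames)
  if (nFrames < 6L) stop("insufficient data: too few frames")
  dts <- diff(capture@timestamps)
  if (diff(range(dts)) > 1e-6 * mean(dts))
    stop("frame interval must be constant")
  dt <- mean(dts)

  body <- toSpermFrame(capture)
  frames <- body@frames
  if (!is.null(smooth)) frames <- lapply(frames, .smoothFrame, spar = smooth)

  res <- lapply(frames, resampleArclength, n = nS)
  lens <- vapply(res, function(f) max(chordLengths(f)), numeric(1))
  L <- stats::median(lens)

  mpRow <- as.integer(floor(materialPoint * (nS - 1L))) + 1L
  track <- t(vapply(res, function(f) f[mpRow, ], numeric(2)))
  T <- estimatePeriod(track, dt, threshold = threshold)
  if (capture@timestamps[nFrames] <= 2 * T)
    stop("insufficient data: capture must span more than two beat periods")

  # unit-length shapes (each frame rescaled by its own digitized length,
  # appropriate for an inextensible flagellum) and rescaled time
  X <- vapply(seq_len(nFrames), function(i) res[[i]][, 1L] / lens[i], numeric(nS))
  Y <- vapply(seq_len(nFrames), function(i) res[[i]][, 2L] / lens[i], numeric(nS))
  tvec <- capture@timestamps / T

  tStar <- findBeatStart(X, Y, tvec)
  tq <- tStar + (0:(nT - 1L)) / nT
  xOut <- vapply(tq, function(t0) .interpFrames(X, tvec, t0), numeric(nS))
  yOut <- vapply(tq, function(t0) .interpFrames(Y, tvec, t0), numeric(nS))
  # final equal-chord pass: time interpolation mixes frames, so each output
  # shape is redistributed until successive chords are equal, then rescaled
  # so the chords sum to exactly one
  for (j in seq_len(nT)) {
    p <- .equalChordResample(cbind(xOut[, j], yOut[, j]), nS)
    tot <- max(chordLengths(p))
    xOut[, j] <- p[, 1L] / tot
    yOut[, j] <- p[, 2L] / tot
  }
  xOut <- sweep(xOut, 2L, xOut[1L, ])
  yOut <- sweep(yOut, 2L, yOut[1L, ])

  beat <- new("NormalizedBeat",
              waveform = CartesianWaveform(xOut, yOut),
              L = L, T = T, beatOffset = tStar, swimmerID = capture@swimmerID,
              capturedFraction = as.numeric(capturedFraction))
  alignPhase(beat)
}
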