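# Fixtures are built in code at test time; no stored data.

# A normalized beat with a prescribed tangent-angle field theta(s, t).
makeBeat <- function(thetaFun, nS = 200L, nT = 50L, L = 55, T = 0.07,
                     id = "fix") {
  s <- seq(0, 1, length.out = nS)
  t <- (seq_len(nT) - 1L) / nT
  th <- outer(s, t, thetaFun)
  w <- angleToCartesian(AngleWaveform(th))
  new("NormalizedBeat", waveform = w, L = L, T = T, beatOffset = 0,
      swimmerID = id, capturedFraction = 0.9)
}

# Traveling-wave beats with per-swimmer parameters, directly on the beat grid
# (no capture simulation); cheap population fixture.
makeWavePopulation <- function(n, nS = 120L, nT = 40L, amplitude = 0.6,
                               amplitudeCV = 0.15, asymmetry = 0.1,
                               seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    A0 <- amplitude * exp(rnorm(1, 0, amplitudeCV))
    ph <- runif(1, 0, 2 * pi)
    makeBeat(function(s, t) asymmetry + A0 * (0.5 + s) * sin(2 * pi * (t - s) + ph),
             nS = nS, nT = nT, L = 55 * exp(rnorm(1, 0, 0.04)),
             T = 0.07 * exp(rnorm(1, 0, 0.1)), id = sprintf("w%03d", i))
  })
}

# Brute-force two-sample KS p-value: enumeration over all label assignments
# of the pooled sample (values assumed distinct).
enumKS <- function(a, b) {
  z <- c(a, b)
  n <- length(a); m <- length(b)
  stat <- function(aa, bb) {
    pts <- sort(unique(c(aa, bb)))
    max(abs(vapply(pts, function(p) mean(aa <= p) - mean(bb <= p), numeric(1))))
  }
  obs <- stat(a, b)
  combos <- utils::combn(n + m, n)
  stats <- apply(combos, 2L, function(idx) stat(z[idx], z[-idx]))
  list(statistic = obs, p.value = mean(stats >= obs - 1e-12))
}

# Brute-force two-sided rank-sum p-value by enumeration (distinct values).
enumRankSum <- function(a, b) {
  z <- c(a, b)
  n <- length(a); m <- length(b)
  u <- function(aa, bb) sum(rank(c(aa, bb))[seq_along(aa)]) - n * (n + 1) / 2
  obs <- u(a, b)
  center <- n * m / 2
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2L, function(idx) u(z[idx], z[-idx]))
  list(statistic = obs,
       p.value = mean(abs(us - center) >= abs(obs - center) - 1e-12))
}

# A rank-structured Cartesian population: straight baseline plus planted
# transverse modes with prescribed coefficient patterns. Perturbations are
# small enough that the planted vectors live in valid waveform space.
plantedPopulation <- function(coefList, modesY, nS = 80L, nT = 20L) {
  s <- seq(0, 1, length.out = nS)
  lapply(coefList, function(co) {
    y <- sapply(seq_len(nT), function(j) {
      rowSums(sapply(seq_along(modesY), function(m) co[[m]][j] * modesY[[m]](s)))
    })
    CartesianWaveform(x = matrix(s, nS, nT), y = y)
  })
}
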