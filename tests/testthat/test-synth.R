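# Small model-distributed dataset of angle waveforms with physical scales.
makeDataset <- function(n, nS = 60L, nT = 20L, seed = 41L) {
  cfg <- simConfig(nSwimmers = n)
  set.seed(seed)
  waves <- lapply(seq_len(n), function(i)
    simulateThetaField(cfg, A0 = cfg$amplitude * exp(rnorm(1, 0, 0.15)),
                       theta0 = rnorm(1, 0.1, 0.02),
                       phi0 = runif(1, 0, 2 * pi), nS = nS, nT = nT))
  EmpiricalDataset(waves, lengths = 55 * exp(rnorm(n, 0, 0.04)),
                   periods = 0.07 * exp(rnorm(n, 0, 0.1)))
}

test_that("dataset assembly checks alignment and stores the exact mean", {
  ds <- makeDataset(8)
  expect_equal(ds@mu, rowMeans(ds@theta, dims = 2), tolerance = 1e-14)
  expect_error(EmpiricalDataset(list()), "non-empty")
  bad <- list(AngleWaveform(matrix(0, 60, 20)), AngleWaveform(matrix(0, 50, 20)))
  expect_error(EmpiricalDataset(bad), "common grid")
})

test_that("drawing one waveform returns it unchanged; drawing all returns the mean", {
  ds <- makeDataset(12)
  s1 <- synthesizeBeat(ds, Ns = 1, seed = 5)
  expect_equal(thetaMatrix(s1@S), ds@theta[, , s1@sourceIndices],
               tolerance = 1e-14)
  sN <- synthesizeBeat(ds, Ns = 12, seed = 6)
  expect_equal(thetaMatrix(sN@S), ds@mu, tolerance = 1e-12)
  expect_error(synthesizeBeat(ds, Ns = 0), "out of range")
  expect_error(synthesizeBeat(ds, Ns = 13), "out of range")
})

test_that("synthesis is reproducible and subset-restrictable", {
  ds <- makeDataset(10)
  a <- synthesizeBeat(ds, Ns = 4, seed = 9)
  b <- synthesizeBeat(ds, Ns = 4, seed = 9)
  expect_identical(thetaMatrix(a@S), thetaMatrix(b@S))
  expect_identical(a@sourceIndices, b@sourceIndices)
  expect_identical(c(a@L, a@T), c(b@L, b@T))

  stratum <- c(2L, 4L, 6L)
  s <- synthesizeBeat(ds, Ns = 3, seed = 10, subset = stratum)
  expect_true(all(s@sourceIndices %in% stratum))
  expect_true(s@L %in% ds@lengths[stratum])
})

test_that("synthetic beats reconstruct to unit-arclength waveforms", {
  ds <- makeDataset(10, nS = 500L)
  for (sd in 1:5) {
    sb <- synthesizeBeat(ds, Ns = 5, seed = sd)
    w <- angleToCartesian(sb@S)
    len <- colSums(sqrt(diff(xCoords(w))^2 + diff(yCoords(w))^2))
    expect_lt(max(abs(len - 1)), 1e-5)
  }
})

test_that("moment preservation holds at small scale with the fpc", {
  ds <- makeDataset(20, nS = 30L, nT = 10L)
  N <- 20
  popVar <- rowMeans(sweep(ds@theta, c(1, 2), ds@mu)^2, dims = 2)  # /N
  for (Ns in c(2L, 5L)) {
    nDraw <- 3000
    set.seed(100 + Ns)
    sum1 <- 0; sum2 <- 0
    for (d in seq_len(nDraw)) {
      S <- thetaMatrix(synthesizeBeat(ds, Ns = Ns)@S)
      sum1 <- sum1 + S; sum2 <- sum2 + S^2
    }
    mS <- sum1 / nDraw
    vS <- sum2 / nDraw - mS^2
    expVar <- popVar * (N - Ns) / (N - 1)
    # deviations are strongly correlated across grid points (one draw moves
    # the whole field), so aggregate the standardized errors
    zMean <- (mS - ds@mu) / sqrt(expVar / nDraw)
    zVar <- (vS - expVar) / (expVar * sqrt(2 / (nDraw - 1)))
    expect_lt(sqrt(mean(zMean^2)), 3)
    expect_lt(max(abs(zMean)), 5)
    expect_lt(sqrt(mean(zVar^2)), 3)
    expect_lt(max(abs(zVar)), 5)
  }
})

test_that("with-replacement draws preserve variance without the fpc", {
  ds <- makeDataset(15, nS = 20L, nT = 8L)
  popVar <- rowMeans(sweep(ds@theta, c(1, 2), ds@mu)^2, dims = 2)
  nDraw <- 3000
  set.seed(44)
  sum1 <- 0; sum2 <- 0
  for (d in seq_len(nDraw)) {
    S <- thetaMatrix(synthesizeBeat(ds, Ns = 5, replace = TRUE)@S)
    sum1 <- sum1 + S; sum2 <- sum2 + S^2
  }
  vS <- sum2 / nDraw - (sum1 / nDraw)^2
  zVar <- (vS - popVar) / (popVar * sqrt(2 / (nDraw - 1)))
  expect_lt(sqrt(mean(zVar^2)), 3)
  expect_lt(max(abs(zVar)), 5)
})

test_that("the output-space count is the exact number of non-empty subsets", {
  expect_identical(as.character(countSyntheticOutputs(0)), "0")
  expect_identical(as.character(countSyntheticOutputs(2)), "3")
  expect_identical(as.character(countSyntheticOutputs(10)), "1023")
  expect_identical(as.character(countSyntheticOutputs(30)),
                   format(2^30 - 1, scientific = FALSE))
  expect_error(countSyntheticOutputs(-1), "non-negative")

  # independent arithmetic oracle: residues of 2^n - 1 modulo small primes
  big <- countSyntheticOutputs(216)
  for (p in c(97, 101, 9973)) {
    r <- 1
    for (i in 1:216) r <- (r * 2) %% p
    expect_identical(flagellaR:::bigMod(big, p), (r - 1) %% p)
  }
})

test_that("physical rescaling is linear in length and period", {
  ds <- makeDataset(6)
  sb <- synthesizeBeat(ds, Ns = 2, seed = 3)
  phys <- toPhysical(sb)
  w <- angleToCartesian(sb@S)
  expect_equal(phys$x, xCoords(w) * sb@L, tolerance = 1e-12)
  expect_equal(max(phys$t), (1 - 1 / 20) * sb@T, tolerance = 1e-12)

  sb2 <- sb
  sb2@L <- 2 * sb@L
  expect_equal(toPhysical(sb2)$x, 2 * phys$x, tolerance = 1e-12)
})

test_that("a single-swimmer dataset round-trips to its own physical waveform", {
  cfg <- simConfig(nSwimmers = 1)
  wave <- simulateThetaField(cfg, nS = 200L, nT = 30L)
  ds <- EmpiricalDataset(list(wave), lengths = 48.5, periods = 0.065)
  sb <- synthesizeBeat(ds, Ns = 1, seed = 1)
  phys <- toPhysical(sb)
  ref <- angleToCartesian(wave)
  expect_lt(max(abs(phys$x - xCoords(ref) * 48.5)), 1e-4)
  expect_lt(max(abs(phys$y - yCoords(ref) * 48.5)), 1e-4)
})

test_that("deviation diagnostics flag a skewed population", {
  set.seed(45)
  sym <- array(rnorm(20 * 10 * 50), c(20, 10, 50))
  waves <- lapply(1:50, function(i) AngleWaveform(0.05 * sym[, , i]))
  ds <- EmpiricalDataset(waves, lengths = rep(50, 50), periods = rep(0.07, 50))
  d <- angleDeviationDiagnostics(ds)
  expect_lt(max(abs(d$skewness)), 1.5)
  skewed <- lapply(1:50, function(i) AngleWaveform(0.05 * exp(sym[, , i])))
  ds2 <- EmpiricalDataset(skewed, lengths = rep(50, 50), periods = rep(0.07, 50))
  d2 <- angleDeviationDiagnostics(ds2)
  expect_gt(mean(d2$skewness), mean(d$skewness))
})
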