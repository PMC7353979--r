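test_that("mean-coefficient sinusoid fit recovers exact parameters", {
  t <- (0:99) / 100
  fit <- fitMeanSinusoid(2 + 3 * cos(2 * pi * t - 1))
  expect_equal(fit$k, 2 * pi, tolerance = 1e-6)
  expect_equal(fit$phi, 1, tolerance = 1e-6)
  expect_equal(fit$alpha, 2, tolerance = 1e-6)
  expect_equal(fit$beta, 3, tolerance = 1e-6)
  expect_lt(fit$rms, 1e-8)

  # beta >= 0 canonicalization: a negative-amplitude wave flips the phase
  fit2 <- fitMeanSinusoid(-1.5 * cos(2 * pi * t - 1))
  expect_gte(fit2$beta, 0)
  expect_equal(fit2$beta, 1.5, tolerance = 1e-6)
  expect_equal(fit2$phi, (1 + pi) %% (2 * pi), tolerance = 1e-5)

  expect_error(fitMeanSinusoid(rep(5, 100)), "degenerate")
})

test_that("wavenumber is stable under coefficient noise", {
  t <- (0:99) / 100
  set.seed(31)
  ks <- replicate(100, fitMeanSinusoid(cos(2 * pi * t) + rnorm(100, 0, 0.05))$k)
  expect_lt(max(abs(ks - 2 * pi)) / (2 * pi), 0.05)
})

test_that("individual linear fits are exact for model-generated swimmers", {
  t <- (0:99) / 100
  k <- 2 * pi; phi <- 0.8
  c1 <- rbind(1.5 + 2.5 * cos(k * t - phi),
              rep(0.7, 100),                       # constant swimmer -> beta 0
              -0.3 + 0.1 * cos(k * t - phi))
  fit <- fitIndividualLinear(c1, k, phi)
  expect_equal(fit@perSwimmer$alpha, c(1.5, 0.7, -0.3), tolerance = 1e-10)
  expect_equal(fit@perSwimmer$beta, c(2.5, 0, 0.1), tolerance = 1e-10)
  expect_lt(max(fit@perSwimmer$rms), 1e-10)
})

test_that("OLS alpha and beta are unbiased under additive noise", {
  t <- (0:99) / 100
  k <- 2 * pi; phi <- 0.8; alpha <- 1.2; beta <- 2.0; sigma <- 0.3
  nRep <- 1000
  set.seed(32)
  C <- matrix(alpha + beta * cos(k * t - phi), nRep, 100, byrow = TRUE) +
    matrix(rnorm(nRep * 100, 0, sigma), nRep, 100)
  fit <- fitIndividualLinear(C, k, phi)
  # closed-form OLS sampling variances from the design matrix
  X <- cbind(1, cos(k * t - phi))
  V <- sigma^2 * solve(crossprod(X))
  seMean <- sqrt(diag(V) / nRep)
  expect_lt(abs(mean(fit@perSwimmer$alpha) - alpha), 3 * seMean[1])
  expect_lt(abs(mean(fit@perSwimmer$beta) - beta), 3 * seMean[2])
})

test_that("KS statistic hits its boundary cases", {
  same <- ksTwoSample(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  disjoint <- ksTwoSample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disjoint$statistic, 1)
  expect_error(ksTwoSample(numeric(0), 1:3), ">= 2")
})

test_that("exact KS p-values equal brute-force label enumeration", {
  set.seed(33)
  cases <- list(list(3, 3), list(4, 5), list(3, 7), list(5, 5))
  for (cs in cases) {
    a <- round(rnorm(cs[[1]]), 6); b <- round(rnorm(cs[[2]], 0.5), 6)
    oracle <- enumKS(a, b)
    got <- ksTwoSample(a, b)
    expect_equal(got$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(got$p.value, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("exact rank-sum p-values equal brute-force label enumeration", {
  got <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p.value, 0.1, tolerance = 1e-12)  # 2 of 20 arrangements

  set.seed(34)
  for (cs in list(c(3, 3), c(4, 4), c(5, 5), c(4, 6))) {
    a <- rnorm(cs[1]); b <- rnorm(cs[2], 1)
    oracle <- enumRankSum(a, b)
    expect_equal(wilcoxonRankSum(a, b)$p.value, oracle$p.value,
                 tolerance = 1e-12)
  }

  ident <- wilcoxonRankSum(c(1, 5, 9, 12), c(1, 5, 9, 12))
  expect_equal(ident$p.value, 1)
})

test_that("rank-sum power exceeds 0.9 for a 2-sigma shift at n = 50", {
  set.seed(35)
  rej <- replicate(500, {
    wilcoxonRankSum(rnorm(50), rnorm(50, 2))$p.value < 0.05
  })
  expect_gt(mean(rej), 0.9)
})

test_that("median-only shifts favour the rank-sum over the KS test", {
  set.seed(36)
  n <- 30; shift <- 0.6
  res <- replicate(300, {
    a <- rnorm(n); b <- rnorm(n, shift)
    c(ks = ksTwoSample(a, b)$reject, rs = wilcoxonRankSum(a, b)$reject)
  })
  expect_gte(mean(res["rs", ]), mean(res["ks", ]))
})

test_that("waveform comparison applies the both-significant conjunction", {
  t <- (0:99) / 100
  k <- 2 * pi; phi <- 0.5
  set.seed(37)
  mk <- function(alphas, betas) {
    C <- t(sapply(seq_along(alphas), function(i)
      alphas[i] + betas[i] * cos(k * t - phi) + rnorm(100, 0, 0.05)))
    fitIndividualLinear(C, k, phi)
  }
  A <- mk(rnorm(40, 1, 0.2), rnorm(40, 2, 0.3))
  Bsame <- mk(rnorm(40, 1, 0.2), rnorm(40, 2, 0.3))
  Bfar <- mk(rnorm(40, 3, 0.2), rnorm(40, 5, 0.3))

  far <- compareWaveforms(A, Bfar)
  expect_true(far$alpha$reject && far$beta$reject && far$reject)

  # identical fit objects: both marginals at p = 1, no rejection
  self <- compareWaveforms(A, A)
  expect_false(self$reject)
  expect_equal(self$alpha$p.value, 1)
  expect_equal(self$beta$p.value, 1)

  # mismatched (k, phi) is a contract violation
  wrong <- fitIndividualLinear(matrix(rnorm(200), 2), k + 0.1, phi)
  expect_error(compareWaveforms(A, wrong), "share")
})

test_that("scalar comparisons combine KS and rank-sum verdicts", {
  set.seed(38)
  a <- rnorm(40, 1, 0.1)
  res <- compareScalars(a, a + 10, level = 0.05)
  expect_true(res$ks$reject && res$ranksum$reject)
  res2 <- compareScalars(a, a, level = 0.05)
  expect_false(res2$ks$reject || res2$ranksum$reject)
  # the period convention: rank-sum at the 1% level
  res3 <- compareScalars(a, a + 10, level = 0.05, ranksumLevel = 0.01)
  expect_equal(res3$ranksum$level, 0.01)
  expect_true(res3$ranksum$reject)
})
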