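test_that("time-correlation estimate matches Pearson correlations and repairs PSD", {
  # single time point: trivially [[1]]
  y1 <- LongitudinalPhenotype(matrix(rnorm(10), 10, 1))
  expect_equal(d0Matrix(estimateTimeCorrelation(y1)), matrix(1, 1, 1))

  # perfectly correlated columns: all-ones matrix (after PSD repair)
  v <- cbind(c(1, 2, 3, 5), 2 * c(1, 2, 3, 5))
  d0 <- d0Matrix(estimateTimeCorrelation(LongitudinalPhenotype(v)))
  expect_equal(d0, matrix(1, 2, 2), tolerance = 1e-6)
  ev <- eigen(d0, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)

  # hand Pearson: covariance 1, variances 5/3 each -> r = 0.6
  v <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))
  d0 <- d0Matrix(estimateTimeCorrelation(LongitudinalPhenotype(v)))
  expect_equal(d0[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(diag(d0), c(1, 1))
})

test_that("time-correlation estimate is invariant to affine column rescaling", {
  ds <- makeDataset(n = 25, seed = 4)
  d0 <- d0Matrix(estimateTimeCorrelation(ds$pheno))
  v2 <- phenoValues(ds$pheno)
  v2[, 2] <- -3.7 * v2[, 2] + 11
  v2[, 3] <- 0.01 * v2[, 3] - 2
  d0b <- d0Matrix(estimateTimeCorrelation(LongitudinalPhenotype(v2)))
  expect_equal(abs(d0b), abs(d0), tolerance = 1e-12)
})

test_that("zero-variance phenotype column is reported by time point", {
  v <- cbind(rnorm(10), rep(2, 10))
  expect_error(estimateTimeCorrelation(
    LongitudinalPhenotype(v, timeLabels = c("t1", "t2"))), "t2")
})

test_that("inverse square root block satisfies W m W = I and matches eigen oracle", {
  expect_equal(inverseSqrtBlock(diag(3)), diag(3))
  expect_equal(inverseSqrtBlock(4 * diag(2)), 0.5 * diag(2))

  # eigenvalues 3 and 1 -> frozen 5-digit values
  w <- inverseSqrtBlock(matrix(c(2, 1, 1, 2), 2))
  expect_equal(w, matrix(c(0.78868, -0.21132, -0.21132, 0.78868), 2),
               tolerance = 1e-4)

  set.seed(2)
  a <- crossprod(matrix(rnorm(25), 5))
  w <- inverseSqrtBlock(a)
  expect_equal(w %*% a %*% w, diag(5), tolerance = 1e-10)
  expect_equal(w, t(w))

  expect_error(inverseSqrtBlock(matrix(c(1, 1, 1, 1), 2)), "eigenvalue")
})

test_that("blockwise null log-likelihood equals the dense-matrix oracle", {
  for (seed in 1:4) {
    ds <- makeDataset(n = 4 + seed, k = 2, m = 2, seed = seed)
    d0 <- estimateTimeCorrelation(ds$pheno)
    for (theta in list(c(1.3, 0.7), c(0.01, 2), c(0, 1))) {
      ll <- nullLogLikelihood(ds$pheno, ds$covars, d0, theta[1], theta[2])
      lld <- denseNullLoglik(ds$pheno, ds$covars, d0Matrix(d0),
                             theta[1], theta[2])
      expect_equal(ll, lld, tolerance = 1e-8)
    }
  }
})

test_that("log-likelihood respects the Gaussian scale family", {
  ds <- makeDataset(n = 20, seed = 7)
  d0 <- estimateTimeCorrelation(ds$pheno)
  fit <- fitNullVarianceComponents(ds$pheno, ds$covars, d0)
  z <- designMatrix(ds$covars)
  y <- as.vector(t(phenoValues(ds$pheno)))
  cc <- 2.5
  # y2 - Z a = cc * (y - Z a') under a bijective reparametrization of a,
  # so the profile log-likelihood shifts by exactly -nK log(cc)
  y2 <- cc * y + (1 - cc) * drop(z %*% alphaHat(fit))
  p2 <- LongitudinalPhenotype(matrix(y2, nrow = nSamples(ds$pheno),
                                     byrow = TRUE))
  th <- c(0.8, 1.1)
  ll1 <- nullLogLikelihood(ds$pheno, ds$covars, d0, th[1], th[2])
  ll2 <- nullLogLikelihood(p2, ds$covars, d0, cc^2 * th[1], cc^2 * th[2])
  expect_equal(ll2, ll1 - length(y) * log(cc), tolerance = 1e-8)
})

test_that("with K = 1 the likelihood depends only on the variance sum", {
  ds <- makeDataset(n = 15, k = 1, m = 2, seed = 3)
  d0 <- new("TimeCorrelation", d0 = matrix(1, 1, 1))
  l1 <- nullLogLikelihood(ds$pheno, ds$covars, d0, 0.3, 0.7)
  l2 <- nullLogLikelihood(ds$pheno, ds$covars, d0, 0.6, 0.4)
  l3 <- nullLogLikelihood(ds$pheno, ds$covars, d0, 0, 1)
  expect_equal(l1, l2, tolerance = 1e-12)
  expect_equal(l1, l3, tolerance = 1e-12)
})

test_that("variance-component MLE handles boundaries and scales equivariantly", {
  # data generated with sigma_v^2 = 0: estimate lands at/near the boundary
  ds <- makeDataset(n = 300, seed = 11, sigmaV2 = 1e-12, sigmaE2 = 1)
  d0 <- new("TimeCorrelation", d0 = compoundSymmetry(3, 0.5))
  fit <- fitNullVarianceComponents(ds$pheno, ds$covars, d0)
  expect_lt(sigmaV2(fit), 0.05)

  # doubling the residuals multiplies both components by 4 (exactly, by the
  # scale-family argument; numerically to optimizer precision)
  ds <- makeDataset(n = 100, seed = 12)
  d0 <- estimateTimeCorrelation(ds$pheno)
  fit1 <- fitNullVarianceComponents(ds$pheno, ds$covars, d0)
  z <- designMatrix(ds$covars)
  y <- as.vector(t(phenoValues(ds$pheno)))
  y2 <- 2 * y - drop(z %*% alphaHat(fit1))
  p2 <- LongitudinalPhenotype(matrix(y2, nrow = 100, byrow = TRUE))
  fit2 <- fitNullVarianceComponents(p2, ds$covars, d0)
  expect_equal(sigmaV2(fit2), 4 * sigmaV2(fit1), tolerance = 1e-3)
  expect_equal(sigmaE2(fit2), 4 * sigmaE2(fit1), tolerance = 1e-3)
})

test_that("fitted whitening block inverts the covariance block", {
  ds <- makeDataset(n = 60, seed = 5, sigmaV2 = 2, sigmaE2 = 0.5)
  fit <- fitNullVarianceComponents(ds$pheno, ds$covars)
  k <- nTimePoints(ds$pheno)
  sig <- sigmaV2(fit) * d0Matrix(fit) + sigmaE2(fit) * diag(k)
  w <- whitenBlock(fit)
  expect_lt(max(abs(w %*% sig %*% t(w) - diag(k))), 1e-10)
  expect_equal(w, t(w))
})

test_that("identifiability fallback collapses to OLS when D0 = I", {
  ds <- makeDataset(n = 40, k = 1, m = 3, seed = 8)
  fit <- fitNullVarianceComponents(ds$pheno, ds$covars)
  expect_identical(sigmaV2(fit), 0)
  z <- designMatrix(ds$covars)
  y <- as.vector(t(phenoValues(ds$pheno)))
  expect_equal(sigmaE2(fit), sum(qr.resid(qr(z), y)^2) / length(y),
               tolerance = 1e-12)
  expect_equal(alphaHat(fit), unname(drop(qr.coef(qr(z), y))),
               tolerance = 1e-10)
})

test_that("whitening applies the block to every individual identically", {
  k <- 3
  d0 <- new("TimeCorrelation", d0 = diag(k))
  mkfit <- function(se2) new("NullModelFit", sigmaV2 = 0, sigmaE2 = se2,
                             alphaHat = 0, d0 = d0,
                             whitenBlock = diag(1 / sqrt(se2), k), logLik = 0)
  x <- matrix(rnorm(30), 15, 2)  # 5 individuals x 3 time points
  expect_equal(whiten(mkfit(1), x), x)
  expect_equal(whiten(mkfit(4), x), x / 2)
  expect_error(whiten(mkfit(1), matrix(rnorm(14), 14, 1)), "divisible")
  # vector input keeps its shape
  expect_equal(whiten(mkfit(4), rnorm(6) -> yy), yy / 2)
})

test_that("whitened null residuals have near-identity covariance", {
  n <- 5000; k <- 3
  cfg <- SimulationConfig(n = n, k = k, m = 2, sigmaV2 = 1.5, sigmaE2 = 0.8,
                          rho = 0.6)
  set.seed(21)
  g <- simulateGenotypes(cfg)
  sim <- simulateLongitudinalPhenotypes(cfg, g)
  d0true <- new("TimeCorrelation", d0 = compoundSymmetry(k, 0.6))
  fit <- fitNullVarianceComponents(sim$pheno, sim$covars, d0true)
  y <- as.vector(t(phenoValues(sim$pheno)))
  z <- designMatrix(sim$covars)
  r <- whiten(fit, y) - whiten(fit, z) %*% ltow:::.glsAlpha(
    ltow:::.rotateByD0(sim$pheno, sim$covars, d0Matrix(d0true)),
    sigmaV2(fit), sigmaE2(fit))
  rmat <- matrix(r, n, k, byrow = TRUE)
  expect_lt(max(abs(cov(rmat) - diag(k))), 0.05)
})

test_that("variance-component recovery is accurate on correctly specified data", {
  # scaled-down recovery check (the full 20-seed study is in the acceptance file)
  cfg <- SimulationConfig(n = 1000, k = 3, m = 2, sigmaV2 = 2, sigmaE2 = 1,
                          rho = 0.5)
  d0 <- new("TimeCorrelation", d0 = compoundSymmetry(3, 0.5))
  est <- t(vapply(1:5, function(s) {
    set.seed(s)
    g <- simulateGenotypes(cfg)
    sim <- simulateLongitudinalPhenotypes(cfg, g)
    f <- fitNullVarianceComponents(sim$pheno, sim$covars, d0)
    c(sigmaV2(f), sigmaE2(f))
  }, numeric(2)))
  expect_equal(colMeans(est), c(2, 1), tolerance = 0.15)
})

test_that("REML criterion is accepted and close to ML on large samples", {
  ds <- makeDataset(n = 400, seed = 31, sigmaV2 = 1.2, sigmaE2 = 0.9)
  d0 <- estimateTimeCorrelation(ds$pheno)
  fml <- fitNullVarianceComponents(ds$pheno, ds$covars, d0)
  frm <- fitNullVarianceComponents(ds$pheno, ds$covars, d0, reml = TRUE)
  expect_equal(sigmaE2(frm), sigmaE2(fml), tolerance = 0.05)
  expect_equal(sigmaV2(frm), sigmaV2(fml), tolerance = 0.1)
})
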