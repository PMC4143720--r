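test_that("genotypes are Hardy-Weinberg draws on the requested MAF spectrum", {
  cfg <- SimulationConfig(n = 50, m = 10, mafRange = c(0, 0))
  set.seed(1)
  expect_true(all(dosages(simulateGenotypes(cfg)) == 0))

  cfg <- SimulationConfig(n = 200, m = 30)
  set.seed(2)
  g <- simulateGenotypes(cfg)
  expect_true(all(dosages(g) %in% c(0, 1, 2)))

  # law of large numbers at fixed MAF 0.1
  cfg <- SimulationConfig(n = 50000, m = 3, mafRange = c(0.1, 0.1))
  set.seed(3)
  g <- simulateGenotypes(cfg)
  expect_lt(max(abs(colMeans(dosages(g)) / 2 - 0.1)), 0.005)
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- SimulationConfig(n = 40, k = 3, m = 12, beta = 0.2)
  gen <- function() {
    set.seed(123)
    g <- simulateGenotypes(cfg)
    sim <- simulateLongitudinalPhenotypes(cfg, g)
    list(d = dosages(g), y = phenoValues(sim$pheno),
         z = sim$covars@covariates)
  }
  expect_identical(gen(), gen())
})

test_that("phenotypes follow the mixed model: noiseless, covariance, null independence", {
  # (near-)noiseless: y reduces to the fixed covariate part
  cfg <- SimulationConfig(n = 30, k = 3, m = 4, sigmaV2 = 0,
                          sigmaE2 = 1e-18, beta = 0)
  set.seed(4)
  g <- simulateGenotypes(cfg)
  sim <- simulateLongitudinalPhenotypes(cfg, g)
  sex <- sim$covars@covariates[, 1, 1]
  age <- sim$covars@covariates[, , 2]
  fixed <- cfg@alpha[1] + cfg@alpha[2] * sex + cfg@alpha[3] * age
  expect_equal(phenoValues(sim$pheno), fixed, tolerance = 1e-6)

  # residual K x K covariance converges to sigma_v^2 D0 + sigma_e^2 I
  cfg <- SimulationConfig(n = 20000, k = 3, m = 2, sigmaV2 = 1.5,
                          sigmaE2 = 0.7, rho = 0.4)
  set.seed(5)
  g <- simulateGenotypes(cfg)
  sim <- simulateLongitudinalPhenotypes(cfg, g)
  sex <- sim$covars@covariates[, 1, 1]
  age <- sim$covars@covariates[, , 2]
  resid <- phenoValues(sim$pheno) -
    (cfg@alpha[1] + cfg@alpha[2] * sex + cfg@alpha[3] * age)
  target <- 1.5 * compoundSymmetry(3, 0.4) + 0.7 * diag(3)
  expect_lt(max(abs(cov(resid) - target)), 0.05)

  # beta = 0: phenotype uncorrelated with the causal dosage burden
  cfg <- SimulationConfig(n = 5000, k = 2, m = 10, beta = 0)
  set.seed(6)
  g <- simulateGenotypes(cfg)
  sim <- simulateLongitudinalPhenotypes(cfg, g)
  burden <- rowSums(dosages(g))
  r <- cor(burden, rowMeans(phenoValues(sim$pheno)))
  expect_lt(abs(r), 3 / sqrt(5000))
})

test_that("simulated random-effect blocks reproduce D0 as n grows", {
  cfg <- SimulationConfig(n = 20000, k = 3, m = 2, sigmaV2 = 2,
                          sigmaE2 = 1e-18, rho = 0.6)
  set.seed(7)
  g <- simulateGenotypes(cfg)
  sim <- simulateLongitudinalPhenotypes(cfg, g)
  # with negligible error variance the phenotype correlation IS cor(v)
  d0hat <- d0Matrix(estimateTimeCorrelation(
    sim$pheno, sim$covars, adjustCovariates = TRUE))
  expect_lt(max(abs(d0hat - compoundSymmetry(3, 0.6))), 0.02)
})

test_that("the calibration harness itself is unbiased (uniform dummy test)", {
  cfg <- SimulationConfig(n = 10, k = 2, m = 2)
  out <- estimateType1Error(cfg, nDatasets = 2000, nPerm = 1,
                            alphaLevels = c(0.05, 0.2, 1), seed = 5,
                            testFun = function(ds, s) runif(1))
  expect_equal(unname(out$rates[3]), 1)  # alpha = 1 rejects everything
  expect_lt(abs(out$rates[1] - 0.05), 0.015)
  expect_lt(abs(out$rates[2] - 0.2), 0.025)
})

test_that("power collapses to size at beta 0 and saturates at huge effects", {
  # beta = 0: power approximates the nominal level
  cfg <- SimulationConfig(n = 60, k = 2, m = 10, beta = 0)
  pw0 <- estimatePower(cfg, methods = "ltow", nDatasets = 150, nPerm = 100,
                       alpha = 0.05, seed = 11)
  expect_lt(abs(pw0$power[["ltow"]] - 0.05), 0.06)

  # standardized effect >> 2: everything rejects
  cfg <- SimulationConfig(n = 100, k = 2, m = 10, beta = 1.5,
                          causalFraction = 0.5)
  pw1 <- estimatePower(cfg, nDatasets = 40, nPerm = 200, alpha = 0.05,
                       seed = 12)
  expect_true(all(pw1$power >= 0.95))
})

test_that("power is non-decreasing in the effect size", {
  betas <- c(0, 0.1, 0.25, 0.6)
  pw <- vapply(betas, function(b) {
    cfg <- SimulationConfig(n = 100, k = 3, m = 30, beta = b)
    estimatePower(cfg, methods = "ltow", nDatasets = 100, nPerm = 150,
                  alpha = 0.05, seed = 13)$power[["ltow"]]
  }, numeric(1))
  mcSlack <- 2 * sqrt(0.25 / 100)  # Monte-Carlo error at 100 replicates
  expect_true(all(diff(pw) >= -mcSlack))
})
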