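# Fixture builders shared across test files. Everything is generated in code
# under fixed seeds; no data files.

# Small balanced longitudinal dataset with sex/age covariates.
makeDataset <- function(n = 30, k = 3, m = 8, seed = 1, beta = 0,
                        sigmaV2 = 1, sigmaE2 = 1, rho = 0.5,
                        mafRange = c(0.05, 0.3)) {
  cfg <- SimulationConfig(n = n, k = k, m = m, beta = beta,
                          sigmaV2 = sigmaV2, sigmaE2 = sigmaE2, rho = rho,
                          mafRange = mafRange)
  set.seed(seed)
  g <- simulateGenotypes(cfg)
  sim <- simulateLongitudinalPhenotypes(cfg, g)
  list(cfg = cfg, geno = g, pheno = sim$pheno, covars = sim$covars,
       causal = sim$causal)
}

# Independent dense-matrix oracle for the null log-likelihood: builds the
# full nK x nK covariance, GLS-profiles alpha, and evaluates the Gaussian
# log-density directly. Never shares code with the blockwise path.
denseNullLoglik <- function(pheno, covars, d0mat, sigmaV2, sigmaE2) {
  yv <- phenoValues(pheno)
  n <- nrow(yv); k <- ncol(yv)
  y <- as.vector(t(yv))
  z <- designMatrix(covars)
  bigD <- kronecker(diag(n), d0mat)
  sig <- sigmaV2 * bigD + sigmaE2 * diag(n * k)
  sigInv <- solve(sig)
  alpha <- solve(t(z) %*% sigInv %*% z, t(z) %*% sigInv %*% y)
  r <- y - z %*% alpha
  ld <- as.numeric(determinant(sig, logarithm = TRUE)$modulus)
  -0.5 * (n * k * log(2 * pi) + ld + as.numeric(t(r) %*% sigInv %*% r))
}

# Bare ResidualizedData from explicit y* and X* (unit-level instances where
# orthogonality bookkeeping is set up by hand).
makeResid <- function(y, x) {
  x <- as.matrix(x)
  new("ResidualizedData", yStar = as.numeric(y), xStar = x,
      keptVariants = seq_len(ncol(x)), a0Diag = colSums(x^2),
      nVariants = ncol(x), variantIds = sprintf("V%d", seq_len(ncol(x))))
}

# Random already-residualized instance: intercept + one covariate projected
# out of phenotype and genotype columns through the package's own projector.
randomResidInstance <- function(n = 12, m = 3, seed = 1) {
  set.seed(seed)
  z <- cbind(1, rnorm(n))
  y <- rnorm(n)
  x <- matrix(rbinom(n * m, 2, 0.3) + 0.1 * rnorm(n * m), n, m)
  ltow:::.buildResidualized(y, z, x)
}

compoundSymmetry <- function(k, rho) {
  m <- matrix(rho, k, k)
  diag(m) <- 1
  m
}
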