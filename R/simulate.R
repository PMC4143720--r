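## Synthetic-data engine. The generative model is exactly the null/alternative
## mixed model the test assumes: y_ij = Z_ij' alpha + beta * c_i + v_ij + e_ij
## with v_i. ~ N(0, sigma_v^2 D0) per individual, e_ij iid N(0, sigma_e^2),
## and c_i a signed (optionally MAF-scaled) sum of causal dosages. Genotypes
## are independent Hardy-Weinberg variants with MAFs from a uniform spectrum.

.cfgD0 <- function(cfg) {
  k <- cfg@k
  if (nrow(cfg@d0) > 0L) {
    m <- cfg@d0
  } else {
    m <- matrix(cfg@rho, k, k)
    diag(m) <- 1
  }
  new("TimeCorrelation", d0 = m)
}

#' Simulate a region of independent Hardy-Weinberg variants
#'
#' Draws one minor-allele frequency per variant from the uniform spectrum in
#' \code{cfg}, then genotypes as \code{Binomial(2, MAF)} per individual
#' (integer dosages 0/1/2).
#'
#' @param cfg a [SimulationConfig-class].
#' @param regionLabel label for the generated region.
#' @return a [GenotypeMatrix-class]; the drawn MAFs are attached as
#'   attribute \code{"maf"} of the dosage matrix's variant order (retrieve
#'   with \code{attr(g, "maf")} on the returned object).
#' @examples
#' set.seed(1)
#' g <- simulateGenotypes(SimulationConfig(n = 50, m = 10))
#' range(dosages(g))
#' @export
simulateGenotypes <- function(cfg, regionLabel = "simulated") {
  stopifnot(is(cfg, "SimulationConfig"))
  maf <- runif(cfg@m, cfg@mafRange[1L], cfg@mafRange[2L])
  d <- matrix(rbinom(cfg@n * cfg@m, 2L, rep(maf, each = cfg@n)),
              cfg@n, cfg@m)
  g <- GenotypeMatrix(d, regionLabel = regionLabel)
  attr(g, "maf") <- maf
  g
}

#' Simulate longitudinal phenotypes and covariates under the mixed model
#'
#' Generates covariates (a binary sex-like covariate, constant over time, and
#' an age-like covariate increasing deterministically by 5 years per visit
#' from a \code{N(45, 10^2)} baseline) and phenotypes from
#' \deqn{y_{ij} = Z_{ij}^T\alpha + \beta c_i + v_{ij} + e_{ij},}
#' with per-individual random effects \eqn{v_{i\cdot} \sim N(0, \sigma_v^2
#' D_0)} and iid errors \eqn{e_{ij} \sim N(0, \sigma_e^2)}. When
#' \code{cfg@beta != 0}, a fraction \code{causalFraction} of variants (the
#' first \code{ceiling(causalFraction * m)} columns) is causal;
#' \eqn{c_i = \sum_m s_m a_m x_{im}} with signs \eqn{s_m} (a
#' \code{negativeFraction} share negative) and amplitudes \eqn{a_m = 1} or
#' \eqn{1/\sqrt{2\,\mathrm{MAF}_m(1-\mathrm{MAF}_m)}} when
#' \code{mafScaleEffects}.
#'
#' @param cfg a [SimulationConfig-class].
#' @param geno a [GenotypeMatrix-class] from [simulateGenotypes()] (or any
#'   matching genotype matrix).
#' @return list with elements \code{pheno} ([LongitudinalPhenotype-class]),
#'   \code{covars} ([CovariateDesign-class]), \code{causal} (causal variant
#'   indices) and \code{geneticValue} (\eqn{\beta c_i} per individual).
#' @export
simulateLongitudinalPhenotypes <- function(cfg, geno) {
  stopifnot(is(cfg, "SimulationConfig"), is(geno, "GenotypeMatrix"))
  n <- cfg@n; k <- cfg@k
  if (nSamples(geno) != n) stop("genotype rows do not match cfg@n")

  sex <- rbinom(n, 1L, 0.5)
  age0 <- rnorm(n, 45, 10)
  ageMat <- outer(age0, 5 * (seq_len(k) - 1L), "+")  # +5 years per visit
  covArr <- array(0, c(n, k, 2L))
  covArr[, , 1L] <- sex          # constant over time
  covArr[, , 2L] <- ageMat
  covars <- CovariateDesign(covArr, covariateNames = c("sex", "age"))

  causal <- integer(0)
  gval <- numeric(n)
  if (cfg@beta != 0 && cfg@causalFraction > 0) {
    nc <- max(1L, as.integer(ceiling(cfg@causalFraction * cfg@m)))
    causal <- seq_len(min(nc, cfg@m))
    x <- dosages(geno)[, causal, drop = FALSE]
    maf <- attr(geno, "maf")
    if (is.null(maf)) maf <- pmax(colMeans(dosages(geno)) / 2, 1e-4)
    amp <- if (cfg@mafScaleEffects)
      1 / sqrt(2 * maf[causal] * (1 - maf[causal])) else rep(1, length(causal))
    sgn <- rep(1, length(causal))
    nneg <- as.integer(floor(cfg@negativeFraction * length(causal)))
    if (nneg > 0L) sgn[seq_len(nneg)] <- -1
    gval <- cfg@beta * drop(x %*% (sgn * amp))
  }

  d0 <- d0Matrix(.cfgD0(cfg))
  ## v_i. ~ N(0, sigma_v^2 D0): n draws through the Cholesky factor
  cl <- chol(d0 + diag(1e-10, k))
  vmat <- sqrt(cfg@sigmaV2) * (matrix(rnorm(n * k), n, k) %*% cl)
  emat <- matrix(rnorm(n * k, sd = sqrt(cfg@sigmaE2)), n, k)

  fixed <- cfg@alpha[1L] + cfg@alpha[2L] * sex  # per individual
  yv <- fixed + gval + cfg@alpha[3L] * ageMat + vmat + emat

  list(pheno = LongitudinalPhenotype(yv, sampleIds = sampleIds(geno)),
       covars = covars, causal = causal, geneticValue = gval)
}

## One complete synthetic dataset (genotypes + phenotypes + covariates).
.simulateDataset <- function(cfg) {
  g <- simulateGenotypes(cfg)
  c(list(geno = g), simulateLongitudinalPhenotypes(cfg, g))
}

#' Empirical type-I error of the longitudinal test
#'
#' Generates \code{nDatasets} independent datasets under the null
#' (\eqn{\beta = 0} enforced), runs [ltowTest()] on each, and reports the
#' rejection fraction at each nominal level together with the full p-value
#' vector for uniformity checks.
#'
#' @param cfg a [SimulationConfig-class]; its \code{beta} is forced to 0.
#' @param nDatasets number of simulated datasets.
#' @param nPerm permutations per test.
#' @param alphaLevels nominal significance levels.
#' @param seed master seed (per-dataset seeds are derived from it).
#' @param testFun the test to calibrate: a \code{function(dataset, seed)}
#'   returning a p-value. The default runs [ltowTest()]. Substituting a dummy
#'   that returns \code{runif(1)} checks the harness itself (the rejection
#'   rate is then the nominal level in expectation).
#' @return list with \code{rates} (named by level), \code{pValues}, and
#'   \code{nDatasets}.
#' @export
estimateType1Error <- function(cfg, nDatasets = 1000, nPerm = 500,
                               alphaLevels = c(0.05, 0.01), seed = 1,
                               testFun = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  cfg@beta <- 0
  if (is.null(testFun))
    testFun <- function(ds, s)
      pValue(ltowTest(ds$pheno, ds$covars, ds$geno, nPerm = nPerm, seed = s))
  pv <- numeric(nDatasets)
  .withSeed(seed, {
    ## separate streams: one seed generates the data, an independent one
    ## drives the permutations, so shuffles are not coupled to the draws
    dataSeeds <- sample.int(2^31 - 1L, nDatasets)
    permSeeds <- sample.int(2^31 - 1L, nDatasets)
    for (i in seq_len(nDatasets)) {
      set.seed(dataSeeds[i])
      ds <- .simulateDataset(cfg)
      pv[i] <- testFun(ds, permSeeds[i])
    }
  })
  rates <- vapply(alphaLevels, function(a) mean(pv <= a), numeric(1))
  names(rates) <- sprintf("alpha=%g", alphaLevels)
  list(rates = rates, pValues = pv, nDatasets = nDatasets)
}

#' Empirical power comparison of the longitudinal and single-time tests
#'
#' Generates \code{nDatasets} datasets under \code{cfg} (which should carry a
#' non-zero \code{beta}) and estimates, at level \code{alpha}, the power of
#' any subset of: \code{"ltow"} (all time points jointly), \code{"tow-ave"}
#' (time-averaged phenotype), \code{"tow-k"} (each single time point), and
#' \code{"tow-single"} (the average of the per-time-point powers — the
#' conventional summary for the single-measurement baseline).
#'
#' @param cfg a [SimulationConfig-class] with \code{beta != 0} (use
#'   \code{beta = 0} to check that power collapses to the nominal size).
#' @param methods subset of \code{c("ltow", "tow-ave", "tow-k")}.
#' @param nDatasets,nPerm,alpha,seed study dimensions.
#' @return list with \code{power} (named vector; includes per-time-point
#'   entries \code{tow-t1..tK} and their average \code{tow-single} when
#'   \code{"tow-k"} is requested), \code{pValues} (dataset x method matrix)
#'   and \code{nDatasets}.
#' @export
estimatePower <- function(cfg, methods = c("ltow", "tow-ave", "tow-k"),
                          nDatasets = 500, nPerm = 500, alpha = 0.05,
                          seed = 1) {
  stopifnot(is(cfg, "SimulationConfig"))
  methods <- match.arg(methods, c("ltow", "tow-ave", "tow-k"),
                       several.ok = TRUE)
  k <- cfg@k
  cols <- c(if ("ltow" %in% methods) "ltow",
            if ("tow-ave" %in% methods) "tow-ave",
            if ("tow-k" %in% methods) sprintf("tow-t%d", seq_len(k)))
  pv <- matrix(NA_real_, nDatasets, length(cols),
               dimnames = list(NULL, cols))
  .withSeed(seed, {
    dataSeeds <- sample.int(2^31 - 1L, nDatasets)
    permSeeds <- sample.int(2^31 - 1L, nDatasets)
    for (i in seq_len(nDatasets)) {
      set.seed(dataSeeds[i])
      ds <- .simulateDataset(cfg)
      if ("ltow" %in% cols)
        pv[i, "ltow"] <- pValue(ltowTest(ds$pheno, ds$covars, ds$geno,
                                         nPerm = nPerm, seed = permSeeds[i]))
      if ("tow-ave" %in% cols)
        pv[i, "tow-ave"] <- pValue(towAverage(ds$pheno, ds$covars, ds$geno,
                                              nPerm = nPerm,
                                              seed = permSeeds[i]))
      if ("tow-k" %in% methods) {
        yv <- phenoValues(ds$pheno)
        for (j in seq_len(k)) {
          cm <- cbind(sex = ds$covars@covariates[, j, 1L],
                      age = ds$covars@covariates[, j, 2L])
          pv[i, sprintf("tow-t%d", j)] <-
            pValue(towSingle(yv[, j], cm, ds$geno, nPerm = nPerm,
                             seed = permSeeds[i]))
        }
      }
    }
  })
  power <- colMeans(pv <= alpha)
  if ("tow-k" %in% methods)
    power <- c(power,
               "tow-single" = unname(mean(power[sprintf("tow-t%d",
                                                        seq_len(k))])))
  list(power = power, pValues = pv, nDatasets = nDatasets)
}
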