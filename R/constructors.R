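#' Construct a GenotypeMatrix
#'
#' @param dosages numeric \code{n x M} matrix of minor-allele dosages in
#'   \eqn{[0, 2]}. Fractional imputed dosages are accepted verbatim.
#' @param sampleIds,variantIds optional labels; taken from dimnames or
#'   auto-generated when missing.
#' @param regionLabel region (gene) name.
#' @param flipMajor if \code{TRUE}, columns with mean dosage > 1 are flipped
#'   (\code{2 - dosage}) so that dosages count the minor allele. The statistic
#'   squares genotype-phenotype covariances, so orientation only affects the
#'   sign and interpretability of the reported weights.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' g <- GenotypeMatrix(matrix(rbinom(20, 2, 0.2), 10, 2), regionLabel = "GENE1")
#' dim(dosages(g))
#' @export
GenotypeMatrix <- function(dosages, sampleIds = NULL, variantIds = NULL,
                           regionLabel = "region", flipMajor = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(dosages))) rownames(dosages)
                 else sprintf("S%d", seq_len(nrow(dosages)))
  if (is.null(variantIds))
    variantIds <- if (!is.null(colnames(dosages))) colnames(dosages)
                  else sprintf("V%d", seq_len(ncol(dosages)))
  if (flipMajor) {
    flip <- colMeans(dosages) > 1
    dosages[, flip] <- 2 - dosages[, flip]
  }
  dimnames(dosages) <- NULL
  new("GenotypeMatrix", dosages = dosages,
      sampleIds = as.character(sampleIds),
      variantIds = as.character(variantIds),
      regionLabel = as.character(regionLabel))
}

#' Construct a LongitudinalPhenotype
#'
#' @param values numeric \code{n x K} matrix, individuals in rows, time points
#'   in columns. No missing values (use [readPhenotypesCsv()] for
#'   complete-case filtering of raw tables).
#' @param sampleIds,timeLabels optional labels.
#' @return a [LongitudinalPhenotype-class] object.
#' @examples
#' y <- LongitudinalPhenotype(matrix(rnorm(30), 10, 3))
#' nTimePoints(y)
#' @export
LongitudinalPhenotype <- function(values, sampleIds = NULL, timeLabels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(values))) rownames(values)
                 else sprintf("S%d", seq_len(nrow(values)))
  if (is.null(timeLabels))
    timeLabels <- if (!is.null(colnames(values))) colnames(values)
                  else sprintf("t%d", seq_len(ncol(values)))
  dimnames(values) <- NULL
  new("LongitudinalPhenotype", values = values,
      sampleIds = as.character(sampleIds), timeLabels = as.character(timeLabels))
}

#' Construct a CovariateDesign
#'
#' @param covariates numeric \code{n x K x P} array of covariate values, or
#'   \code{NULL} for an intercept-only design (pass \code{n} and \code{k}).
#' @param covariateNames optional covariate labels.
#' @param n,k dimensions, required when \code{covariates} is \code{NULL}.
#' @return a [CovariateDesign-class] object.
#' @examples
#' cd <- CovariateDesign(array(rnorm(60), c(10, 3, 2)))
#' dim(designMatrix(cd))
#' @export
CovariateDesign <- function(covariates = NULL, covariateNames = NULL,
                            n = NULL, k = NULL) {
  if (is.null(covariates)) {
    stopifnot(!is.null(n), !is.null(k))
    covariates <- array(numeric(0), c(as.integer(n), as.integer(k), 0L))
  }
  covariates <- as.array(covariates)
  if (length(dim(covariates)) == 2L)  # single covariate given as n x K matrix
    covariates <- array(covariates, c(dim(covariates), 1L))
  storage.mode(covariates) <- "double"
  p <- dim(covariates)[3L]
  if (is.null(covariateNames))
    covariateNames <- if (!is.null(dimnames(covariates)[[3L]])) dimnames(covariates)[[3L]]
                      else if (p) sprintf("cov%d", seq_len(p)) else character(0)
  dimnames(covariates) <- NULL
  new("CovariateDesign", covariates = covariates,
      covariateNames = as.character(covariateNames))
}

#' Construct a SimulationConfig
#'
#' Defaults describe a GAW18-scale null region: 142 individuals, 3 time
#' points, 100 variants with minor-allele frequencies uniform on
#' \eqn{[0.005, 0.05]}, compound-symmetric time correlation \eqn{\rho = 0.5},
#' variance components \eqn{\sigma_v^2 = 1}, \eqn{\sigma_e^2 = 1}, covariate
#' effects for an intercept, a binary sex-like covariate and an age-like
#' covariate increasing over visits, and no genetic effect (\eqn{\beta = 0}).
#'
#' @param n,k,m individuals, time points, variants.
#' @param mafRange uniform support for variant minor-allele frequencies.
#' @param causalFraction fraction of variants made causal when \code{beta != 0}.
#' @param beta effect magnitude on the causal dosage combination. 0 is the
#'   null; 0.12 with the other defaults is the package's standard
#'   moderate-power alternative (~50\% L-TOW power at n = 142).
#' @param negativeFraction fraction of causal variants with negative sign.
#' @param mafScaleEffects scale causal effects by
#'   \eqn{1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})}} (rarer variants, larger
#'   per-allele effects).
#' @param alpha length-3 fixed effects: intercept, sex, age (per year).
#' @param sigmaV2,sigmaE2 variance components.
#' @param rho compound-symmetry time correlation.
#' @param d0 optional explicit \code{K x K} correlation matrix.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(n = 100, k = 3, m = 20)
#' cfg
#' @export
SimulationConfig <- function(n = 142, k = 3, m = 100,
                             mafRange = c(0.005, 0.05),
                             causalFraction = 0.2, beta = 0,
                             negativeFraction = 0, mafScaleEffects = TRUE,
                             alpha = c(10, 0.5, 0.05),
                             sigmaV2 = 1, sigmaE2 = 1, rho = 0.5,
                             d0 = NULL) {
  if (is.null(d0)) d0 <- matrix(numeric(0), 0L, 0L)
  new("SimulationConfig", n = as.integer(n), k = as.integer(k),
      m = as.integer(m), mafRange = as.numeric(mafRange),
      causalFraction = as.numeric(causalFraction), beta = as.numeric(beta),
      negativeFraction = as.numeric(negativeFraction),
      mafScaleEffects = as.logical(mafScaleEffects),
      alpha = as.numeric(alpha), sigmaV2 = as.numeric(sigmaV2),
      sigmaE2 = as.numeric(sigmaE2), rho = as.numeric(rho),
      d0 = as.matrix(d0))
}
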