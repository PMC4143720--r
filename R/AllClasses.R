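#' @import methods
#' @importFrom stats cor cov optim rbinom rnorm runif sd var complete.cases
NULL

## Central containers for the longitudinal optimally-weighted association test.
## All stacked vectors/matrices use the individual-major, time-minor row order
## (y11..y1K, ..., yn1..ynK); validity methods enforce the cross-object
## sample-order contract at construction time.

#' GenotypeMatrix: dosages for one genomic region
#'
#' Holds minor-allele dosages for \code{n} individuals at \code{M} variants in
#' one region (a gene or a window). Dosages are real values in \eqn{[0, 2]}:
#' hard genotype calls are the integers 0/1/2, imputed dosages are the expected
#' minor-allele count and may be fractional.
#'
#' @slot dosages numeric \code{n x M} matrix, entries in \eqn{[0, 2]}.
#' @slot sampleIds character vector of \code{n} sample labels.
#' @slot variantIds character vector of \code{M} variant labels.
#' @slot regionLabel single character region (gene) name.
#'
#' @seealso [GenotypeMatrix()] for the user constructor.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(
    dosages = "matrix",
    sampleIds = "character",
    variantIds = "character",
    regionLabel = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  if (!is.numeric(d)) return("'dosages' must be a numeric matrix")
  if (anyNA(d)) return("'dosages' contains missing values")
  if (any(d < 0 | d > 2)) {
    bad <- which(d < 0 | d > 2, arr.ind = TRUE)[1L, ]
    return(sprintf("dosage outside [0, 2] at row %d, column %d", bad[1L], bad[2L]))
  }
  if (nrow(d) != length(object@sampleIds))
    return("length of 'sampleIds' must equal nrow(dosages)")
  if (ncol(d) != length(object@variantIds))
    return("length of 'variantIds' must equal ncol(dosages)")
  if (anyDuplicated(object@sampleIds)) return("duplicated sample ids")
  if (length(object@regionLabel) != 1L) return("'regionLabel' must be a single string")
  TRUE
})

#' LongitudinalPhenotype: one quantitative trait at K time points
#'
#' A complete-case \code{n x K} matrix of trait values, one row per individual,
#' one column per time point. Missing values are not allowed; complete-case
#' filtering happens in the reader ([readPhenotypesCsv()]).
#'
#' @slot values numeric \code{n x K} matrix of trait values.
#' @slot sampleIds character vector of \code{n} sample labels.
#' @slot timeLabels character vector of \code{K} time-point labels.
#'
#' @seealso [LongitudinalPhenotype()] for the user constructor.
#' @exportClass LongitudinalPhenotype
setClass("LongitudinalPhenotype",
  representation(
    values = "matrix",
    sampleIds = "character",
    timeLabels = "character"
  )
)

setValidity("LongitudinalPhenotype", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (anyNA(v)) return("'values' contains missing entries; apply complete-case filtering first")
  if (nrow(v) < 2L) return("need at least 2 individuals")
  if (ncol(v) < 1L) return("need at least 1 time point")
  if (nrow(v) != length(object@sampleIds))
    return("length of 'sampleIds' must equal nrow(values)")
  if (ncol(v) != length(object@timeLabels))
    return("length of 'timeLabels' must equal ncol(values)")
  if (anyDuplicated(object@sampleIds)) return("duplicated sample ids")
  TRUE
})

#' CovariateDesign: covariates per individual and time point
#'
#' An \code{n x K x P} array of covariate values (sex, age, medication, ...),
#' possibly with \code{P = 0} (intercept-only model). Covariates constant over
#' time are simply repeated across the K slices. The fixed-effect design matrix
#' \code{Z} (\code{nK x (P+1)}, leading intercept column, individual-major row
#' order) is obtained with [designMatrix()].
#'
#' @slot covariates numeric \code{n x K x P} array.
#' @slot covariateNames character vector of \code{P} covariate labels.
#'
#' @seealso [CovariateDesign()] for the user constructor.
#' @exportClass CovariateDesign
setClass("CovariateDesign",
  representation(
    covariates = "array",
    covariateNames = "character"
  )
)

setValidity("CovariateDesign", function(object) {
  a <- object@covariates
  if (length(dim(a)) != 3L) return("'covariates' must be an n x K x P array")
  if (anyNA(a)) return("'covariates' contains missing values")
  if (dim(a)[3L] != length(object@covariateNames))
    return("length of 'covariateNames' must equal dim(covariates)[3]")
  TRUE
})

#' TimeCorrelation: K x K correlation of the time-point random effect
#'
#' The working correlation matrix \eqn{D_0} of the per-individual random effect
#' across time points: symmetric, unit diagonal, positive semidefinite
#' (repaired by eigenvalue clipping if a raw sample correlation matrix is
#' indefinite). The full \eqn{nK \times nK} block-diagonal
#' \eqn{D = \mathrm{diag}(D_0, \ldots, D_0)} is implied and never materialized.
#'
#' @slot d0 numeric \code{K x K} matrix.
#'
#' @seealso [estimateTimeCorrelation()]
#' @exportClass TimeCorrelation
setClass("TimeCorrelation", representation(d0 = "matrix"))

setValidity("TimeCorrelation", function(object) {
  m <- object@d0
  if (!is.numeric(m) || nrow(m) != ncol(m)) return("'d0' must be a square numeric matrix")
  if (anyNA(m)) return("'d0' contains missing values")
  if (max(abs(m - t(m))) > 1e-8) return("'d0' must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) return("'d0' must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) return("'d0' must be positive semidefinite (apply PSD repair)")
  TRUE
})

#' NullModelFit: variance components fitted under the no-association null
#'
#' Maximum-likelihood fit of the null mixed model
#' \eqn{y = Z\alpha + v + e}, \eqn{v \sim N(0, \sigma_v^2 D)},
#' \eqn{e \sim N(0, \sigma_e^2 I)}, together with the \code{K x K} whitening
#' block \eqn{(\hat\sigma_v^2 D_0 + \hat\sigma_e^2 I)^{-1/2}} applied
#' per-individual by [whiten()].
#'
#' @slot sigmaV2 fitted \eqn{\hat\sigma_v^2} (\eqn{\ge 0}).
#' @slot sigmaE2 fitted \eqn{\hat\sigma_e^2} (\eqn{> 0}).
#' @slot alphaHat generalized-least-squares \eqn{\hat\alpha} at the optimum.
#' @slot d0 the [TimeCorrelation-class] used in the fit.
#' @slot whitenBlock symmetric \code{K x K} inverse square root of
#'   \eqn{\hat\sigma_v^2 D_0 + \hat\sigma_e^2 I_K}.
#' @slot logLik maximized null log-likelihood.
#'
#' @seealso [fitNullVarianceComponents()]
#' @exportClass NullModelFit
setClass("NullModelFit",
  representation(
    sigmaV2 = "numeric",
    sigmaE2 = "numeric",
    alphaHat = "numeric",
    d0 = "TimeCorrelation",
    whitenBlock = "matrix",
    logLik = "numeric"
  )
)

setValidity("NullModelFit", function(object) {
  if (length(object@sigmaV2) != 1L || object@sigmaV2 < 0)
    return("'sigmaV2' must be a single value >= 0")
  if (length(object@sigmaE2) != 1L || object@sigmaE2 <= 0)
    return("'sigmaE2' must be a single value > 0")
  k <- nrow(object@d0@d0)
  w <- object@whitenBlock
  if (nrow(w) != k || ncol(w) != k) return("'whitenBlock' must be K x K")
  if (max(abs(w - t(w))) > 1e-8) return("'whitenBlock' must be symmetric")
  sigma <- object@sigmaV2 * object@d0@d0 + object@sigmaE2 * diag(k)
  if (max(abs(w %*% sigma %*% w - diag(k))) > 1e-6)
    return("'whitenBlock' is not the inverse square root of the fitted covariance block")
  TRUE
})

#' ResidualizedData: whitened, covariate-residualized phenotype and genotypes
#'
#' The quantities the optimally weighted statistic is computed from:
#' \eqn{y^*} (whitened phenotype residualized against the whitened covariate
#' design) and \eqn{X^*} (each whitened, expanded variant column residualized
#' the same way). Variants whose residual column is numerically zero
#' (monomorphic or fully explained by covariates) are dropped and recorded.
#'
#' @slot yStar numeric \code{nK}-vector \eqn{y^*}.
#' @slot xStar numeric \code{nK x M'} matrix of kept residual variant columns.
#' @slot keptVariants integer indices (into the original M columns) of kept variants.
#' @slot a0Diag numeric vector of \eqn{X_m^{*T} X_m^*} for kept variants.
#' @slot nVariants original number of variants M.
#' @slot variantIds character labels of the original M variants.
#'
#' @seealso [residualizeRegion()], [ltowStatistic()]
#' @exportClass ResidualizedData
setClass("ResidualizedData",
  representation(
    yStar = "numeric",
    xStar = "matrix",
    keptVariants = "integer",
    a0Diag = "numeric",
    nVariants = "integer",
    variantIds = "character"
  )
)

setValidity("ResidualizedData", function(object) {
  if (ncol(object@xStar) != length(object@keptVariants))
    return("ncol(xStar) must equal length(keptVariants)")
  if (length(object@a0Diag) != length(object@keptVariants))
    return("length(a0Diag) must equal length(keptVariants)")
  if (nrow(object@xStar) != length(object@yStar))
    return("nrow(xStar) must equal length(yStar)")
  if (length(object@keptVariants) && any(object@a0Diag <= 0))
    return("'a0Diag' must be positive for kept variants")
  if (any(object@keptVariants > object@nVariants))
    return("'keptVariants' indices exceed nVariants")
  TRUE
})

#' RegionTestResult: one region-level association test
#'
#' @slot statistic the observed statistic (\eqn{T_{L-TOW}} or single-time TOW).
#' @slot pValue permutation p-value, in \eqn{(0, 1]}, add-one convention.
#' @slot nPermutations number of permutations B.
#' @slot weights length-M optimal weight vector \eqn{w^o} (0 for dropped variants).
#' @slot nVariantsTested number of variants entering the statistic.
#' @slot nVariantsDropped number of monomorphic/fully-explained variants dropped.
#' @slot seed RNG seed used for the permutations.
#' @slot regionLabel region (gene) name.
#' @slot method one of \code{"ltow"}, \code{"tow-single"}, \code{"tow-ave"}.
#'
#' @seealso [ltowTest()], [towSingle()]
#' @exportClass RegionTestResult
setClass("RegionTestResult",
  representation(
    statistic = "numeric",
    pValue = "numeric",
    nPermutations = "integer",
    weights = "numeric",
    nVariantsTested = "integer",
    nVariantsDropped = "integer",
    seed = "integer",
    regionLabel = "character",
    method = "character"
  )
)

setValidity("RegionTestResult", function(object) {
  if (object@statistic < -1e-12) return("'statistic' must be non-negative")
  b <- object@nPermutations
  if (object@pValue <= 0 || object@pValue > 1) return("'pValue' must lie in (0, 1]")
  if (object@pValue < 1 / (b + 1) - 1e-12)
    return("'pValue' below the permutation floor 1/(B+1)")
  TRUE
})

#' SimulationConfig: generative model for synthetic studies
#'
#' Describes one synthetic study condition: cohort size, number of time points
#' and variants, the minor-allele-frequency spectrum, which variants are causal
#' and with what effects, covariate fixed effects, variance components and the
#' between-time-point correlation structure. Defaults mirror a GAW18-scale null
#' region: n = 142 individuals, K = 3 time points, M = 100 variants.
#'
#' @slot n integer, number of individuals.
#' @slot k integer, number of time points.
#' @slot m integer, number of variants in the region.
#' @slot mafRange numeric length-2, uniform support for minor-allele frequencies.
#' @slot causalFraction fraction of variants carrying an effect.
#' @slot beta common effect magnitude applied to the causal dosage combination.
#' @slot negativeFraction fraction of causal variants with a negative sign.
#' @slot mafScaleEffects logical; scale each causal effect by
#'   \eqn{1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})}} so rarer variants carry
#'   larger per-allele effects.
#' @slot alpha fixed effects (intercept, sex, age) of the covariate model.
#' @slot sigmaV2,sigmaE2 variance components of the random effect and error.
#' @slot rho compound-symmetry correlation used when \code{d0} is not given.
#' @slot d0 explicit \code{K x K} correlation matrix (overrides \code{rho})
#'   or a 0 x 0 matrix to use compound symmetry.
#'
#' @seealso [SimulationConfig()], [simulateGenotypes()],
#'   [simulateLongitudinalPhenotypes()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    n = "integer",
    k = "integer",
    m = "integer",
    mafRange = "numeric",
    causalFraction = "numeric",
    beta = "numeric",
    negativeFraction = "numeric",
    mafScaleEffects = "logical",
    alpha = "numeric",
    sigmaV2 = "numeric",
    sigmaE2 = "numeric",
    rho = "numeric",
    d0 = "matrix"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@n < 2L) return("'n' must be >= 2")
  if (object@k < 1L) return("'k' must be >= 1")
  if (object@m < 1L) return("'m' must be >= 1")
  mr <- object@mafRange
  if (length(mr) != 2L || mr[1L] > mr[2L] || mr[1L] < 0 || mr[2L] > 0.5)
    return("'mafRange' must be an increasing pair within [0, 0.5]")
  if (object@causalFraction < 0 || object@causalFraction > 1)
    return("'causalFraction' must lie in [0, 1]")
  if (object@negativeFraction < 0 || object@negativeFraction > 1)
    return("'negativeFraction' must lie in [0, 1]")
  if (object@sigmaV2 < 0) return("'sigmaV2' must be >= 0")
  if (object@sigmaE2 <= 0) return("'sigmaE2' must be > 0")
  if (abs(object@rho) > 1) return("'rho' must lie in [-1, 1]")
  if (nrow(object@d0) > 0L && nrow(object@d0) != object@k)
    return("explicit 'd0' must be K x K")
  if (length(object@alpha) != 3L)
    return("'alpha' must be length 3: intercept, sex effect, age effect")
  TRUE
})
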