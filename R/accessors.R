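## Generics and accessors. Slots are never reached into from user code.

#' @name ltow-accessors
#' @title Accessors for ltow containers
#' @description Small accessor generics for the package's S4 containers.
#' @param object an ltow S4 object.
#' @return the requested component.
#' @examples
#' y <- LongitudinalPhenotype(matrix(rnorm(12), 4, 3))
#' nSamples(y); nTimePoints(y)
NULL

#' @rdname ltow-accessors
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))
#' @rdname ltow-accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(object) object@dosages)

#' @rdname ltow-accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname ltow-accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(object) object@sampleIds)
#' @rdname ltow-accessors
#' @export
setMethod("sampleIds", "LongitudinalPhenotype", function(object) object@sampleIds)

#' @rdname ltow-accessors
#' @export
setGeneric("variantIds", function(object) standardGeneric("variantIds"))
#' @rdname ltow-accessors
#' @export
setMethod("variantIds", "GenotypeMatrix", function(object) object@variantIds)

#' @rdname ltow-accessors
#' @export
setGeneric("regionLabel", function(object) standardGeneric("regionLabel"))
#' @rdname ltow-accessors
#' @export
setMethod("regionLabel", "GenotypeMatrix", function(object) object@regionLabel)
#' @rdname ltow-accessors
#' @export
setMethod("regionLabel", "RegionTestResult", function(object) object@regionLabel)

#' @rdname ltow-accessors
#' @export
setGeneric("phenoValues", function(object) standardGeneric("phenoValues"))
#' @rdname ltow-accessors
#' @export
setMethod("phenoValues", "LongitudinalPhenotype", function(object) object@values)

#' @rdname ltow-accessors
#' @export
setGeneric("timeLabels", function(object) standardGeneric("timeLabels"))
#' @rdname ltow-accessors
#' @export
setMethod("timeLabels", "LongitudinalPhenotype", function(object) object@timeLabels)

#' @rdname ltow-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname ltow-accessors
#' @export
setMethod("nSamples", "LongitudinalPhenotype", function(object) nrow(object@values))
#' @rdname ltow-accessors
#' @export
setMethod("nSamples", "GenotypeMatrix", function(object) nrow(object@dosages))
#' @rdname ltow-accessors
#' @export
setMethod("nSamples", "CovariateDesign", function(object) dim(object@covariates)[1L])

#' @rdname ltow-accessors
#' @export
setGeneric("nTimePoints", function(object) standardGeneric("nTimePoints"))
#' @rdname ltow-accessors
#' @export
setMethod("nTimePoints", "LongitudinalPhenotype", function(object) ncol(object@values))
#' @rdname ltow-accessors
#' @export
setMethod("nTimePoints", "CovariateDesign", function(object) dim(object@covariates)[2L])

#' @rdname ltow-accessors
#' @export
setGeneric("nVariants", function(object) standardGeneric("nVariants"))
#' @rdname ltow-accessors
#' @export
setMethod("nVariants", "GenotypeMatrix", function(object) ncol(object@dosages))

#' @rdname ltow-accessors
#' @export
setGeneric("covariateNames", function(object) standardGeneric("covariateNames"))
#' @rdname ltow-accessors
#' @export
setMethod("covariateNames", "CovariateDesign", function(object) object@covariateNames)

#' Expand a covariate design into the fixed-effect matrix Z
#'
#' Builds the \code{nK x (P+1)} design matrix with a leading intercept column,
#' rows stacked individual-major, time-minor (\eqn{y_{11}, \ldots, y_{1K},
#' \ldots, y_{n1}, \ldots, y_{nK}}).
#'
#' @param object a [CovariateDesign-class].
#' @return numeric \code{nK x (P+1)} matrix.
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @rdname designMatrix
#' @export
setMethod("designMatrix", "CovariateDesign", function(object) {
  dm <- dim(object@covariates)
  n <- dm[1L]; k <- dm[2L]; p <- dm[3L]
  z <- matrix(1, n * k, p + 1L)
  if (p) {
    # covariates[i, j, p] -> row (i-1)K + j: transpose the n x K slice
    for (q in seq_len(p))
      z[, q + 1L] <- as.vector(t(object@covariates[, , q, drop = TRUE]))
  }
  colnames(z) <- c("(Intercept)", object@covariateNames)
  z
})

#' @rdname ltow-accessors
#' @export
setGeneric("d0Matrix", function(object) standardGeneric("d0Matrix"))
#' @rdname ltow-accessors
#' @export
setMethod("d0Matrix", "TimeCorrelation", function(object) object@d0)
#' @rdname ltow-accessors
#' @export
setMethod("d0Matrix", "NullModelFit", function(object) object@d0@d0)

#' @rdname ltow-accessors
#' @export
setGeneric("sigmaV2", function(object) standardGeneric("sigmaV2"))
#' @rdname ltow-accessors
#' @export
setMethod("sigmaV2", "NullModelFit", function(object) object@sigmaV2)

#' @rdname ltow-accessors
#' @export
setGeneric("sigmaE2", function(object) standardGeneric("sigmaE2"))
#' @rdname ltow-accessors
#' @export
setMethod("sigmaE2", "NullModelFit", function(object) object@sigmaE2)

#' @rdname ltow-accessors
#' @export
setGeneric("alphaHat", function(object) standardGeneric("alphaHat"))
#' @rdname ltow-accessors
#' @export
setMethod("alphaHat", "NullModelFit", function(object) object@alphaHat)

#' @rdname ltow-accessors
#' @export
setGeneric("whitenBlock", function(object) standardGeneric("whitenBlock"))
#' @rdname ltow-accessors
#' @export
setMethod("whitenBlock", "NullModelFit", function(object) object@whitenBlock)

#' @rdname ltow-accessors
#' @export
setGeneric("nullLogLik", function(object) standardGeneric("nullLogLik"))
#' @rdname ltow-accessors
#' @export
setMethod("nullLogLik", "NullModelFit", function(object) object@logLik)

#' @rdname ltow-accessors
#' @export
setGeneric("yStar", function(object) standardGeneric("yStar"))
#' @rdname ltow-accessors
#' @export
setMethod("yStar", "ResidualizedData", function(object) object@yStar)

#' @rdname ltow-accessors
#' @export
setGeneric("xStar", function(object) standardGeneric("xStar"))
#' @rdname ltow-accessors
#' @export
setMethod("xStar", "ResidualizedData", function(object) object@xStar)

#' @rdname ltow-accessors
#' @export
setGeneric("keptVariants", function(object) standardGeneric("keptVariants"))
#' @rdname ltow-accessors
#' @export
setMethod("keptVariants", "ResidualizedData", function(object) object@keptVariants)

#' @rdname ltow-accessors
#' @export
setGeneric("a0Diag", function(object) standardGeneric("a0Diag"))
#' @rdname ltow-accessors
#' @export
setMethod("a0Diag", "ResidualizedData", function(object) object@a0Diag)

#' @rdname ltow-accessors
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))
#' @rdname ltow-accessors
#' @export
setMethod("statistic", "RegionTestResult", function(object) object@statistic)

#' @rdname ltow-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname ltow-accessors
#' @export
setMethod("pValue", "RegionTestResult", function(object) object@pValue)

#' @rdname ltow-accessors
#' @export
setGeneric("weights", function(object) standardGeneric("weights"))
#' @rdname ltow-accessors
#' @export
setMethod("weights", "RegionTestResult", function(object) object@weights)

#' @rdname ltow-accessors
#' @export
setGeneric("nPermutations", function(object) standardGeneric("nPermutations"))
#' @rdname ltow-accessors
#' @export
setMethod("nPermutations", "RegionTestResult", function(object) object@nPermutations)

## show methods -------------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix '%s': %d samples x %d variants\n",
              object@regionLabel, nrow(object@dosages), ncol(object@dosages)))
  mafs <- colMeans(object@dosages) / 2
  cat(sprintf("  allele frequency range: [%.4g, %.4g]\n",
              min(mafs), max(mafs)))
})

setMethod("show", "LongitudinalPhenotype", function(object) {
  cat(sprintf("LongitudinalPhenotype: %d samples x %d time points (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(object@timeLabels, collapse = ", ")))
})

setMethod("show", "CovariateDesign", function(object) {
  dm <- dim(object@covariates)
  cat(sprintf("CovariateDesign: %d samples x %d time points, %d covariate(s)%s\n",
              dm[1L], dm[2L], dm[3L],
              if (dm[3L]) paste0(" [", paste(object@covariateNames, collapse = ", "), "]")
              else ""))
})

setMethod("show", "TimeCorrelation", function(object) {
  cat(sprintf("TimeCorrelation (K = %d):\n", nrow(object@d0)))
  print(round(object@d0, 4))
})

setMethod("show", "NullModelFit", function(object) {
  cat("Null mixed-model fit (ML)\n")
  cat(sprintf("  sigma_v^2 = %.6g, sigma_e^2 = %.6g\n",
              object@sigmaV2, object@sigmaE2))
  cat(sprintf("  logLik = %.4f, K = %d\n", object@logLik, nrow(object@whitenBlock)))
})

setMethod("show", "ResidualizedData", function(object) {
  cat(sprintf("ResidualizedData: %d observations, %d/%d variants kept\n",
              length(object@yStar), length(object@keptVariants),
              object@nVariants))
})

setMethod("show", "RegionTestResult", function(object) {
  cat(sprintf("%s test of region '%s'\n", toupper(object@method),
              object@regionLabel))
  cat(sprintf("  statistic = %.6g, p = %.4g (%d permutations, seed %d)\n",
              object@statistic, object@pValue, object@nPermutations,
              object@seed))
  cat(sprintf("  variants: %d tested, %d dropped\n",
              object@nVariantsTested, object@nVariantsDropped))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: n = %d, K = %d, M = %d\n",
              object@n, object@k, object@m))
  cat(sprintf("  MAF ~ U(%.4g, %.4g); beta = %.3g (causal fraction %.2f)\n",
              object@mafRange[1L], object@mafRange[2L], object@beta,
              object@causalFraction))
  cat(sprintf("  sigma_v^2 = %.3g, sigma_e^2 = %.3g, rho = %.2f\n",
              object@sigmaV2, object@sigmaE2, object@rho))
})
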