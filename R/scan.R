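## Per-region scan driver. Each region gets its own RNG seed derived from the
## master seed and the region label, so results do not depend on the order in
## which regions are scanned.

#' RegionDefinition: a named subset of variants
#'
#' @slot label region (gene) name.
#' @slot variants character variant ids (resolved against the dosage file's
#'   header) or integer column indices.
#' @seealso [runRegionScan()]
#' @exportClass RegionDefinition
setClass("RegionDefinition",
  representation(label = "character", variants = "ANY"))

setValidity("RegionDefinition", function(object) {
  if (length(object@label) != 1L) return("'label' must be a single string")
  if (length(object@variants) < 1L) return("a region needs at least one variant")
  if (!is.character(object@variants) && !is.numeric(object@variants))
    return("'variants' must be variant ids or column indices")
  TRUE
})

#' @rdname RegionDefinition-class
#' @param label region name.
#' @param variants variant ids (character) or column indices (integer).
#' @return a \code{RegionDefinition}.
#' @export
RegionDefinition <- function(label, variants) {
  new("RegionDefinition", label = as.character(label), variants = variants)
}

setMethod("show", "RegionDefinition", function(object) {
  cat(sprintf("RegionDefinition '%s': %d variant(s)\n", object@label,
              length(object@variants)))
})

#' Derive a reproducible per-region seed
#'
#' Combines the master seed with a polynomial hash of the region label, so a
#' region's result is identical whether it is tested alone or inside a scan,
#' and independent of scan order.
#'
#' @param masterSeed integer master seed.
#' @param label region label.
#' @return a positive integer seed below \eqn{2^{31}}.
#' @export
regionSeed <- function(masterSeed, label) {
  h <- 0
  for (code in utf8ToInt(as.character(label)))
    h <- (h * 31 + code) %% 2147480009
  as.integer((as.numeric(masterSeed) %% 2147480009 + h) %% 2147480009 + 1)
}

.resolveRegion <- function(geno, region) {
  v <- region@variants
  idx <- if (is.character(v)) match(v, variantIds(geno)) else as.integer(v)
  if (anyNA(idx) || any(idx < 1L) || any(idx > nVariants(geno)))
    stop(sprintf("region '%s': unresolvable variant(s): %s", region@label,
                 paste(v[is.na(match(if (is.character(v)) v else idx,
                                     if (is.character(v)) variantIds(geno)
                                     else seq_len(nVariants(geno))))],
                       collapse = ", ")))
  GenotypeMatrix(dosages(geno)[, idx, drop = FALSE],
                 sampleIds = sampleIds(geno),
                 variantIds = variantIds(geno)[idx],
                 regionLabel = region@label)
}

#' Scan a list of regions for association
#'
#' Runs one association test per region and collects the results in a data
#' frame. Inputs may be file paths (read with [readDosageCsv()] /
#' [readPhenotypesCsv()]) or in-memory objects. Per-region failures are
#' caught, reported as a warning, and leave an \code{NA} row; the scan
#' continues.
#'
#' @param geno a [GenotypeMatrix-class] holding all candidate variants, or a
#'   dosage CSV path.
#' @param pheno a [LongitudinalPhenotype-class] or a phenotype CSV path.
#' @param covars a [CovariateDesign-class]; ignored (taken from the file)
#'   when \code{pheno} is a path.
#' @param regions list of [RegionDefinition-class]; \code{NULL} tests all
#'   variants as one region.
#' @param method \code{"ltow"}, \code{"tow-single"} or \code{"tow-ave"}.
#' @param timePoint time point used by \code{"tow-single"}.
#' @param nPerm permutations per region.
#' @param seed master seed; per-region seeds come from [regionSeed()].
#' @param bonferroni add a Bonferroni-adjusted p-value column.
#' @param phenoName phenotype column prefix when reading from file.
#' @return \code{data.frame} with one row per region: \code{region},
#'   \code{method}, \code{statistic}, \code{p_value}, variant counts,
#'   \code{seed} and \code{runtime_s}.
#' @export
runRegionScan <- function(geno, pheno, covars = NULL, regions = NULL,
                          method = c("ltow", "tow-single", "tow-ave"),
                          timePoint = 1L, nPerm = 1000, seed = 1,
                          bonferroni = FALSE, phenoName = "y") {
  method <- match.arg(method)
  if (is.character(geno)) geno <- readDosageCsv(geno)
  if (is.character(pheno)) {
    pc <- readPhenotypesCsv(pheno, phenoName = phenoName)
    pheno <- pc$pheno
    covars <- pc$covars
    keep <- match(sampleIds(pheno), sampleIds(geno))
    if (anyNA(keep))
      stop("phenotype samples missing from the dosage file")
    geno <- GenotypeMatrix(dosages(geno)[keep, , drop = FALSE],
                           sampleIds = sampleIds(pheno),
                           variantIds = variantIds(geno),
                           regionLabel = regionLabel(geno))
  }
  if (is.null(covars))
    covars <- CovariateDesign(n = nSamples(pheno), k = nTimePoints(pheno))
  if (is.null(regions))
    regions <- list(RegionDefinition(regionLabel(geno),
                                     variantIds(geno)))

  emptyScan <- data.frame(region = character(0), method = character(0),
                          statistic = numeric(0), p_value = numeric(0),
                          n_variants_tested = integer(0),
                          n_variants_dropped = integer(0), seed = integer(0),
                          runtime_s = numeric(0))
  if (!length(regions)) {
    if (bonferroni) emptyScan$p_bonferroni <- numeric(0)
    return(emptyScan)
  }

  rows <- lapply(regions, function(rg) {
    rseed <- regionSeed(seed, rg@label)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      sub <- .resolveRegion(geno, rg)
      switch(method,
        "ltow" = ltowTest(pheno, covars, sub, nPerm = nPerm, seed = rseed),
        "tow-single" = {
          j <- as.integer(timePoint)
          if (j < 1L || j > nTimePoints(pheno))
            stop(sprintf("timePoint %d outside 1..%d", j, nTimePoints(pheno)))
          p <- dim(covars@covariates)[3L]
          cm <- if (p) {
            m <- matrix(covars@covariates[, j, ], ncol = p)
            colnames(m) <- covariateNames(covars)
            m
          } else NULL
          towSingle(phenoValues(pheno)[, j], cm, sub, nPerm = nPerm,
                    seed = rseed)
        },
        "tow-ave" = towAverage(pheno, covars, sub, nPerm = nPerm,
                               seed = rseed))
    }, error = function(e) {
      warning(sprintf("region '%s' failed: %s", rg@label, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    dt <- proc.time()[["elapsed"]] - t0
    if (is.null(res))
      data.frame(region = rg@label, method = method, statistic = NA_real_,
                 p_value = NA_real_, n_variants_tested = NA_integer_,
                 n_variants_dropped = NA_integer_, seed = rseed,
                 runtime_s = dt)
    else
      data.frame(region = rg@label, method = method,
                 statistic = statistic(res), p_value = pValue(res),
                 n_variants_tested = res@nVariantsTested,
                 n_variants_dropped = res@nVariantsDropped, seed = rseed,
                 runtime_s = dt)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (bonferroni)
    out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}
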