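## The optimally weighted region statistic and its permutation null.
##
## After whitening and covariate residualization the statistic for one region
## is T = sum_m (y*' X_m*)^2 / (X_m*' X_m*), the maximum over weight vectors w
## of the score-type ratio T0(w) = (w' X*' y*)^2 / (w' A0 w) with A0 the
## diagonal of X*'X*. Significance comes from element-wise permutation of y*.

.V_TOL <- 1e-10  # residual sum-of-squares below this drops a variant

#' Expand per-individual dosages to the stacked longitudinal layout
#'
#' Repeats each individual's dosage row \code{k} times so genotype columns
#' align with the individual-major, time-minor stacking of the phenotype
#' vector: \eqn{X_m = (x_{1m}, \ldots, x_{1m}, \cdots, x_{nm}, \ldots,
#' x_{nm})^T}.
#'
#' @param geno a [GenotypeMatrix-class] (or plain \code{n x M} matrix).
#' @param k number of time points.
#' @return numeric \code{nK x M} matrix.
#' @examples
#' g <- GenotypeMatrix(matrix(c(1, 2), 2, 1))
#' expandGenotypes(g, 3)  # column (1,1,1,2,2,2)
#' @export
expandGenotypes <- function(geno, k) {
  x <- if (is(geno, "GenotypeMatrix")) dosages(geno) else as.matrix(geno)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (k == 1L) return(x)
  x[rep(seq_len(nrow(x)), each = k), , drop = FALSE]
}

#' Residualize columns against a design matrix
#'
#' Projects each column of \code{x} onto the orthogonal complement of the
#' column span of \code{zT}: \code{(I - Z(Z'Z)^{-1}Z') x}, via QR. Idempotent;
#' the output is orthogonal to every column of \code{zT}.
#'
#' @param x numeric vector or \code{nK x C} matrix.
#' @param zT design matrix (\code{nK x (P+1)}), full column rank.
#' @return residuals, same shape as \code{x}.
#' @examples
#' z <- cbind(1, c(0, 1, 2))
#' residualize(c(1, 2, 4), z)  # (1/6, -1/3, 1/6)
#' @export
residualize <- function(x, zT) {
  zT <- as.matrix(zT)
  qz <- qr(zT)
  if (qz$rank < ncol(zT)) {
    bad <- qz$pivot[seq.int(qz$rank + 1L, ncol(zT))]
    nm <- colnames(zT)
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(if (is.null(nm)) bad else nm[bad], collapse = ", ")))
  }
  vec <- is.null(dim(x))
  out <- qr.resid(qz, as.matrix(x))
  if (vec) drop(out) else out
}

## Assemble a ResidualizedData from already-whitened stacked pieces.
.buildResidualized <- function(yT, zT, xT, variantIds = NULL) {
  yStar <- residualize(yT, zT)
  xAll <- residualize(xT, zT)
  a0 <- colSums(xAll^2)
  kept <- which(a0 > .V_TOL)
  m <- ncol(xT)
  if (is.null(variantIds)) variantIds <- sprintf("V%d", seq_len(m))
  new("ResidualizedData", yStar = as.numeric(yStar),
      xStar = xAll[, kept, drop = FALSE], keptVariants = as.integer(kept),
      a0Diag = a0[kept], nVariants = as.integer(m),
      variantIds = as.character(variantIds))
}

#' Whiten and residualize one region
#'
#' Convenience constructor of [ResidualizedData-class]: whitens the stacked
#' phenotype, covariate design and expanded genotype columns with a fitted
#' null model, then residualizes phenotype and genotypes against the whitened
#' design. Monomorphic or fully covariate-explained variants (residual sum of
#' squares \eqn{\le} \code{1e-10}) are dropped and recorded.
#'
#' @param pheno a [LongitudinalPhenotype-class].
#' @param covars a [CovariateDesign-class].
#' @param geno a [GenotypeMatrix-class].
#' @param fit a [NullModelFit-class]; fitted from \code{pheno}/\code{covars}
#'   when \code{NULL}.
#' @return a [ResidualizedData-class].
#' @export
residualizeRegion <- function(pheno, covars, geno, fit = NULL) {
  stopifnot(is(pheno, "LongitudinalPhenotype"), is(covars, "CovariateDesign"),
            is(geno, "GenotypeMatrix"))
  if (!identical(sampleIds(pheno), sampleIds(geno)))
    stop("sample ids of phenotype and genotypes do not match (same order required)")
  if (is.null(fit)) fit <- fitNullVarianceComponents(pheno, covars)
  k <- nTimePoints(pheno)
  y <- as.vector(t(phenoValues(pheno)))
  z <- designMatrix(covars)
  x <- expandGenotypes(geno, k)
  .buildResidualized(whiten(fit, y), whiten(fit, z), whiten(fit, x),
                     variantIds(geno))
}

#' Optimal variant weights
#'
#' The weight vector maximizing the score-type ratio \eqn{T_0(w)}:
#' \eqn{w^o = A_0^{-1} X^{*T} y^*}, i.e. per variant
#' \eqn{w_m = (X_m^{*T} y^*) / (X_m^{*T} X_m^*)}. Dropped variants get
#' weight 0.
#'
#' @param resid a [ResidualizedData-class].
#' @return numeric length-M weight vector (original variant order).
#' @export
optimalWeights <- function(resid) {
  stopifnot(is(resid, "ResidualizedData"))
  if (length(keptVariants(resid)) == 0L)
    stop("no polymorphic variants after residualization")
  w <- numeric(resid@nVariants)
  w[keptVariants(resid)] <-
    drop(crossprod(xStar(resid), yStar(resid))) / a0Diag(resid)
  w
}

#' Score-type ratio statistic at a given weight vector
#'
#' \eqn{T_0(w) = (w^T X^{*T} y^*)^2 / (w^T A_0 w)} with
#' \eqn{A_0 = \mathrm{diag}(X_m^{*T} X_m^*)}. Invariant to rescaling of
#' \code{w}; maximized (over all \code{w}) by the optimal weights, where it
#' equals [ltowStatistic()].
#'
#' @param w numeric weight vector, length M (original variant order) or
#'   length equal to the number of kept variants.
#' @param resid a [ResidualizedData-class].
#' @return the statistic value.
#' @export
t0Statistic <- function(w, resid) {
  stopifnot(is(resid, "ResidualizedData"))
  kept <- keptVariants(resid)
  if (length(w) == resid@nVariants) w <- w[kept]
  else if (length(w) != length(kept))
    stop("'w' must have length M or length(keptVariants)")
  denom <- sum(w^2 * a0Diag(resid))
  if (denom <= 0) stop("w' A0 w must be positive")
  num <- drop(crossprod(w, crossprod(xStar(resid), yStar(resid))))
  num^2 / denom
}

#' The optimally weighted region statistic
#'
#' \eqn{T = y^{*T} X^* A_0^{-1} X^{*T} y^* = \sum_m (y^{*T} X_m^*)^2 /
#' (X_m^{*T} X_m^*)} over kept variants — the maximum of [t0Statistic()]
#' over weight vectors, attained at [optimalWeights()].
#'
#' @param resid a [ResidualizedData-class].
#' @return the statistic (non-negative).
#' @export
ltowStatistic <- function(resid) {
  stopifnot(is(resid, "ResidualizedData"))
  if (length(keptVariants(resid)) == 0L)
    stop("no polymorphic variants after residualization")
  ct <- drop(crossprod(xStar(resid), yStar(resid)))
  sum(ct^2 / a0Diag(resid))
}

## Evaluate the statistic for a batch of permuted phenotype residuals.
## yPerm: nK x B matrix of shuffled y* columns. One GEMM per batch.
.permStatistics <- function(resid, yPerm) {
  ct <- crossprod(xStar(resid), yPerm)          # M' x B
  colSums(ct^2 / a0Diag(resid))
}

## Run a function with a private, reproducible RNG stream, restoring the
## caller's stream afterwards (bit-reproducible results given `seed`).
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(expr)
}

#' Permutation p-value of the optimally weighted statistic
#'
#' Builds the permutation null by shuffling the entries of \eqn{y^*} uniformly
#' at random (the whitened, residualized observations are exchangeable under
#' the fitted null) while \eqn{X^*} and the fitted projector stay fixed, and
#' recomputing the statistic each time. The p-value uses the add-one
#' convention \eqn{p = (1 + \#\{T_b \ge T_{obs}\}) / (B + 1)}, so it is never
#' zero and never below \eqn{1/(B+1)}.
#'
#' With \code{blockPermute = TRUE}, whole individuals (blocks of \code{k}
#' consecutive entries) are permuted instead — a conservative alternative when
#' the whitening model may be misspecified.
#'
#' @param resid a [ResidualizedData-class].
#' @param nPerm number of permutations B.
#' @param seed integer RNG seed; results are reproducible given the seed.
#' @param blockPermute permute K-blocks (individuals) instead of elements.
#' @param k block size, required when \code{blockPermute = TRUE}.
#' @param regionLabel,method bookkeeping carried into the result.
#' @return a [RegionTestResult-class].
#' @export
permutationPvalue <- function(resid, nPerm = 1000, seed = 1,
                              blockPermute = FALSE, k = NULL,
                              regionLabel = "region", method = "ltow") {
  stopifnot(is(resid, "ResidualizedData"), nPerm >= 1)
  nPerm <- as.integer(nPerm)
  tObs <- ltowStatistic(resid)
  w <- optimalWeights(resid)
  ys <- yStar(resid)
  nk <- length(ys)
  if (blockPermute) {
    if (is.null(k)) stop("'k' is required for block permutation")
    k <- as.integer(k)
    if (nk %% k != 0L) stop("length of y* not divisible by block size 'k'")
    n <- nk %/% k
  }

  count <- 0L
  .withSeed(seed, {
    batch <- max(1L, min(nPerm, as.integer(ceiling(2e6 / nk))))
    done <- 0L
    while (done < nPerm) {
      b <- min(batch, nPerm - done)
      idx <- if (blockPermute)
        vapply(seq_len(b), function(i)
          rep((sample.int(n) - 1L) * k, each = k) + seq_len(k), integer(nk))
      else
        vapply(seq_len(b), function(i) sample.int(nk), integer(nk))
      yPerm <- matrix(ys[idx], nk, b)
      count <- count + sum(.permStatistics(resid, yPerm) >= tObs - 1e-12)
      done <- done + b
    }
  })

  new("RegionTestResult", statistic = tObs,
      pValue = (1 + count) / (nPerm + 1), nPermutations = nPerm,
      weights = w, nVariantsTested = length(keptVariants(resid)),
      nVariantsDropped = resid@nVariants - length(keptVariants(resid)),
      seed = as.integer(seed), regionLabel = as.character(regionLabel),
      method = method)
}

#' Region-based association test for a longitudinal phenotype (L-TOW)
#'
#' The full pipeline for one genomic region: estimate the between-time-point
#' correlation \eqn{D_0}, fit the null variance components by ML, whiten the
#' phenotype, covariates and expanded genotype dosages with
#' \eqn{\hat\Sigma^{-1/2}}, residualize against the whitened covariate design,
#' and evaluate the optimally weighted statistic by permutation of \eqn{y^*}.
#' \eqn{\hat\Sigma}, \eqn{\hat\alpha} and the projector are computed once from
#' the observed data and held fixed across permutations.
#'
#' @param pheno a [LongitudinalPhenotype-class] (\code{n x K}).
#' @param covars a [CovariateDesign-class]; intercept-only when \code{NULL}.
#' @param geno a [GenotypeMatrix-class] with matching sample order.
#' @param nPerm number of permutations.
#' @param seed integer RNG seed.
#' @param d0 optional pre-computed [TimeCorrelation-class].
#' @param adjustCovariates estimate \eqn{D_0} from covariate-adjusted
#'   residuals instead of raw phenotype columns.
#' @param blockPermute permute individuals (K-blocks) instead of elements.
#' @param reml use REML instead of ML for the variance components.
#' @return a [RegionTestResult-class].
#' @examples
#' cfg <- SimulationConfig(n = 80, k = 3, m = 10)
#' set.seed(7)
#' g <- simulateGenotypes(cfg)
#' sim <- simulateLongitudinalPhenotypes(cfg, g)
#' ltowTest(sim$pheno, sim$covars, g, nPerm = 200, seed = 42)
#' @export
ltowTest <- function(pheno, covars = NULL, geno, nPerm = 1000, seed = 1,
                     d0 = NULL, adjustCovariates = FALSE,
                     blockPermute = FALSE, reml = FALSE) {
  stopifnot(is(pheno, "LongitudinalPhenotype"), is(geno, "GenotypeMatrix"))
  if (is.null(covars))
    covars <- CovariateDesign(n = nSamples(pheno), k = nTimePoints(pheno))
  if (is.null(d0))
    d0 <- estimateTimeCorrelation(pheno, covars,
                                  adjustCovariates = adjustCovariates)
  fit <- fitNullVarianceComponents(pheno, covars, d0, reml = reml)
  resid <- residualizeRegion(pheno, covars, geno, fit)
  permutationPvalue(resid, nPerm = nPerm, seed = seed,
                    blockPermute = blockPermute, k = nTimePoints(pheno),
                    regionLabel = regionLabel(geno), method = "ltow")
}

#' Single-time-point TOW baseline
#'
#' The test of the optimally weighted combination of variants for a phenotype
#' measured once: ordinary-least-squares covariate residualization (no
#' between-time-point structure, \eqn{\sigma_v^2 = 0}; residuals are scaled
#' by \eqn{1/\hat\sigma_e} so the pipeline is the exact \code{K = 1} special
#' case of [ltowTest()] — the scaling is constant across permutations and
#' leaves the p-value untouched), then the same optimally weighted statistic
#' and permutation scheme.
#'
#' @param y numeric length-n phenotype vector (one time point).
#' @param covars covariates for that time point: a \code{n x P} numeric
#'   matrix (an intercept is added; constant columns are dropped), a
#'   \code{K = 1} [CovariateDesign-class], or \code{NULL}.
#' @param geno a [GenotypeMatrix-class].
#' @param nPerm,seed as in [ltowTest()].
#' @param method label stored in the result (\code{"tow-single"} or
#'   \code{"tow-ave"}).
#' @return a [RegionTestResult-class].
#' @export
towSingle <- function(y, covars = NULL, geno, nPerm = 1000, seed = 1,
                      method = "tow-single") {
  stopifnot(is(geno, "GenotypeMatrix"))
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(covars)) {
    cd <- CovariateDesign(n = n, k = 1L)
  } else if (is(covars, "CovariateDesign")) {
    if (nTimePoints(covars) != 1L)
      stop("'covars' must have a single time point for towSingle")
    cd <- covars
  } else {
    cm <- as.matrix(covars)
    keep <- apply(cm, 2L, function(col) sd(col) > 0)  # intercept added below
    cm <- cm[, keep, drop = FALSE]
    cd <- CovariateDesign(array(cm, c(n, 1L, ncol(cm))),
                          covariateNames = colnames(cm))
  }
  pheno <- LongitudinalPhenotype(matrix(y, ncol = 1L),
                                 sampleIds = sampleIds(geno))
  fit <- fitNullVarianceComponents(pheno, cd)
  resid <- residualizeRegion(pheno, cd, geno, fit)
  res <- permutationPvalue(resid, nPerm = nPerm, seed = seed,
                           regionLabel = regionLabel(geno), method = method)
  res
}

#' TOW on the time-averaged phenotype (TOW-Ave)
#'
#' Averages the phenotype (and any time-varying covariates) over the K time
#' points and runs the single-time-point test on the averages.
#'
#' @param pheno a [LongitudinalPhenotype-class].
#' @param covars a [CovariateDesign-class] or \code{NULL}.
#' @param geno a [GenotypeMatrix-class].
#' @param nPerm,seed as in [ltowTest()].
#' @return a [RegionTestResult-class].
#' @export
towAverage <- function(pheno, covars = NULL, geno, nPerm = 1000, seed = 1) {
  stopifnot(is(pheno, "LongitudinalPhenotype"))
  yAve <- rowMeans(phenoValues(pheno))
  cm <- NULL
  if (!is.null(covars) && dim(covars@covariates)[3L] > 0L) {
    cm <- apply(covars@covariates, c(1L, 3L), mean)
    colnames(cm) <- covariateNames(covars)
  }
  towSingle(yAve, cm, geno, nPerm = nPerm, seed = seed, method = "tow-ave")
}
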