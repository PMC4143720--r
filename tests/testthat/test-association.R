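test_that("genotype expansion repeats each individual K times", {
  g <- GenotypeMatrix(matrix(c(1, 2, 0, 1), 2, 2))
  expect_identical(expandGenotypes(g, 1), dosages(g))
  x3 <- expandGenotypes(g, 3)
  expect_equal(x3[, 1], c(1, 1, 1, 2, 2, 2))
  expect_equal(colSums(x3), 3 * colSums(dosages(g)))
})

test_that("residualization is the orthogonal projection off the design", {
  z <- cbind(1, c(0, 1, 2))
  # hand OLS: slope 3/2, intercept 5/6 -> residuals (1/6, -1/3, 1/6)
  expect_equal(residualize(c(1, 2, 4), z), c(1 / 6, -1 / 3, 1 / 6),
               tolerance = 1e-12)

  set.seed(5)
  zz <- cbind(1, rnorm(10), rnorm(10))
  x <- matrix(rnorm(30), 10, 3)
  r <- residualize(x, zz)
  expect_lt(max(abs(crossprod(zz, r))), 1e-10)      # orthogonality
  expect_equal(residualize(r, zz), r, tolerance = 1e-10)  # idempotent
  expect_equal(drop(residualize(zz %*% c(1, 2, 3), zz)),
               rep(0, 10), tolerance = 1e-10)       # kernel
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  z <- cbind(a = rep(1, 6), b = rnorm(6))
  z <- cbind(z, c = 2 * z[, "b"])
  expect_error(residualize(rnorm(6), z), "c")
})

test_that("optimal weights are the per-variant regression coefficients", {
  # no signal: y* orthogonal to every column
  x <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  y <- c(1, 1, 2, 2)
  expect_equal(optimalWeights(makeResid(y, x)), c(0, 0))

  # forced arithmetic: X'X = 2, X'y = 4 -> w = 2
  x1 <- matrix(c(1, 1, 0, 0), 4, 1)  # X'X = 2
  y1 <- c(2, 2, 5, -5)               # X'y = 4
  expect_equal(optimalWeights(makeResid(y1, x1)), 2)

  # general: w_m = (X_m' y) / (X_m' X_m)
  set.seed(3)
  inst <- randomResidInstance(n = 15, m = 4, seed = 3)
  w <- optimalWeights(inst)
  manual <- drop(crossprod(xStar(inst), yStar(inst))) / a0Diag(inst)
  expect_equal(w[keptVariants(inst)], manual, tolerance = 1e-12)
})

test_that("weight direction matches a numerical maximizer of the ratio", {
  inst <- randomResidInstance(n = 12, m = 3, seed = 42)
  wo <- optimalWeights(inst)[keptVariants(inst)]
  best <- -Inf; wbest <- NULL
  set.seed(99)
  for (s in 1:10) {
    opt <- optim(rnorm(length(wo)), function(w) {
      d <- sum(w^2 * a0Diag(inst))
      if (d < 1e-12) return(1e10)
      -t0Statistic(w, inst)
    }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
    if (-opt$value > best) { best <- -opt$value; wbest <- opt$par }
  }
  cosine <- abs(sum(wbest * wo)) / sqrt(sum(wbest^2) * sum(wo^2))
  expect_gt(cosine, 0.999)   # T0 is scale-invariant: direction is identified
  expect_equal(best, ltowStatistic(inst), tolerance = 1e-6)
})

test_that("the statistic equals the quadratic form and maximizes the ratio", {
  inst <- randomResidInstance(n = 20, m = 5, seed = 7)
  tObs <- ltowStatistic(inst)
  expect_gte(tObs, 0)

  # second formula path: quadratic form y*' X* A0^-1 X*' y*
  a0inv <- diag(1 / a0Diag(inst), length(a0Diag(inst)))
  quad <- drop(t(yStar(inst)) %*% xStar(inst) %*% a0inv %*%
                 t(xStar(inst)) %*% yStar(inst))
  expect_equal(tObs, quad, tolerance = 1e-10)

  # equals the ratio at the optimal weights; dominates random directions
  expect_equal(t0Statistic(optimalWeights(inst), inst), tObs,
               tolerance = 1e-10)
  set.seed(11)
  for (i in 1:200)
    expect_lte(t0Statistic(rnorm(5), inst), tObs + 1e-10)

  # scale invariance of the ratio
  w <- rnorm(5)
  expect_equal(t0Statistic(3.7 * w, inst), t0Statistic(w, inst),
               tolerance = 1e-12)
  expect_error(t0Statistic(rep(0, 5), inst), "positive")
})

test_that("degenerate statistics: orthogonal and self-regression cases", {
  x <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  expect_equal(ltowStatistic(makeResid(c(1, 1, 2, 2), x)), 0)
  y <- c(0.5, -1, 2, 0.3)
  expect_equal(ltowStatistic(makeResid(y, matrix(y))), sum(y^2),
               tolerance = 1e-12)
})

test_that("permutation p-values are reproducible, floored and tie-safe", {
  inst <- randomResidInstance(n = 18, m = 3, seed = 13)
  r1 <- permutationPvalue(inst, nPerm = 300, seed = 17)
  r2 <- permutationPvalue(inst, nPerm = 300, seed = 17)
  expect_identical(pValue(r1), pValue(r2))
  expect_gte(pValue(r1), 1 / 301)

  # constant y*: every shuffle reproduces the same vector -> p = 1
  const <- makeResid(rep(2, 6), matrix(c(1, 0, 1, 2, 0, 1)))
  expect_equal(pValue(permutationPvalue(const, nPerm = 50, seed = 1)), 1)
})

test_that("block permutation mode permutes whole individuals", {
  ds <- makeDataset(n = 25, seed = 19)
  fit <- fitNullVarianceComponents(ds$pheno, ds$covars)
  inst <- residualizeRegion(ds$pheno, ds$covars, ds$geno, fit)
  rb <- permutationPvalue(inst, nPerm = 200, seed = 3, blockPermute = TRUE,
                          k = 3)
  expect_gte(pValue(rb), 1 / 201)
  expect_error(permutationPvalue(inst, nPerm = 10, blockPermute = TRUE),
               "'k'")
})

test_that("residualized region data satisfy the orthogonality contract", {
  ds <- makeDataset(n = 40, m = 10, seed = 23)
  fit <- fitNullVarianceComponents(ds$pheno, ds$covars)
  inst <- residualizeRegion(ds$pheno, ds$covars, ds$geno, fit)
  zT <- whiten(fit, designMatrix(ds$covars))
  expect_lt(max(abs(crossprod(zT, yStar(inst)))), 1e-8)
  expect_lt(max(abs(crossprod(zT, xStar(inst)))), 1e-8)
  expect_true(all(a0Diag(inst) > 0))
})

test_that("monomorphic variants are dropped with zero weights", {
  ds <- makeDataset(n = 30, m = 4, seed = 29)
  d <- dosages(ds$geno)
  d[, 2] <- 0  # monomorphic column
  g <- GenotypeMatrix(d, sampleIds = sampleIds(ds$geno))
  res <- ltowTest(ds$pheno, ds$covars, g, nPerm = 100, seed = 1)
  expect_identical(res@nVariantsDropped, 1L)
  expect_identical(weights(res)[2], 0)
  expect_identical(res@nVariantsTested, 3L)
})

test_that("a fully monomorphic region is rejected with a clear error", {
  ds <- makeDataset(n = 20, m = 2, seed = 31)
  g <- GenotypeMatrix(matrix(0, 20, 2), sampleIds = sampleIds(ds$geno))
  expect_error(ltowTest(ds$pheno, ds$covars, g, nPerm = 50, seed = 1),
               "no polymorphic variants")
})

test_that("on K = 1 data the longitudinal test reduces exactly to TOW", {
  ds <- makeDataset(n = 60, k = 1, m = 6, seed = 37)
  y <- phenoValues(ds$pheno)[, 1]
  cm <- cbind(sex = ds$covars@covariates[, 1, 1],
              age = ds$covars@covariates[, 1, 2])
  a <- ltowTest(ds$pheno, ds$covars, ds$geno, nPerm = 400, seed = 5)
  b <- towSingle(y, cm, ds$geno, nPerm = 400, seed = 5)
  expect_identical(statistic(a), statistic(b))
  expect_identical(pValue(a), pValue(b))
  expect_identical(weights(a), weights(b))
})

test_that("a strong persistent effect is detected", {
  ds <- makeDataset(n = 142, m = 20, seed = 41, beta = 0.5)
  res <- ltowTest(ds$pheno, ds$covars, ds$geno, nPerm = 1000, seed = 9)
  expect_lte(pValue(res), 0.01)
})

test_that("the statistic is invariant to relabeling individuals", {
  ds <- makeDataset(n = 35, m = 6, seed = 43)
  r1 <- ltowTest(ds$pheno, ds$covars, ds$geno, nPerm = 50, seed = 2)
  set.seed(77)
  perm <- sample(35)
  p2 <- LongitudinalPhenotype(phenoValues(ds$pheno)[perm, ],
                              sampleIds = sampleIds(ds$pheno)[perm])
  c2 <- CovariateDesign(ds$covars@covariates[perm, , , drop = FALSE],
                        covariateNames = covariateNames(ds$covars))
  g2 <- GenotypeMatrix(dosages(ds$geno)[perm, ],
                       sampleIds = sampleIds(ds$geno)[perm])
  r2 <- ltowTest(p2, c2, g2, nPerm = 50, seed = 2)
  expect_equal(statistic(r2), statistic(r1), tolerance = 1e-9)
})

test_that("single-time TOW is location invariant and powers the averaged variant", {
  ds <- makeDataset(n = 50, k = 3, m = 5, seed = 47)
  y1 <- phenoValues(ds$pheno)[, 1]
  cm <- cbind(sex = ds$covars@covariates[, 1, 1],
              age = ds$covars@covariates[, 1, 2])
  a <- towSingle(y1, cm, ds$geno, nPerm = 200, seed = 4)
  b <- towSingle(y1 + 100, cm, ds$geno, nPerm = 200, seed = 4)
  expect_equal(statistic(a), statistic(b), tolerance = 1e-9)
  expect_identical(pValue(a), pValue(b))

  # TOW-Ave is TOW on the per-individual time average
  ave <- towAverage(ds$pheno, ds$covars, ds$geno, nPerm = 200, seed = 4)
  cmAve <- cbind(sex = apply(ds$covars@covariates[, , 1], 1, mean),
                 age = apply(ds$covars@covariates[, , 2], 1, mean))
  direct <- towSingle(rowMeans(phenoValues(ds$pheno)), cmAve, ds$geno,
                      nPerm = 200, seed = 4)
  expect_identical(statistic(ave), statistic(direct))
  expect_identical(pValue(ave), pValue(direct))
})
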