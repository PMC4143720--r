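## Null mixed model for a longitudinal quantitative trait:
##   y = Z alpha + v + e,  v ~ N(0, sigma_v^2 D),  e ~ N(0, sigma_e^2 I),
## with D = blockdiag(D0, ..., D0). All likelihood work is done blockwise via
## one K x K eigendecomposition of D0; the nK x nK covariance is never formed.

## Apply a K x K matrix to every K-block of a stacked (individual-major)
## vector or matrix. Column-major layout makes this a single GEMM.
.blockMultiply <- function(w, x) {
  x <- as.matrix(x)
  k <- nrow(w)
  if (nrow(x) %% k != 0L)
    stop(sprintf("row count %d not divisible by block size K = %d", nrow(x), k))
  matrix(w %*% matrix(x, nrow = k), nrow(x), ncol(x))
}

#' Estimate the between-time-point correlation matrix D0
#'
#' Estimates the working correlation \eqn{D_0} of the time-point random effect
#' by the pairwise Pearson sample correlations of the phenotype columns. The
#' result is repaired to positive semidefiniteness by clipping eigenvalues
#' below \code{1e-8}, reconstructing, and renormalizing the diagonal to 1.
#'
#' By default the raw phenotype columns are used. With
#' \code{adjustCovariates = TRUE}, per-observation covariate effects are first
#' removed by ordinary least squares and the residual columns are correlated
#' instead; this can matter when a covariate trends strongly over visits.
#'
#' @param pheno a [LongitudinalPhenotype-class].
#' @param covars a [CovariateDesign-class]; only used when
#'   \code{adjustCovariates = TRUE}.
#' @param adjustCovariates correlate covariate-adjusted residuals instead of
#'   raw phenotype values.
#' @return a [TimeCorrelation-class] (\code{K x K}, unit diagonal).
#' @examples
#' y <- LongitudinalPhenotype(matrix(rnorm(60), 20, 3))
#' estimateTimeCorrelation(y)
#' @export
estimateTimeCorrelation <- function(pheno, covars = NULL,
                                    adjustCovariates = FALSE) {
  stopifnot(is(pheno, "LongitudinalPhenotype"))
  v <- phenoValues(pheno)
  n <- nrow(v); k <- ncol(v)
  if (k == 1L)
    return(new("TimeCorrelation", d0 = matrix(1, 1, 1)))
  if (n < 3L)
    stop("need at least 3 individuals to estimate time-point correlations")
  if (adjustCovariates) {
    if (is.null(covars)) stop("'covars' required when adjustCovariates = TRUE")
    z <- designMatrix(covars)
    r <- qr.resid(qr(z), as.vector(t(v)))
    v <- matrix(r, n, k, byrow = TRUE)
  }
  sds <- apply(v, 2L, sd)
  if (any(sds == 0))
    stop(sprintf("phenotype has zero variance at time point %s",
                 paste(timeLabels(pheno)[sds == 0], collapse = ", ")))
  d0 <- cor(v)
  ## PSD repair: clip, reconstruct, rescale to a correlation matrix
  ev <- eigen(d0, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    d0 <- ev$vectors %*% (vals * t(ev$vectors))
    d0 <- d0 / sqrt(diag(d0) %o% diag(d0))
  }
  d0 <- (d0 + t(d0)) / 2
  diag(d0) <- 1
  dimnames(d0) <- NULL
  new("TimeCorrelation", d0 = d0)
}

#' Symmetric inverse square root of a K x K positive-definite matrix
#'
#' Returns the symmetric \code{W} with \code{W \%*\% m \%*\% W = I}, computed
#' by symmetric eigendecomposition. Used to build the per-individual whitening
#' block of the fitted null covariance.
#'
#' @param m symmetric positive-definite matrix.
#' @param tol eigenvalues at or below \code{tol} raise an error.
#' @return symmetric matrix of the same dimension.
#' @examples
#' inverseSqrtBlock(4 * diag(2))  # 0.5 * I
#' @export
inverseSqrtBlock <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("'m' must be a symmetric square matrix")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(ev$values) <= tol)
    stop(sprintf("matrix not positive definite: smallest eigenvalue %.3g <= tolerance %.3g",
                 min(ev$values), tol))
  w <- ev$vectors %*% ((1 / sqrt(ev$values)) * t(ev$vectors))
  (w + t(w)) / 2
}

## Shared machinery: eigen-transform of the data by the eigenvectors of D0.
## In the rotated basis the K x K block covariance is diagonal with entries
## d_j = sigma_v^2 * lambda_j + sigma_e^2, so GLS reduces to weighted OLS.
.rotateByD0 <- function(pheno, covars, d0mat) {
  v <- phenoValues(pheno)
  n <- nrow(v); k <- ncol(v)
  z <- designMatrix(covars)
  if (nrow(z) != n * k)
    stop("covariate design rows do not match n * K of the phenotype")
  y <- as.vector(t(v))  # individual-major stacking
  ed <- eigen((d0mat + t(d0mat)) / 2, symmetric = TRUE)
  list(
    n = n, k = k, lambda = ed$values, u = ed$vectors,
    yTil = .blockMultiply(t(ed$vectors), y),
    zTil = .blockMultiply(t(ed$vectors), z)
  )
}

## Profile log-likelihood in the rotated basis (alpha profiled out by GLS).
## Returns -Inf outside the admissible region instead of erroring so the
## optimizer can probe freely.
.profileLoglik <- function(rot, sigmaV2, sigmaE2, reml = FALSE) {
  d <- sigmaV2 * rot$lambda + sigmaE2
  if (any(d <= 0)) return(-Inf)
  wts <- rep(1 / d, rot$n)  # rotated obs are j-within-i, so weights recycle
  sw <- sqrt(wts)
  zw <- rot$zTil * sw
  yw <- rot$yTil * sw
  xtx <- crossprod(zw)
  ch <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, forwardsolve(t(ch), crossprod(zw, yw)))
  rss <- sum((yw - zw %*% alpha)^2)
  nk <- rot$n * rot$k
  ll <- -0.5 * (nk * log(2 * pi) + rot$n * sum(log(d)) + rss)
  if (reml) ll <- ll - sum(log(diag(ch)))  # -0.5 log|Z' Sigma^-1 Z|
  ll
}

.glsAlpha <- function(rot, sigmaV2, sigmaE2) {
  d <- sigmaV2 * rot$lambda + sigmaE2
  wts <- rep(1 / d, rot$n)
  sw <- sqrt(wts)
  zw <- rot$zTil * sw
  yw <- rot$yTil * sw
  drop(solve(crossprod(zw), crossprod(zw, yw)))
}

#' Null log-likelihood of the longitudinal mixed model
#'
#' Profile log-likelihood of \eqn{y \sim N(Z\alpha,\; \sigma_v^2 D +
#' \sigma_e^2 I)} under no genetic effect, with \eqn{\alpha} profiled out by
#' generalized least squares. Computed blockwise from one \code{K x K}
#' eigendecomposition reused across the \code{n} individuals; the
#' \code{nK x nK} covariance is never formed.
#'
#' @param pheno a [LongitudinalPhenotype-class].
#' @param covars a [CovariateDesign-class].
#' @param d0 a [TimeCorrelation-class].
#' @param sigmaV2 random-effect variance, \eqn{\ge 0}.
#' @param sigmaE2 error variance, \eqn{> 0}.
#' @param reml if \code{TRUE}, the restricted (REML) criterion.
#' @return the log-likelihood (a single number).
#' @export
nullLogLikelihood <- function(pheno, covars, d0, sigmaV2, sigmaE2,
                              reml = FALSE) {
  stopifnot(is(pheno, "LongitudinalPhenotype"), is(covars, "CovariateDesign"),
            is(d0, "TimeCorrelation"))
  if (sigmaV2 < 0) stop("'sigmaV2' must be >= 0")
  if (sigmaE2 <= 0) stop("'sigmaE2' must be > 0")
  rot <- .rotateByD0(pheno, covars, d0Matrix(d0))
  dvals <- sigmaV2 * rot$lambda + sigmaE2
  if (min(dvals) <= 1e-12 * max(dvals))
    stop("sigma_v^2 * D0 + sigma_e^2 * I is numerically singular")
  ll <- .profileLoglik(rot, sigmaV2, sigmaE2, reml = reml)
  if (!is.finite(ll)) stop("log-likelihood not finite at the given variance components")
  ll
}

#' Fit the null variance components by maximum likelihood
#'
#' Maximizes the \eqn{\alpha}-profiled null likelihood over
#' \eqn{(\sigma_v^2, \sigma_e^2) \in [0,\infty) \times (0,\infty)} with a
#' bounded quasi-Newton search (multi-start: method-of-moments initials and a
#' pure-error start). When \code{K = 1} or \eqn{D_0} is numerically the
#' identity the two components are confounded; the fit then collapses to
#' ordinary least squares with \eqn{\sigma_v^2 = 0}.
#'
#' @param pheno a [LongitudinalPhenotype-class].
#' @param covars a [CovariateDesign-class].
#' @param d0 a [TimeCorrelation-class]; estimated from \code{pheno} when
#'   \code{NULL}.
#' @param reml use the restricted-likelihood criterion instead of plain ML.
#' @return a [NullModelFit-class] carrying \eqn{\hat\sigma_v^2,
#'   \hat\sigma_e^2, \hat\alpha}, the whitening block
#'   \eqn{(\hat\sigma_v^2 D_0 + \hat\sigma_e^2 I)^{-1/2}} and the maximized
#'   criterion.
#' @examples
#' cfg <- SimulationConfig(n = 60, k = 3, m = 5)
#' set.seed(1)
#' g <- simulateGenotypes(cfg)
#' sim <- simulateLongitudinalPhenotypes(cfg, g)
#' fitNullVarianceComponents(sim$pheno, sim$covars)
#' @export
fitNullVarianceComponents <- function(pheno, covars, d0 = NULL, reml = FALSE) {
  stopifnot(is(pheno, "LongitudinalPhenotype"), is(covars, "CovariateDesign"))
  if (is.null(d0)) d0 <- estimateTimeCorrelation(pheno)
  stopifnot(is(d0, "TimeCorrelation"))
  d0mat <- d0Matrix(d0)
  k <- ncol(phenoValues(pheno))
  n <- nrow(phenoValues(pheno))
  if (nrow(d0mat) != k) stop("'d0' dimension does not match the phenotype time points")

  offdiag <- if (k > 1L) max(abs(d0mat[upper.tri(d0mat)])) else 0
  z <- designMatrix(covars)
  y <- as.vector(t(phenoValues(pheno)))

  if (k == 1L || offdiag < 1e-6) {
    ## sigma_v^2 and sigma_e^2 are confounded when D0 = I: fix sigma_v^2 = 0
    qz <- qr(z)
    if (qz$rank < ncol(z)) stop("covariate design is rank deficient")
    r <- qr.resid(qz, y)
    dfree <- if (reml) n * k - ncol(z) else n * k
    se2 <- sum(r^2) / dfree
    alpha <- drop(qr.coef(qz, y))
    ll <- -0.5 * (n * k * log(2 * pi) + n * k * log(se2) + sum(r^2) / se2)
    return(new("NullModelFit", sigmaV2 = 0, sigmaE2 = se2,
               alphaHat = unname(alpha), d0 = d0,
               whitenBlock = diag(1 / sqrt(se2), k), logLik = ll))
  }

  rot <- .rotateByD0(pheno, covars, d0mat)
  negll <- function(theta) {
    if (theta[1L] < 0 || theta[2L] <= 0) return(1e12)
    v <- -.profileLoglik(rot, theta[1L], theta[2L], reml = reml)
    if (!is.finite(v)) 1e12 else v
  }

  ## Method-of-moments start: match average within-individual covariance to
  ## sigma_v^2 * D0 and the diagonal to sigma_v^2 + sigma_e^2.
  qz <- qr(z)
  if (qz$rank < ncol(z)) stop("covariate design is rank deficient")
  rmat <- matrix(qr.resid(qz, y), n, k, byrow = TRUE)
  cm <- cov(rmat)
  tot <- mean(diag(cm))
  off <- upper.tri(d0mat) & abs(d0mat) > 0.01
  sv0 <- if (any(off)) mean(cm[off] / d0mat[off]) else tot / 2
  sv0 <- min(max(sv0, 1e-3 * tot), 0.999 * tot)
  starts <- list(c(sv0, max(tot - sv0, 1e-3 * tot)),
                 c(1e-8, tot))

  lower <- c(0, 1e-8 * tot)
  upper <- c(50 * tot, 50 * tot)
  best <- NULL
  for (s in starts) {
    ## quasi-Newton step; line-search breakdowns at the sigma_e^2 -> 0
    ## boundary still return a usable iterate, kept as a candidate
    opt <- tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.null(best)) {
    ## derivative-free polish; also certifies boundary solutions
    pol <- optim(best$par, negll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.finite(pol$value) && pol$value <= best$value) best <- pol
  }
  if (is.null(best) || !is.finite(best$value) ||
      best$value >= 1e12) {
    last <- if (!is.null(best)) best$par else starts[[1L]]
    f0 <- negll(last)
    eps <- 1e-6 * (abs(last) + 1e-8)
    grad <- vapply(1:2, function(i) {
      th <- last; th[i] <- th[i] + eps[i]
      (negll(th) - f0) / eps[i]
    }, numeric(1))
    stop(sprintf(paste0("variance-component optimizer failed to converge; ",
                        "last iterate (%.6g, %.6g), gradient norm %.3g"),
                 last[1L], last[2L], sqrt(sum(grad^2))))
  }

  sv2 <- max(best$par[1L], 0); se2 <- max(best$par[2L], lower[2L])
  if (sv2 < 1e-10) sv2 <- 0
  alpha <- .glsAlpha(rot, sv2, se2)
  wb <- inverseSqrtBlock(sv2 * d0mat + se2 * diag(k))
  new("NullModelFit", sigmaV2 = sv2, sigmaE2 = se2, alphaHat = unname(alpha),
      d0 = d0, whitenBlock = wb, logLik = -best$value)
}

#' Whiten stacked longitudinal data with the fitted null covariance
#'
#' Multiplies every individual's \code{K}-block of the input by the fitted
#' whitening block \eqn{(\hat\sigma_v^2 D_0 + \hat\sigma_e^2 I)^{-1/2}}, the
#' blockwise realization of \eqn{\hat\Sigma^{-1/2}}. Applied identically to
#' the phenotype vector, the covariate design and every expanded variant
#' column; whitened null residuals have (approximately) identity covariance.
#'
#' @param fit a [NullModelFit-class].
#' @param x stacked vector or \code{nK x C} matrix, individual-major,
#'   time-minor row order.
#' @return object of the same shape as \code{x}.
#' @export
setGeneric("whiten", function(fit, x) standardGeneric("whiten"))

#' @rdname whiten
#' @export
setMethod("whiten", "NullModelFit", function(fit, x) {
  vec <- is.null(dim(x))
  out <- .blockMultiply(whitenBlock(fit), x)
  if (vec) drop(out) else out
})
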