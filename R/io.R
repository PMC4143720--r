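## Readers and writers for the package's CSV dialects. Comma-separated,
## UTF-8, first column the sample id; gzip is handled transparently by R's
## file connections (by extension/magic). The simulator's writers and these
## readers round-trip exactly.

.openRead <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  path  # file() auto-detects gzip compression on read
}

.openWrite <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Read a dosage CSV into a GenotypeMatrix
#'
#' Expects a header row of variant ids, one row per individual, first column
#' the sample id, remaining columns real minor-allele dosages in
#' \eqn{[0, 2]} (the dialect of imputed-dosage files such as
#' \code{chrN-dose.csv.gz}). \code{.gz} files are decompressed transparently.
#'
#' @param path CSV or CSV.gz file.
#' @param sampleSubset optional character vector of sample ids: the result is
#'   subset to exactly these samples, in this order.
#' @param regionLabel region name attached to the result.
#' @param flipMajor flip columns with mean dosage > 1 to minor-allele counts.
#' @return a [GenotypeMatrix-class].
#' @export
readDosageCsv <- function(path, sampleSubset = NULL, regionLabel = NULL,
                          flipMajor = FALSE) {
  df <- utils::read.csv(.openRead(path), check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("dosage file needs a sample-id column plus >= 1 variant")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing dosage at row %d, column '%s'",
                 bad[1L], colnames(m)[bad[2L]]))
  }
  if (any(m < 0 | m > 2)) {
    bad <- which(m < 0 | m > 2, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage outside [0, 2] at row %d (sample '%s'), column '%s'",
                 bad[1L], ids[bad[1L]], colnames(m)[bad[2L]]))
  }
  if (!is.null(sampleSubset)) {
    idx <- match(sampleSubset, ids)
    if (anyNA(idx))
      stop(sprintf("unknown sample id(s): %s",
                   paste(sampleSubset[is.na(idx)], collapse = ", ")))
    m <- m[idx, , drop = FALSE]
    ids <- ids[idx]
  }
  if (is.null(regionLabel))
    regionLabel <- sub("\\.csv(\\.gz)?$", "", basename(path))
  GenotypeMatrix(m, sampleIds = ids, variantIds = colnames(m),
                 regionLabel = regionLabel, flipMajor = flipMajor)
}

#' Write a GenotypeMatrix as a dosage CSV
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output CSV (gzipped when the extension is \code{.gz}).
#' @return \code{path}, invisibly.
#' @export
writeDosageCsv <- function(geno, path) {
  stopifnot(is(geno, "GenotypeMatrix"))
  df <- data.frame(id = sampleIds(geno), dosages(geno),
                   check.names = FALSE)
  colnames(df) <- c("id", variantIds(geno))
  con <- .openWrite(path)
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide longitudinal phenotype/covariate CSV
#'
#' Wide format: first column the sample id; phenotype columns named
#' \code{<phenoName>_t<j>} for time points \code{j = 1..K}; covariate columns
#' either time-varying (\code{<cov>_t<j>}) or constant (\code{<cov>},
#' replicated across time points). Individuals missing any phenotype or
#' covariate value are dropped (complete-case analysis) and reported.
#'
#' @param path CSV or CSV.gz file.
#' @param phenoName prefix of the phenotype columns (default \code{"y"}).
#' @param covariates covariate name prefixes to load; \code{NULL} loads every
#'   non-id, non-phenotype column.
#' @return list with \code{pheno} ([LongitudinalPhenotype-class]),
#'   \code{covars} ([CovariateDesign-class]) and \code{dropped} (character
#'   ids of incomplete individuals).
#' @export
readPhenotypesCsv <- function(path, phenoName = "y", covariates = NULL) {
  df <- utils::read.csv(.openRead(path), check.names = FALSE,
                        stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  cols <- colnames(df)[-1L]

  pat <- paste0("^", phenoName, "_t(\\d+)$")
  pcols <- grep(pat, colnames(df), value = TRUE)
  if (!length(pcols)) stop(sprintf("no phenotype columns matching '%s_t<j>'",
                                   phenoName))
  ord <- order(as.integer(sub(pat, "\\1", pcols)))
  pcols <- pcols[ord]
  k <- length(pcols)

  other <- setdiff(cols, pcols)
  tvPat <- "^(.*)_t(\\d+)$"
  # covariates keep their file order: time-varying groups collapse to their
  # base name at first appearance, constant columns stand for themselves
  covNames <- unique(ifelse(grepl(tvPat, other), sub(tvPat, "\\1", other),
                            other))
  if (!is.null(covariates)) covNames <- intersect(covNames, covariates)

  used <- c(pcols, unlist(lapply(covNames, function(cv) {
    tc <- sprintf("%s_t%d", cv, seq_len(k))
    if (all(tc %in% other)) tc else cv
  })))
  cc <- stats::complete.cases(df[, used, drop = FALSE])
  dropped <- ids[!cc]
  if (!any(cc)) stop("no complete cases after filtering missing phenotypes/covariates")
  if (length(dropped))
    message(sprintf("dropped %d individual(s) with missing values: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  df <- df[cc, , drop = FALSE]
  ids <- ids[cc]
  n <- length(ids)

  yv <- as.matrix(df[, pcols, drop = FALSE])
  storage.mode(yv) <- "double"
  pheno <- LongitudinalPhenotype(yv, sampleIds = ids,
                                 timeLabels = sprintf("t%d", seq_len(k)))

  arr <- array(0, c(n, k, length(covNames)))
  for (q in seq_along(covNames)) {
    tc <- sprintf("%s_t%d", covNames[q], seq_len(k))
    if (all(tc %in% colnames(df))) {
      arr[, , q] <- as.matrix(df[, tc])
    } else {
      arr[, , q] <- matrix(as.numeric(df[[covNames[q]]]), n, k)
    }
  }
  covars <- CovariateDesign(arr, covariateNames = covNames)
  list(pheno = pheno, covars = covars, dropped = dropped)
}

#' Write phenotype and covariates as a wide CSV
#'
#' Inverse of [readPhenotypesCsv()]: phenotype columns \code{<phenoName>_t<j>},
#' covariates written time-varying (\code{<cov>_t<j>}) whenever they vary over
#' time and constant otherwise.
#'
#' @param pheno a [LongitudinalPhenotype-class].
#' @param covars a [CovariateDesign-class] or \code{NULL}.
#' @param path output CSV (gzipped for \code{.gz}).
#' @param phenoName phenotype column prefix.
#' @return \code{path}, invisibly.
#' @export
writePhenotypesCsv <- function(pheno, covars = NULL, path, phenoName = "y") {
  stopifnot(is(pheno, "LongitudinalPhenotype"))
  k <- nTimePoints(pheno)
  df <- data.frame(id = sampleIds(pheno), check.names = FALSE)
  yv <- phenoValues(pheno)
  for (j in seq_len(k)) df[[sprintf("%s_t%d", phenoName, j)]] <- yv[, j]
  if (!is.null(covars) && dim(covars@covariates)[3L] > 0L) {
    for (q in seq_len(dim(covars@covariates)[3L])) {
      sl <- covars@covariates[, , q, drop = FALSE]
      dim(sl) <- dim(sl)[1:2]
      nm <- covariateNames(covars)[q]
      if (k > 1L && max(apply(sl, 1L, function(r) diff(range(r)))) > 0) {
        for (j in seq_len(k)) df[[sprintf("%s_t%d", nm, j)]] <- sl[, j]
      } else {
        df[[nm]] <- sl[, 1L]
      }
    }
  }
  con <- .openWrite(path)
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotype dosages from a VCF (DS FORMAT field)
#'
#' Thin wrapper over \pkg{VariantAnnotation}: loads the \code{DS} (imputed
#' dosage) FORMAT field and returns it as a samples-by-variants
#' [GenotypeMatrix-class].
#'
#' @param path VCF file (optionally bgzipped).
#' @param sampleSubset optional sample ids, subset and reorder as requested.
#' @param regionLabel region name; defaults to the file name.
#' @return a [GenotypeMatrix-class].
#' @export
readDosageVcf <- function(path, sampleSubset = NULL, regionLabel = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("package 'VariantAnnotation' is required for VCF input")
  vcf <- VariantAnnotation::readVcf(path)
  gmat <- VariantAnnotation::geno(vcf)$DS
  if (is.null(gmat)) stop("VCF has no DS (dosage) FORMAT field")
  m <- t(as.matrix(gmat))  # samples x variants
  storage.mode(m) <- "double"
  ids <- rownames(m)
  if (!is.null(sampleSubset)) {
    idx <- match(sampleSubset, ids)
    if (anyNA(idx))
      stop(sprintf("unknown sample id(s): %s",
                   paste(sampleSubset[is.na(idx)], collapse = ", ")))
    m <- m[idx, , drop = FALSE]
    ids <- ids[idx]
  }
  if (is.null(regionLabel)) regionLabel <- basename(path)
  GenotypeMatrix(m, sampleIds = ids, variantIds = colnames(m),
                 regionLabel = regionLabel)
}

#' Combine two related phenotypes into one derived phenotype
#'
#' \code{"sum"} adds the two traits elementwise. \code{"pc1"} z-scores each
#' trait over all \code{n x K} values, then per time point projects the
#' standardized pair on the first principal component of its 2 x 2
#' covariance, with the sign fixed so the loading on \code{a} is positive.
#'
#' @param a,b two [LongitudinalPhenotype-class] objects with identical
#'   samples and time points.
#' @param method \code{"sum"} or \code{"pc1"}.
#' @return a [LongitudinalPhenotype-class].
#' @export
combinePhenotypes <- function(a, b, method = c("sum", "pc1")) {
  method <- match.arg(method)
  stopifnot(is(a, "LongitudinalPhenotype"), is(b, "LongitudinalPhenotype"))
  if (!identical(sampleIds(a), sampleIds(b)) ||
      nTimePoints(a) != nTimePoints(b))
    stop("phenotypes must share samples and time points")
  av <- phenoValues(a); bv <- phenoValues(b)
  if (method == "sum") {
    out <- av + bv
  } else {
    za <- (av - mean(av)) / sd(as.vector(av))
    zb <- (bv - mean(bv)) / sd(as.vector(bv))
    out <- matrix(0, nrow(av), ncol(av))
    for (j in seq_len(ncol(av))) {
      pair <- cbind(za[, j], zb[, j])
      v <- eigen(cov(pair), symmetric = TRUE)$vectors[, 1L]
      if (v[1L] < 0) v <- -v
      out[, j] <- pair %*% v
    }
  }
  LongitudinalPhenotype(out, sampleIds = sampleIds(a),
                        timeLabels = timeLabels(a))
}

#' Histogram of region-scan p-values
#'
#' Simple uniformity diagnostic: a histogram of p-values with the uniform
#' density marked, the standard visual check that a null scan is calibrated.
#'
#' @param pValues numeric vector of p-values.
#' @param breaks number of histogram cells.
#' @param main plot title.
#' @return the histogram object, invisibly.
#' @export
plotPvalueHistogram <- function(pValues, breaks = 20,
                                main = "P-value histogram") {
  h <- graphics::hist(pValues, breaks = seq(0, 1, length.out = breaks + 1L),
                      freq = FALSE, xlab = "p-value", main = main,
                      col = "grey85", border = "white")
  graphics::abline(h = 1, lty = 2, col = "red3")
  invisible(h)
}
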