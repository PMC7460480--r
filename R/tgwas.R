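#' Principal components of the genotype matrix
#'
#' First `k` principal-component scores of the column-centered (and by
#' default unit-variance scaled) genotype matrix, used to absorb family
#' structure in the single-marker scan.  Computed from the eigendecomposition
#' of the individual-by-individual cross-product, so the cost scales with the
#' sample size rather than the marker count.
#'
#' @param geno a [genotype_matrix()].
#' @param k number of components requested.
#' @param standardize scale each marker to unit variance before the
#'   decomposition.
#' @return Numeric matrix `n x k'` of scores (`k' <= k`, with a warning when
#'   the rank falls short), columns ordered by decreasing explained variance,
#'   with the eigenvalues as attribute `"explained"`.
#' @export
genotype_pcs <- function(geno, k = 10, standardize = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- impute_mean(geno$X)
  v <- apply(X, 2, var)
  X <- X[, v > 0, drop = FALSE]
  n <- nrow(X)
  if (n <= k) stop("need more individuals than requested components")
  if (ncol(X) < k) stop("need at least k polymorphic markers")
  X <- scale(X, center = TRUE, scale = standardize)
  # eigenvalues of XX'/(n-1) are the nonzero covariance eigenvalues
  K <- tcrossprod(X) / (n - 1)
  ee <- eigen(K, symmetric = TRUE)
  pos <- which(ee$values > max(ee$values) * 1e-10)
  if (length(pos) < k) {
    warning("genotype matrix rank ", length(pos), " < k; returning ",
            length(pos), " components")
  }
  keep <- head(pos, k)
  scores <- ee$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(pmax(ee$values[keep], 0) * (n - 1)), length(keep))
  rownames(scores) <- rownames(geno$X)
  colnames(scores) <- paste0("PC", seq_along(keep))
  attr(scores, "explained") <- ee$values[keep]
  scores
}

#' Single-marker regression scan
#'
#' Ordinary least squares of the corrected phenotype on each marker's allele
#' count, adjusted for an intercept and the supplied covariate columns
#' (typically principal components), with a two-sided t test on the allele
#' effect.  Monomorphic markers get effect 0 and p = 1.
#'
#' @param pheno data frame with `id` and the response column.
#' @param geno a [genotype_matrix()].
#' @param covariates numeric matrix of covariates (rows aligned with
#'   `pheno`), or `NULL`.
#' @param response response column name.
#' @return Tibble `marker`, `chrom`, `bp`, `beta`, `se`, `statistic`,
#'   `p.value`.
#' @export
single_marker_scan <- function(pheno, geno, covariates = NULL,
                               response = "residual") {
  pheno <- tibble::as_tibble(pheno)
  stopifnot(all(c("id", response) %in% names(pheno)))
  ids <- as.character(pheno$id)
  geno <- subset_genotypes(geno, ids = ids)
  y <- as.numeric(pheno[[response]])
  n <- length(y)
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("covariate matrix (with intercept) is rank deficient")
  q <- ncol(C)
  if (n <= q + 2) stop("too few individuals for the covariate-adjusted scan")
  X <- impute_mean(geno$X)
  # Frisch-Waugh: residualize phenotype and genotypes on the covariates
  y_r <- qr.resid(qrC, y)
  X_r <- qr.resid(qrC, X)
  sxx <- colSums(X_r^2)
  syy <- sum(y_r^2)
  sxy <- colSums(X_r * y_r)
  ok <- sxx > 1e-12
  beta <- ifelse(ok, sxy / sxx, 0)
  df <- n - q - 1
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- ifelse(ok, sqrt(rss / df / sxx), NA_real_)
  tstat <- ifelse(ok & !is.na(se) & se > 0, beta / se, 0)
  p <- ifelse(ok, 2 * pt(-abs(tstat), df), 1)
  exact <- ok & !is.na(se) & se == 0 & abs(beta) > 0  # noiseless fit
  tstat[exact] <- Inf * sign(beta[exact])
  p[exact] <- 0
  tibble::tibble(marker = geno$map$marker, chrom = geno$map$chrom,
                 bp = geno$map$bp, beta = unname(beta), se = unname(se),
                 statistic = unname(tstat), p.value = unname(p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone enforced) and significance flags.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q FDR level for the flags.
#' @return Tibble `p.value`, `q.value`, `significant`.
#' @export
fdr_adjust <- function(p, q = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  qv <- p.adjust(p, method = "BH")
  tibble::tibble(p.value = p, q.value = qv, significant = qv <= q)
}

#' Single-marker GWAS with PC correction and FDR
#'
#' The comparator pipeline: extract `n_pcs` genotype principal components,
#' regress the corrected phenotype on each marker with the PCs as
#' covariates, and control the FDR by Benjamini-Hochberg.
#'
#' @param pheno data frame with `id` and the response (corrected phenotype).
#' @param geno a [genotype_matrix()].
#' @param n_pcs number of principal components (0 for none).
#' @param fdr FDR level.
#' @param response response column name.
#' @param standardize passed to [genotype_pcs()].
#' @return A `tgwas_scan` tibble: `marker`, `chrom`, `bp`, `beta`, `se`,
#'   `statistic`, `p.value`, `q.value`, `significant`.
#' @export
run_tgwas <- function(pheno, geno, n_pcs = 10, fdr = 0.05,
                      response = "residual", standardize = TRUE) {
  pheno <- tibble::as_tibble(pheno)
  covs <- NULL
  if (n_pcs > 0) {
    sub <- subset_genotypes(geno, ids = as.character(pheno$id))
    covs <- suppressWarnings(genotype_pcs(sub, k = n_pcs,
                                          standardize = standardize))
  }
  scan <- single_marker_scan(pheno, geno, covariates = covs,
                             response = response)
  adj <- fdr_adjust(scan$p.value, q = fdr)
  scan$q.value <- adj$q.value
  scan$significant <- adj$significant
  class(scan) <- c("tgwas_scan", class(scan))
  scan
}
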