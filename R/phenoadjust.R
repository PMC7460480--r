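#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p_k (1 - p_k))` where `Z` is the allele-frequency
#' centered genotype matrix.  Monomorphic markers are dropped; missing
#' genotypes are mean-imputed per marker.
#'
#' @param geno a [genotype_matrix()].
#' @return Symmetric `n x n` matrix with individual ids as dimnames.
#' @export
make_grm <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- impute_mean(geno$X)
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1 & apply(X, 2, var) > 0
  if (sum(poly) < 2) stop("need at least 2 polymorphic markers for a GRM")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  (G + t(G)) / 2
}

#' Mixed-model phenotype pre-adjustment
#'
#' Fits `y = X b + g + e` by REML, with `g ~ N(0, sigma2_a G)` a genomic
#' animal effect (`G` from [make_grm()]) and i.i.d. residuals.  The variance
#' ratio is profiled on a one-dimensional REML likelihood through the
#' eigendecomposition of `G`; an optional second i.i.d. random intercept
#' (e.g. herd) is handled by nested profiling of a second ratio.  Corrected
#' phenotypes are the residuals `y - X b - g_hat` (or `y - X b` with
#' `residual_type = "fixed_only"`).
#'
#' @param pheno data frame with an `id` column, the response and the model
#'   terms; one row per individual, ids matching `geno`.
#' @param geno a [genotype_matrix()] covering (at least) the `pheno` ids.
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect factor columns.
#' @param covariates character vector of numeric covariate columns.
#' @param random_iid optional name of a factor column fitted as a second,
#'   i.i.d. random intercept.
#' @param residual_type `"full"` (subtract fixed effects and BLUPs) or
#'   `"fixed_only"`.
#' @param bounds search interval for each variance ratio.
#' @param tol convergence tolerance of the profiled optimization.
#' @return An `lmm_fit`: tibble of `residuals` (`id`, `residual`), variance
#'   components `sigma2_a`, `sigma2_e` (and `sigma2_iid` when requested),
#'   `h2 = sigma2_a / (sigma2_a + sigma2_e)`, the REML log-likelihood and the
#'   fitted fixed effects.  `tidy()` returns the residual table, `glance()`
#'   the variance components.
#' @export
fit_lmm <- function(pheno, geno, response = "phenotype",
                    fixed = character(), covariates = character(),
                    random_iid = NULL,
                    residual_type = c("full", "fixed_only"),
                    bounds = c(1e-6, 1e6), tol = 1e-8) {
  residual_type <- match.arg(residual_type)
  pheno <- tibble::as_tibble(pheno)
  need <- c("id", response, fixed, covariates, random_iid)
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("pheno lacks columns: ", paste(miss, collapse = ", "))
  ids <- as.character(pheno$id)
  if (!all(ids %in% rownames(geno$X))) {
    stop("pheno ids missing from the genotype matrix")
  }
  y <- as.numeric(pheno[[response]])
  n <- length(y)
  X <- fixed_design(pheno, fixed, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  G <- make_grm(subset_genotypes(geno, ids = ids))
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors
  dvals <- pmax(eg$values, 0)
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)

  if (is.null(random_iid)) {
    prof <- function(ll) reml_profile(exp(ll), dvals, yr, Xr)$loglik
    opt <- optimize(prof, interval = log(bounds), maximum = TRUE, tol = tol)
    if (!is.finite(opt$objective)) {
      stop("REML optimization failed to converge; profile log-likelihood at ",
           "lambda = ", signif(exp(opt$maximum), 4), " is not finite")
    }
    lambda <- exp(opt$maximum)
    fit <- reml_profile(lambda, dvals, yr, Xr)
    sigma2_e <- fit$sigma2
    sigma2_a <- lambda * sigma2_e
    beta <- fit$beta
    # BLUP of g: in the rotated basis u_r = (lambda d / (lambda d + 1)) r
    rr <- yr - Xr %*% beta
    g_hat <- as.numeric(U %*% ((lambda * dvals / (lambda * dvals + 1)) * rr))
    extra <- NULL
  } else {
    z <- factor(pheno[[random_iid]])
    Z2 <- model.matrix(~ z - 1)
    inner <- function(l2) {
      # fold the iid term into an effective covariance and profile lambda1
      obj <- function(l1) reml_general(exp(l1), exp(l2), G, Z2, y, X)$loglik
      o <- optimize(obj, interval = log(bounds), maximum = TRUE, tol = 1e-6)
      list(l1 = o$maximum, val = o$objective)
    }
    o2 <- optimize(function(l2) inner(l2)$val, interval = log(bounds),
                   maximum = TRUE, tol = 1e-6)
    l2 <- o2$maximum
    l1 <- inner(l2)$l1
    fit <- reml_general(exp(l1), exp(l2), G, Z2, y, X)
    sigma2_e <- fit$sigma2
    sigma2_a <- exp(l1) * sigma2_e
    beta <- fit$beta
    g_hat <- fit$g_hat
    opt <- list(objective = fit$loglik)
    extra <- exp(l2) * sigma2_e
  }

  res <- if (residual_type == "full") y - as.numeric(X %*% beta) - g_hat
  else y - as.numeric(X %*% beta)
  structure(list(
    residuals = tibble::tibble(id = ids, residual = res),
    sigma2_a = sigma2_a, sigma2_e = sigma2_e, sigma2_iid = extra,
    h2 = sigma2_a / (sigma2_a + sigma2_e),
    loglik = opt$objective, beta = setNames(as.numeric(beta), colnames(X)),
    residual_type = residual_type, response = response),
    class = "lmm_fit")
}

fixed_design <- function(pheno, fixed, covariates) {
  df <- as.data.frame(pheno)
  for (f in fixed) {
    df[[f]] <- as.factor(df[[f]])
    if (any(table(df[[f]]) < 2)) {
      stop("fixed effect '", f, "' has levels with fewer than 2 individuals")
    }
  }
  terms <- c("1", fixed, covariates)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  model.matrix(fml, df)
}

# profiled REML log-likelihood and GLS solution at variance ratio lambda
reml_profile <- function(lambda, dvals, yr, Xr) {
  w <- lambda * dvals + 1
  q <- ncol(Xr)
  n <- length(yr)
  XtWX <- crossprod(Xr / w, Xr)
  XtWy <- crossprod(Xr / w, yr)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf, beta = rep(0, q), sigma2 = NA))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- yr - Xr %*% beta
  rss <- sum(r^2 / w)
  sigma2 <- rss / (n - q)
  ll <- -0.5 * ((n - q) * log(sigma2) + sum(log(w)) +
                  2 * sum(log(diag(ch))) + (n - q))
  list(loglik = ll, beta = beta, sigma2 = sigma2)
}

# direct (dense) REML for G + iid second term; n kept small by callers
reml_general <- function(l1, l2, G, Z2, y, X) {
  n <- length(y)
  q <- ncol(X)
  V <- l1 * G + l2 * tcrossprod(Z2) + diag(n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtVX <- crossprod(X, Vi_X)
  ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch2)) return(list(loglik = -Inf))
  beta <- backsolve(ch2, forwardsolve(t(ch2), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  rss <- sum(r * Vi_r)
  sigma2 <- rss / (n - q)
  ll <- -0.5 * ((n - q) * log(sigma2) + 2 * sum(log(diag(ch))) +
                  2 * sum(log(diag(ch2))) + (n - q))
  g_hat <- as.numeric(l1 * G %*% Vi_r)
  list(loglik = ll, beta = beta, sigma2 = sigma2, g_hat = g_hat)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> n = ", nrow(x$residuals),
      ", sigma2_a = ", signif(x$sigma2_a, 4),
      ", sigma2_e = ", signif(x$sigma2_e, 4),
      ", h2 = ", signif(x$h2, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.lmm_fit <- function(x, ...) x$residuals

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(sigma2_a = x$sigma2_a, sigma2_e = x$sigma2_e,
                 sigma2_iid = ifelse(is.null(x$sigma2_iid), NA_real_,
                                     x$sigma2_iid),
                 h2 = x$h2, loglik = x$loglik)
}

#' Split animals into low/high phenotype groups
#'
#' Ranks corrected phenotypes and labels the lower half `LP` and the upper
#' half `HP`.  With an odd count the single median individual is dropped so
#' the groups stay exactly equal; boundary ties are broken deterministically
#' by id order.
#'
#' @param residuals data frame with `id` and `residual` columns (e.g. from
#'   `tidy()` of an [fit_lmm()] object).
#' @return Tibble `id`, `residual`, `group` (factor `LP` < `HP`), equal group
#'   sizes.
#' @export
split_groups <- function(residuals) {
  residuals <- tibble::as_tibble(residuals)
  stopifnot(all(c("id", "residual") %in% names(residuals)))
  n <- nrow(residuals)
  if (n < 4) stop("need at least 4 individuals to form groups")
  ord <- order(residuals$residual, as.character(residuals$id))
  half <- n %/% 2
  keep <- if (n %% 2 == 1) ord[-(half + 1)] else ord
  out <- residuals[keep, c("id", "residual")]
  out$group <- factor(rep(c("LP", "HP"), each = half), levels = c("LP", "HP"))
  out
}
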