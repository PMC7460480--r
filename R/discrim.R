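#' Pooled within-group covariance matrix
#'
#' `W = ((n1-1) S1 + (n2-1) S2) / (n1 + n2 - 2)` for exactly two groups.
#'
#' @param X numeric matrix (individuals x variables).
#' @param labels two-level factor (or coercible) of group membership.
#' @return Symmetric matrix `p x p`.
#' @export
pooled_within_cov <- function(X, labels) {
  g <- check_two_groups(X, labels)
  X1 <- X[g$i1, , drop = FALSE]
  X2 <- X[g$i2, , drop = FALSE]
  C1 <- crossprod(scale(X1, center = TRUE, scale = FALSE))
  C2 <- crossprod(scale(X2, center = TRUE, scale = FALSE))
  W <- (C1 + C2) / (g$n1 + g$n2 - 2)
  (W + t(W)) / 2
}

check_two_groups <- function(X, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  i1 <- which(labels == levels(labels)[1])
  i2 <- which(labels == levels(labels)[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("each group needs at least 2 members")
  }
  if (nrow(X) != length(labels)) stop("X rows and labels length differ")
  list(levels = levels(labels), i1 = i1, i2 = i2,
       n1 = length(i1), n2 = length(i2))
}

# symmetric pseudo-inverse action with relative eigenvalue tolerance;
# returns the solve of W (+ ridge) against b plus the rank used
psolve_sym <- function(W, b, ridge = 0, tol = 1e-10) {
  if (ridge > 0) W <- W + diag(ridge, nrow(W))
  ee <- eigen(W, symmetric = TRUE)
  keep <- ee$values > tol * max(ee$values, 0)
  rank <- sum(keep)
  if (rank == 0) return(list(x = rep(0, length(b)), rank = 0L))
  V <- ee$vectors[, keep, drop = FALSE]
  x <- V %*% ((crossprod(V, b)) / ee$values[keep])
  list(x = as.numeric(x), rank = as.integer(rank))
}

#' Two-group canonical discriminant analysis
#'
#' Fits the single canonical function of a two-group CDA,
#' `CAN = d1 X1 + ... + dp Xp`.  The raw direction is
#' `d = W^+ (m2 - m1)` (Moore-Penrose pseudo-inverse, optionally
#' ridge-stabilized), scaled so the pooled within-group variance of the
#' canonical scores is 1; the standardized coefficient of variable `i`
#' (`cnc`) is `d_i * sqrt(W_ii)`.  Orientation is fixed so the second factor
#' level (the high-phenotype group in the pipeline) has the higher centroid.
#'
#' @param X numeric matrix (individuals x markers) without missing values.
#' @param labels two-level factor; the second level is the "high" group.
#' @param ridge non-negative ridge added to `W` before inversion.
#' @param tol relative eigenvalue tolerance of the pseudo-inverse.
#' @return A `cda_fit`: raw coefficients `coef`, standardized `cnc`, group
#'   `centroids` on the canonical axis, Mahalanobis `d2`, the rank of `W`
#'   used, and group sizes.  `tidy()` gives the per-marker table.
#' @export
cda_fit <- function(X, labels, ridge = 0, tol = 1e-10) {
  X <- as.matrix(X)
  g <- check_two_groups(X, labels)
  m1 <- colMeans(X[g$i1, , drop = FALSE])
  m2 <- colMeans(X[g$i2, , drop = FALSE])
  delta <- m2 - m1
  W <- pooled_within_cov(X, labels)
  ps <- psolve_sym(W, delta, ridge = ridge, tol = tol)
  d <- ps$x
  if (ps$rank == 0 && sqrt(sum(delta^2)) == 0) {
    stop("undefined canonical direction: identical group means and zero ",
         "within-group covariance")
  }
  d2 <- sum(delta * d)                    # Mahalanobis D^2 = delta' W^+ delta
  s2 <- as.numeric(t(d) %*% W %*% d)      # pooled within-class score variance
  if (isTRUE(s2 > .Machine$double.eps)) {
    d <- d / sqrt(s2)
  } else if (sum(d^2) > 0) {
    d <- d / sqrt(sum(d^2))               # degenerate zero-variance case
  } else {
    stop("undefined canonical direction: zero mean difference within the ",
         "span of W")
  }
  c1 <- sum(m1 * d); c2 <- sum(m2 * d)
  if (c2 < c1) { d <- -d; c1 <- -c1; c2 <- -c2 }
  cnc <- d * sqrt(pmax(diag(W), 0))
  markers <- colnames(X)
  if (is.null(markers)) markers <- paste0("V", seq_along(d))
  structure(list(markers = markers, coef = setNames(d, markers),
                 cnc = setNames(cnc, markers),
                 centroids = setNames(c(c1, c2), g$levels),
                 d2 = max(d2, 0), rank = ps$rank,
                 n1 = g$n1, n2 = g$n2, levels = g$levels,
                 w_diag = setNames(diag(W), markers)),
            class = "cda_fit")
}

#' @export
print.cda_fit <- function(x, ...) {
  cat("<cda_fit> ", length(x$coef), " markers, groups ",
      paste0(x$levels, " (n=", c(x$n1, x$n2), ")", collapse = " vs "),
      "\n  Mahalanobis D^2 = ", signif(x$d2, 4),
      ", rank(W) = ", x$rank, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cda_fit <- function(x, ...) {
  tibble::tibble(marker = x$markers, raw_coef = unname(x$coef),
                 cnc = unname(x$cnc))
}

#' @export
glance.cda_fit <- function(x, ...) {
  ht <- hotelling_test(x$d2, x$n1, x$n2, x$rank)
  tibble::tibble(n_markers = length(x$coef), d2 = x$d2, t2 = ht$t2,
                 statistic = ht$statistic, df1 = ht$df1, df2 = ht$df2,
                 p.value = ht$p.value)
}

#' Mahalanobis squared distance between group means
#'
#' `D^2 = (m2 - m1)' W^+ (m2 - m1)`.
#'
#' @param m1,m2 group mean vectors.
#' @param W pooled within-group covariance (positive semi-definite).
#' @param tol pseudo-inverse tolerance.
#' @return Non-negative scalar.
#' @export
mahalanobis_d2 <- function(m1, m2, W, tol = 1e-10) {
  if (length(m1) != length(m2) || length(m1) != nrow(as.matrix(W))) {
    stop("dimension mismatch between means and W")
  }
  delta <- m2 - m1
  max(sum(delta * psolve_sym(as.matrix(W), delta, tol = tol)$x), 0)
}

#' Hotelling's two-sample T-squared test
#'
#' `T^2 = (n1 n2 / (n1 + n2)) D^2`;
#' `F = T^2 (n1 + n2 - p - 1) / ((n1 + n2 - 2) p)` on `(p, n1 + n2 - p - 1)`
#' degrees of freedom, where `p` is the effective dimension (the rank of the
#' covariance matrix actually inverted).
#'
#' @param d2 Mahalanobis squared distance.
#' @param n1,n2 group sizes.
#' @param p effective dimension.
#' @return Tibble `d2`, `t2`, `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
hotelling_test <- function(d2, n1, n2, p) {
  if (p < 1) stop("effective dimension must be >= 1")
  df2 <- n1 + n2 - p - 1
  if (df2 < 1) {
    stop("insufficient degrees of freedom (n1 + n2 - p - 1 = ", df2,
         "); reduce the marker set or its rank")
  }
  t2 <- (n1 * n2 / (n1 + n2)) * d2
  f <- t2 * df2 / ((n1 + n2 - 2) * p)
  tibble::tibble(d2 = d2, t2 = t2, statistic = f, df1 = p, df2 = df2,
                 p.value = pf(f, p, df2, lower.tail = FALSE))
}

#' Stepwise discriminant variable selection
#'
#' Forward selection with backward removal on Wilks' lambda: at each step the
#' candidate with the smallest partial-F p-value enters if `p <= sle`; any
#' entered variable whose partial F given the others has `p > sls` is then
#' removed.  Variables nearly collinear with the entered set (squared
#' multiple correlation above `1 - tolerance`) are excluded.  Selection stops
#' when no entry or removal is possible or `max_vars` is reached.
#'
#' @param X numeric matrix (individuals x variables).
#' @param labels two-level factor.
#' @param sle,sls significance levels to enter and to stay.
#' @param max_vars maximum number of entered variables
#'   (default `n1 + n2 - 2`).
#' @param tolerance collinearity tolerance on the residual total variance.
#' @return Character vector of entered variable names in entry order, with a
#'   `log` attribute (tibble of the step history).
#' @export
sda_select <- function(X, labels, sle = 0.15, sls = 0.15, max_vars = NULL,
                       tolerance = 1e-8) {
  X <- as.matrix(X)
  g <- check_two_groups(X, labels)
  n <- g$n1 + g$n2
  p <- ncol(X)
  if (is.null(max_vars)) max_vars <- n - 2
  max_vars <- min(max_vars, p, n - 2)
  if (p == 0 || max_vars < 1) return(empty_sda())
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))

  # total and within SSCP; sweeping both tracks Wilks' lambda ratios
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  Wm <- pooled_within_cov(X, labels) * (n - 2)
  t_diag0 <- pmax(diag(Tm), 0)
  Ts <- Tm; Ws <- Wm
  inset <- rep(FALSE, p)
  log <- list()
  last_removed <- NA_integer_
  step <- 0L
  repeat {
    k <- sum(inset)
    # --- entry ---
    entered <- FALSE
    if (k < max_vars) {
      cand <- which(!inset)
      td <- diag(Ts)[cand]; wd <- diag(Ws)[cand]
      ok <- t_diag0[cand] > 0 & td > tolerance * t_diag0[cand] & td > 0 & wd > 0
      df2 <- n - 2 - k
      if (any(ok) && df2 >= 1) {
        r <- pmin(pmax(wd[ok] / td[ok], 0), 1)
        f <- ifelse(r > 0, (1 - r) / r * df2, Inf)
        pv <- pf(f, 1, df2, lower.tail = FALSE)
        best <- which.min(pv)
        if (pv[best] <= sle) {
          j <- cand[ok][best]
          if (identical(j, last_removed)) break  # enter/remove cycle guard
          Ts <- sweep_op(Ts, j); Ws <- sweep_op(Ws, j)
          inset[j] <- TRUE
          step <- step + 1L
          log[[length(log) + 1L]] <- tibble::tibble(
            step = step, action = "enter", variable = vars[j],
            statistic = unname(f[best]), p.value = unname(pv[best]))
          entered <- TRUE
        }
      }
    }
    # --- removal ---
    removed <- FALSE
    k <- sum(inset)
    if (k > 0) {
      ins <- which(inset)
      # for swept-in variables the diagonals hold the negated inverse
      # diagonals, so lambda(S)/lambda(S-j) = Ts_jj / Ws_jj
      r <- diag(Ts)[ins] / diag(Ws)[ins]
      r <- pmin(pmax(r, 0), 1)
      df2 <- n - 2 - (k - 1)
      f <- ifelse(r > 0, (1 - r) / r * df2, Inf)
      pv <- pf(f, 1, df2, lower.tail = FALSE)
      worst <- which.max(pv)
      if (pv[worst] > sls) {
        j <- ins[worst]
        Ts <- sweep_op(Ts, j); Ws <- sweep_op(Ws, j)  # sweep toggles out
        inset[j] <- FALSE
        last_removed <- j
        step <- step + 1L
        log[[length(log) + 1L]] <- tibble::tibble(
          step = step, action = "remove", variable = vars[j],
          statistic = unname(f[worst]), p.value = unname(pv[worst]))
        removed <- TRUE
      }
    }
    if (!entered && !removed) break
    if (step > 4L * max_vars + 10L) break  # safety net against cycling
  }
  sel <- vars[inset]
  hist <- if (length(log)) dplyr::bind_rows(log) else empty_sda_log()
  # report in entry order of the surviving variables
  ord <- hist$variable[hist$action == "enter"]
  ord <- ord[ord %in% sel][!duplicated(ord[ord %in% sel])]
  structure(union(ord, sel), log = hist)
}

empty_sda <- function() structure(character(0), log = empty_sda_log())
empty_sda_log <- function() {
  tibble::tibble(step = integer(), action = character(), variable = character(),
                 statistic = numeric(), p.value = numeric())
}

# reversible sweep of a symmetric matrix on pivot k
sweep_op <- function(A, k) {
  d <- A[k, k]
  if (!isTRUE(abs(d) > 0)) stop("sweep pivot is zero")
  ak <- A[, k]
  A <- A - outer(ak, ak) / d
  A[, k] <- ak / d
  A[k, ] <- ak / d
  A[k, k] <- -1 / d
  A
}

#' Discriminant classification by centroid cutoff
#'
#' Scores each individual with the canonical function and assigns the group
#' on its side of the cutoff, the group-size-weighted mean of the two
#' training centroids `(n1 c1 + n2 c2) / (n1 + n2)`.  Scores below the
#' cutoff go to the group with the lower centroid; a score exactly at the
#' cutoff goes to the higher-centroid group.
#'
#' @param fit a [cda_fit()].
#' @param X matrix over the same markers as `fit`.
#' @param labels optional true labels; when given, accuracy is computed.
#' @return List with `scores`, `assigned` (factor), `cutoff` and `accuracy`
#'   (`NA` without labels).
#' @export
da_classify <- function(fit, X, labels = NULL) {
  stopifnot(inherits(fit, "cda_fit"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(fit$coef)) stop("marker mismatch between model and X")
  } else {
    if (!all(fit$markers %in% colnames(X))) {
      stop("marker mismatch between model and X")
    }
    X <- X[, fit$markers, drop = FALSE]
  }
  scores <- as.numeric(X %*% fit$coef)
  cutoff <- (fit$n1 * fit$centroids[1] + fit$n2 * fit$centroids[2]) /
    (fit$n1 + fit$n2)
  lower <- fit$levels[which.min(fit$centroids)]
  upper <- fit$levels[which.max(fit$centroids)]
  assigned <- factor(ifelse(scores < cutoff, lower, upper), levels = fit$levels)
  accuracy <- NA_real_
  if (!is.null(labels)) {
    labels <- factor(as.character(labels), levels = fit$levels)
    accuracy <- mean(assigned == labels)
  }
  list(scores = scores, assigned = assigned, cutoff = unname(cutoff),
       accuracy = accuracy)
}
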