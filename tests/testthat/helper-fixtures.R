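# shared fixtures, all generated in code

# a tiny deterministic genotype matrix; alt_minor complements columns so the
# counted (alternate) allele is always the minor one
tiny_geno <- function(n = 6, m = 8, seed = 1, missing = 0, alt_minor = FALSE) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(paste0("ind", seq_len(n)),
                              paste0("snp", seq_len(m))))
  if (alt_minor) {
    flip <- colMeans(X) > 1
    X[, flip] <- 2L - X[, flip]
  }
  if (missing > 0) X[sample(length(X), missing)] <- NA
  map <- tibble::tibble(marker = colnames(X),
                        chrom = rep_len(c("1", "2"), m),
                        bp = rep(seq_len(ceiling(m / 2)) * 1e5, length.out = m))
  genotype_matrix(X, map)
}

# two well-separated Gaussian groups for discriminant tests
two_group_data <- function(n_per = 20, p = 5, shift = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = shift / sqrt(p)), n_per, p))
  colnames(X) <- paste0("V", seq_len(p))
  labels <- factor(rep(c("LP", "HP"), each = n_per), levels = c("LP", "HP"))
  list(X = X, labels = labels)
}

# fast micro-scale simulation config: enough mutation-drift variation to be
# polymorphic at a tiny locus count
micro_config <- function(seed = 1, ...) {
  args <- list(n_chromosomes = 4L, n_snps = 240L, n_qtls = 12L,
               n_hist_generations = 150L, hist_pop_size = 80L,
               hist_bottleneck_size = NULL, mutation_rate = 1e-3,
               n_sires = 4L, n_dams = 60L, n_recent_generations = 4L,
               n_genotyped_generations = 2L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(mdagwas::sim_config, args)
}

# brute-force stepwise discriminant oracle on Wilks' lambda using explicit
# determinants; mirrors the entry/removal rules independently of sda_select
sda_oracle <- function(X, labels, sle = 0.15, sls = 0.15, max_vars = NULL) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  n <- nrow(X)
  if (is.null(max_vars)) max_vars <- n - 2
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  W1 <- crossprod(scale(X[labels == levels(labels)[1], , drop = FALSE],
                        center = TRUE, scale = FALSE))
  W2 <- crossprod(scale(X[labels == levels(labels)[2], , drop = FALSE],
                        center = TRUE, scale = FALSE))
  Wm <- W1 + W2
  lam <- function(S) {
    if (length(S) == 0) return(1)
    det(Wm[S, S, drop = FALSE]) / det(Tm[S, S, drop = FALSE])
  }
  S <- integer(0)
  repeat {
    changed <- FALSE
    if (length(S) < max_vars) {
      cand <- setdiff(seq_len(ncol(X)), S)
      df2 <- n - 2 - length(S)
      ps <- vapply(cand, function(j) {
        lt <- det(Tm[c(S, j), c(S, j), drop = FALSE])
        if (!is.finite(lt) || abs(lt) < 1e-12 * prod(diag(Tm)[c(S, j)])) {
          return(NA_real_)
        }
        r <- lam(c(S, j)) / lam(S)
        if (!is.finite(r) || r <= 0) return(NA_real_)
        pf((1 - r) / r * df2, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) <= sle) {
        S <- c(S, cand[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(S) > 0) {
      df2 <- n - 2 - (length(S) - 1)
      ps <- vapply(seq_along(S), function(i) {
        r <- lam(S) / lam(S[-i])
        pf((1 - r) / r * df2, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      if (max(ps) > sls) {
        S <- S[-which.max(ps)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  colnames(X)[S]
}

# direct step-up BH flags
bh_oracle_flags <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  thresh <- seq_len(m) * q / m
  ok <- which(p[ord] <= thresh)
  flags <- rep(FALSE, m)
  if (length(ok)) flags[ord[seq_len(max(ok))]] <- TRUE
  flags
}
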