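#' Genotype matrix container
#'
#' Bundles an individuals-by-markers matrix of alternate-allele counts
#' (0/1/2, `NA` for missing) with its marker map.  Markers are kept sorted
#' by (chromosome, position); individual ids are the matrix rownames.
#'
#' @param X integer matrix, individuals in rows (rownames = ids), markers in
#'   columns (colnames = marker ids).
#' @param map data frame with columns `marker`, `chrom`, `bp` and optionally
#'   allele labels `a1`, `a2` (defaults `"A"`/`"B"`; counts are of `a2`).
#' @return An object of class `genotype_matrix`: a list with elements `X`
#'   (integer matrix) and `map` (tibble sorted by chromosome and position).
#' @export
genotype_matrix <- function(X, map) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  map <- tibble::as_tibble(map)
  stopifnot(all(c("marker", "chrom", "bp") %in% names(map)))
  if (is.null(colnames(X))) colnames(X) <- map$marker
  if (nrow(map) != ncol(X)) {
    stop("map has ", nrow(map), " markers but X has ", ncol(X), " columns")
  }
  if (ncol(X) > 0 && !identical(as.character(map$marker), colnames(X))) {
    stop("map marker ids do not match X column names")
  }
  if (anyDuplicated(map$marker)) stop("duplicated marker ids")
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  if (anyDuplicated(rownames(X))) stop("duplicated individual ids")
  bad <- X[!is.na(X) & !(X %in% 0:2)]
  if (length(bad)) stop("genotype values must be 0, 1, 2 or NA")
  map$chrom <- as.character(map$chrom)
  if (!"a1" %in% names(map)) map$a1 <- "A"
  if (!"a2" %in% names(map)) map$a2 <- "B"
  ord <- order(chrom_rank(map$chrom), map$bp)
  map <- map[ord, c("marker", "chrom", "bp", "a1", "a2")]
  X <- X[, ord, drop = FALSE]
  structure(list(X = X, map = map), class = "genotype_matrix")
}

# numeric-aware chromosome ordering ("2" before "10", non-numeric labels last)
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(as.character(chrom)))
  num[is.na(num)] <- Inf
  rank(interaction(num, as.character(chrom), lex.order = TRUE),
       ties.method = "min")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$X), " individuals x ", ncol(x$X),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  n_na <- sum(is.na(x$X))
  if (n_na > 0) cat("  missing genotypes: ", n_na, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$X)

#' Subset a genotype matrix
#'
#' @param geno a [genotype_matrix()].
#' @param markers marker ids to keep (order ignored; map order is preserved).
#' @param ids individual ids to keep, in the order given.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, markers = NULL, ids = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$X
  map <- geno$map
  if (!is.null(markers)) {
    miss <- setdiff(markers, map$marker)
    if (length(miss)) stop("unknown markers: ", paste(head(miss, 5), collapse = ", "))
    keep <- map$marker %in% markers
    X <- X[, keep, drop = FALSE]
    map <- map[keep, ]
  }
  if (!is.null(ids)) {
    miss <- setdiff(as.character(ids), rownames(X))
    if (length(miss)) stop("unknown individuals: ", paste(head(miss, 5), collapse = ", "))
    X <- X[as.character(ids), , drop = FALSE]
  }
  genotype_matrix(X, map)
}

#' Allele frequencies and polymorphism
#'
#' @param geno a [genotype_matrix()].
#' @return Tibble with `marker`, alternate-allele frequency `p_alt`, and
#'   `polymorphic` flag (both alleles observed).
#' @export
allele_freq <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  p <- colMeans(geno$X, na.rm = TRUE) / 2
  tibble::tibble(marker = geno$map$marker, p_alt = unname(p),
                 polymorphic = !is.na(p) & p > 0 & p < 1)
}

# numeric matrix with per-marker mean imputation of missing genotypes;
# multivariate routines cannot take NAs
impute_mean <- function(X) {
  X <- matrix(as.numeric(X), nrow = nrow(X), dimnames = dimnames(X))
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X
}
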