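#' Read PLINK genotype files
#'
#' Reads a `.ped`/`.map` pair or a `.bed`/`.bim`/`.fam` triple into a
#' [genotype_matrix()].  By default genotypes are recoded as counts of the
#' minor allele (frequency ties broken toward the lexicographically smaller
#' allele); with `count_a1 = TRUE` the A1 allele is counted as written
#' (for `.ped` input, A1 is the first allele observed at the marker).
#'
#' @param prefix path prefix; `<prefix>.bed` is preferred when both dialects
#'   exist.
#' @param count_a1 count the file's A1 allele instead of the minor allele.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix, count_a1 = FALSE) {
  if (file.exists(paste0(prefix, ".bed"))) {
    read_plink_bed(prefix, count_a1 = count_a1)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_plink_ped(prefix, count_a1 = count_a1)
  } else {
    stop("no ", prefix, ".bed or ", prefix, ".ped found")
  }
}

read_map_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), marker = character(),
                          cm = numeric(), bp = integer()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4)) {
    stop("parse error in ", path, " line ", which(nf != 4)[1],
         ": expected 4 fields, got ", nf[which(nf != 4)[1]])
  }
  m <- do.call(rbind, fields)
  bp <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(bp)) stop("parse error in ", path, " line ", which(is.na(bp))[1],
                      ": non-numeric bp position")
  if (anyDuplicated(m[, 2])) {
    stop("parse error in ", path, ": duplicated marker id ",
         m[duplicated(m[, 2]), 2][1])
  }
  tibble::tibble(chrom = m[, 1], marker = m[, 2],
                 cm = as.numeric(m[, 3]), bp = bp)
}

read_plink_ped <- function(prefix, count_a1 = FALSE) {
  ped_path <- paste0(prefix, ".ped")
  map <- read_map_file(paste0(prefix, ".map"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ids <- character(n)
  A <- matrix(NA_character_, n, 2 * m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m) {
      stop("parse error in ", ped_path, " line ", i, ": expected ",
           6 + 2 * m, " fields, got ", length(f))
    }
    ids[i] <- f[2]
    if (m > 0) A[i, ] <- f[-(1:6)]
  }
  X <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    al <- A[, c(2 * j - 1, 2 * j), drop = FALSE]
    al[al == "0"] <- NA_character_
    seen <- unique(stats::na.omit(as.vector(t(al))))
    if (length(seen) > 2) {
      stop("parse error in ", ped_path, ": marker ", map$marker[j],
           " has more than two alleles (", paste(seen, collapse = ","), ")")
    }
    if (length(seen) == 0) seen <- c("A", "B")
    if (length(seen) == 1) seen <- c(seen, NA_character_)
    counted <- pick_counted_allele(al, seen, count_a1)
    a2[j] <- counted
    a1[j] <- setdiff2(seen, counted)
    X[, j] <- rowSums(al == counted)
    X[is.na(al[, 1]) | is.na(al[, 2]), j] <- NA_integer_
  }
  rownames(X) <- ids
  colnames(X) <- map$marker
  genotype_matrix(X, tibble::tibble(marker = map$marker, chrom = map$chrom,
                                    bp = map$bp, a1 = a1, a2 = a2))
}

# decide which allele is counted: A1-as-written (first seen) or the minor
# allele with lexicographic tie-break
pick_counted_allele <- function(al, seen, count_a1) {
  if (count_a1 || is.na(seen[2])) return(seen[1])
  n1 <- sum(al == seen[1], na.rm = TRUE)
  n2 <- sum(al == seen[2], na.rm = TRUE)
  if (n1 < n2) seen[1]
  else if (n2 < n1) seen[2]
  else sort(seen)[1]
}

setdiff2 <- function(seen, counted) {
  other <- seen[!is.na(seen) & seen != counted]
  if (length(other) == 0) if (counted == "A") "B" else "A" else other[1]
}

read_plink_bed <- function(prefix, count_a1 = FALSE) {
  bim <- read_bim_file(paste0(prefix, ".bim"))
  fam_lines <- readLines(paste0(prefix, ".fam"))
  fam_lines <- fam_lines[nzchar(trimws(fam_lines))]
  ids <- vapply(strsplit(trimws(fam_lines), "[ \t]+"), `[`, character(1), 2)
  n <- length(ids); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3 + ceiling(n / 4) * max(m, 1))
  if (length(raw) < 3 || !identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))) {
    stop("parse error in ", prefix, ".bed: bad magic bytes (expect SNP-major bed)")
  }
  bpm <- ceiling(n / 4)
  if (length(raw) != 3 + bpm * m) {
    stop("parse error in ", prefix, ".bed: expected ", 3 + bpm * m,
         " bytes, found ", length(raw))
  }
  X <- matrix(NA_integer_, n, m)
  # 2-bit codes, lowest bits first: 00 hom A1, 01 missing, 10 het, 11 hom A2
  code_to_a1 <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  body <- as.integer(raw[-(1:3)])
  for (j in seq_len(m)) {
    bytes <- body[((j - 1) * bpm + 1):(j * bpm)]
    codes <- c(bytes %% 4L, (bytes %/% 4L) %% 4L,
               (bytes %/% 16L) %% 4L, bytes %/% 64L)
    codes <- matrix(codes, nrow = bpm)[cbind(((seq_len(n) - 1) %/% 4) + 1,
                                             ((seq_len(n) - 1) %% 4) + 1)]
    X[, j] <- code_to_a1[codes + 1L]
  }
  a1 <- bim$a1; a2 <- bim$a2
  counted <- a1; other <- a2
  if (!count_a1) {
    for (j in seq_len(m)) {
      cnt <- sum(X[, j], na.rm = TRUE)
      tot <- 2 * sum(!is.na(X[, j]))
      flip <- if (tot == 0) FALSE
      else if (cnt * 2 > tot) TRUE
      else if (cnt * 2 == tot) !is.na(a2[j]) && sort(c(a1[j], a2[j]))[1] == a2[j]
      else FALSE
      if (flip) {
        X[, j] <- 2L - X[, j]
        counted[j] <- a2[j]; other[j] <- a1[j]
      }
    }
  }
  rownames(X) <- ids
  colnames(X) <- bim$marker
  genotype_matrix(X, tibble::tibble(marker = bim$marker, chrom = bim$chrom,
                                    bp = bim$bp, a1 = other, a2 = counted))
}

read_bim_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), marker = character(),
                          cm = numeric(), bp = integer(),
                          a1 = character(), a2 = character()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6)) {
    stop("parse error in ", path, " line ", which(nf != 6)[1],
         ": expected 6 fields")
  }
  m <- do.call(rbind, fields)
  if (anyDuplicated(m[, 2])) stop("parse error in ", path, ": duplicated marker ids")
  tibble::tibble(chrom = m[, 1], marker = m[, 2], cm = as.numeric(m[, 3]),
                 bp = as.integer(m[, 4]), a1 = m[, 5], a2 = m[, 6])
}

#' Write PLINK genotype files
#'
#' Writes `.ped`/`.map` and/or the binary `.bed`/`.bim`/`.fam` triple
#' (SNP-major `.bed`, magic bytes `0x6c 0x1b 0x01`).  The counted
#' (alternate) allele is written as A1 in the `.bim`, so
#' `read_plink(prefix, count_a1 = TRUE)` reproduces the matrix exactly.
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix.
#' @param format `"both"`, `"ped"` or `"bed"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, format = c("both", "ped", "bed")) {
  stopifnot(inherits(geno, "genotype_matrix"))
  format <- match.arg(format)
  ids <- rownames(geno$X)
  if (any(is.na(ids)) || any(!nzchar(ids))) stop("missing individual ids")
  if (format %in% c("both", "ped")) write_plink_ped(geno, prefix)
  if (format %in% c("both", "bed")) write_plink_bed(geno, prefix)
  invisible(prefix)
}

write_plink_ped <- function(geno, prefix) {
  map <- geno$map
  map_lines <- if (nrow(map)) paste(map$chrom, map$marker, 0, map$bp) else character(0)
  writeLines(map_lines, paste0(prefix, ".map"))
  n <- nrow(geno$X); m <- ncol(geno$X)
  geno_str <- matrix("0 0", n, max(m, 1))
  for (j in seq_len(m)) {
    g <- geno$X[, j]
    s <- c(paste(map$a1[j], map$a1[j]), paste(map$a1[j], map$a2[j]),
           paste(map$a2[j], map$a2[j]))[g + 1L]
    s[is.na(g)] <- "0 0"
    geno_str[, j] <- s
  }
  lead <- paste(rownames(geno$X), rownames(geno$X), 0, 0, 0, -9)
  body <- if (m > 0) apply(geno_str, 1, paste, collapse = " ") else rep("", n)
  writeLines(trimws(paste(lead, body)), paste0(prefix, ".ped"))
}

write_plink_bed <- function(geno, prefix) {
  map <- geno$map
  ids <- rownames(geno$X)
  writeLines(paste(ids, ids, 0, 0, 0, -9), paste0(prefix, ".fam"))
  # counted allele written as A1
  bim_lines <- if (nrow(map)) {
    paste(map$chrom, map$marker, 0, map$bp, map$a2, map$a1)
  } else character(0)
  writeLines(bim_lines, paste0(prefix, ".bim"))
  n <- nrow(geno$X); m <- ncol(geno$X)
  bpm <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  count_to_code <- function(g) {
    code <- rep(1L, length(g))             # missing
    code[!is.na(g) & g == 2L] <- 0L        # hom counted (A1)
    code[!is.na(g) & g == 1L] <- 2L        # het
    code[!is.na(g) & g == 0L] <- 3L        # hom other (A2)
    code
  }
  for (j in seq_len(m)) {
    code <- count_to_code(geno$X[, j])
    length(code) <- 4 * bpm                # pad with NA -> treated as 0 below
    code[is.na(code)] <- 0L
    cm <- matrix(code, nrow = 4)
    bytes <- cm[1, ] + 4L * cm[2, ] + 16L * cm[3, ] + 64L * cm[4, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a QTL map
#'
#' Tab-separated file with header `chrom bp effect`, 1-based positions.
#'
#' @param path file path.
#' @return Tibble `chrom`, `bp`, `effect` sorted by (chrom, bp), with a
#'   `locus` id column when present in the file.
#' @export
read_qtl_map <- function(path) {
  qtl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "bp", "effect")
  if (!all(need %in% names(qtl))) {
    stop("parse error in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(qtl) > 0 && (!is.numeric(qtl$bp) || !is.numeric(qtl$effect))) {
    stop("parse error in ", path, ": non-numeric bp or effect")
  }
  qtl$chrom <- as.character(qtl$chrom)
  qtl$bp <- as.integer(qtl$bp)
  qtl$effect <- as.numeric(qtl$effect)
  qtl <- qtl[order(chrom_rank(qtl$chrom), qtl$bp), ]
  if (!"locus" %in% names(qtl)) {
    qtl$locus <- if (nrow(qtl)) paste0("qtl", seq_len(nrow(qtl))) else character(0)
  }
  tibble::as_tibble(qtl[, c("locus", "chrom", "bp", "effect")])
}

#' Write a QTL map
#'
#' @param qtl tibble with `chrom`, `bp`, `effect` (and optionally `locus`).
#' @param path output path (tab-separated with header).
#' @return `path`, invisibly.
#' @export
write_qtl_map <- function(qtl, path) {
  cols <- intersect(c("locus", "chrom", "bp", "effect"), names(qtl))
  readr::write_tsv(qtl[, cols], path, progress = FALSE)
  invisible(path)
}
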