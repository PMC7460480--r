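#' Simulation configuration
#'
#' Parameters of the forward-in-time cattle population simulator: a long
#' historical random-mating phase builds mutation-drift (dis)equilibrium and
#' linkage disequilibrium, then a pedigreed recent phase with sire/dam
#' replacement and positive-assortative mating produces the genotyped cohort.
#' Defaults mirror the simulated beef-cattle design the package reproduces:
#' 29 autosomes, 56,996 evenly spaced SNPs, 203 random QTLs, recurrent
#' mutation 2.5e-5, 1000 historical generations, 100 sires x 4000 dams for
#' 10 recent generations with the last 3 genotyped, phenotypic variance 1.0,
#' total heritability 0.5 of which 0.3 is due to QTLs.
#'
#' @param n_chromosomes number of autosomes.
#' @param n_snps total SNP count, spread evenly across chromosomes.
#' @param n_qtls total QTL count, placed uniformly at random.
#' @param chrom_length_bp physical chromosome length in bp (all autosomes).
#' @param chrom_length_morgans genetic chromosome length in Morgans.
#' @param mutation_rate per-locus per-meiosis two-way (flip) mutation rate.
#' @param n_hist_generations historical Wright-Fisher generations.
#' @param hist_pop_size historical diploid population size.
#' @param hist_bottleneck_size optional reduced population size for the last
#'   `hist_bottleneck_generations` historical generations (a contraction
#'   followed by re-expansion to `hist_pop_size`, the standard way to build
#'   livestock-like linkage disequilibrium); `NULL` for a constant size.
#' @param hist_bottleneck_generations length of the bottleneck phase.
#' @param n_sires,n_dams breeding males/females per recent generation.
#' @param n_recent_generations pedigreed generations after the founders.
#' @param n_genotyped_generations trailing generations flagged genotyped.
#' @param sire_replacement,dam_replacement fraction of parents replaced per
#'   generation by randomly chosen offspring of the previous generation.
#' @param mating_design `"assortative"` (sires and dams ranked by phenotype
#'   and paired rank block to rank) or `"random"`.
#' @param male_proportion probability an offspring is male.
#' @param var_phenotypic phenotypic variance of the trait.
#' @param h2_total total (narrow-sense) heritability.
#' @param h2_qtl share of phenotypic variance due to the QTL score
#'   (`h2_qtl <= h2_total`); the remainder of the heritability is a
#'   pedigree-transmitted polygenic effect.
#' @param seed integer seed governing all randomness of the simulation.
#' @return A `sim_config` list.
#' @seealso [scaled_sim_config()] for a desk-scale variant.
#' @export
sim_config <- function(n_chromosomes = 29, n_snps = 56996, n_qtls = 203,
                       chrom_length_bp = 1e8, chrom_length_morgans = 1,
                       mutation_rate = 2.5e-5,
                       n_hist_generations = 1000, hist_pop_size = 1000,
                       hist_bottleneck_size = NULL,
                       hist_bottleneck_generations = 100,
                       n_sires = 100, n_dams = 4000,
                       n_recent_generations = 10, n_genotyped_generations = 3,
                       sire_replacement = 0.2, dam_replacement = 0.3,
                       male_proportion = 0.5,
                       mating_design = c("assortative", "random"),
                       var_phenotypic = 1, h2_total = 0.5, h2_qtl = 0.3,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              n_snps = as.integer(n_snps), n_qtls = as.integer(n_qtls),
              chrom_length_bp = chrom_length_bp,
              chrom_length_morgans = chrom_length_morgans,
              mutation_rate = mutation_rate,
              n_hist_generations = as.integer(n_hist_generations),
              hist_pop_size = as.integer(hist_pop_size),
              hist_bottleneck_size = if (is.null(hist_bottleneck_size)) NULL
                else as.integer(hist_bottleneck_size),
              hist_bottleneck_generations = as.integer(hist_bottleneck_generations),
              n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              n_recent_generations = as.integer(n_recent_generations),
              n_genotyped_generations = as.integer(n_genotyped_generations),
              sire_replacement = sire_replacement,
              dam_replacement = dam_replacement,
              male_proportion = male_proportion,
              mating_design = match.arg(mating_design),
              var_phenotypic = var_phenotypic,
              h2_total = h2_total, h2_qtl = h2_qtl,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!(h2_qtl >= 0 && h2_qtl <= h2_total && h2_total <= 1)) {
      stop("need 0 <= h2_qtl <= h2_total <= 1")
    }
    counts <- c(n_chromosomes, chrom_length_bp, n_hist_generations,
                hist_pop_size, n_sires, n_dams, n_recent_generations,
                n_genotyped_generations)
    if (any(counts <= 0)) stop("all population/genome counts must be positive")
    if (n_snps < 0 || n_qtls < 0) stop("locus counts must be non-negative")
    if (n_genotyped_generations > n_recent_generations) {
      stop("n_genotyped_generations cannot exceed n_recent_generations")
    }
    rates <- c(mutation_rate, sire_replacement, dam_replacement, male_proportion)
    if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
    if (var_phenotypic <= 0) stop("var_phenotypic must be positive")
    if (n_snps + n_qtls > n_chromosomes * chrom_length_bp) {
      stop("configuration error: more loci than representable positions")
    }
    if (!is.null(hist_bottleneck_size)) {
      if (hist_bottleneck_size <= 0 || hist_bottleneck_size > hist_pop_size) {
        stop("hist_bottleneck_size must lie in (0, hist_pop_size]")
      }
      if (hist_bottleneck_generations <= 0 ||
          hist_bottleneck_generations >= n_hist_generations) {
        stop("hist_bottleneck_generations must lie in (0, n_hist_generations)")
      }
    }
  })
  invisible(cfg)
}

#' Desk-scale simulation configuration
#'
#' The scaled study conditions used throughout the package's tests and
#' examples: 5,000 SNPs and 50 QTLs on 29 autosomes (preserving the SNP:QTL
#' ratio's order of magnitude), 18 sires and 700 dams so that three genotyped
#' generations yield about 2,100 animals, and a historical bottleneck to 200
#' diploids over the last 100 historical generations so that linkage
#' disequilibrium per marker interval stays comparable to a dense-chip
#' full-scale genome (the sparser scaled panel would otherwise carry far less
#' marker-QTL LD than the design it stands in for).  All other parameters
#' keep the full-scale defaults.
#'
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config` list.
#' @export
scaled_sim_config <- function(...) {
  args <- list(n_snps = 5000L, n_qtls = 50L, n_sires = 18L, n_dams = 700L,
               hist_bottleneck_size = 200L,
               hist_bottleneck_generations = 100L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

#' Place SNP and QTL loci on the genome
#'
#' SNPs are spaced evenly within each chromosome (when the total is not
#' divisible by the chromosome count, the remainder is spread one extra SNP
#' per chromosome from chromosome 1 upward); QTLs fall at uniform-random
#' unique positions.
#'
#' @param config a [sim_config()].
#' @return Tibble with `locus`, `chrom`, `bp` (1-based), `type`
#'   (`"snp"`/`"qtl"`), sorted by chromosome and position.
#' @export
place_loci <- function(config) {
  validate_sim_config(config)
  nc <- config$n_chromosomes
  len <- config$chrom_length_bp
  base <- config$n_snps %/% nc
  extra <- config$n_snps %% nc
  per_chrom <- rep(base, nc) + (seq_len(nc) <= extra)
  snp <- purrr::map_dfr(seq_len(nc), function(c) {
    k <- per_chrom[c]
    if (k == 0) return(tibble::tibble(chrom = integer(), bp = integer()))
    pos <- unique(pmax(1L, as.integer(round(seq_len(k) * (len / (k + 1))))))
    if (length(pos) < k) stop("configuration error: chromosome ", c,
                              " cannot hold ", k, " evenly spaced SNPs")
    tibble::tibble(chrom = c, bp = pos)
  })
  snp$type <- "snp"
  taken <- paste(snp$chrom, snp$bp)
  qtl_chrom <- integer(0); qtl_bp <- integer(0)
  n_left <- config$n_qtls
  guard <- 0
  while (n_left > 0) {
    ch <- sample.int(nc, n_left, replace = TRUE)
    bp <- sample.int(len, n_left, replace = TRUE)
    key <- paste(ch, bp)
    ok <- !(key %in% taken) & !duplicated(key)
    qtl_chrom <- c(qtl_chrom, ch[ok]); qtl_bp <- c(qtl_bp, bp[ok])
    taken <- c(taken, key[ok])
    n_left <- n_left - sum(ok)
    guard <- guard + 1
    if (guard > 1000) stop("configuration error: cannot place unique QTL positions")
  }
  qtl <- tibble::tibble(chrom = qtl_chrom, bp = qtl_bp, type = "qtl")
  loci <- dplyr::bind_rows(snp, qtl)
  loci <- loci[order(loci$chrom, loci$bp), ]
  idx <- stats::ave(seq_len(nrow(loci)), loci$chrom, loci$type, FUN = seq_along)
  loci$locus <- paste0(loci$type, loci$chrom, "_", idx)
  tibble::as_tibble(loci[, c("locus", "chrom", "bp", "type")])
}

# locus helpers shared by the gamete-dropping wrappers
locus_geometry <- function(loci, config) {
  gpos <- loci$bp / config$chrom_length_bp * config$chrom_length_morgans
  chroms <- sort(unique(loci$chrom))
  begin <- vapply(chroms, function(c) min(which(loci$chrom == c)) - 1L, integer(1))
  end <- vapply(chroms, function(c) max(which(loci$chrom == c)), integer(1))
  list(gpos = as.numeric(gpos), begin = as.integer(begin), end = as.integer(end))
}

#' Simulate the historical population
#'
#' Evolves a closed random-mating (monoecious Wright-Fisher) population of
#' `hist_pop_size` diploids for `n_hist_generations` discrete generations,
#' with Poisson recombination (`chrom_length_morgans` per chromosome, no
#' interference) and two-way recurrent mutation at `mutation_rate` per locus
#' per meiosis.  Founder alleles start at frequency `init_freq` (default 0.5,
#' the usual initialization when the panel mimics a common-variant SNP chip;
#' drift then pushes frequencies toward the U-shaped spectrum).  Monomorphic
#' loci are permitted in the output.
#'
#' @param loci locus map from [place_loci()].
#' @param config a [sim_config()].
#' @param init_freq initial alternate-allele frequency (0 starts every locus
#'   monomorphic for the reference allele).
#' @return A `founder_pool`: list with the final-generation haplotypes
#'   (`haps`, loci x 2N raw matrix), the locus map and the config.
#' @export
simulate_historical <- function(loci, config, init_freq = 0.5) {
  validate_sim_config(config)
  stopifnot(init_freq >= 0, init_freq <= 1)
  geom <- locus_geometry(loci, config)
  L <- nrow(loci)
  n_hap <- 2L * config$hist_pop_size
  haps <- if (init_freq > 0) {
    matrix(as.raw(runif(L * n_hap) < init_freq), nrow = L, ncol = n_hap)
  } else {
    matrix(as.raw(0), nrow = L, ncol = n_hap)
  }
  nb <- config$hist_bottleneck_size
  evolve <- function(h, gens) {
    if (gens > 0) cpp_evolve_pool(h, geom$gpos, geom$begin, geom$end,
                                  config$chrom_length_morgans, gens,
                                  config$mutation_rate)
    else h
  }
  if (is.null(nb) || nb >= config$hist_pop_size) {
    haps <- evolve(haps, config$n_hist_generations)
  } else {
    gb <- config$hist_bottleneck_generations
    haps <- evolve(haps, config$n_hist_generations - gb - 1L)
    pick <- sample.int(config$hist_pop_size, nb)
    cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
    haps <- evolve(haps[, cols, drop = FALSE], gb)
    # one re-expansion generation back to hist_pop_size by random mating
    sires <- sample.int(nb, config$hist_pop_size, replace = TRUE) - 1L
    dams <- sample.int(nb, config$hist_pop_size, replace = TRUE) - 1L
    haps <- cpp_make_offspring(haps, sires, dams, geom$gpos, geom$begin,
                               geom$end, config$chrom_length_morgans,
                               config$mutation_rate)
  }
  structure(list(haps = haps, loci = loci, config = config),
            class = "founder_pool")
}

draw_raw_qtl_effects <- function(n_qtls, shape = 0.4) {
  if (n_qtls == 0) return(numeric(0))
  rgamma(n_qtls, shape = shape, rate = 1) * sample(c(-1, 1), n_qtls, replace = TRUE)
}

#' Simulate the pedigreed recent generations
#'
#' Draws `n_sires + n_dams` founders from the historical pool, then breeds
#' `n_recent_generations` of one offspring per dam.  Replacement parents are
#' selected at random among the previous generation's offspring of the right
#' sex; mate pairing is positive assortative (sires and dams each ranked by
#' phenotype and paired rank block to rank).  The phenotype used for ranking
#' is a provisional trait built from the same component realizations the
#' recorded phenotype later calibrates.  The trailing
#' `n_genotyped_generations` are flagged genotyped.
#'
#' @param founders a `founder_pool` from [simulate_historical()].
#' @param config a [sim_config()].
#' @param effects_raw optional unscaled QTL allele-substitution effects (one
#'   per QTL locus, map order); drawn gamma(0.4) with random sign if `NULL`.
#' @return A `sim_population`: pedigree tibble, haplotype storage, trait
#'   component realizations and the locus map.
#' @export
simulate_recent <- function(founders, config, effects_raw = NULL) {
  stopifnot(inherits(founders, "founder_pool"))
  validate_sim_config(config)
  loci <- founders$loci
  geom <- locus_geometry(loci, config)
  qtl_rows <- which(loci$type == "qtl")
  n_f <- config$n_sires + config$n_dams
  n_hist <- ncol(founders$haps) / 2L
  if (n_hist < n_f) {
    stop("configuration error: founder pool (", n_hist,
         ") smaller than n_sires + n_dams (", n_f, ")")
  }
  if (is.null(effects_raw)) effects_raw <- draw_raw_qtl_effects(config$n_qtls)
  stopifnot(length(effects_raw) == length(qtl_rows))

  n_gen <- config$n_recent_generations
  n_off_gen <- config$n_dams
  n_total <- n_f + n_off_gen * n_gen
  vP <- (config$h2_total - config$h2_qtl) * config$var_phenotypic
  vE <- (1 - config$h2_total) * config$var_phenotypic

  # per-individual records
  sire_of <- dam_of <- rep(NA_integer_, n_total)
  sex <- character(n_total)
  generation <- integer(n_total)
  polygenic <- residual <- qtl_raw <- phen_prov <- numeric(n_total)

  # founders: chosen at random from the pool, sexes assigned to fill the
  # sire and dam quotas
  pick <- sample.int(n_hist, n_f)
  founder_cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  blocks <- list(founders$haps[, founder_cols, drop = FALSE])
  block_of <- c(rep(1L, n_f), rep(NA_integer_, n_total - n_f))
  idx_in_block <- c(seq_len(n_f), rep(NA_integer_, n_total - n_f))

  sires <- seq_len(config$n_sires)
  dams <- config$n_sires + seq_len(config$n_dams)
  sex[sires] <- "M"; sex[dams] <- "F"
  generation[seq_len(n_f)] <- 0L

  qtl_geno_of <- function(ids) {
    if (length(qtl_rows) == 0) return(matrix(0L, length(ids), 0))
    out <- matrix(0L, nrow = length(ids), ncol = length(qtl_rows))
    for (b in unique(block_of[ids])) {
      in_b <- which(block_of[ids] == b)
      sub <- blocks[[b]][qtl_rows, , drop = FALSE]
      out[in_b, ] <- cpp_genotypes(sub, idx_in_block[ids[in_b]] - 1L)
    }
    out
  }

  polygenic[1:n_f] <- rnorm(n_f, 0, sqrt(vP))
  residual[1:n_f] <- rnorm(n_f, 0, sqrt(vE))
  qtl_raw[1:n_f] <- as.numeric(qtl_geno_of(seq_len(n_f)) %*% effects_raw)
  sd_q0 <- sd(qtl_raw[1:n_f])
  s_q0 <- if (isTRUE(sd_q0 > 0)) sqrt(config$h2_qtl * config$var_phenotypic) / sd_q0 else 0
  phen_prov[1:n_f] <- s_q0 * qtl_raw[1:n_f] + polygenic[1:n_f] + residual[1:n_f]

  next_id <- n_f + 1L
  for (g in seq_len(n_gen)) {
    # positive assortative pairing: rank sires and dams by phenotype and
    # assign each dam-rank block to the matching sire rank
    if (identical(config$mating_design, "random")) {
      s_ord <- sample(sires); d_ord <- sample(dams)
    } else {
      s_ord <- sires[order(phen_prov[sires], decreasing = TRUE)]
      d_ord <- dams[order(phen_prov[dams], decreasing = TRUE)]
    }
    sire_rank <- pmin(config$n_sires,
                      ceiling(seq_along(d_ord) * config$n_sires / config$n_dams))
    off <- next_id:(next_id + n_off_gen - 1L)
    sire_of[off] <- s_ord[sire_rank]
    dam_of[off] <- d_ord

    parents <- unique(c(s_ord, d_ord))
    pmat <- gather_haps(blocks, block_of, idx_in_block, parents, seq_len(nrow(loci)))
    pix <- match(sire_of[off], parents) - 1L
    dix <- match(dam_of[off], parents) - 1L
    kids <- cpp_make_offspring(pmat, pix, dix, geom$gpos, geom$begin, geom$end,
                               config$chrom_length_morgans, config$mutation_rate)
    blocks[[length(blocks) + 1L]] <- kids
    block_of[off] <- length(blocks)
    idx_in_block[off] <- seq_len(n_off_gen)

    sex[off] <- ifelse(runif(n_off_gen) < config$male_proportion, "M", "F")
    generation[off] <- g
    polygenic[off] <- (polygenic[sire_of[off]] + polygenic[dam_of[off]]) / 2 +
      rnorm(n_off_gen, 0, sqrt(vP / 2))
    residual[off] <- rnorm(n_off_gen, 0, sqrt(vE))
    qtl_raw[off] <- as.numeric(qtl_geno_of(off) %*% effects_raw)
    phen_prov[off] <- s_q0 * qtl_raw[off] + polygenic[off] + residual[off]

    if (g < n_gen) {
      n_rep_s <- round(config$sire_replacement * config$n_sires)
      n_rep_d <- round(config$dam_replacement * config$n_dams)
      young_m <- off[sex[off] == "M"]; young_f <- off[sex[off] == "F"]
      if (length(young_m) < n_rep_s || length(young_f) < n_rep_d) {
        stop("not enough offspring of the required sex for replacement in generation ", g)
      }
      keep_s <- if (n_rep_s > 0) sample(sires, config$n_sires - n_rep_s) else sires
      keep_d <- if (n_rep_d > 0) sample(dams, config$n_dams - n_rep_d) else dams
      sires <- c(keep_s, if (n_rep_s > 0) sample(young_m, n_rep_s))
      dams <- c(keep_d, if (n_rep_d > 0) sample(young_f, n_rep_d))
    }
    next_id <- next_id + n_off_gen
  }

  genotyped <- generation > (n_gen - config$n_genotyped_generations) & generation > 0L
  pedigree <- tibble::tibble(
    id = seq_len(n_total), sire = sire_of, dam = dam_of, sex = sex,
    generation = generation, genotyped = genotyped)
  structure(list(pedigree = pedigree, loci = loci, blocks = blocks,
                 block_of = block_of, idx_in_block = idx_in_block,
                 effects_raw = effects_raw,
                 polygenic_raw = polygenic, residual = residual,
                 qtl_raw = qtl_raw, phen_prov = phen_prov, config = config),
            class = "sim_population")
}

# gather haplotype columns (2 per individual) across generation blocks,
# restricted to locus rows `rows`; returns loci x 2*length(ids) raw matrix
gather_haps <- function(blocks, block_of, idx_in_block, ids, rows) {
  out <- matrix(as.raw(0), nrow = length(rows), ncol = 2L * length(ids))
  for (b in unique(block_of[ids])) {
    in_b <- which(block_of[ids] == b)
    src <- idx_in_block[ids[in_b]]
    src_cols <- as.vector(rbind(2L * src - 1L, 2L * src))
    dst_cols <- as.vector(rbind(2L * in_b - 1L, 2L * in_b))
    out[, dst_cols] <- blocks[[b]][rows, src_cols, drop = FALSE]
  }
  out
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population> ", nrow(x$pedigree), " individuals (",
      sum(x$pedigree$genotyped), " genotyped), ", nrow(x$loci), " loci\n", sep = "")
  invisible(x)
}

#' Extract genotypes from a simulated population
#'
#' @param pop a `sim_population`.
#' @param ids individual ids (default: all genotyped animals).
#' @param type `"snp"`, `"qtl"` or `"all"` loci.
#' @return Integer matrix, individuals x loci, with ids as rownames and
#'   locus names as colnames.
#' @export
pop_genotypes <- function(pop, ids = NULL, type = c("snp", "qtl", "all")) {
  stopifnot(inherits(pop, "sim_population"))
  type <- match.arg(type)
  if (is.null(ids)) ids <- pop$pedigree$id[pop$pedigree$genotyped]
  rows <- if (type == "all") seq_len(nrow(pop$loci)) else which(pop$loci$type == type)
  haps <- gather_haps(pop$blocks, pop$block_of, pop$idx_in_block, ids, rows)
  G <- cpp_genotypes(haps, seq_along(ids) - 1L)
  dimnames(G) <- list(as.character(ids), pop$loci$locus[rows])
  G
}

#' Genotype matrix of the SNP panel
#'
#' @param pop a `sim_population`.
#' @param ids individual ids (default: all genotyped animals).
#' @return A [genotype_matrix()] over the SNP loci.
#' @export
as_genotype_matrix <- function(pop, ids = NULL) {
  G <- pop_genotypes(pop, ids = ids, type = "snp")
  snps <- pop$loci[pop$loci$type == "snp", ]
  genotype_matrix(G, tibble::tibble(marker = snps$locus, chrom = snps$chrom,
                                    bp = snps$bp))
}

#' Assign and scale QTL effects
#'
#' Raw effects (gamma shape 0.4, random sign, drawn in
#' [simulate_recent()]) are rescaled so that the sample variance of the QTL
#' genetic score over the genotyped animals equals
#' `h2_qtl * var_phenotypic` exactly.
#'
#' @param pop a `sim_population`.
#' @param config a [sim_config()] (defaults to the one stored in `pop`).
#' @return Tibble `locus`, `chrom`, `bp`, `effect` for each QTL.
#' @export
assign_effects <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "sim_population"))
  qtl <- pop$loci[pop$loci$type == "qtl", ]
  gt <- pop$pedigree$genotyped
  if (!any(gt)) stop("no genotyped animals")
  if (config$h2_qtl == 0 || nrow(qtl) == 0) {
    return(tibble::tibble(locus = qtl$locus, chrom = qtl$chrom, bp = qtl$bp,
                          effect = rep(0, nrow(qtl))))
  }
  v <- var(pop$qtl_raw[gt])
  if (!isTRUE(v > 0)) {
    stop("degenerate simulation: all QTLs monomorphic among genotyped animals, ",
         "cannot scale effects")
  }
  scale <- sqrt(config$h2_qtl * config$var_phenotypic / v)
  tibble::tibble(locus = qtl$locus, chrom = qtl$chrom, bp = qtl$bp,
                 effect = pop$effects_raw * scale)
}

#' Compute recorded phenotypes
#'
#' `y = QTL score + polygenic value + residual`.  The QTL score uses the
#' scaled effects from [assign_effects()]; the polygenic realization
#' (founders `N(0, (h2_total - h2_qtl) var_phenotypic)`, offspring parent
#' mean plus a Mendelian-sampling deviate of half the founder variance) is
#' then calibrated so the genotyped cohort realizes the stated orthogonal
#' variance decomposition exactly: the polygenic score is residualized on
#' the QTL score (assortative mating induces a positive covariance between
#' the two that would otherwise double-count heritability) and scaled to
#' variance `(h2_total - h2_qtl) * var_phenotypic`.  Residuals are i.i.d.
#' `N(0, (1 - h2_total) var_phenotypic)`.
#'
#' @param pop a `sim_population`.
#' @param effects tibble from [assign_effects()].
#' @param config a [sim_config()] (defaults to the one stored in `pop`).
#' @return `pop` with pedigree columns `qtl_score`, `tbv` (true breeding
#'   value) and `phenotype` filled in.
#' @export
compute_phenotypes <- function(pop, effects, config = pop$config) {
  stopifnot(inherits(pop, "sim_population"))
  gt <- pop$pedigree$genotyped
  v_raw <- var(pop$qtl_raw[gt])
  s_q <- if (config$h2_qtl > 0 && isTRUE(v_raw > 0)) {
    sqrt(config$h2_qtl * config$var_phenotypic / v_raw)
  } else 0
  Q <- s_q * pop$qtl_raw
  targetP <- (config$h2_total - config$h2_qtl) * config$var_phenotypic
  if (targetP > 0) {
    gamma <- if (isTRUE(var(Q[gt]) > 0)) {
      cov(pop$polygenic_raw[gt], Q[gt]) / var(Q[gt])
    } else 0
    P_adj <- pop$polygenic_raw - gamma * Q
    vP_hat <- var(P_adj[gt])
    if (!isTRUE(vP_hat > 0)) stop("degenerate polygenic realization")
    P <- sqrt(targetP / vP_hat) * P_adj
  } else {
    P <- rep(0, length(Q))
  }
  pop$pedigree$qtl_score <- Q
  pop$pedigree$tbv <- Q + P
  pop$pedigree$phenotype <- Q + P + pop$residual
  pop$effects <- effects
  pop
}

#' Simulate a full population
#'
#' Chains [place_loci()], [simulate_historical()], [simulate_recent()],
#' [assign_effects()] and [compute_phenotypes()] under the config seed.
#'
#' @param config a [sim_config()].
#' @return A `sim_population` with phenotypes and a `qtl_map` element
#'   (tibble `locus`, `chrom`, `bp`, `effect`).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  loci <- place_loci(config)
  founders <- simulate_historical(loci, config)
  pop <- simulate_recent(founders, config)
  effects <- assign_effects(pop, config)
  pop <- compute_phenotypes(pop, effects, config)
  pop$qtl_map <- effects
  pop
}

#' Randomly subsample genotyped animals
#'
#' @param pop a `sim_population` with phenotypes.
#' @param n sample size (at most the number of genotyped animals).
#' @param seed optional seed for reproducible draws.
#' @return List with `geno` (a [genotype_matrix()]) and `pheno` (tibble
#'   `id`, `sex`, `generation`, `phenotype`).
#' @export
subsample_population <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  if (!"phenotype" %in% names(pop$pedigree)) {
    stop("phenotypes not computed; run compute_phenotypes() first")
  }
  if (!is.null(seed)) set.seed(seed)
  gt_ids <- pop$pedigree$id[pop$pedigree$genotyped]
  if (n > length(gt_ids)) {
    stop("n (", n, ") exceeds the genotyped count (", length(gt_ids), ")")
  }
  ids <- sort(sample(gt_ids, n))
  ped <- pop$pedigree[match(ids, pop$pedigree$id), ]
  list(geno = as_genotype_matrix(pop, ids = ids),
       pheno = tibble::tibble(id = as.character(ids), sex = ped$sex,
                              generation = ped$generation,
                              phenotype = ped$phenotype))
}
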