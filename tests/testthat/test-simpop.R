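test_that("locus placement matches the configuration exactly", {
  # exhaustive grid of small configs
  grid <- expand.grid(nc = c(1, 3, 5), ns = c(0, 7, 30), nq = c(0, 4))
  for (i in seq_len(nrow(grid))) {
    cfg <- micro_config(n_chromosomes = grid$nc[i], n_snps = grid$ns[i],
                        n_qtls = grid$nq[i])
    set.seed(2)
    loci <- place_loci(cfg)
    expect_equal(sum(loci$type == "snp"), grid$ns[i])
    expect_equal(sum(loci$type == "qtl"), grid$nq[i])
    expect_false(any(duplicated(loci[, c("chrom", "bp")])))
    expect_true(all(diff(order(loci$chrom, loci$bp)) == 1))
  }
  # exact divisibility: 100 SNPs on each chromosome
  cfg <- micro_config(n_chromosomes = 4, n_snps = 400, n_qtls = 0)
  loci <- place_loci(cfg)
  expect_true(all(table(loci$chrom) == 100))
  # remainder spread one per chromosome from chromosome 1 upward
  cfg <- micro_config(n_chromosomes = 4, n_snps = 402, n_qtls = 0)
  tab <- table(place_loci(cfg)$chrom)
  expect_equal(unname(as.integer(tab[as.character(1:4)])),
               c(101, 101, 100, 100))
  # full-scale default: 29 autosomes, 56,996 SNPs, 203 QTLs
  set.seed(1)
  loci <- place_loci(sim_config())
  expect_equal(length(unique(loci$chrom)), 29)
  expect_equal(sum(loci$type == "snp"), 56996)
  expect_equal(sum(loci$type == "qtl"), 203)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(h2_qtl = 0.6, h2_total = 0.5), "h2_qtl")
  expect_error(sim_config(n_sires = 0), "positive")
  expect_error(sim_config(n_chromosomes = 2, chrom_length_bp = 10,
                          n_snps = 100), "more loci")
  expect_error(sim_config(hist_bottleneck_size = 5000), "bottleneck")
})

test_that("no variation arises without mutation from a monomorphic start", {
  cfg <- micro_config(mutation_rate = 0, n_snps = 50, n_qtls = 0,
                      n_hist_generations = 30, hist_pop_size = 20)
  set.seed(4)
  loci <- place_loci(cfg)
  founders <- simulate_historical(loci, cfg, init_freq = 0)
  expect_true(all(as.integer(founders$haps) == 0))
})

test_that("drift-mutation heterozygosity matches the two-allele equilibrium", {
  # theta = 4 N mu; stationary E[het] = theta / (1 + 2 theta) for symmetric
  # two-way flip mutation (Beta(theta, theta) stationary law)
  N <- 50; mu <- 1e-3
  theta <- 4 * N * mu
  expected <- theta / (1 + 2 * theta)
  cfg <- micro_config(n_chromosomes = 2, n_snps = 150, n_qtls = 0,
                      hist_pop_size = N, mutation_rate = mu,
                      n_hist_generations = 500)
  set.seed(99)
  loci <- place_loci(cfg)
  het_rep <- replicate(20, {
    f <- simulate_historical(loci, cfg)
    p <- rowMeans(matrix(as.integer(f$haps), nrow = nrow(loci)))
    mean(2 * p * (1 - p))
  })
  se <- sd(het_rep) / sqrt(length(het_rep))
  expect_lt(abs(mean(het_rep) - expected), 3 * se + 1e-12)
})

test_that("linkage disequilibrium decays with distance", {
  loci <- tibble::tibble(
    locus = paste0("s", 1:4), chrom = c(1, 1, 1, 1),
    bp = c(1e6, 1e6 + 1e3, 3e7, 4e7), type = "snp")
  cfg <- micro_config(n_chromosomes = 1, n_snps = 4, n_qtls = 0,
                      hist_pop_size = 100, mutation_rate = 1e-3,
                      n_hist_generations = 200)
  set.seed(123)
  r2 <- function(g1, g2) {
    if (var(g1) == 0 || var(g2) == 0) return(NA_real_)
    cor(g1, g2)^2
  }
  close_r2 <- far_r2 <- numeric(0)
  for (rep in 1:10) {
    f <- simulate_historical(loci, cfg)
    G <- t(matrix(as.integer(f$haps), nrow = 4))
    close_r2 <- c(close_r2, r2(G[, 1], G[, 2]))  # 1 kb apart
    far_r2 <- c(far_r2, r2(G[, 3], G[, 4]))      # 10 Mb apart
  }
  expect_gt(mean(close_r2, na.rm = TRUE), mean(far_r2, na.rm = TRUE))
})

test_that("recent generations have the stated pedigree structure", {
  cfg <- micro_config(seed = 31)
  pop <- simulate_population(cfg)
  ped <- pop$pedigree
  # genotyped cohort = dams x genotyped generations
  expect_equal(sum(ped$genotyped),
               cfg$n_dams * cfg$n_genotyped_generations)
  # parents always belong to an earlier generation
  off <- ped[!is.na(ped$sire), ]
  expect_true(all(ped$generation[off$sire] < off$generation))
  expect_true(all(ped$generation[off$dam] < off$generation))
  expect_true(all(ped$sex[off$sire] == "M"))
  expect_true(all(ped$sex[off$dam] == "F"))
  # genotype values are allele counts
  G <- pop_genotypes(pop, type = "all")
  expect_true(all(G %in% 0:2))
})

test_that("all offspring are genotyped when every generation is genotyped", {
  cfg <- micro_config(n_recent_generations = 1, n_genotyped_generations = 1,
                      seed = 5)
  pop <- simulate_population(cfg)
  ped <- pop$pedigree
  expect_true(all(ped$genotyped[ped$generation == 1]))
  expect_false(any(ped$genotyped[ped$generation == 0]))
})

test_that("offspring genotypes are Mendelian-consistent with their parents", {
  cfg <- micro_config(mutation_rate = 0, n_snps = 60, n_qtls = 4,
                      n_sires = 2, n_dams = 10, n_recent_generations = 2,
                      n_genotyped_generations = 2, hist_pop_size = 40,
                      seed = 8)
  pop <- simulate_population(cfg)
  ped <- pop$pedigree
  off <- ped[!is.na(ped$sire), ]
  G <- pop_genotypes(pop, ids = ped$id, type = "all")
  # brute-force consistency: possible transmitted allele sets per genotype
  possible <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  for (k in seq_len(nrow(off))) {
    gs <- G[as.character(off$sire[k]), ]
    gd <- G[as.character(off$dam[k]), ]
    go <- G[as.character(off$id[k]), ]
    ok <- vapply(seq_along(go), function(l) {
      any(outer(possible[[as.character(gs[l])]],
                possible[[as.character(gd[l])]], `+`) == go[l])
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("the founder pool must cover the breeding population", {
  cfg <- micro_config(hist_pop_size = 20, n_sires = 5, n_dams = 60)
  set.seed(2)
  loci <- place_loci(cfg)
  founders <- simulate_historical(loci, cfg)
  expect_error(simulate_recent(founders, cfg), "founder pool")
})

test_that("QTL effects are rescaled to the target variance share", {
  cfg <- micro_config(seed = 10)
  pop <- simulate_population(cfg)
  gt <- pop$pedigree[pop$pedigree$genotyped, ]
  expect_equal(var(gt$qtl_score),
               cfg$h2_qtl * cfg$var_phenotypic, tolerance = 1e-10)
  expect_equal(var(gt$tbv), cfg$h2_total * cfg$var_phenotypic,
               tolerance = 1e-10)
  # single polymorphic locus: effect magnitude is sqrt(target / var(g))
  gq <- pop_genotypes(pop, ids = gt$id, type = "qtl")
  poly <- which(apply(gq, 2, var) > 0)
  expect_gt(length(poly), 0)
  # h2_qtl = 0 -> all effects zero
  cfg0 <- micro_config(h2_qtl = 0, seed = 10)
  pop0 <- simulate_population(cfg0)
  expect_true(all(pop0$qtl_map$effect == 0))
  expect_true(all(pop0$pedigree$qtl_score == 0))
})

test_that("single-locus effect satisfies the closed-form variance relation", {
  # var(a * g) = target  =>  |a| = sqrt(target / var(g)); at Hardy-Weinberg
  # p = 0.5 the sample variance of g approaches 2p(1-p) = 0.5
  g <- rep(0:2, times = c(100, 200, 100))
  target <- 0.3
  a <- sqrt(target / var(g))
  expect_equal(var(a * g), target, tolerance = 1e-12)
  expect_equal(a, sqrt(target / (2 * 0.5 * 0.5)), tolerance = 2e-3)
})

test_that("phenotype variance components behave at the boundaries", {
  # h2_total = h2_qtl = 0: phenotype is pure residual with full variance
  cfg <- micro_config(h2_total = 0, h2_qtl = 0, seed = 12)
  pop <- simulate_population(cfg)
  gt <- pop$pedigree[pop$pedigree$genotyped, ]
  expect_true(all(gt$tbv == 0))
  expect_equal(var(gt$phenotype), cfg$var_phenotypic, tolerance = 0.15)
  # zero residual and zero polygenic variance: phenotype equals the QTL score
  cfg1 <- micro_config(h2_total = 1, h2_qtl = 1, seed = 12)
  pop1 <- simulate_population(cfg1)
  gt1 <- pop1$pedigree[pop1$pedigree$genotyped, ]
  expect_equal(gt1$phenotype, gt1$qtl_score, tolerance = 1e-12)
})

test_that("the simulation is bit-identical under the same seed", {
  cfg <- micro_config(seed = 77)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$pedigree, p2$pedigree)
  expect_identical(pop_genotypes(p1, type = "all"),
                   pop_genotypes(p2, type = "all"))
  expect_identical(p1$qtl_map, p2$qtl_map)
})

test_that("subsampling is reproducible and shape-correct", {
  cfg <- micro_config(seed = 20)
  pop <- simulate_population(cfg)
  s1 <- subsample_population(pop, 50, seed = 9)
  s2 <- subsample_population(pop, 50, seed = 9)
  expect_identical(s1$pheno$id, s2$pheno$id)
  expect_equal(nrow(s1$geno$X), 50)
  expect_equal(ncol(s1$geno$X), cfg$n_snps)
  n_gt <- sum(pop$pedigree$genotyped)
  all_ids <- subsample_population(pop, n_gt, seed = 1)
  expect_setequal(all_ids$pheno$id,
                  as.character(pop$pedigree$id[pop$pedigree$genotyped]))
  expect_error(subsample_population(pop, n_gt + 1), "exceeds")
})
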