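#' Flag markers close to a known QTL
#'
#' A marker is "true associated" when a QTL lies on the same chromosome
#' within `window` bp (inclusive) upstream or downstream.
#'
#' @param markers tibble with `marker`, `chrom`, `bp`.
#' @param qtls QTL map tibble with `chrom`, `bp` (and optionally `locus`).
#' @param window half-window in bp (inclusive boundary).
#' @return `markers` with logical column `true_associated`.
#' @export
flag_true_associated <- function(markers, qtls, window = 250000) {
  markers <- tibble::as_tibble(markers)
  qtls <- tibble::as_tibble(qtls)
  flag <- vapply(seq_len(nrow(markers)), function(i) {
    same <- as.character(qtls$chrom) == as.character(markers$chrom[i])
    any(same & abs(qtls$bp - markers$bp[i]) <= window)
  }, logical(1))
  dplyr::mutate(markers, true_associated = flag)
}

#' QTLs detected by a marker set
#'
#' A QTL counts as detected when at least one marker of the set lies within
#' the window; each QTL is counted once however many markers hit it.
#'
#' @inheritParams flag_true_associated
#' @return Character vector of detected QTL ids.
#' @export
count_detected_qtls <- function(markers, qtls, window = 250000) {
  markers <- tibble::as_tibble(markers)
  qtls <- tibble::as_tibble(qtls)
  if (!"locus" %in% names(qtls)) qtls$locus <- paste0("qtl", seq_len(nrow(qtls)))
  hit <- vapply(seq_len(nrow(qtls)), function(j) {
    same <- as.character(markers$chrom) == as.character(qtls$chrom[j])
    any(same & abs(markers$bp - qtls$bp[j]) <= window)
  }, logical(1))
  qtls$locus[hit]
}

#' QTLs detected by both of two methods
#'
#' @param setA,setB detected-QTL id vectors.
#' @return Count of the intersection.
#' @export
common_qtls <- function(setA, setB) length(intersect(setA, setB))

#' Scaled simulation experiment comparing the two association methods
#'
#' For each replicate a population is simulated under `config` (independent
#' seeds derived from `seed`), phenotypes are pre-adjusted on the full
#' genotyped cohort with the mixed model (generation and sex fixed, genomic
#' animal effect), and for each sample size a random sub-dataset is drawn,
#' split into LP/HP groups, and analyzed by both the multivariate pipeline
#' and the single-marker comparator; associated markers are scored against
#' the known QTL positions.  Stage failures are recorded per cell and the
#' run continues.
#'
#' @param config a [sim_config()] (typically [scaled_sim_config()]).
#' @param sizes sub-dataset sample sizes.
#' @param replicates number of independent simulation replicates.
#' @param seed master seed; replicate r uses `seed + r - 1`.
#' @param window QTL detection window in bp.
#' @param alpha,cnc_top,n_pcs,fdr method parameters, passed through.
#' @param ... further arguments to [run_mgwas()].
#' @return An `mgwas_experiment`: `results` (one row per replicate, size and
#'   method: associated/true-associated marker counts and detected QTLs),
#'   `common` (per replicate and size, QTLs found by both methods), and
#'   `summary` (medians across replicates).
#' @export
run_experiment <- function(config, sizes = c(250, 500, 750),
                           replicates = 5, seed = 1, window = 250000,
                           alpha = 0.001, cnc_top = 0.25, n_pcs = 10,
                           fdr = 0.05, ...) {
  rows <- list(); commons <- list()
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r - 1)
    pop <- simulate_population(cfg)
    gt <- pop$pedigree[pop$pedigree$genotyped, ]
    pheno_full <- tibble::tibble(id = as.character(gt$id),
                                 generation = gt$generation, sex = gt$sex,
                                 phenotype = gt$phenotype)
    geno_full <- as_genotype_matrix(pop)
    lmm <- fit_lmm(pheno_full, geno_full, response = "phenotype",
                   fixed = c("generation", "sex"))
    resid_full <- tidy(lmm)
    qtls <- pop$qtl_map
    for (n in sizes) {
      # derived sub-seed, kept inside the 32-bit integer range
      set.seed((cfg$seed %% 1000000L) * 1000L + n)
      ids <- sort(sample(resid_full$id, n))
      groups <- split_groups(resid_full[resid_full$id %in% ids, ])
      geno_sub <- subset_genotypes(geno_full, ids = ids)
      det <- list(mgwas = character(0), tgwas = character(0))

      m_row <- tryCatch({
        mg <- run_mgwas(geno_sub, groups, alpha = alpha, cnc_top = cnc_top, ...)
        assoc <- flag_true_associated(mg$stages$minimal, qtls, window)
        det$mgwas <- count_detected_qtls(assoc, qtls, window)
        tibble::tibble(replicate = r, n = n, method = "mgwas",
                       n_associated = nrow(assoc),
                       n_true = sum(assoc$true_associated),
                       n_qtls_detected = length(det$mgwas),
                       p.value = mg$test$p.value, accuracy = mg$accuracy,
                       status = "ok")
      }, error = function(e) {
        tibble::tibble(replicate = r, n = n, method = "mgwas",
                       n_associated = 0L, n_true = 0L, n_qtls_detected = 0L,
                       p.value = NA_real_, accuracy = NA_real_,
                       status = conditionMessage(e))
      })
      t_row <- tryCatch({
        scan <- run_tgwas(groups, geno_sub, n_pcs = n_pcs, fdr = fdr)
        sig <- scan[scan$significant, c("marker", "chrom", "bp")]
        assoc <- flag_true_associated(sig, qtls, window)
        det$tgwas <- count_detected_qtls(assoc, qtls, window)
        tibble::tibble(replicate = r, n = n, method = "tgwas",
                       n_associated = nrow(assoc),
                       n_true = sum(assoc$true_associated),
                       n_qtls_detected = length(det$tgwas),
                       p.value = NA_real_, accuracy = NA_real_, status = "ok")
      }, error = function(e) {
        tibble::tibble(replicate = r, n = n, method = "tgwas",
                       n_associated = 0L, n_true = 0L, n_qtls_detected = 0L,
                       p.value = NA_real_, accuracy = NA_real_,
                       status = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- dplyr::bind_rows(m_row, t_row)
      commons[[length(commons) + 1L]] <- tibble::tibble(
        replicate = r, n = n, common_qtls = common_qtls(det$mgwas, det$tgwas))
    }
  }
  results <- dplyr::bind_rows(rows)
  common <- dplyr::bind_rows(commons)
  summary <- results |>
    dplyr::group_by(.data$n, .data$method) |>
    dplyr::summarise(
      n_associated = stats::median(.data$n_associated),
      n_true = stats::median(.data$n_true),
      n_qtls_detected = stats::median(.data$n_qtls_detected),
      replicates = dplyr::n(), .groups = "drop")
  structure(list(results = results, common = common, summary = summary,
                 sizes = sizes, replicates = replicates, seed = seed),
            class = "mgwas_experiment")
}

#' @export
print.mgwas_experiment <- function(x, ...) {
  cat("<mgwas_experiment> ", x$replicates, " replicate(s), sizes ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.mgwas_experiment <- function(x, ...) x$results

#' @export
glance.mgwas_experiment <- function(x, ...) x$summary
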