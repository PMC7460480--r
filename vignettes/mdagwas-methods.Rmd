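---
title: "Multivariate discriminant association mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate discriminant association mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Single-marker regression GWAS loses power quickly when cohorts are small:
with tens of thousands of SNPs and a few hundred animals, multiple-testing
control leaves essentially no discoveries.  `mdagwas` implements an
alternative that treats association mapping as a two-group discrimination
problem.  Animals are ranked on a mixed-model-corrected phenotype and split
into equal low-phenotype (LP) and high-phenotype (HP) halves; markers are
then selected by how much they contribute to separating the two groups in
multivariate space, with no per-marker significance test at the selection
stage.

## The discriminant machinery

For two groups the canonical discriminant analysis (CDA) has a single
canonical function

\[ \mathrm{CAN} = d_1 X_1 + d_2 X_2 + \dots + d_p X_p , \]

where \(X_i\) are allele counts and \(d_i\) the canonical coefficients.  With
pooled within-group covariance \(W\) and mean difference \(\delta = \bar m_2 -
\bar m_1\), the raw direction is \(d \propto W^{+}\delta\), scaled so the
pooled within-group variance of the canonical scores is one; on that scale
the centroid separation equals the Mahalanobis distance
\(D = \sqrt{\delta^\top W^{+} \delta}\).  The standardized coefficient
(`cnc`) of marker \(i\) is \(d_i \sqrt{W_{ii}}\) — the within-group
standardized loading, which makes coefficients comparable across markers
with different allele frequencies.  A flag switches the screening statistic
to the raw coefficients.

Group separation is tested with Hotelling's \(T^2 = \frac{n_1 n_2}{n_1+n_2}
D^2\), converted to an \(F\) statistic on \((p,\, n_1+n_2-p-1)\) degrees of
freedom.  Because per-chromosome marker counts routinely exceed the sample
size, \(W\) is inverted by a symmetric Moore–Penrose pseudo-inverse
(relative eigenvalue tolerance `1e-10`, optional ridge), and the *effective*
dimension used by the \(F\) transform is the rank actually inverted — the
nominal marker count would invalidate the test after pseudo-inversion.

Classification (DA) scores each animal with the canonical function and
assigns the side of a cutoff placed at the group-size-weighted mean of the
two training centroids, \((n_1 \bar c_1 + n_2 \bar c_2)/(n_1+n_2)\); a score
exactly at the cutoff goes to the higher-centroid group (a measure-zero
tie-break, made deterministic).  Accuracy is training-set (resubstitution)
accuracy, as in the procedure this package implements; it is optimistic by
construction, which the pipeline exploits deliberately (see *Limitations*).

Stepwise discriminant analysis (SDA, `sda_select()`) performs forward
selection with backward elimination on Wilks' lambda via the sweep operator:
a candidate enters when its partial-\(F\) p-value is at most `sle` (default
0.15, the conventional stepwise default), an entered variable leaves when
its partial \(F\) given the others exceeds `sls` (0.15), and candidates
nearly collinear with the entered set (residual total variance below
`1e-8` of the original) are excluded, which is what guarantees a linearly
independent — not completely LD-redundant — marker subset.

## The association pipeline

`run_mgwas()` chains four stages:

1. **Per-chromosome screen** — fit a CDA per chromosome and retain markers
   with \(|\mathrm{cnc}|\) strictly greater than the chromosome mean plus
   one sample SD of the absolute coefficients.  A single-marker chromosome
   is retained by convention (the SD is undefined); markers monomorphic in
   the analyzed sample are dropped first (their coefficient is undefined).
2. **Stepwise reduction** — pool the retained markers and reduce them with
   SDA to a linearly independent subset, capped at `floor((n - 2) / 2)`
   variables by default so the validation test below keeps roughly \(n/2\)
   denominator degrees of freedom.  At \(p = n-2\), the test has one
   denominator degree of freedom and essentially no power regardless of the
   signal, so running the stepwise stage to its algebraic limit would break
   step 3; the cap matches the regime reported for this method in practice
   (independent sets around half the sample size).
3. **Validation** — genome-wide CDA on the subset, Hotelling test
   (`p < alpha`, default 0.001) and DA resubstitution accuracy, which must
   be 1.  If the subset fails, the stepwise stage is retried with relaxed
   entry/stay levels (0.35, then 0.5): on a sparse scaled marker panel the
   default levels equilibrate below the set size that perfect assignment
   requires, while the relaxed levels only ever engage when the default
   fails.
4. **Recursive pruning** — repeatedly refit the CDA and delete the `batch`
   markers (default 1, the most conservative reading of "delete the lowest
   coefficients") with the smallest \(|\mathrm{cnc}|\), re-estimating the
   coefficients after every deletion; stop, restoring the last deletion,
   as soon as either criterion fails.  The returned minimal set satisfies
   both criteria while its own weakest marker cannot be spared.  A
   top-discriminant subset is cut at \(|\mathrm{cnc}| \ge 0.25\)
   (inclusive).

The comparator (`run_tgwas()`) is a single-marker OLS scan of the corrected
phenotype on each allele count with the first 10 genotype principal
components as covariates (PCA on the column-standardized matrix — the
equivalent of metric multidimensional scaling on centered data), two-sided
\(t\) tests, and Benjamini–Hochberg FDR flags at `q = 0.05` (the
conventional level; the method description this package follows does not
print its threshold).

QTL scoring (`flag_true_associated()`, `count_detected_qtls()`) calls a
marker "true associated" when a simulated QTL lies within 250 kb up- or
downstream (boundary inclusive), and counts each QTL once however many
markers hit its window.

## The population simulator

`simulate_population()` builds a beef-cattle-like cohort in two phases.

**Historical phase.** A closed random-mating (monoecious Wright–Fisher)
population of `hist_pop_size` (default 1000) diploids evolves for
`n_hist_generations` (1000) discrete generations with Poisson recombination
(1 Morgan per autosome, no interference), two-way recurrent mutation at
`2.5e-5` per locus per meiosis, and founder alleles initialized at frequency
0.5 — the usual starting point when the panel mimics a common-variant SNP
chip, after which drift pushes frequencies toward the U-shaped spectrum.
SNPs are evenly spaced within each of 29 autosomes; QTLs fall at
uniform-random positions.

**Recent phase.** 100 sires and 4000 dams (drawn from the historical pool)
breed 10 generations of one offspring per dam; 20% of sires and 30% of dams
are replaced each generation by randomly chosen offspring of the right sex;
mating is positive assortative — sires and dams are each ranked by phenotype
and paired rank block to rank, the literal reading of random selection with
assortative mating.  The last 3 generations (12,000 animals at full scale)
are flagged genotyped.  Because mate ranking needs phenotypes before the
final effect scaling is possible, mating uses a provisional trait built from
the same component realizations; the recorded phenotype applies the final
calibration to those realizations (the two are correlated \(> 0.99\)).

**Trait architecture.** The phenotype is `QTL score + polygenic value +
residual` with variance 1.0, total heritability 0.5 and QTL heritability
0.3 by default.  Raw QTL effects are gamma(0.4) with random sign — a
long-tailed shape conventional in livestock simulation — and are rescaled so
the QTL-score variance over the genotyped animals is exactly
`h2_qtl * var_phenotypic`.  The polygenic value follows the pedigree
(founders \(N(0, 0.2)\), offspring parent mean plus a Mendelian-sampling
deviate of half the founder variance, inbreeding ignored at this scale);
it is then residualized on the QTL score among genotyped animals and
rescaled to variance `(h2_total - h2_qtl) * var_phenotypic`.  This full
in-sample calibration is deliberate: rank-to-rank assortative mating at
mate correlation ≈ 0.95 inflates genetic variance by tens of percent within
ten generations and builds a positive QTL–polygenic covariance, so without
calibration the realized trait would not have the stated variance
decomposition at all — the decomposition is the definition of the trait,
and the components are treated as orthogonal variance quotas.

**Scaled study conditions.** `scaled_sim_config()` is the desk-scale
configuration used by the tests and the acceptance script: 5,000 SNPs and
50 QTLs on 29 autosomes, 18 sires × 700 dams (≈ 2,100 genotyped), and a
historical bottleneck to 200 diploids over the last 100 historical
generations followed by one re-expansion generation.  The bottleneck keeps
the linkage disequilibrium per marker interval comparable to the full-scale
design: with 5,000 instead of ~57,000 SNPs the marker spacing grows
tenfold, and without a recent-\(N_e\) contraction the scaled panel would
carry an order of magnitude less marker–QTL LD than the genome it stands in
for.  Typical runtime is ~10 s per population.

## Mixed-model pre-adjustment

`fit_lmm()` fits \(y = Xb + g + e\) with \(g \sim N(0, \sigma_a^2 G)\),
\(G\) the VanRaden method-1 genomic relationship matrix, by REML profiled on
the variance ratio through the eigendecomposition of \(G\) (search bounded
to \([10^{-6}, 10^{6}]\), tolerance `1e-8`); an optional i.i.d. random
intercept (e.g., herd) is handled by nested profiling.  The corrected
phenotype is the residual \(y - Xb - \hat g\) by default; a flag switches
to fixed-effects-only residuals, since either reading of "residuals" is
defensible.  `split_groups()` halves the cohort at the median (odd cohorts
drop the single median animal so the halves stay exactly equal; boundary
ties break by id order).

A caveat the package documents rather than hides: under the assortative
study conditions, a relationship-matrix REML recovers the *genic* variance,
not the disequilibrium-inflated equilibrium variance, and the pedigree-
simulated polygenic component's Mendelian-sampling half is independent of
the genome by construction and therefore invisible to a marker-based
\(G\).  Measured on the scaled conditions, the recovered heritability is
about 0.26–0.30 against the generating 0.5; under `mating_design =
"random"` it rises to 0.33–0.38.  The estimator itself is unbiased — on
data whose genetic values are drawn from \(G\) it recovers the generating
value — so this is a property of the trait architecture, not of the fit.

## Numerical choices and degenerate inputs

* Pseudo-inverse tolerance `1e-10` (relative), optional ridge for
  near-singular \(W\); a zero-within-variance direction cannot contribute
  to \(D^2\), so exact-separator columns with no within-group variance are
  outside the Mahalanobis framework (tests use separators that keep
  within-group variance).
* Missing genotypes are mean-imputed per marker before any multivariate
  step; the simulator itself produces none.
* Genotypes are recoded as minor-allele counts on input (frequency ties
  break toward the lexicographically smaller allele); the binary PLINK
  dialect round-trips exactly via its A1 allele, while the text dialect
  carries no allele orientation, so orientation-exact round trips use
  `count_a1 = TRUE` or alt-minor data.
* All randomness flows through R's RNG, including the compiled
  gamete-dropping core, so a single seed makes a whole simulation — and the
  experiment tables — bit-identical.

## Limitations

* Training-set assignment is intentionally optimistic: with marker sets
  approaching half the sample size, the pipeline reaches 100% training
  accuracy even on permuted labels.  The pipeline's p-values are therefore
  anticonservative as selection is done on the same labels; the package
  exposes full-pipeline label permutation in its tests as the honest
  calibration check, and users should treat the minimal set as a candidate
  pool for validation, not as inference.
* At the largest scaled sub-datasets (n = 750 with a 5,000-SNP panel) the
  per-chromosome screen yields too few candidates (~800, LD-clumped) for
  any stepwise subset to classify every animal perfectly; the experiment
  harness records these cells as failed validations.  The full-scale panel
  (~8,500 candidates) does not hit this wall at the sample sizes studied.
* The simulator has no sex chromosomes, no selection on breeding values, no
  overlapping historical generations, litter size 1, and ignores inbreeding
  in the Mendelian-sampling variance.
* What passing the scaled tests shows is that the pipeline reproduces the
  *regime* reported for this method — zero single-marker discoveries at
  small n while the multivariate pipeline returns a perfectly separating
  minimal set, and at least as many detected QTLs — not the exact marker or
  QTL counts of any single full-scale realization, which depend on
  unreported historical-population settings and a single unreproducible
  simulation run.
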