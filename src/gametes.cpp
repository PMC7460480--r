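#include <Rcpp.h>
#include <cstring>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Haplotypes are stored locus-major: a RawMatrix with one row per locus and
// one column per haplotype, so a haplotype is a contiguous block of memory.
// Genetic positions are in Morgans within chromosome; chrom_begin/chrom_end
// give 0-based [begin, end) locus ranges per chromosome.  All randomness
// comes from R's RNG so set.seed() governs the whole simulation.

static void drop_gamete(const unsigned char* h0, const unsigned char* h1,
                        unsigned char* out, const double* gpos,
                        const int* cbeg, const int* cend, int n_chr,
                        double chr_morgans, double mu, int n_loci) {
  std::vector<double> bks;
  for (int c = 0; c < n_chr; ++c) {
    int b = cbeg[c], e = cend[c];
    if (b >= e) continue;
    int k = (int) R::rpois(chr_morgans);
    bks.clear();
    for (int i = 0; i < k; ++i) bks.push_back(unif_rand() * chr_morgans);
    std::sort(bks.begin(), bks.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int seg = b;
    for (size_t i = 0; i < bks.size(); ++i) {
      // first locus index at or beyond the breakpoint
      const double* lo = std::lower_bound(gpos + seg, gpos + e, bks[i]);
      int cut = (int)(lo - gpos);
      if (cut > seg) {
        std::memcpy(out + seg, (cur ? h1 : h0) + seg, cut - seg);
        seg = cut;
      }
      cur ^= 1;
    }
    if (seg < e)
      std::memcpy(out + seg, (cur ? h1 : h0) + seg, e - seg);
  }
  if (mu > 0) {
    int nm = (int) R::rbinom((double) n_loci, mu);
    for (int i = 0; i < nm; ++i) {
      int ix = (int)(unif_rand() * n_loci);
      if (ix >= n_loci) ix = n_loci - 1;
      out[ix] ^= 1;
    }
  }
}

// Evolve a closed random-mating (monoecious, Wright-Fisher) population for
// n_gen discrete generations with recombination and two-way recurrent
// mutation; returns the final generation's haplotypes (loci x 2N).
// [[Rcpp::export]]
RawMatrix cpp_evolve_pool(RawMatrix haps, NumericVector gpos,
                          IntegerVector chrom_begin, IntegerVector chrom_end,
                          double chr_morgans, int n_gen, double mu) {
  int L = haps.nrow();
  int H = haps.ncol();            // 2N haplotypes
  int N = H / 2;
  if (H % 2 != 0) stop("haplotype count must be even");
  int n_chr = chrom_begin.size();
  RawMatrix cur = clone(haps);
  RawMatrix nxt(L, H);
  for (int g = 0; g < n_gen; ++g) {
    unsigned char* curp = (unsigned char*) RAW(cur);
    unsigned char* nxtp = (unsigned char*) RAW(nxt);
    for (int i = 0; i < N; ++i) {
      int s = (int)(unif_rand() * N); if (s >= N) s = N - 1;
      int d = (int)(unif_rand() * N); if (d >= N) d = N - 1;
      drop_gamete(curp + (size_t)(2 * s) * L, curp + (size_t)(2 * s + 1) * L,
                  nxtp + (size_t)(2 * i) * L, REAL(gpos),
                  INTEGER(chrom_begin), INTEGER(chrom_end), n_chr,
                  chr_morgans, mu, L);
      drop_gamete(curp + (size_t)(2 * d) * L, curp + (size_t)(2 * d + 1) * L,
                  nxtp + (size_t)(2 * i + 1) * L, REAL(gpos),
                  INTEGER(chrom_begin), INTEGER(chrom_end), n_chr,
                  chr_morgans, mu, L);
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// One offspring per (sire_ix, dam_ix) pair; indices are 0-based individuals
// in parent_haps (loci x 2P).  Returns loci x (2 * n_off): columns 2i and
// 2i+1 are the paternal and maternal gametes of offspring i.
// [[Rcpp::export]]
RawMatrix cpp_make_offspring(RawMatrix parent_haps,
                             IntegerVector sire_ix, IntegerVector dam_ix,
                             NumericVector gpos,
                             IntegerVector chrom_begin, IntegerVector chrom_end,
                             double chr_morgans, double mu) {
  int L = parent_haps.nrow();
  int n_off = sire_ix.size();
  if (dam_ix.size() != n_off) stop("sire_ix and dam_ix lengths differ");
  int n_chr = chrom_begin.size();
  int P = parent_haps.ncol() / 2;
  RawMatrix out(L, 2 * n_off);
  unsigned char* pp = (unsigned char*) RAW(parent_haps);
  unsigned char* op = (unsigned char*) RAW(out);
  for (int i = 0; i < n_off; ++i) {
    int s = sire_ix[i], d = dam_ix[i];
    if (s < 0 || s >= P || d < 0 || d >= P) stop("parent index out of range");
    drop_gamete(pp + (size_t)(2 * s) * L, pp + (size_t)(2 * s + 1) * L,
                op + (size_t)(2 * i) * L, REAL(gpos),
                INTEGER(chrom_begin), INTEGER(chrom_end), n_chr,
                chr_morgans, mu, L);
    drop_gamete(pp + (size_t)(2 * d) * L, pp + (size_t)(2 * d + 1) * L,
                op + (size_t)(2 * i + 1) * L, REAL(gpos),
                INTEGER(chrom_begin), INTEGER(chrom_end), n_chr,
                chr_morgans, mu, L);
  }
  return out;
}

// Allele-count genotypes (individuals x loci) from locus-major haplotypes.
// [[Rcpp::export]]
IntegerMatrix cpp_genotypes(RawMatrix haps, IntegerVector ind_ix) {
  int L = haps.nrow();
  int n = ind_ix.size();
  IntegerMatrix G(n, L);
  unsigned char* hp = (unsigned char*) RAW(haps);
  for (int i = 0; i < n; ++i) {
    int id = ind_ix[i];
    if (id < 0 || 2 * id + 1 >= haps.ncol()) stop("individual index out of range");
    const unsigned char* h0 = hp + (size_t)(2 * id) * L;
    const unsigned char* h1 = hp + (size_t)(2 * id + 1) * L;
    for (int l = 0; l < L; ++l) G(i, l) = (int) h0[l] + (int) h1[l];
  }
  return G;
}
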