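#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Haplotype storage convention: an L x 2n raw matrix, one locus per row,
// columns 2i-1, 2i (1-based) are the two phased strands of individual i.
// Alleles are 0/1. Columns are contiguous in memory, so a gamete is one
// memcpy per non-recombined segment.

// One meiosis: Haldane model (no interference). Crossover count is
// Poisson(length_cM / 100), breakpoints uniform on (0, length_cM); the
// gamete starts on a random strand and alternates at each breakpoint.
// Mutation then flips Binomial(L, mut_rate) uniformly chosen loci (0 <-> 1).
static inline void make_gamete(const RawMatrix &par, int p,
                               const NumericVector &pos, double len_cM,
                               double mut_rate, RawMatrix &out, int ocol,
                               std::vector<double> &xo) {
  const int L = pos.size();
  const Rbyte *s0 = &par(0, 2 * p);
  const Rbyte *s1 = &par(0, 2 * p + 1);
  Rbyte *g = &out(0, ocol);
  int k = (len_cM > 0.0) ? (int)R::rpois(len_cM / 100.0) : 0;
  int strand = (unif_rand() < 0.5) ? 0 : 1;
  if (k == 0) {
    std::memcpy(g, strand ? s1 : s0, L);
  } else {
    xo.resize(k);
    for (int i = 0; i < k; ++i) xo[i] = unif_rand() * len_cM;
    std::sort(xo.begin(), xo.end());
    int j = 0, s = strand;
    const double *pb = pos.begin();
    for (int i = 0; i <= k; ++i) {
      int j2 = (i < k) ? (int)(std::lower_bound(pb + j, pb + L, xo[i]) - pb)
                       : L;
      if (j2 > j) std::memcpy(g + j, (s ? s1 : s0) + j, j2 - j);
      s ^= 1;
      j = j2;
    }
  }
  if (mut_rate > 0.0) {
    int nm = (int)R::rbinom((double)L, mut_rate);
    for (int i = 0; i < nm; ++i) {
      int j = (int)(unif_rand() * L);
      if (j >= L) j = L - 1;
      g[j] = g[j] ? (Rbyte)0 : (Rbyte)1;
    }
  }
}

// [[Rcpp::export]]
RawMatrix cpp_gametes(RawMatrix parents, IntegerVector parent,
                      NumericVector pos, double length_cM, double mut_rate) {
  const int G = parent.size(), L = pos.size();
  RawMatrix out(L, G);
  std::vector<double> xo;
  for (int g = 0; g < G; ++g)
    make_gamete(parents, parent[g] - 1, pos, length_cM, mut_rate, out, g, xo);
  return out;
}

// Paternal gamete in column 2i-1, maternal in column 2i (1-based).
// [[Rcpp::export]]
RawMatrix cpp_drop_offspring(RawMatrix parents, IntegerVector sire,
                             IntegerVector dam, NumericVector pos,
                             double length_cM, double mut_rate) {
  const int N = sire.size(), L = pos.size();
  RawMatrix out(L, 2 * N);
  std::vector<double> xo;
  for (int i = 0; i < N; ++i) {
    make_gamete(parents, sire[i] - 1, pos, length_cM, mut_rate, out, 2 * i, xo);
    make_gamete(parents, dam[i] - 1, pos, length_cM, mut_rate, out, 2 * i + 1,
                xo);
  }
  return out;
}

// Genotype dosage (0/1/2) for the given loci (1-based row indices).
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(RawMatrix haplo, IntegerVector loci) {
  const int n = haplo.ncol() / 2, m = loci.size();
  IntegerMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const int l = loci[j] - 1;
    int *oc = &out(0, j);
    for (int i = 0; i < n; ++i)
      oc[i] = (int)haplo(l, 2 * i) + (int)haplo(l, 2 * i + 1);
  }
  return out;
}

// Allele-1 frequency per locus.
// [[Rcpp::export]]
NumericVector cpp_allele_freq(RawMatrix haplo) {
  const int L = haplo.nrow(), H = haplo.ncol();
  NumericVector out(L);
  for (int c = 0; c < H; ++c) {
    const Rbyte *col = &haplo(0, c);
    for (int l = 0; l < L; ++l) out[l] += col[l];
  }
  for (int l = 0; l < L; ++l) out[l] /= (double)H;
  return out;
}
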