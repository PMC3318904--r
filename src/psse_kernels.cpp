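#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// 48-bit LCG with the POSIX drand48 family constants.  States are passed to
// and from R as doubles: every value below 2^48 is exactly representable in
// a double, and R has no native 64-bit integer.
static const uint64_t LCG_A = 25214903917ULL;  // 0x5DEECE66D
static const uint64_t LCG_C = 11ULL;
static const uint64_t LCG_MASK = (1ULL << 48) - 1;

static inline uint64_t lcg_step(uint64_t s) {
  return (LCG_A * s + LCG_C) & LCG_MASK;
}

// srand48 convention: state = (seed mod 2^32) << 16 | 0x330E
// [[Rcpp::export]]
double lcg_seed_(double seed_value) {
  uint64_t s = (uint64_t)seed_value;
  s &= 0xFFFFFFFFULL;
  return (double)((s << 16) | 0x330EULL);
}

// one draw: advance the state, emit the top 31 bits (bits 47..17)
// [[Rcpp::export]]
List lcg_next_(double state) {
  uint64_t s = lcg_step((uint64_t)state);
  return List::create(_["state"] = (double)s, _["draw"] = (double)(s >> 17));
}

// [[Rcpp::export]]
List lcg_draws_(double state, int n) {
  uint64_t s = (uint64_t)state;
  NumericVector draws(n);
  for (int i = 0; i < n; ++i) {
    s = lcg_step(s);
    draws[i] = (double)(s >> 17);
  }
  return List::create(_["state"] = (double)s, _["draws"] = draws);
}

// Durstenfeld Fisher-Yates, descending, j = draw mod (i + 1), fresh stream
// seeded with stream_seed.
static void fy_permute(int* idx, int n, double stream_seed) {
  uint64_t s = (uint64_t)lcg_seed_(stream_seed);
  for (int i = n - 1; i >= 1; --i) {
    s = lcg_step(s);
    uint64_t draw = s >> 17;
    int j = (int)(draw % (uint64_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export]]
IntegerVector permute_indices_(int n, double stream_seed) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  fy_permute(idx.data(), n, stream_seed);
  return wrap(idx);
}

// [[Rcpp::export]]
IntegerVector permute_codes_(IntegerVector codes, double stream_seed) {
  std::vector<int> out(codes.begin(), codes.end());
  fy_permute(out.data(), (int)out.size(), stream_seed);
  return wrap(out);
}

static const int NEG_INF = INT_MIN / 4;

// Score-only affine-gap Smith-Waterman (Gotoh), row-major over the subject.
// prof: |alphabet| x L query profile, prof(a, j) = score of subject residue a
// against query position j.  A gap of length k costs open + extend*k, so the
// first gap residue is charged open + extend.
static int sw_core(const int* subj, int n, const IntegerMatrix& prof,
                   int gap_open, int gap_extend) {
  const int L = prof.ncol();
  const int gfirst = gap_open + gap_extend;
  std::vector<int> H(L + 1, 0), F(L + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const int b = subj[i - 1];
    int e = NEG_INF;
    int diag = H[0];  // H[i-1][0] == 0
    for (int j = 1; j <= L; ++j) {
      e = std::max(H[j - 1] - gfirst, e - gap_extend);  // H[j-1] is current row
      const int f = std::max(H[j] - gfirst, F[j] - gap_extend);
      int h = diag + prof(b, j - 1);
      if (h < 0) h = 0;
      if (e > h) h = e;
      if (f > h) h = f;
      diag = H[j];
      H[j] = h;
      F[j] = f;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
int sw_score_(IntegerVector subject_codes, IntegerMatrix profile,
              int gap_open, int gap_extend) {
  return sw_core(INTEGER(subject_codes), subject_codes.size(), profile,
                 gap_open, gap_extend);
}

// Same recurrences evaluated in anti-diagonal (wavefront) order, the
// intra-task schedule: all cells with i + j == d are independent given
// diagonals d-1 and d-2.  Rolling buffers indexed by subject position i.
// [[Rcpp::export]]
int sw_score_wavefront_(IntegerVector subject_codes, IntegerMatrix profile,
                        int gap_open, int gap_extend) {
  const int n = subject_codes.size();
  const int L = profile.ncol();
  const int gfirst = gap_open + gap_extend;
  std::vector<int> H2(n + 1, 0), H1(n + 1, 0), H0(n + 1, 0);
  std::vector<int> E1(n + 1, NEG_INF), E0(n + 1, NEG_INF);
  std::vector<int> F1(n + 1, NEG_INF), F0(n + 1, NEG_INF);
  int best = 0;
  for (int d = 2; d <= n + L; ++d) {
    const int ilo = std::max(1, d - L);
    const int ihi = std::min(n, d - 1);
    std::fill(H0.begin(), H0.end(), 0);
    std::fill(E0.begin(), E0.end(), NEG_INF);
    std::fill(F0.begin(), F0.end(), NEG_INF);
    for (int i = ilo; i <= ihi; ++i) {
      const int j = d - i;
      // cell (i, j-1) lives on diagonal d-1 at index i; j-1 == 0 is boundary
      const int hl = (j >= 2) ? H1[i] : 0;
      const int el = (j >= 2) ? E1[i] : NEG_INF;
      // cell (i-1, j) lives on diagonal d-1 at index i-1; i-1 == 0 is boundary
      const int hu = (i >= 2) ? H1[i - 1] : 0;
      const int fu = (i >= 2) ? F1[i - 1] : NEG_INF;
      // cell (i-1, j-1) on diagonal d-2
      const int hd = (i >= 2 && j >= 2) ? H2[i - 1] : 0;
      const int e = std::max(hl - gfirst, el - gap_extend);
      const int f = std::max(hu - gfirst, fu - gap_extend);
      int h = hd + profile(subject_codes[i - 1], j - 1);
      if (h < 0) h = 0;
      if (e > h) h = e;
      if (f > h) h = f;
      H0[i] = h;
      E0[i] = e;
      F0[i] = f;
      if (h > best) best = h;
    }
    std::swap(H2, H1);
    std::swap(H1, H0);
    std::swap(E1, E0);
    std::swap(F1, F0);
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector sw_score_batch_(List subjects_codes, IntegerMatrix profile,
                              int gap_open, int gap_extend, bool wavefront) {
  const int n = subjects_codes.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    IntegerVector subj = subjects_codes[k];
    out[k] = wavefront
      ? sw_score_wavefront_(subj, profile, gap_open, gap_extend)
      : sw_core(INTEGER(subj), subj.size(), profile, gap_open, gap_extend);
  }
  return out;
}

// Permute the subject once per seed and score each copy: the inner loop of
// the permutation null.  Copy k uses a fresh LCG stream seeded with seeds[k].
// [[Rcpp::export]]
IntegerVector sw_permuted_scores_(IntegerVector subject_codes,
                                  NumericVector seeds, IntegerMatrix profile,
                                  int gap_open, int gap_extend) {
  const int N = seeds.size();
  const int n = subject_codes.size();
  IntegerVector out(N);
  std::vector<int> buf(n);
  for (int k = 0; k < N; ++k) {
    std::copy(subject_codes.begin(), subject_codes.end(), buf.begin());
    fy_permute(buf.data(), n, seeds[k]);
    out[k] = sw_core(buf.data(), n, profile, gap_open, gap_extend);
  }
  return out;
}
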