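#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// Base-pair maximization (Nussinov-style) used by the fallback folding
// engine.  Pairs allowed: A-U, G-C, G-U (both orientations); minimum
// hairpin loop length is enforced between paired positions.  The DP is
// kept in int16_t with an explicit transpose so both inner-loop reads
// are contiguous, which matters when folding every window of a genome.

static inline void encode(const std::string &seq, std::vector<int> &out) {
  out.resize(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    switch (seq[i]) {
      case 'A': case 'a': out[i] = 0; break;
      case 'C': case 'c': out[i] = 1; break;
      case 'G': case 'g': out[i] = 2; break;
      case 'T': case 't': case 'U': case 'u': out[i] = 3; break;
      default: stop("non-ACGTU character in sequence");
    }
  }
}

// canpair[a*4+b]: AU, UA, GC, CG, GU, UG
static const int16_t CANPAIR[16] = {
  /*A*/ 0, 0, 0, 1,
  /*C*/ 0, 0, 1, 0,
  /*G*/ 0, 1, 0, 1,
  /*T*/ 1, 0, 1, 0
};

struct PairmaxWork {
  std::vector<int16_t> dp;    // row-major: dp[i*n + j]
  std::vector<int16_t> dpT;   // transpose: dpT[j*n + i]
  std::vector<int16_t> mask;  // branchless pairing mask for the current i
  explicit PairmaxWork(int n)
    : dp((size_t) n * n), dpT((size_t) n * n), mask((size_t) n) {}
};

// dp[i][j] = max(dp[i+1][j], max over k in [i+minloop+1, j], pair(i,k):
//                1 + dp[i+1][k-1] + dp[k+1][j])
static int pairmax_run(const int *s, int n, int minloop, PairmaxWork &w) {
  if (n <= minloop + 1) return 0;
  const int16_t BIG = 4096;
  int16_t *dp = w.dp.data();
  int16_t *dpT = w.dpT.data();
  int16_t *mask = w.mask.data();
  std::memset(dp, 0, sizeof(int16_t) * n * n);
  std::memset(dpT, 0, sizeof(int16_t) * n * n);
  for (int i = n - minloop - 2; i >= 0; --i) {
    const int16_t *pairi = CANPAIR + 4 * s[i];
    for (int k = i + minloop + 1; k < n; ++k)
      mask[k] = pairi[s[k]] ? 1 : (int16_t) (-BIG);
    const int16_t *rowi1 = dp + (size_t) (i + 1) * n;
    for (int j = i + minloop + 1; j < n; ++j) {
      int16_t best = rowi1[j];
      // pair (i, j) closes the whole span
      int16_t vj = (int16_t) (rowi1[j - 1] + mask[j]);
      if (vj > best) best = vj;
      const int16_t *colj = dpT + (size_t) j * n;  // dp[.][j]
      for (int k = i + minloop + 1; k < j; ++k) {
        int16_t v = (int16_t) (rowi1[k - 1] + colj[k + 1] + mask[k]);
        if (v > best) best = v;
      }
      dp[(size_t) i * n + j] = best;
      dpT[(size_t) j * n + i] = best;
    }
  }
  return dp[n - 1];  // dp[0][n-1]
}

//' @noRd
// [[Rcpp::export(name = ".pairmax_count")]]
int pairmax_count(std::string seq, int minloop = 3) {
  std::vector<int> s;
  encode(seq, s);
  int n = (int) s.size();
  if (n == 0) return 0;
  PairmaxWork w(n);
  return pairmax_run(s.data(), n, minloop, w);
}

//' @noRd
// [[Rcpp::export(name = ".pairmax_windows")]]
NumericVector pairmax_windows(std::string seq, int window, int minloop = 3) {
  std::vector<int> s;
  encode(seq, s);
  int n = (int) s.size();
  NumericVector out(n, NA_REAL);
  if (window > n) return out;
  PairmaxWork w(window);
  int hw = (window - 1) / 2;
  for (int start = 0; start + window <= n; ++start) {
    out[start + hw] = pairmax_run(s.data() + start, window, minloop, w);
    if (start % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
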