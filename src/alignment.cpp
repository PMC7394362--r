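#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct AlnStats {
  double score;
  int matches;
  int aligned;
};

// Global (Needleman-Wunsch) alignment with a linear gap penalty. Among all
// optimal-score alignments the DP selects the one maximising the number of
// identical residue pairs, then the number of aligned (non-gap) pairs, so
// that the reported identity is deterministic when the optimum is tied.
AlnStats nw_align(const std::string &a, const std::string &b, double match,
                  double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  const double eps = 1e-9;
  std::vector<double> Sp(m + 1), Sc(m + 1);
  std::vector<int> Mp(m + 1), Mc(m + 1), Ap(m + 1), Ac(m + 1);
  for (int j = 0; j <= m; ++j) {
    Sp[j] = gap * j;
    Mp[j] = 0;
    Ap[j] = 0;
  }
  for (int i = 1; i <= n; ++i) {
    Sc[0] = gap * i;
    Mc[0] = 0;
    Ac[0] = 0;
    for (int j = 1; j <= m; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      double s = Sp[j - 1] + (eq ? match : mismatch);
      int mm = Mp[j - 1] + (eq ? 1 : 0);
      int aa = Ap[j - 1] + 1;
      const double su = Sp[j] + gap; // gap in b
      if (su > s + eps ||
          (su > s - eps && (Mp[j] > mm || (Mp[j] == mm && Ap[j] > aa)))) {
        s = su;
        mm = Mp[j];
        aa = Ap[j];
      }
      const double sl = Sc[j - 1] + gap; // gap in a
      if (sl > s + eps ||
          (sl > s - eps &&
           (Mc[j - 1] > mm || (Mc[j - 1] == mm && Ac[j - 1] > aa)))) {
        s = sl;
        mm = Mc[j - 1];
        aa = Ac[j - 1];
      }
      Sc[j] = s;
      Mc[j] = mm;
      Ac[j] = aa;
    }
    std::swap(Sp, Sc);
    std::swap(Mp, Mc);
    std::swap(Ap, Ac);
  }
  AlnStats out;
  out.score = Sp[m];
  out.matches = Mp[m];
  out.aligned = Ap[m];
  return out;
}

inline double identity_of(const AlnStats &st, size_t la, size_t lb) {
  const size_t shorter = la < lb ? la : lb;
  return shorter > 0 ? (double)st.matches / (double)shorter : 0.0;
}

// Bit-parallel longest-common-subsequence length. The LCS is an upper bound
// on the identical pairs of any alignment, so LCS / shorter-length bounds
// the identity from above and serves as a cheap prescreen before the exact
// alignment DP.
int llcs_bits(const std::string &a, const std::string &b) {
  const int n = (int)a.size();
  if (n == 0 || b.empty()) return 0;
  const int W = (n + 63) / 64;
  std::vector<uint64_t> PM(256 * W, 0ULL);
  for (int i = 0; i < n; ++i) {
    PM[(unsigned char)a[i] * W + (i >> 6)] |= (1ULL << (i & 63));
  }
  std::vector<uint64_t> V(W, ~0ULL);
  for (char cb : b) {
    const uint64_t *pm = &PM[(unsigned char)cb * W];
    uint64_t carry = 0;
    for (int w = 0; w < W; ++w) {
      const uint64_t U = V[w] & pm[w]; // U subset of V: no borrow across words
      const uint64_t sum = V[w] + U + carry;
      carry = (sum < V[w] || (carry && sum == V[w])) ? 1 : 0;
      V[w] = sum | (V[w] - U);
    }
  }
  int ones = 0;
  for (int w = 0; w < W; ++w) {
    uint64_t word = V[w];
    if (w == W - 1 && (n & 63)) word &= (1ULL << (n & 63)) - 1;
    while (word) {
      word &= word - 1;
      ++ones;
    }
  }
  return n - ones;
}

} // namespace

// [[Rcpp::export]]
int llcs_cpp(std::string a, std::string b) { return llcs_bits(a, b); }

// [[Rcpp::export]]
NumericVector nw_stats_cpp(std::string a, std::string b, double match,
                           double mismatch, double gap) {
  AlnStats st = nw_align(a, b, match, mismatch, gap);
  const double shorter = (double)std::min(a.size(), b.size());
  return NumericVector::create(
      _["identity"] = shorter > 0 ? st.matches / shorter : NA_REAL,
      _["coverage"] = shorter > 0 ? st.aligned / shorter : NA_REAL,
      _["score"] = st.score, _["matches"] = (double)st.matches,
      _["aligned"] = (double)st.aligned);
}

// Greedy centroid clustering over sequences already sorted by the caller
// (descending length, ties broken by id). Each sequence joins the earliest
// created centroid at identity >= threshold, else founds a new cluster.
// Returns the 1-based cluster index (in creation order) per sequence.
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold,
                                 double match, double mismatch, double gap) {
  const int n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<std::string>(seqs[i]);
  std::vector<const std::string *> centroids;
  for (int i = 0; i < n; ++i) {
    int hit = 0;
    for (size_t c = 0; c < centroids.size(); ++c) {
      const double shorter =
          (double)std::min(sv[i].size(), centroids[c]->size());
      if (shorter == 0) continue;
      // LCS bounds identity from above: skip the exact DP when even the
      // bound misses the threshold (the decision is unchanged).
      if ((double)llcs_bits(sv[i], *centroids[c]) / shorter < threshold) {
        continue;
      }
      AlnStats st = nw_align(sv[i], *centroids[c], match, mismatch, gap);
      if (identity_of(st, sv[i].size(), centroids[c]->size()) >= threshold) {
        hit = (int)c + 1;
        break;
      }
    }
    if (hit == 0) {
      centroids.push_back(&sv[i]);
      hit = (int)centroids.size();
    }
    assign[i] = hit;
  }
  return assign;
}
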