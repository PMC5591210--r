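#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct AlnResult {
  int matches;
  int columns;   // alignment columns in the aligned span (incl. gap columns)
  int span1;     // residues of seq1 inside the aligned span
  int span2;     // residues of seq2 inside the aligned span
  int score;
};

// Global alignment with free end gaps (overlap alignment).
// Scoring: match +1, mismatch 0, gap -1 (linear).
// Deterministic: cell fill prefers diagonal > up > left; the end cell is the
// best-scoring cell on the last row or last column, ties broken by smaller
// row index, then smaller column index.  H and TB are scratch buffers reused
// across calls.
AlnResult overlap_align(const std::string& s1, const std::string& s2,
                        std::vector<int>& H, std::vector<unsigned char>& TB) {
  const int n = (int)s1.size(), m = (int)s2.size();
  const int W = m + 1;
  H.assign((size_t)(n + 1) * W, 0);
  TB.assign((size_t)(n + 1) * W, 0);  // 0 = start, 1 = diag, 2 = up, 3 = left
  for (int i = 1; i <= n; ++i) {
    const char a = s1[i - 1];
    int* Hi = &H[(size_t)i * W];
    const int* Hp = &H[(size_t)(i - 1) * W];
    unsigned char* Ti = &TB[(size_t)i * W];
    for (int j = 1; j <= m; ++j) {
      int best = Hp[j - 1] + (a == s2[j - 1] ? 1 : 0);
      unsigned char dir = 1;
      const int up = Hp[j] - 1;
      if (up > best) { best = up; dir = 2; }
      const int left = Hi[j - 1] - 1;
      if (left > best) { best = left; dir = 3; }
      Hi[j] = best;
      Ti[j] = dir;
    }
  }
  int bi = -1, bj = -1, bscore = INT_MIN;
  for (int i = 0; i <= n; ++i) {
    if (i < n) {
      const int sc = H[(size_t)i * W + m];
      if (sc > bscore) { bscore = sc; bi = i; bj = m; }
    } else {
      for (int j = 0; j <= m; ++j) {
        const int sc = H[(size_t)n * W + j];
        if (sc > bscore) { bscore = sc; bi = n; bj = j; }
      }
    }
  }
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    const unsigned char dir = TB[(size_t)i * W + j];
    if (dir == 1) {
      if (s1[i - 1] == s2[j - 1]) ++matches;
      --i; --j;
    } else if (dir == 2) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  AlnResult r;
  r.matches = matches;
  r.columns = cols;
  r.span1 = bi - i;
  r.span2 = bj - j;
  r.score = bscore;
  return r;
}

// Canonical pair order makes results symmetric in the inputs: longer sequence
// first; for equal lengths, lexicographically smaller first.
struct PairStats {
  double identity_shorter;
  double identity_alignment;
  double coverage_shorter;
  int aligned_length;  // residues of the shorter sequence inside the span
};

PairStats pair_stats(const std::string& a, const std::string& b,
                     std::vector<int>& H, std::vector<unsigned char>& TB) {
  const std::string* s1 = &a;
  const std::string* s2 = &b;
  if (b.size() > a.size() || (b.size() == a.size() && b < a)) {
    s1 = &b;
    s2 = &a;
  }
  const AlnResult r = overlap_align(*s1, *s2, H, TB);
  const int len1 = (int)s1->size(), len2 = (int)s2->size();
  const int min_len = len1 < len2 ? len1 : len2;
  // span on the shorter sequence; for equal lengths take the smaller span
  int span_short;
  if (len1 > len2) span_short = r.span2;
  else span_short = r.span1 < r.span2 ? r.span1 : r.span2;
  PairStats p;
  p.identity_shorter = min_len > 0 ? (double)r.matches / min_len : 0.0;
  p.identity_alignment = r.columns > 0 ? (double)r.matches / r.columns : 0.0;
  p.coverage_shorter = min_len > 0 ? (double)span_short / min_len : 0.0;
  p.aligned_length = span_short;
  return p;
}

}  // namespace

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b) {
  std::vector<int> H;
  std::vector<unsigned char> TB;
  const PairStats p = pair_stats(a, b, H, TB);
  return List::create(_["identity_shorter"] = p.identity_shorter,
                      _["identity_alignment"] = p.identity_alignment,
                      _["coverage_shorter"] = p.coverage_shorter,
                      _["aligned_length"] = p.aligned_length);
}

// Greedy incremental clustering over proteins already sorted in processing
// order (decreasing length, ties lexicographic by gene id).  Each sequence
// joins the FIRST existing cluster whose representative it matches at both
// thresholds, else founds a new cluster.  Returns 1-based cluster indices in
// founding order plus similarity/coverage versus the representative.
// [[Rcpp::export]]
List greedy_cluster_cpp(CharacterVector proteins, double identity_threshold,
                        double coverage_threshold, bool denom_shorter) {
  const int n = proteins.size();
  std::vector<std::string> seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = as<std::string>(proteins[i]);
  std::vector<int> reps;         // indices of representatives, founding order
  IntegerVector cluster(n);
  NumericVector similarity(n), coverage(n);
  std::vector<int> H;
  std::vector<unsigned char> TB;
  for (int g = 0; g < n; ++g) {
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
    int assigned = -1;
    double sim = 1.0, cov = 1.0;
    for (size_t c = 0; c < reps.size(); ++c) {
      const PairStats p = pair_stats(seqs[reps[c]], seqs[g], H, TB);
      const double ident =
          denom_shorter ? p.identity_shorter : p.identity_alignment;
      if (ident >= identity_threshold && p.coverage_shorter >= coverage_threshold) {
        assigned = (int)c;
        sim = ident;
        cov = p.coverage_shorter;
        break;
      }
    }
    if (assigned < 0) {
      reps.push_back(g);
      cluster[g] = (int)reps.size();
      similarity[g] = 1.0;
      coverage[g] = 1.0;
    } else {
      cluster[g] = assigned + 1;
      similarity[g] = sim;
      coverage[g] = cov;
    }
  }
  IntegerVector rep_idx(reps.size());
  for (size_t c = 0; c < reps.size(); ++c) rep_idx[c] = reps[c] + 1;
  return List::create(_["cluster"] = cluster, _["similarity"] = similarity,
                      _["coverage"] = coverage, _["representative"] = rep_idx);
}
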