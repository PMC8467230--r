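#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with unit mismatch and unit gap
// costs. The objective is lexicographic: minimise total cost, then
// maximise the number of matched columns. The second criterion makes
// identity and p-distance well defined even when several unit-cost
// optima exist (e.g. "AB" vs "BA": one mismatch-free gapped optimum and
// one all-mismatch diagonal optimum have equal cost but different match
// counts). Given the sequence lengths la, lb and an optimal (cost, M):
//   mismatched columns X = la + lb - 2*M - cost
//   gap columns       G = cost - X
//   alignment length    = M + cost
// so all column counts derive from the two returned integers.
//
// The DP runs inside a diagonal band that is doubled until the result
// is provably the unbanded optimum (Ukkonen's device): an alignment of
// cost c contains at most c gap columns, so its path deviates at most
// (c - |n - m|) / 2 cells from the corridor spanned by the main and
// end-shifted diagonals. Once the banded cost satisfies that bound
// against the band half-width, every cost-optimal (and therefore every
// matches-maximal cost-optimal) path lies strictly inside the band and
// the banded answer equals the full-matrix answer exactly.

static const int BIG = INT_MAX / 4;

struct NWStats { int cost; int matches; };

// one banded pass; returns banded-optimal (cost, matches)
static NWStats nw_band(const std::string& a, const std::string& b, int w,
                       std::vector<unsigned char>* dir, int* out_dlo) {
  const int n = a.size(), m = b.size();
  const int dlo = std::min(0, m - n) - w;
  const int dhi = std::max(0, m - n) + w;
  const int width = dhi - dlo + 1;
  if (out_dlo) *out_dlo = dlo;
  if (dir) dir->assign((size_t)(n + 1) * width, 0);
  std::vector<int> pc(width, BIG), pm(width, 0), cc(width, BIG), cm(width, 0);
  // row 0: entry (0, j) sits at index j - dlo
  for (int j = std::max(0, dlo); j <= std::min(m, dhi); ++j) {
    pc[j - dlo] = j; pm[j - dlo] = 0;
    if (dir) (*dir)[j - dlo] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(0, i + dlo), jhi = std::min(m, i + dhi);
    std::fill(cc.begin(), cc.end(), BIG);
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const int idx = j - (i + dlo);
      int bc = BIG, bm = 0;
      unsigned char bd = 0;
      if (j == 0) { bc = i; bm = 0; bd = 2; }
      else {
        // diagonal predecessor (i-1, j-1) -> previous-row index idx
        if (pc[idx] < BIG) {
          const int eq = (ai == b[j - 1]);
          bc = pc[idx] + 1 - eq; bm = pm[idx] + eq; bd = 1;
        }
        // up predecessor (i-1, j) -> previous-row index idx + 1
        if (idx + 1 < width && pc[idx + 1] < BIG) {
          const int uc = pc[idx + 1] + 1, um = pm[idx + 1];
          if (uc < bc || (uc == bc && um > bm)) { bc = uc; bm = um; bd = 2; }
        }
        // left predecessor (i, j-1) -> current-row index idx - 1
        if (idx - 1 >= 0 && cc[idx - 1] < BIG) {
          const int lc = cc[idx - 1] + 1, lm = cm[idx - 1];
          if (lc < bc || (lc == bc && lm > bm)) { bc = lc; bm = lm; bd = 3; }
        }
      }
      cc[idx] = bc; cm[idx] = bm;
      if (dir) (*dir)[(size_t)i * width + idx] = bd;
    }
    std::swap(cc, pc); std::swap(cm, pm);
  }
  const int idx_end = m - (n + dlo);
  NWStats r; r.cost = pc[idx_end]; r.matches = pm[idx_end];
  return r;
}

static bool band_exact(const NWStats& r, int n, int m, int w) {
  if (w >= std::max(n, m)) return true;           // band covers everything
  if (r.cost >= BIG) return false;                // end cell unreachable
  return (r.cost - std::abs(n - m)) / 2 < w;      // all optima inside band
}

static NWStats nw_stats_exact(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  for (int w = 16;; w *= 4) {
    NWStats r = nw_band(a, b, w, nullptr, nullptr);
    if (band_exact(r, n, m, w)) return r;
  }
}

// [[Rcpp::export]]
IntegerVector nw_stats_cpp(std::string a, std::string b) {
  NWStats r = nw_stats_exact(a, b);
  return IntegerVector::create(_["cost"] = r.cost, _["matches"] = r.matches);
}

// Same optimum with a deterministic traceback (diagonal > gap-in-b >
// gap-in-a among moves achieving the lexicographic optimum).

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<unsigned char> dir;
  NWStats r; int dlo = 0, w = 16;
  for (;; w *= 4) {
    r = nw_band(a, b, w, &dir, &dlo);
    if (band_exact(r, n, m, w)) break;
  }
  const int width = (std::max(0, m - n) + w) - dlo + 1;
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const unsigned char d = dir[(size_t)i * width + (j - (i + dlo))];
    if (d == 1) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; }
    else if (d == 2) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
    else { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["cost"] = r.cost, _["matches"] = r.matches);
}

// Hamming mismatch count of `pattern` against every offset of `seq`
// (forward strand). Returns an integer vector of length
// nchar(seq) - nchar(pattern) + 1, or length 0 when the pattern is longer.

// [[Rcpp::export]]
IntegerVector hamming_scan_cpp(std::string seq, std::string pattern) {
  const int n = seq.size(), m = pattern.size();
  if (m == 0 || m > n) return IntegerVector(0);
  IntegerVector out(n - m + 1);
  for (int s = 0; s <= n - m; ++s) {
    int mm = 0;
    for (int k = 0; k < m; ++k) mm += (seq[s + k] != pattern[k]);
    out[s] = mm;
  }
  return out;
}
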