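// Global pairwise alignment kernels: full Needleman-Wunsch and the
// diagonal-banded variant that only evaluates cells (i, j) with
// |j - i| <= d + k, k = |len(a) - len(b)|.  Linear gap penalties.
// 'N' mismatches everything, including another 'N'.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>

using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

static inline int subst(char x, char y, int match, int mismatch) {
  return (x == y && x != 'N' && x != 'n') ? match : mismatch;
}

// [[Rcpp::export]]
List nw_full_cpp(std::string a, std::string b,
                 int match, int mismatch, int gap) {
  const int la = (int)a.size(), lb = (int)b.size();
  const double ncells = (double)(la + 1) * (double)(lb + 1);
  if (ncells > 2.6e8)
    stop("full DP matrix too large (%d x %d cells)", la + 1, lb + 1);
  std::vector<int> H((size_t)(la + 1) * (lb + 1));
  const size_t stride = lb + 1;
  for (int j = 0; j <= lb; ++j) H[j] = j * gap;
  for (int i = 1; i <= la; ++i) {
    H[(size_t)i * stride] = i * gap;
    const char ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int diag = H[(size_t)(i - 1) * stride + (j - 1)] +
                 subst(ai, b[j - 1], match, mismatch);
      int up   = H[(size_t)(i - 1) * stride + j] + gap;
      int left = H[(size_t)i * stride + (j - 1)] + gap;
      H[(size_t)i * stride + j] = std::max(diag, std::max(up, left));
    }
  }
  // traceback, tie-break: diagonal, then up (gap in b), then left (gap in a)
  std::string ra, rb;
  ra.reserve(la + lb); rb.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int h = H[(size_t)i * stride + j];
    if (i > 0 && j > 0 &&
        h == H[(size_t)(i - 1) * stride + (j - 1)] +
             subst(a[i - 1], b[j - 1], match, mismatch)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && h == H[(size_t)(i - 1) * stride + j] + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = H[(size_t)la * stride + lb],
                      _["cells_filled"] = ncells);
}

// [[Rcpp::export]]
List nw_banded_cpp(std::string a, std::string b,
                   int match, int mismatch, int gap, int d) {
  const int la = (int)a.size(), lb = (int)b.size();
  const int k = std::abs(la - lb);
  const long long W = (long long)d + k;  // band half-width

  // row extents within the band
  std::vector<int> lo(la + 1), hi(la + 1);
  std::vector<long long> rowptr(la + 2);
  rowptr[0] = 0;
  double ncells = 0;
  for (int i = 0; i <= la; ++i) {
    long long l = (long long)i - W, h = (long long)i + W;
    lo[i] = (int)std::max(0LL, l);
    hi[i] = (int)std::min((long long)lb, h);
    if (lo[i] > hi[i])
      stop("infeasible band: no cells on row %d for d = %d", i, d);
    rowptr[i + 1] = rowptr[i] + (hi[i] - lo[i] + 1);
    ncells += hi[i] - lo[i] + 1;
  }
  if ((double)rowptr[la + 1] > 2.6e8)
    stop("banded DP storage too large (%.0f cells)", (double)rowptr[la + 1]);
  if (lo[la] > lb || hi[la] < lb)
    stop("infeasible band: terminus outside band for d = %d", d);

  std::vector<int> H((size_t)rowptr[la + 1], NEG_INF);
  #define CELL(i, j) H[(size_t)rowptr[(i)] + ((j) - lo[(i)])]
  #define INB(i, j) ((j) >= lo[(i)] && (j) <= hi[(i)])

  for (int j = lo[0]; j <= hi[0]; ++j) CELL(0, j) = j * gap;
  for (int i = 1; i <= la; ++i) {
    const char ai = a[i - 1];
    for (int j = lo[i]; j <= hi[i]; ++j) {
      if (j == 0) { CELL(i, 0) = i * gap; continue; }
      int best = NEG_INF;
      if (INB(i - 1, j - 1)) {
        int v = CELL(i - 1, j - 1);
        if (v > NEG_INF) best = std::max(best, v + subst(ai, b[j - 1], match, mismatch));
      }
      if (INB(i - 1, j)) {
        int v = CELL(i - 1, j);
        if (v > NEG_INF) best = std::max(best, v + gap);
      }
      if (j - 1 >= lo[i]) {
        int v = CELL(i, j - 1);
        if (v > NEG_INF) best = std::max(best, v + gap);
      }
      CELL(i, j) = best;
    }
  }
  int score = CELL(la, lb);
  if (score <= NEG_INF)
    stop("infeasible band: terminus unreachable for d = %d", d);

  std::string ra, rb;
  ra.reserve(la + lb); rb.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    int h = CELL(i, j);
    bool moved = false;
    if (i > 0 && j > 0 && INB(i - 1, j - 1)) {
      int v = CELL(i - 1, j - 1);
      if (v > NEG_INF &&
          h == v + subst(a[i - 1], b[j - 1], match, mismatch)) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; moved = true;
      }
    }
    if (!moved && i > 0 && INB(i - 1, j)) {
      int v = CELL(i - 1, j);
      if (v > NEG_INF && h == v + gap) {
        ra.push_back(a[i - 1]); rb.push_back('-'); --i; moved = true;
      }
    }
    if (!moved && j > 0 && j - 1 >= lo[i]) {
      int v = CELL(i, j - 1);
      if (v > NEG_INF && h == v + gap) {
        ra.push_back('-'); rb.push_back(b[j - 1]); --j; moved = true;
      }
    }
    if (!moved) stop("banded traceback failed (internal error)");
  }
  #undef CELL
  #undef INB
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score, _["cells_filled"] = ncells,
                      _["d"] = d, _["k"] = k);
}
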