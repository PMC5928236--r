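#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Semi-global (ends-free, "overlap") pairwise alignment with affine gaps,
// Gotoh recursion. Sequences arrive 1-based-encoded into the rows/columns of
// the substitution matrix. A gap of length L costs gap_open + L * gap_extend.
//
// End gaps in either sequence are free; the returned alignment nevertheless
// spans both sequences in full, with the unaligned overhangs emitted as
// leading/trailing gap columns, so every reference position occupies exactly
// one alignment column.
//
// Determinism: ties in the traceback are resolved in a fixed operation order
// (diagonal match/mismatch, then gap-in-query, then gap-in-reference); the
// traceback start cell is the first maximum found scanning the last column
// top-to-bottom and then the last row left-to-right.

// [[Rcpp::export]]
List semiglobal_align_cpp(IntegerVector ref, IntegerVector qry,
                          NumericMatrix sub, double gap_open,
                          double gap_extend) {
  const int n = ref.size();   // reference, rows
  const int m = qry.size();   // query, cols
  if (n < 1) stop("empty reference");
  if (m < 1) stop("empty query");
  const double NEG = -std::numeric_limits<double>::infinity();
  const double open1 = gap_open + gap_extend;  // cost of the first gapped pos

  // H: best score for ref[1..i] vs qry[1..j]; D ends with ref_i over a gap
  // (gap in query); I ends with qry_j over a gap (gap in reference).
  std::vector<double> H((n + 1) * (m + 1)), D((n + 1) * (m + 1)),
      I((n + 1) * (m + 1));
  const int W = m + 1;
#define AT(M, i, j) M[(size_t)(i) * W + (j)]

  for (int j = 0; j <= m; ++j) {
    AT(H, 0, j) = 0.0;        // free leading gap in reference
    AT(D, 0, j) = NEG;
    AT(I, 0, j) = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    AT(H, i, 0) = 0.0;        // free leading gap in query
    AT(D, i, 0) = NEG;
    AT(I, i, 0) = NEG;
    for (int j = 1; j <= m; ++j) {
      double d = std::max(AT(H, i - 1, j) - open1, AT(D, i - 1, j) - gap_extend);
      double ins = std::max(AT(H, i, j - 1) - open1, AT(I, i, j - 1) - gap_extend);
      double diag = AT(H, i - 1, j - 1) + sub(ref[i - 1] - 1, qry[j - 1] - 1);
      AT(D, i, j) = d;
      AT(I, i, j) = ins;
      AT(H, i, j) = std::max(diag, std::max(d, ins));
    }
  }

  // Traceback start: best cell on the last column, then the last row.
  int bi = n, bj = m;
  double best = NEG;
  for (int i = 0; i <= n; ++i)
    if (AT(H, i, m) > best) { best = AT(H, i, m); bi = i; bj = m; }
  for (int j = 0; j <= m; ++j)
    if (AT(H, n, j) > best) { best = AT(H, n, j); bi = n; bj = j; }

  std::vector<int> ridx, qidx;  // 0 encodes a gap
  ridx.reserve(n + m);
  qidx.reserve(n + m);
  // trailing overhangs (free end gaps)
  for (int j = m; j > bj; --j) { ridx.push_back(0); qidx.push_back(j); }
  for (int i = n; i > bi; --i) { ridx.push_back(i); qidx.push_back(0); }

  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = D, 2 = I
  while (i > 0 && j > 0) {
    if (state == 0) {
      double diag = AT(H, i - 1, j - 1) + sub(ref[i - 1] - 1, qry[j - 1] - 1);
      if (AT(H, i, j) == diag) {
        ridx.push_back(i); qidx.push_back(j); --i; --j;
      } else if (AT(H, i, j) == AT(D, i, j)) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ridx.push_back(i); qidx.push_back(0);
      if (AT(D, i, j) == AT(H, i - 1, j) - open1) state = 0;
      --i;
    } else {
      ridx.push_back(0); qidx.push_back(j);
      if (AT(I, i, j) == AT(H, i, j - 1) - open1) state = 0;
      --j;
    }
  }
  // leading overhangs
  while (i > 0) { ridx.push_back(i); qidx.push_back(0); --i; }
  while (j > 0) { ridx.push_back(0); qidx.push_back(j); --j; }
#undef AT

  std::reverse(ridx.begin(), ridx.end());
  std::reverse(qidx.begin(), qidx.end());
  return List::create(_["ref_idx"] = wrap(ridx), _["qry_idx"] = wrap(qidx),
                      _["score"] = best);
}
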