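#include <Rcpp.h>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gap penalties
// (Gotoh three-state DP).  A gap of length L scores open + L * ext
// (open and ext are negative).  Ties are broken deterministically:
// diagonal (match state) > up (gap in b, consuming a) > left
// (gap in a, consuming b), both in the layer maxima and in the
// traceback, so the reported alignment is unique.
//
// a, b: 0-based integer codes indexing the substitution matrix.
// Returns the two aligned index vectors (-1 marks a gap) and the score.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b,
                  NumericMatrix sub, double open, double ext) {
  const int n = a.size(), m = b.size();
  // layers: 0 = M (diagonal), 1 = X (gap in b), 2 = Y (gap in a)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    X(i, 0) = open + ext * i;
    Y(i, 0) = NEG_INF;
    pX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = open + ext * j;
    pY(0, j) = 2;
  }

  // pick the best of (m, x, y) with preference M > X > Y on ties
  auto best3 = [](double vm, double vx, double vy, int &ptr) -> double {
    double best = vm; ptr = 0;
    if (vx > best) { best = vx; ptr = 1; }
    if (vy > best) { best = vy; ptr = 2; }
    return best;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int ptr;
      double s = sub(a[i - 1], b[j - 1]);
      M(i, j) = s + best3(M(i - 1, j - 1), X(i - 1, j - 1),
                          Y(i - 1, j - 1), ptr);
      pM(i, j) = ptr;
      X(i, j) = best3(M(i - 1, j) + open + ext,
                      X(i - 1, j) + ext,
                      Y(i - 1, j) + open + ext, ptr);
      pX(i, j) = ptr;
      Y(i, j) = best3(M(i, j - 1) + open + ext,
                      X(i, j - 1) + open + ext,
                      Y(i, j - 1) + ext, ptr);
      pY(i, j) = ptr;
    }
  }

  int state;
  double score = best3(M(n, m), X(n, m), Y(n, m), state);

  std::vector<int> ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0) {
      prev = pM(i, j);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = pX(i, j);
      ra.push_back(a[i - 1]); rb.push_back(-1);
      --i;
    } else {
      prev = pY(i, j);
      ra.push_back(-1); rb.push_back(b[j - 1]);
      --j;
    }
    state = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = wrap(ra), _["b"] = wrap(rb),
                      _["score"] = score);
}
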