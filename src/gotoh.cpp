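#include <Rcpp.h>
using namespace Rcpp;

// Gotoh three-state affine-gap global alignment (maximising).
// Gap of length L costs gap_open + (L - 1) * gap_extend.
// States: M = aligned pair, X = gap in query row (column consumes the
// reference only), Y = gap in reference row (column consumes the query only).
// Traceback ties resolved M > X > Y for a deterministic alignment.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = -(gap_open + (i - 1) * gap_extend);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = -(gap_open + (j - 1) * gap_extend);
  }

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;  // 1-based codes from R
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] - 1;
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      M(i, j) = best + S(ai, bj);

      double xo = M(i - 1, j) - gap_open;
      double xe = X(i - 1, j) - gap_extend;
      double xy = Y(i - 1, j) - gap_open;
      X(i, j) = std::max(xo, std::max(xe, xy));

      double yo = M(i, j - 1) - gap_open;
      double yx = X(i, j - 1) - gap_open;
      double ye = Y(i, j - 1) - gap_extend;
      Y(i, j) = std::max(yo, std::max(yx, ye));
    }
  }

  // traceback: state preference M > X > Y at every decision
  int i = n, j = m;
  int state;  // 0 = M, 1 = X, 2 = Y
  double sc = M(n, m);
  state = 0;
  if (X(n, m) > sc) { sc = X(n, m); state = 1; }
  if (Y(n, m) > sc) { sc = Y(n, m); state = 2; }
  const double score = sc;

  std::vector<int> moves;  // recorded end -> start; 1 = M, 2 = X, 3 = Y
  moves.reserve(n + m);
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      moves.push_back(1);
      double need = M(i, j) - S(a[i - 1] - 1, b[j - 1] - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - need) < eps) state = 0;
      else if (std::abs(X(i, j) - need) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      moves.push_back(2);
      double cur = X(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - gap_open - cur) < eps) state = 0;
      else if (std::abs(X(i, j) - gap_extend - cur) < eps) state = 1;
      else state = 2;
    } else {
      moves.push_back(3);
      double cur = Y(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - gap_open - cur) < eps) state = 0;
      else if (std::abs(X(i, j) - gap_open - cur) < eps) state = 1;
      else state = 2;
    }
  }
  std::reverse(moves.begin(), moves.end());

  return List::create(_["score"] = score,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}
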