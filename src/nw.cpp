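#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global pairwise alignment (Gotoh affine-gap Needleman-Wunsch) with a fixed,
// deterministic traceback: ties resolved preferring diagonal, then a gap in
// the second sequence ("up", consumes a), then a gap in the first ("left").
// A gap of length L costs gap_open + (L - 1) * gap_extend; pass
// gap_open == gap_extend for linear gap costs.
// free_a / free_b make the terminal overhang of that sequence free
// (overlap-style alignment): with free_b, b may hang over both ends of the
// aligned region unpenalized, and symmetrically for free_a. Both together
// give a full overlap alignment (fragment inside a longer template); free_b
// alone keeps a fully aligned while b's flanks (e.g. binding-site pads) are
// free.
// Scores are kept in two rolling rows; only the byte-sized traceback
// pointers are stored in full.

enum State { DIAG = 0, UP = 1, LEFT = 2 };

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend,
                  bool free_a, bool free_b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("nw_align: empty sequence");
  const double NEG = -1e18;
  const size_t row = m + 1;

  std::vector<double> M0(row), X0(row), Y0(row), M1(row), X1(row), Y1(row);
  std::vector<signed char> pM(row * (n + 1)), pX(row * (n + 1)),
      pY(row * (n + 1));
  // scores in the last column, needed for free-end selection
  std::vector<double> colM(n + 1), colX(n + 1), colY(n + 1);

  M0[0] = 0.0; X0[0] = NEG; Y0[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG; X0[j] = NEG;
    Y0[j] = free_b ? 0.0 : gap_open + (j - 1) * gap_extend;
    pY[j] = LEFT;
  }
  colM[0] = M0[m]; colX[0] = X0[m]; colY[0] = Y0[m];

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    signed char *pMi = &pM[(size_t)i * row];
    signed char *pXi = &pX[(size_t)i * row];
    signed char *pYi = &pY[(size_t)i * row];
    M1[0] = NEG; Y1[0] = NEG;
    X1[0] = free_a ? 0.0 : gap_open + (i - 1) * gap_extend;
    pXi[0] = UP;
    for (int j = 1; j <= m; ++j) {
      const double s = (ai == b[j - 1]) ? match : mismatch;
      // M: diagonal move; tie preference DIAG > UP > LEFT
      {
        double best = M0[j - 1]; signed char st = DIAG;
        if (X0[j - 1] > best) { best = X0[j - 1]; st = UP; }
        if (Y0[j - 1] > best) { best = Y0[j - 1]; st = LEFT; }
        M1[j] = best + s; pMi[j] = st;
      }
      // X: gap in b (consume a)
      {
        double best = M0[j] + gap_open; signed char st = DIAG;
        double v = X0[j] + gap_extend;
        if (v > best) { best = v; st = UP; }
        v = Y0[j] + gap_open;
        if (v > best) { best = v; st = LEFT; }
        X1[j] = best; pXi[j] = st;
      }
      // Y: gap in a (consume b)
      {
        double best = M1[j - 1] + gap_open; signed char st = DIAG;
        double v = X1[j - 1] + gap_open;
        if (v > best) { best = v; st = UP; }
        v = Y1[j - 1] + gap_extend;
        if (v > best) { best = v; st = LEFT; }
        Y1[j] = best; pYi[j] = st;
      }
    }
    colM[i] = M1[m]; colX[i] = X1[m]; colY[i] = Y1[m];
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  // after the loop, M0/X0/Y0 hold row n

  auto pick3 = [](double vM, double vX, double vY, int &state) {
    double best = vM; state = DIAG;
    if (vX > best) { best = vX; state = UP; }
    if (vY > best) { best = vY; state = LEFT; }
    return best;
  };

  int ei = n, ej = m, estate;
  double score = pick3(colM[n], colX[n], colY[n], estate);
  // free trailing overhang: of b when the end sits on the last row
  // (a exhausted first), of a when it sits on the last column; (n, m)
  // wins ties, then cells closer to it
  if (free_a) {
    for (int i = n - 1; i >= 1; --i) {
      int st; double v = pick3(colM[i], colX[i], colY[i], st);
      if (v > score) { score = v; ei = i; ej = m; estate = st; }
    }
  }
  if (free_b) {
    for (int j = m - 1; j >= 1; --j) {
      int st; double v = pick3(M0[j], X0[j], Y0[j], st);
      if (v > score) { score = v; ei = n; ej = j; estate = st; }
    }
  }

  std::string ra, rb;
  // trailing free end gaps
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

  int i = ei, j = ej, state = estate;
  while (i > 0 || j > 0) {
    if (state == DIAG) {
      if (i == 0 || j == 0) break; // free-end boundary: pad below
      signed char prev = pM[(size_t)i * row + j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == UP) {
      if (i == 0) break;
      signed char prev = pX[(size_t)i * row + j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      if (j == 0) break;
      signed char prev = pY[(size_t)i * row + j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  // leading free end gaps
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}
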