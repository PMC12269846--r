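#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps.
// Gap convention: a gap run of length k costs gap_open + k * gap_extend
// (both penalties <= 0). Terminal gaps are penalized like internal ones.
// Traceback tie-break: diagonal > gap-in-b (residue in a over gap) >
// gap-in-a, applied both to the final state and to every predecessor
// choice, so the reported alignment is deterministic.

static const double NEG_INF = -1e30;

// state codes: 0 = M (match/mismatch), 1 = X (gap in b), 2 = Y (gap in a)

// [[Rcpp::export(name = ".gotohAlign")]]
List gotohAlign(std::string a, std::string b, NumericMatrix sub,
                std::string alphabet, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();

  int idx[256];
  std::memset(idx, -1, sizeof(idx));
  for (size_t k = 0; k < alphabet.size(); ++k)
    idx[(unsigned char) alphabet[k]] = (int) k;

  if (n == 0 && m == 0)
    return List::create(_["gapped_a"] = "", _["gapped_b"] = "",
                        _["score"] = 0.0);
  if (n == 0) {
    std::string ga(m, '-');
    return List::create(_["gapped_a"] = ga, _["gapped_b"] = b,
                        _["score"] = gap_open + m * gap_extend);
  }
  if (m == 0) {
    std::string gb(n, '-');
    return List::create(_["gapped_a"] = a, _["gapped_b"] = gb,
                        _["score"] = gap_open + n * gap_extend);
  }

  const size_t W = (size_t)(m + 1);
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // predecessor state of each cell, per state matrix
  std::vector<unsigned char> pM((n + 1) * W), pX((n + 1) * W), pY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + i * gap_extend;
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + j * gap_extend;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const int ai = idx[(unsigned char) a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int bj = idx[(unsigned char) b[j - 1]];
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);

      // M: preference M > X > Y on ties
      double best = M[d]; unsigned char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = sub(ai, bj) + best;
      pM[c] = arg;

      // X (gap in b, consumes a): open from M/Y or extend X
      double openx = (M[u] >= Y[u]) ? M[u] : Y[u];
      unsigned char argx = (M[u] >= Y[u]) ? 0 : 2;
      openx += gap_open + gap_extend;
      if (openx >= X[u] + gap_extend) { X[c] = openx; pX[c] = argx; }
      else { X[c] = X[u] + gap_extend; pX[c] = 1; }

      // Y (gap in a, consumes b): open from M/X or extend Y
      double openy = (M[l] >= X[l]) ? M[l] : X[l];
      unsigned char argy = (M[l] >= X[l]) ? 0 : 1;
      openy += gap_open + gap_extend;
      if (openy >= Y[l] + gap_extend) { Y[c] = openy; pY[c] = argy; }
      else { Y[c] = Y[l] + gap_extend; pY[c] = 2; }
    }
  }

  const size_t e = (size_t) n * W + m;
  double score = M[e]; int state = 0;
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }

  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = (size_t) i * W + j;
    if (state == 0) {
      const int prev = pM[c];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      const int prev = pX[c];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; state = prev;
    } else {
      const int prev = pY[c];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["gapped_a"] = ga, _["gapped_b"] = gb,
                      _["score"] = score);
}
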