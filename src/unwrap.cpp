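// Reliability-sorting region-growing 2D phase unwrapper
// (Herraez/Burton/Lalor/Gdeisat style). Pixels are joined along edges in
// decreasing order of reliability; each join shifts one whole group by an
// integer multiple of 2*pi, so the output is pixelwise congruent to the
// input modulo 2*pi and the algorithm is total (no failure mode).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

static inline double wrap_pi(double d) {
  // map to [-pi, pi)
  return d - TWO_PI * std::floor((d + M_PI) / TWO_PI);
}

// [[Rcpp::export]]
List unwrap_phase_cpp(NumericMatrix wrapped) {
  const int R = wrapped.nrow(), C = wrapped.ncol();
  const int N = R * C;
  std::vector<double> value(N);
  for (int j = 0; j < C; ++j)
    for (int i = 0; i < R; ++i)
      value[i + (size_t)j * R] = wrapped(i, j);

  // pixel reliability: inverse second-difference measure; border pixels
  // get the worst score so region growing starts in the interior
  std::vector<double> rel(N, -std::numeric_limits<double>::max() / 4);
  for (int j = 1; j < C - 1; ++j) {
    for (int i = 1; i < R - 1; ++i) {
      const size_t c = i + (size_t)j * R;
      const double w = value[c];
      double H  = wrap_pi(value[c - R] - w) - wrap_pi(w - value[c + R]);
      double V  = wrap_pi(value[c - 1] - w) - wrap_pi(w - value[c + 1]);
      double D1 = wrap_pi(value[c - R - 1] - w) - wrap_pi(w - value[c + R + 1]);
      double D2 = wrap_pi(value[c - R + 1] - w) - wrap_pi(w - value[c + R - 1]);
      rel[c] = -std::sqrt(H * H + V * V + D1 * D1 + D2 * D2);
    }
  }

  // edges: horizontal (right neighbour) then vertical (lower neighbour)
  const size_t nE = (size_t)R * (C - 1) + (size_t)(R - 1) * C;
  std::vector<int> ea(nE), eb(nE);
  std::vector<double> erel(nE);
  size_t e = 0;
  for (int j = 0; j < C - 1; ++j)
    for (int i = 0; i < R; ++i, ++e) {
      int a = i + j * R;
      ea[e] = a; eb[e] = a + R; erel[e] = rel[a] + rel[a + R];
    }
  for (int j = 0; j < C; ++j)
    for (int i = 0; i < R - 1; ++i, ++e) {
      int a = i + j * R;
      ea[e] = a; eb[e] = a + 1; erel[e] = rel[a] + rel[a + 1];
    }
  std::vector<size_t> order(nE);
  for (size_t k = 0; k < nE; ++k) order[k] = k;
  std::stable_sort(order.begin(), order.end(),
                   [&](size_t x, size_t y) { return erel[x] > erel[y]; });

  // groups as linked lists; merging the smaller into the larger keeps the
  // total relabelling cost O(N log N)
  std::vector<int> group(N), nxt(N, -1), head(N), tail(N), cnt(N, 1);
  for (int k = 0; k < N; ++k) { group[k] = k; head[k] = k; tail[k] = k; }

  for (size_t k = 0; k < nE; ++k) {
    const int a = ea[order[k]], b = eb[order[k]];
    int ga = group[a], gb = group[b];
    if (ga == gb) continue;
    // shift group of b so that value[b] lines up with value[a]
    double delta = TWO_PI * std::round((value[a] - value[b]) / TWO_PI);
    int from, into;
    double add;
    if (cnt[ga] >= cnt[gb]) { from = gb; into = ga; add = delta; }
    else                    { from = ga; into = gb; add = -delta; }
    for (int p = head[from]; p != -1; p = nxt[p]) {
      if (add != 0.0) value[p] += add;
      group[p] = into;
    }
    nxt[tail[into]] = head[from];
    tail[into] = tail[from];
    cnt[into] += cnt[from];
  }

  // residue count (diagnostic): nonzero wrapped loop integrals on 2x2 cells
  int residues = 0;
  for (int j = 0; j < C - 1; ++j) {
    for (int i = 0; i < R - 1; ++i) {
      double s = wrap_pi(wrapped(i, j + 1) - wrapped(i, j)) +
                 wrap_pi(wrapped(i + 1, j + 1) - wrapped(i, j + 1)) +
                 wrap_pi(wrapped(i + 1, j) - wrapped(i + 1, j + 1)) +
                 wrap_pi(wrapped(i, j) - wrapped(i + 1, j));
      if (std::fabs(s) > M_PI) ++residues;
    }
  }

  NumericMatrix out(R, C);
  for (int j = 0; j < C; ++j)
    for (int i = 0; i < R; ++i)
      out(i, j) = value[i + (size_t)j * R];
  return List::create(_["unwrapped"] = out, _["residues"] = residues);
}
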