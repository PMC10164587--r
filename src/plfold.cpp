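#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int rna_code2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

static const double RT37 = 0.6163;      // kcal/mol at 37 C
static const double HELIX_INIT = 4.1;   // nucleation cost per helix

// simple-model pair energy (same table as the duplex DP)
static inline double pe2(int x, int y) {
  if ((x == 2 && y == 1) || (x == 1 && y == 2)) return -3.0;
  if ((x == 0 && y == 3) || (x == 3 && y == 0)) return -2.0;
  if ((x == 2 && y == 3) || (x == 3 && y == 2)) return -1.0;
  return 0.0; // not pairable (caller checks)
}

static inline bool can_pair(int x, int y) {
  if (x < 0 || y < 0) return false;
  return (x + y == 3) || (x == 2 && y == 3) || (x == 3 && y == 2);
}

// Equilibrium probability that each base is paired, for one sequence window,
// over the ensemble of non-crossing structures with WC + G:U pairs, hairpin
// loops >= minloop nt and no lonely pairs (every helix >= 2 stacked pairs).
// Grammar: Q = any structure; N[a][b] = structure on [a,b] without pair (a,b);
// H[p][b] = structure where (p,b) is the outermost pair of its (maximal-inward)
// helix; C[i][j] = continuation after pair (i,j) within a helix.
static void window_pair_prob(const std::vector<int>& s, int off, int n,
                             int minloop, std::vector<double>& prob) {
  int dim = n + 2;
  std::vector<double> Q(dim * dim, 0.0), N(dim * dim, 0.0),
      C(dim * dim, 0.0), H(dim * dim, 0.0),
      OQ(dim * dim, 0.0), ON(dim * dim, 0.0),
      OC(dim * dim, 0.0), OH(dim * dim, 0.0);
  std::vector<double> W(dim * dim, 0.0); // pair Boltzmann weights
  auto at = [dim](int i, int j) { return i * dim + j; };
  for (int i = 1; i <= n; ++i)
    for (int j = i + minloop + 1; j <= n; ++j)
      if (can_pair(s[off + i - 1], s[off + j - 1]))
        W[at(i, j)] = std::exp(-pe2(s[off + i - 1], s[off + j - 1]) / RT37);

  // empty segments: Q = 1 (represented implicitly via qval lambda)
  auto qval = [&](int a, int b) { return (b < a) ? 1.0 : Q[a * dim + b]; };
  auto nbar = [&](int a, int b) { return (b < a) ? 1.0 : N[a * dim + b]; };

  // inside, by increasing span
  for (int L = 0; L < n; ++L) {
    // H and C first (they can feed same-span Q/N)
    for (int i = 1; i + L <= n; ++i) {
      int j = i + L;
      if (W[at(i, j)] > 0.0) {
        double winner = (i + 1 <= n && j - 1 >= 1) ? W[at(i + 1, j - 1)] : 0.0;
        double cc = nbar(i + 1, j - 1);
        if (winner > 0.0) cc += winner * C[at(i + 1, j - 1)];
        C[at(i, j)] = cc;
        if (winner > 0.0)
          H[at(i, j)] = std::exp(-HELIX_INIT / RT37) *
            W[at(i, j)] * winner * C[at(i + 1, j - 1)];
      }
    }
    for (int a = 1; a + L <= n; ++a) {
      int b = a + L;
      double q = qval(a, b - 1), nn = qval(a, b - 1);
      for (int p = a; p <= b; ++p) {
        double h = H[at(p, b)];
        if (h > 0.0) {
          double left = qval(a, p - 1);
          q += left * h;
          if (p > a) nn += left * h;
        }
      }
      Q[at(a, b)] = q; N[at(a, b)] = nn;
    }
  }
  double Z = qval(1, n);
  if (Z <= 0.0) return;

  // outside, by decreasing span
  OQ[at(1, n)] = 1.0;
  for (int L = n - 1; L >= 0; --L) {
    for (int a = 1; a + L <= n; ++a) {
      int b = a + L;
      double oq = OQ[at(a, b)], on = ON[at(a, b)];
      if (oq != 0.0 || on != 0.0) {
        if (b - 1 >= a) { OQ[at(a, b - 1)] += oq + on; }
        for (int p = a; p <= b; ++p) {
          double h = H[at(p, b)];
          if (h <= 0.0) continue;
          double left = qval(a, p - 1);
          double w = oq + ((p > a) ? on : 0.0);
          if (w != 0.0) {
            if (p - 1 >= a) OQ[at(a, p - 1)] += w * h;
            OH[at(p, b)] += w * left;
          }
        }
      }
    }
    for (int i = 1; i + L <= n; ++i) {
      int j = i + L;
      if (W[at(i, j)] <= 0.0) continue;
      double winner = (i + 1 <= n && j - 1 >= 1) ? W[at(i + 1, j - 1)] : 0.0;
      double oh = OH[at(i, j)], oc = OC[at(i, j)];
      if (oh != 0.0 && winner > 0.0)
        OC[at(i + 1, j - 1)] += oh * std::exp(-HELIX_INIT / RT37) *
          W[at(i, j)] * winner;
      if (oc != 0.0) {
        if (j - 1 >= i + 1) ON[at(i + 1, j - 1)] += oc;
        if (winner > 0.0) OC[at(i + 1, j - 1)] += oc * winner;
      }
    }
  }

  // pair probabilities -> per-base paired probability
  for (int x = 1; x <= n; ++x) {
    for (int y = x + minloop + 1; y <= n; ++y) {
      if (W[at(x, y)] <= 0.0) continue;
      double mass = OH[at(x, y)] * H[at(x, y)];
      if (x - 1 >= 1 && y + 1 <= n) {
        mass += OH[at(x - 1, y + 1)] * H[at(x - 1, y + 1)];
        mass += OC[at(x - 1, y + 1)] * W[at(x, y)] * C[at(x, y)];
      }
      double p = mass / Z;
      if (p > 0.0) {
        prob[x - 1] += p;
        prob[y - 1] += p;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (prob[i] < 0.0) prob[i] = 0.0;
    if (prob[i] > 1.0) prob[i] = 1.0;
  }
}

// Windowed per-base paired probability: windows of length `window` slid one
// nucleotide at a time; each base's value is the mean over windows covering it.
// [[Rcpp::export]]
NumericVector cpp_pairing_probabilities(std::string sequence, int window,
                                        int minloop) {
  int T = (int)sequence.size();
  std::vector<int> s(T);
  for (int i = 0; i < T; ++i) s[i] = rna_code2(sequence[i]);
  NumericVector out(T);
  std::vector<double> count(T, 0.0);
  int W = std::min(window, T);
  int nwin = T - W + 1;
  for (int w0 = 0; w0 < nwin; ++w0) {
    std::vector<double> prob(W, 0.0);
    window_pair_prob(s, w0, W, minloop, prob);
    for (int i = 0; i < W; ++i) {
      out[w0 + i] += prob[i];
      count[w0 + i] += 1.0;
    }
  }
  for (int i = 0; i < T; ++i) out[i] = (count[i] > 0) ? out[i] / count[i] : 0.0;
  return out;
}
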