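#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// RNA alphabet: A=0 C=1 G=2 U/T=3
static inline int rna_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// pair type: 0 AU, 1 UA, 2 GC, 3 CG, 4 GU, 5 UG, -1 not pairable
static inline int pair_type(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 2 && y == 1) return 2;
  if (x == 1 && y == 2) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

// simple model: per-pair energies (kcal/mol)
static inline double pair_energy_simple(int pt) {
  switch (pt) {
  case 2: case 3: return -3.0; // G:C
  case 0: case 1: return -2.0; // A:U
  case 4: case 5: return -1.0; // G:U wobble
  default: return 0.0;
  }
}

// nearest-neighbour stack table st[prev][cur]: pair `cur` stacked 3' of
// `prev` (approximate Turner-style values, documented in the package
// vignette). The table satisfies st[p][q] == st[flip(q)][flip(p)] (flip =
// swap the two strands), so the duplex energy is invariant under exchanging
// the arms.
static const double ST[6][6] = {
  /* AU */ {-0.90, -1.10, -2.10, -2.20, -0.60, -1.40},
  /* UA */ {-1.30, -0.90, -2.40, -2.10, -1.00, -0.90},
  /* GC */ {-2.10, -2.20, -2.85, -3.40, -1.50, -2.30},
  /* CG */ {-2.40, -2.10, -3.30, -2.85, -2.10, -1.95},
  /* GU */ {-0.90, -1.40, -1.95, -2.30, -0.45, -0.40},
  /* UG */ {-1.00, -0.60, -2.10, -1.50, -0.30, -0.45}
};
static const double NN_INIT = 4.1;   // duplex initiation
static const int    MAX_LOOP = 30;   // per-arm unpaired bound between helices

static inline double nn_loop_penalty(int u1, int u2) {
  int u = u1 + u2;
  if (u1 == 0 || u2 == 0) return 3.2 + 1.0 * std::log((double)u); // bulge
  return 2.0 + 1.1 * std::log((double)u) + 0.5 * std::abs(u1 - u2);
}

// Intermolecular MFE between arm1 and arm2 (antiparallel, non-crossing,
// WC + G:U pairs, no intramolecular pairs, no lonely pairs: every helix has
// >= 2 stacked pairs). model: 0 = simple (pair energies + 1 kcal/mol per
// unpaired loop nucleotide), 1 = nearest-neighbour stacks with loop penalties
// and a duplex initiation term.
// [[Rcpp::export]]
List cpp_duplex_mfe(std::string arm1, std::string arm2, int model) {
  const double INF = std::numeric_limits<double>::infinity();
  int n = (int)arm1.size(), m = (int)arm2.size();
  std::vector<int> a(n), b(m);
  for (int i = 0; i < n; ++i) a[i] = rna_code(arm1[i]);
  // b = reversed arm2 so pairs are increasing in both indices
  for (int k = 0; k < m; ++k) b[k] = rna_code(arm2[m - 1 - k]);

  std::vector<double> S(n * m, INF), A(n * m, INF);
  // back-pointers: for S, 0 = from S[i-1][k-1], 1 = from A[i-1][k-1];
  // for A: -1 = helix starts the structure, else predecessor cell index into S
  std::vector<int> bpS(n * m, -9), bpA(n * m, -9);
  // prefix-min of S[i][k] - c*(i+k) for the simple-model loop transition
  std::vector<double> P(n * m, INF);
  std::vector<int> Pidx(n * m, -1);
  const double c = 1.0; // simple-model loop cost per unpaired nt

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      int id = i * m + k;
      int pt = pair_type(a[i], b[k]);
      if (pt >= 0) {
        if (model == 0) {
          double pe = pair_energy_simple(pt);
          // helix start: external (0) or after a loop from a valid helix end
          double best = 0.0; int bb = -1;
          if (i > 0 && k > 0) {
            int pid = (i - 1) * m + (k - 1);
            if (P[pid] < INF) {
              double loop = P[pid] + c * (double)(i + k - 2);
              if (loop < best) { best = loop; bb = Pidx[pid]; }
            }
          }
          A[id] = pe + best; bpA[id] = bb;
          // stack continuation
          if (i > 0 && k > 0 && pair_type(a[i - 1], b[k - 1]) >= 0) {
            int pid = (i - 1) * m + (k - 1);
            double fromS = S[pid], fromA = A[pid];
            if (fromS <= fromA && fromS < INF) { S[id] = pe + fromS; bpS[id] = 0; }
            else if (fromA < INF)              { S[id] = pe + fromA; bpS[id] = 1; }
          }
        } else {
          // nearest-neighbour: energy lives on stacks; helix start costs 0,
          // loops cost nn_loop_penalty, one global initiation added at the end
          double best = 0.0; int bb = -1;
          for (int u1 = 0; u1 <= MAX_LOOP && i - 1 - u1 >= 0; ++u1) {
            for (int u2 = (u1 == 0 ? 1 : 0); u2 <= MAX_LOOP && k - 1 - u2 >= 0; ++u2) {
              int pi = i - 1 - u1, pk = k - 1 - u2;
              int pid = pi * m + pk;
              if (S[pid] >= INF) continue;
              double e = S[pid] + nn_loop_penalty(u1, u2);
              if (e < best) { best = e; bb = pid; }
            }
          }
          A[id] = best; bpA[id] = bb;
          if (i > 0 && k > 0) {
            int ppt = pair_type(a[i - 1], b[k - 1]);
            if (ppt >= 0) {
              int pid = (i - 1) * m + (k - 1);
              double st = ST[ppt][pt];
              double fromS = S[pid], fromA = A[pid];
              if (fromS <= fromA && fromS < INF) { S[id] = st + fromS; bpS[id] = 0; }
              else if (fromA < INF)              { S[id] = st + fromA; bpS[id] = 1; }
            }
          }
        }
      }
      // update prefix-min (simple model only uses it)
      double t = (S[id] < INF) ? S[id] - c * (double)(i + k) : INF;
      double pm = t; int pmi = (t < INF) ? id : -1;
      if (i > 0 && P[(i - 1) * m + k] < pm) { pm = P[(i - 1) * m + k]; pmi = Pidx[(i - 1) * m + k]; }
      if (k > 0 && P[i * m + (k - 1)] < pm) { pm = P[i * m + (k - 1)]; pmi = Pidx[i * m + (k - 1)]; }
      P[id] = pm; Pidx[id] = pmi;
    }
  }

  // best terminal: structures must end on a stacked pair (helix >= 2)
  double best = INF; int bid = -1;
  for (int id = 0; id < n * m; ++id)
    if (S[id] < best) { best = S[id]; bid = id; }
  double energy = (bid >= 0) ? best + (model == 1 ? NN_INIT : 0.0) : 0.0;
  if (bid < 0 || energy >= 0.0) {
    return List::create(_["energy"] = 0.0,
                        _["i"] = IntegerVector(0), _["j"] = IntegerVector(0));
  }
  // traceback
  std::vector<int> pi_, pj_;
  int id = bid; bool inS = true;
  while (id >= 0) {
    int i = id / m, k = id % m;
    pi_.push_back(i); pj_.push_back(m - 1 - k); // back to arm2 coordinates
    if (inS) {
      int bp = bpS[id];
      id = (i - 1) * m + (k - 1);
      inS = (bp == 0);
    } else {
      int bp = bpA[id];
      if (bp < 0) break;
      id = bp; inS = true;
    }
  }
  int np = (int)pi_.size();
  IntegerVector oi(np), oj(np);
  for (int x = 0; x < np; ++x) { oi[x] = pi_[np - 1 - x]; oj[x] = pj_[np - 1 - x]; }
  return List::create(_["energy"] = energy, _["i"] = oi, _["j"] = oj);
}
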