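// Simplified nearest-neighbor RNA minimum-free-energy folder.
//
// Zuker-style dynamic program over stack energies with hairpin, bulge and
// internal-loop initiation penalties and a linear multiloop cost. 37 C
// parameters; Watson-Crick plus (optionally) GU wobble pairs; no dangling
// ends, terminal mismatches or coaxial stacking. The open chain has energy
// zero, so the returned MFE is always <= 0.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const double INF = 1e9;
static const int MAXLOOP = 12;   // max unpaired bases in a bulge/internal loop
static const double ML_CLOSE = 3.4, ML_BRANCH = 0.4, ML_UNPAIRED = 0.0;
static const double LOOP_EXTRAP = 1.079;  // 1.75 * RT at 37 C, kcal/mol

// pair type order: CG, GC, GU, UG, AU, UA; -1 = not pairable
static int pair_type(int a, int b, bool allow_gu) {
  // base codes: A=0, C=1, G=2, U=3
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return allow_gu ? 2 : -1;
  if (a == 3 && b == 2) return allow_gu ? 3 : -1;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

// stack free energies, rows = outer pair (i,j), cols = inner pair (i+1,j-1)
static const double STACK[6][6] = {
  /* CG */ {-3.26, -2.36, -1.41, -2.11, -2.11, -2.08},
  /* GC */ {-3.42, -3.26, -1.53, -2.51, -2.35, -2.24},
  /* GU */ {-2.51, -2.11, -0.50,  1.29, -1.00, -1.36},
  /* UG */ {-1.53, -1.41, -0.30, -0.50, -1.27, -0.55},
  /* AU */ {-2.24, -2.08, -0.55, -1.36, -0.93, -1.10},
  /* UA */ {-2.35, -2.11, -1.27, -1.00, -1.33, -0.93}
};

static double hairpin_init(int s) {
  static const double H[7] = {5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4}; // sizes 3..9
  if (s < 3) return INF;
  if (s <= 9) return H[s - 3];
  return 6.4 + LOOP_EXTRAP * std::log((double)s / 9.0);
}

static double bulge_init(int s) {
  static const double B[6] = {3.8, 2.8, 3.2, 3.6, 4.0, 4.4}; // sizes 1..6
  if (s <= 6) return B[s - 1];
  return 4.4 + LOOP_EXTRAP * std::log((double)s / 6.0);
}

static double internal_init(int s) {
  static const double I[5] = {1.5, 1.6, 1.7, 2.0, 2.0}; // sizes 2..6
  if (s <= 6) return I[s - 2];
  return 2.0 + LOOP_EXTRAP * std::log((double)s / 6.0);
}

static double fold_one(const std::string& seq, bool allow_gu) {
  const int n = (int)seq.size();
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) {
    switch (seq[i]) {
      case 'A': b[i] = 0; break;
      case 'C': b[i] = 1; break;
      case 'G': b[i] = 2; break;
      case 'U': case 'T': b[i] = 3; break;
      default: stop("invalid base '%s' in sequence", std::string(1, seq[i]));
    }
  }
  if (n < 5) return 0.0;

  std::vector<double> V((size_t)n * n, INF), WM((size_t)n * n, INF);
  std::vector<double> W(n, 0.0);
  #define IX(i, j) ((size_t)(i) * n + (j))

  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pt = pair_type(b[i], b[j], allow_gu);
      if (pt >= 0) {
        double e = hairpin_init(j - i - 1);
        // stacks, bulges, internal loops
        for (int ip = i + 1; ip <= i + 1 + MAXLOOP && ip < j - 4; ++ip) {
          int l1 = ip - i - 1;
          for (int jp = j - 1; jp > ip + 3 && (l1 + (j - jp - 1)) <= MAXLOOP; --jp) {
            int l2 = j - jp - 1;
            double inner = V[IX(ip, jp)];
            if (inner >= INF) continue;
            int ptin = pair_type(b[ip], b[jp], allow_gu);
            double cost;
            if (l1 == 0 && l2 == 0) {
              cost = STACK[pt][ptin];
            } else if (l1 == 0 || l2 == 0) {
              cost = bulge_init(l1 + l2);
              if (l1 + l2 == 1) cost += STACK[pt][ptin];  // helix continuity
            } else {
              double asym = 0.5 * std::abs(l1 - l2);
              cost = internal_init(l1 + l2) + (asym < 3.0 ? asym : 3.0);
            }
            double cand = cost + inner;
            if (cand < e) e = cand;
          }
        }
        // multiloop closing: >= 2 branches inside
        for (int k = i + 1; k < j - 1; ++k) {
          double left = WM[IX(i + 1, k)], right = WM[IX(k + 1, j - 1)];
          if (left < INF && right < INF) {
            double cand = ML_CLOSE + ML_BRANCH + left + right;
            if (cand < e) e = cand;
          }
        }
        V[IX(i, j)] = e;
      }
      // WM: at least one branch in [i, j] inside a multiloop
      double m = INF;
      if (V[IX(i, j)] < INF) m = V[IX(i, j)] + ML_BRANCH;
      if (WM[IX(i + 1, j)] < INF) m = std::min(m, WM[IX(i + 1, j)] + ML_UNPAIRED);
      if (WM[IX(i, j - 1)] < INF) m = std::min(m, WM[IX(i, j - 1)] + ML_UNPAIRED);
      for (int k = i + 1; k < j; ++k) {
        double left = WM[IX(i, k - 1)], right = WM[IX(k, j)];
        if (left < INF && right < INF) m = std::min(m, left + right);
      }
      WM[IX(i, j)] = m;
    }
  }

  for (int j = 1; j < n; ++j) {
    W[j] = W[j - 1];
    for (int i = 0; i < j - 3; ++i) {
      double v = V[IX(i, j)];
      if (v < INF) {
        double cand = (i > 0 ? W[i - 1] : 0.0) + v;
        if (cand < W[j]) W[j] = cand;
      }
    }
  }
  double mfe = W[n - 1];
  return mfe < 0.0 ? mfe : 0.0;
  #undef IX
}

// [[Rcpp::export]]
NumericVector nnfold_mfe(CharacterVector seqs, bool allow_gu = true) {
  const int m = seqs.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    std::string s = as<std::string>(seqs[k]);
    // round to 0.01 kcal/mol, the reporting precision
    out[k] = std::round(fold_one(s, allow_gu) * 100.0) / 100.0;
  }
  return out;
}
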