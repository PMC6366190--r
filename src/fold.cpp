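#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
#include <array>
#include <cmath>
using namespace Rcpp;

// Secondary-structure prediction by energy-scored base-pair maximisation.
//
// Model (pseudo-kcal/mol, exactly reproducible): every admissible pair
// (i,j) contributes a pairing energy (GC < AU < GU); adjacent pairs
// (i,j)/(i+1,j-1) earn a stacking bonus; a pair enclosing no other pair
// pays a hairpin-loop opening penalty; loops shorter than min_loop are
// disallowed.  The scale is calibrated so long perfect GC stems score
// far below zero.
//
// DP tables:
//   V(i,j)  = min energy of a structure on [i,j] in which (i,j) pair,
//   Wp(i,j) = min energy of a structure on [i,j] with at least one pair,
//   W0(i,j) = min(0, Wp(i,j))  (the empty structure has energy 0).

static const double INF = 1e18;

struct Params {
  double e_gc, e_au, e_gu, stack, hairpin;
  int min_loop;
};

static inline int code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2;
  case 'T': case 'U': return 3; case 'N': return 4;
  default: return -1;
  }
}

static inline double pair_energy(int a, int b, const Params &p) {
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return p.e_gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return p.e_au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return p.e_gu;
  return INF;  // cannot pair
}

// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(std::string seq, double e_gc, double e_au, double e_gu,
                 double stack, double hairpin, int min_loop) {
  Params par{e_gc, e_au, e_gu, stack, hairpin, min_loop};
  const int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    int c = code((char) toupper(seq[i]));
    if (c < 0) stop("sequence letter outside {A,C,G,U,T,N} at position %d", i + 1);
    s[i] = c;
  }
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);

  std::vector<std::vector<double>> V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double>> Wp(n, std::vector<double>(n, INF));

  auto W0 = [&](int i, int j) -> double {
    if (i > j || Wp[i][j] >= INF) return 0.0;
    return std::min(0.0, Wp[i][j]);
  };
  // min energy inside (i..j) with >=1 pair, excluding "(i,j) paired":
  // used for the interior of V with i,j the positions just inside the
  // closing pair.
  auto ns_energy = [&](int i, int j) -> double {
    if (i > j) return INF;
    double best = INF;
    if (i + 1 <= j && Wp[i + 1][j] < INF) best = std::min(best, Wp[i + 1][j]);
    for (int k = i + par.min_loop + 1; k < j; ++k)   // k == j is the stack case
      if (V[i][k] < INF) best = std::min(best, V[i][k] + W0(k + 1, j));
    return best;
  };

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double pe = pair_energy(s[i], s[j], par);
      if (pe < INF && j - i - 1 >= par.min_loop) {
        double best = par.hairpin;  // no pair inside: hairpin loop
        if (j - 2 - (i + 1) >= par.min_loop && V[i + 1][j - 1] < INF)
          best = std::min(best, V[i + 1][j - 1] + par.stack);
        double ns = ns_energy(i + 1, j - 1);
        if (ns < INF) best = std::min(best, ns);
        V[i][j] = pe + best;
      }
      // Wp(i,j)
      double w = INF;
      if (i + 1 <= j && Wp[i + 1][j] < INF) w = std::min(w, Wp[i + 1][j]);
      for (int k = i + par.min_loop + 1; k <= j; ++k)
        if (V[i][k] < INF) w = std::min(w, V[i][k] + W0(k + 1, j));
      Wp[i][j] = w;
    }
  }

  // traceback: frames are (i, j, mode) with mode 0 = Wp, 1 = V
  const double eps = 1e-6;
  std::string db(n, '.');
  std::stack<std::array<int, 3>> st;
  if (n >= 2 && Wp[0][n - 1] < 0.0) st.push({0, n - 1, 0});
  while (!st.empty()) {
    auto fr = st.top(); st.pop();
    int i = fr[0], j = fr[1], mode = fr[2];
    if (i > j) continue;
    if (mode == 0) {
      double w = Wp[i][j];
      if (w >= INF) continue;
      if (i + 1 <= j && Wp[i + 1][j] < INF && std::fabs(Wp[i + 1][j] - w) < eps) {
        st.push({i + 1, j, 0});
        continue;
      }
      for (int k = i + par.min_loop + 1; k <= j; ++k) {
        if (V[i][k] < INF && std::fabs(V[i][k] + W0(k + 1, j) - w) < eps) {
          st.push({i, k, 1});
          if (k + 1 <= j && Wp[k + 1][j] < INF && Wp[k + 1][j] < 0.0)
            st.push({k + 1, j, 0});
          break;
        }
      }
      continue;
    }
    // mode 1: (i,j) paired
    db[i] = '('; db[j] = ')';
    double target = V[i][j] - pair_energy(s[i], s[j], par);
    if (std::fabs(target - par.hairpin) < eps) continue;
    if (j - 2 - (i + 1) >= par.min_loop && V[i + 1][j - 1] < INF &&
        std::fabs(V[i + 1][j - 1] + par.stack - target) < eps) {
      st.push({i + 1, j - 1, 1});
      continue;
    }
    // non-stacked interior: i+1 unpaired, or i+1 paired to k < j-1
    int a = i + 1, b = j - 1;
    if (a + 1 <= b && Wp[a + 1][b] < INF && std::fabs(Wp[a + 1][b] - target) < eps) {
      st.push({a + 1, b, 0});
      continue;
    }
    for (int k = a + par.min_loop + 1; k < b; ++k) {
      if (V[a][k] < INF && std::fabs(V[a][k] + W0(k + 1, b) - target) < eps) {
        st.push({a, k, 1});
        if (k + 1 <= b && Wp[k + 1][b] < INF && Wp[k + 1][b] < 0.0)
          st.push({k + 1, b, 0});
        break;
      }
    }
  }

  double mfe = (n >= 2) ? W0(0, n - 1) : 0.0;
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
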