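#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Lightweight thermodynamic folding used as the package's internal backend.
// Two-matrix DP in the Nussinov/Zuker-lite family:
//   C[i][j] : minimum energy of i..j given that (i,j) is a base pair
//   W[i][j] : minimum energy of any structure on i..j (empty allowed, 0)
// Pair energies (kcal/mol): GC -3, AU -2, GU -1; a stacking bonus of -1
// rewards helices; hairpin loops need >= 3 unpaired bases. Not a full
// nearest-neighbour model, but deterministic, dependency-free and accurate
// enough to rank hairpin-forming subsequences against shuffled background.

static const double INF = 1e9;
static const double STACK_BONUS = -1.0;
static const int MIN_LOOP = 3;

static inline int code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline double pairEnergy(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3.0; // GC
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2.0; // AU
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1.0; // GU
  return INF;
}

struct FoldDP {
  int n;
  std::vector<int> s;
  std::vector<double> C, W;
  double &c(int i, int j) { return C[(size_t)i * n + j]; }
  double &w(int i, int j) { return W[(size_t)i * n + j]; }

  explicit FoldDP(const std::string &seq) {
    n = (int)seq.size();
    s.resize(n);
    for (int i = 0; i < n; ++i) {
      s[i] = code(seq[i]);
      if (s[i] < 0) stop("invalid character in RNA sequence: '%s'",
                         std::string(1, seq[i]).c_str());
    }
    C.assign((size_t)n * n, INF);
    W.assign((size_t)n * n, 0.0);
    fill();
  }

  void fill() {
    for (int len = 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        double pe = pairEnergy(s[i], s[j]);
        if (pe < INF / 2) {
          double best = INF;
          if (j - i - 1 >= MIN_LOOP) best = 0.0; // hairpin loop closure
          if (i + 1 < j - 1) {
            double inner = c(i + 1, j - 1);
            if (inner < INF / 2 && inner + STACK_BONUS < best)
              best = inner + STACK_BONUS; // helix stack
            double wi = w(i + 1, j - 1);
            if (wi < 0.0 && wi < best) best = wi; // interior / multiloop
          }
          if (best < INF / 2) c(i, j) = pe + best;
        }
        double bw = 0.0;
        if (w(i + 1, j) < bw) bw = w(i + 1, j);
        if (w(i, j - 1) < bw) bw = w(i, j - 1);
        if (c(i, j) < bw) bw = c(i, j);
        for (int k = i + 1; k < j; ++k) {
          double v = w(i, k) + w(k + 1, j);
          if (v < bw) bw = v;
        }
        w(i, j) = bw;
      }
    }
  }

  // traceback helpers -------------------------------------------------
  void traceC(int i, int j, std::string &db, int off);
  void traceW(int i, int j, std::string &db, int off);
};

void FoldDP::traceC(int i, int j, std::string &db, int off) {
  db[i - off] = '(';
  db[j - off] = ')';
  double pe = pairEnergy(s[i], s[j]);
  double target = c(i, j) - pe;
  if (j - i - 1 >= MIN_LOOP && std::abs(target) < 1e-9) return; // hairpin
  if (i + 1 < j - 1) {
    if (c(i + 1, j - 1) < INF / 2 &&
        std::abs(c(i + 1, j - 1) + STACK_BONUS - target) < 1e-9) {
      traceC(i + 1, j - 1, db, off);
      return;
    }
    if (w(i + 1, j - 1) < 0.0 &&
        std::abs(w(i + 1, j - 1) - target) < 1e-9) {
      traceW(i + 1, j - 1, db, off);
      return;
    }
  }
  // numerically safest fallback: leave loop unpaired
}

void FoldDP::traceW(int i, int j, std::string &db, int off) {
  while (i < j) {
    double v = w(i, j);
    if (v >= 0.0) return;
    if (w(i + 1, j) == v) { ++i; continue; }
    if (w(i, j - 1) == v) { --j; continue; }
    if (c(i, j) == v) { traceC(i, j, db, off); return; }
    bool split = false;
    for (int k = i + 1; k < j; ++k) {
      if (std::abs(w(i, k) + w(k + 1, j) - v) < 1e-9) {
        traceW(i, k, db, off);
        i = k + 1;
        split = true;
        break;
      }
    }
    if (!split) return;
  }
}

// [[Rcpp::export(name = ".foldLocalCpp")]]
DataFrame foldLocalCpp(std::string seq, double maxEnergy = -1.0,
                       int minSpan = 15) {
  FoldDP dp(seq);
  int n = dp.n;
  std::vector<int> starts, ends;
  std::vector<double> energies;
  std::vector<std::string> structures;
  for (int i = 0; i < n; ++i) {
    for (int j = i + minSpan - 1; j < n; ++j) {
      double e = dp.c(i, j);
      if (e > maxEnergy) continue;
      // keep only locally maximal helices: skip spans whose one-step
      // extension pairs at least as favourably (RNALfold-style locality)
      if (i > 0 && j < n - 1) {
        double eo = dp.c(i - 1, j + 1);
        if (eo < INF / 2 && eo <= e) continue;
      }
      std::string db(j - i + 1, '.');
      dp.traceC(i, j, db, i);
      starts.push_back(i + 1);
      ends.push_back(j + 1);
      energies.push_back(e);
      structures.push_back(db);
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["mfe"] = energies,
                           _["structure"] = structures,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".foldGlobalCpp")]]
List foldGlobalCpp(std::string seq) {
  FoldDP dp(seq);
  int n = dp.n;
  std::string db(n, '.');
  if (n >= 2 && dp.w(0, n - 1) < 0.0) dp.traceW(0, n - 1, db, 0);
  double e = (n >= 2) ? dp.w(0, n - 1) : 0.0;
  return List::create(_["structure"] = db, _["mfe"] = e);
}
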