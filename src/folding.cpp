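// Dynamic-programming core for circular RNA folding.
//
// The circle of length N is handled through its doubled sequence s[0..2N-1]
// (s[p] == s[p+N]); any 5'->3' fragment of the circle maps to a window
// a..b with b - a <= N - 1.  For every such window with terminal pair
// (a, b) we compute
//   Eb(a,b)    minimum free energy of the fragment, terminal nucleotides
//              paired with each other (energy of the loop closed by (a,b)
//              plus everything nested inside; the pair itself carries no
//              standalone term - all energy lives in stacks and loops)
//   Qb(a,b)    the matching Boltzmann-weighted conditional partition
//              function (per-nucleotide rescaling avoids overflow)
// Hard constraints (forced partners, forced-unpaired positions, forbidden
// pairs) are expressed per circle position and respected by every
// recursion case.
//
// Energy cases per closing pair: hairpin; stack/bulge/interior (total
// unpaired size capped at maxloop); multiloop with affine a + b*branches +
// c*unpaired.  Interior recursions are the standard O(L^3) ones with the
// usual O(L^2 * maxloop^2) interior-loop term.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double BIGE = 1.0e18;

struct Params {
  std::vector<double> stackE;       // 256 entries, ((o5*4+o3)*4+i5)*4+i3
  std::vector<double> hpE;          // index size-1, size = 1..N
  std::vector<double> bulgeE;       // index size-1
  std::vector<double> intE;         // index size-1 (total size both strands)
  double mlA, mlB, mlC, kT, inf;
  int maxloop;
};

static inline int sidx(int o5, int o3, int i5, int i3) {
  return ((o5 * 4 + o3) * 4 + i5) * 4 + i3;
}

class FoldDP {
public:
  int N, M;
  std::vector<int> s;            // base codes 0..3 (A,C,G,U), length 2N
  Params par;
  std::vector<int> partner;      // circle, -1 = free
  std::vector<char> unpair;      // circle
  std::vector<char> forb;        // N*N, circle
  std::vector<int> mustPre;      // doubled prefix counts of must-pair positions
  std::vector<double> Eb, Em, Em1;
  std::vector<double> Qb, Qm, Qm1;
  std::vector<double> fpow;      // fpow[l] = f^l
  double sigma, f, cf, bf, mlw;  // Q-side constants
  bool haveQ;

  FoldDP(const IntegerVector &codes, int n, const List &p, const List &rules)
      : N(n), M(2 * n), sigma(0.0), f(1.0), haveQ(false) {
    s.assign(codes.begin(), codes.end());
    for (int i = 0; i < M; ++i) s[i] -= 1;   // to 0-based codes
    NumericVector st = p["stackE"], hp = p["hpE"], bu = p["bulgeE"], in = p["intE"];
    par.stackE.assign(st.begin(), st.end());
    par.hpE.assign(hp.begin(), hp.end());
    par.bulgeE.assign(bu.begin(), bu.end());
    par.intE.assign(in.begin(), in.end());
    par.mlA = p["mlA"]; par.mlB = p["mlB"]; par.mlC = p["mlC"];
    par.kT = p["kT"]; par.inf = p["inf"]; par.maxloop = p["maxloop"];
    IntegerVector pt = rules["partner"], up = rules["unpair"];
    IntegerMatrix fb = rules["forbidden"];
    partner.assign(N, -1);
    unpair.assign(N, 0);
    forb.assign((size_t)N * N, 0);
    for (int i = 0; i < N; ++i) {
      partner[i] = pt[i] == 0 ? -1 : pt[i] - 1;
      unpair[i] = up[i] != 0;
    }
    for (int r = 0; r < fb.nrow(); ++r) {
      int x = fb(r, 0) - 1, y = fb(r, 1) - 1;
      forb[(size_t)x * N + y] = 1;
      forb[(size_t)y * N + x] = 1;
    }
    mustPre.assign(M + 1, 0);
    for (int i = 0; i < M; ++i)
      mustPre[i + 1] = mustPre[i] + (partner[i % N] != -1 ? 1 : 0);
  }

  inline int circ(int a) const { return a % N; }
  inline bool canon(int x, int y) const {
    return (x == 0 && y == 3) || (x == 3 && y == 0) ||
           (x == 1 && y == 2) || (x == 2 && y == 1) ||
           (x == 2 && y == 3) || (x == 3 && y == 2);
  }
  inline bool pairAllowed(int a, int b) const {
    int ca = circ(a), cb = circ(b);
    if (ca == cb) return false;
    if (!canon(s[a], s[b])) return false;
    if (unpair[ca] || unpair[cb]) return false;
    if (forb[(size_t)ca * N + cb]) return false;
    if (partner[ca] != -1 && partner[ca] != cb) return false;
    if (partner[cb] != -1 && partner[cb] != ca) return false;
    return true;
  }
  // positions a..b (doubled, inclusive) may all stay unpaired
  inline bool freeRun(int a, int b) const {
    if (a > b) return true;
    return mustPre[b + 1] - mustPre[a] == 0;
  }
  inline bool unpairOK(int b) const { return partner[circ(b)] == -1; }

  inline double hpLookup(int size) const {
    if (size < 1 || size > (int)par.hpE.size()) return par.inf;
    return par.hpE[size - 1];
  }
  inline double interiorE(int s1, int s2, int a, int b, int p, int q) const {
    if (s1 == 0 && s2 == 0) return par.stackE[sidx(s[a], s[b], s[p], s[q])];
    int sz = s1 + s2;
    if (sz > (int)par.bulgeE.size()) return par.inf;
    if (s1 == 0 || s2 == 0) return par.bulgeE[sz - 1];
    return par.intE[sz - 1];
  }

  inline double &EB(int a, int b) { return Eb[(size_t)a * M + b]; }
  inline double &EM(int a, int b) { return Em[(size_t)a * M + b]; }
  inline double &EM1(int a, int b) { return Em1[(size_t)a * M + b]; }
  inline double &QB(int a, int b) { return Qb[(size_t)a * M + b]; }
  inline double &QM(int a, int b) { return Qm[(size_t)a * M + b]; }
  inline double &QM1(int a, int b) { return Qm1[(size_t)a * M + b]; }
  inline double getE(int a, int b) const { return Eb[(size_t)a * M + b]; }

  void computeMFE() {
    Eb.assign((size_t)M * M, par.inf);
    Em.assign((size_t)M * M, par.inf);
    Em1.assign((size_t)M * M, par.inf);
    for (int d = 1; d <= N - 1; ++d) {
      for (int a = 0; a + d < M; ++a) {
        int b = a + d;
        // --- Eb ---
        double e = par.inf;
        if (pairAllowed(a, b)) {
          if (freeRun(a + 1, b - 1)) e = std::min(e, hpLookup(d - 1));
          int pmax = std::min(a + 1 + par.maxloop, b - 2);
          for (int p = a + 1; p <= pmax; ++p) {
            if (!freeRun(a + 1, p - 1)) break;
            int s1 = p - a - 1;
            int qlo = std::max(p + 1, b - 1 - (par.maxloop - s1));
            for (int q = b - 1; q >= qlo; --q) {
              if (!freeRun(q + 1, b - 1)) break;
              double inner = getE(p, q);
              if (inner >= par.inf) continue;
              double g = interiorE(s1, b - q - 1, a, b, p, q) + inner;
              e = std::min(e, g);
            }
          }
          double bestm = BIGE;
          for (int m = a + 2; m <= b - 2; ++m) {
            double x = EM(a + 1, m - 1) + EM1(m, b - 1);
            bestm = std::min(bestm, x);
          }
          if (bestm < par.inf) e = std::min(e, par.mlA + par.mlB + bestm);
        }
        EB(a, b) = std::min(e, par.inf);
        // --- Em1 ---
        double e1 = par.inf;
        if (unpairOK(b) && EM1(a, b - 1) < par.inf)
          e1 = EM1(a, b - 1) + par.mlC;
        if (EB(a, b) < par.inf) e1 = std::min(e1, EB(a, b) + par.mlB);
        EM1(a, b) = std::min(e1, par.inf);
        // --- Em ---
        double em = par.inf;
        if (unpairOK(b) && EM(a, b - 1) < par.inf) em = EM(a, b - 1) + par.mlC;
        for (int p = a; p <= b - 1; ++p) {
          double br = getE(p, b);
          if (br >= par.inf) continue;
          br += par.mlB;
          if (freeRun(a, p - 1)) em = std::min(em, par.mlC * (p - a) + br);
          if (p > a && EM(a, p - 1) < par.inf)
            em = std::min(em, EM(a, p - 1) + br);
        }
        EM(a, b) = std::min(em, par.inf);
      }
    }
  }

  // best circular decomposition energy (over all circle pairs), or 0
  double circMFE() const {
    double best = 0.0;
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) {
        double e = Eb[(size_t)i * M + j] + Eb[(size_t)j * M + (i + N)];
        best = std::min(best, e);
      }
    return best;
  }

  void computeQ() {
    double emfe = std::min(0.0, circMFE());
    sigma = emfe / N;                       // <= 0
    f = std::exp(sigma / par.kT);           // <= 1
    cf = std::exp(-par.mlC / par.kT);
    bf = std::exp(-par.mlB / par.kT);
    mlw = std::exp(-(par.mlA + par.mlB) / par.kT);
    fpow.assign(M + 2, 1.0);
    for (int l = 1; l <= M + 1; ++l) fpow[l] = fpow[l - 1] * f;
    Qb.assign((size_t)M * M, 0.0);
    Qm.assign((size_t)M * M, 0.0);
    Qm1.assign((size_t)M * M, 0.0);
    for (int d = 1; d <= N - 1; ++d) {
      for (int a = 0; a + d < M; ++a) {
        int b = a + d;
        double q = 0.0;
        if (pairAllowed(a, b)) {
          if (freeRun(a + 1, b - 1)) {
            double g = hpLookup(d - 1);
            if (g < par.inf) q += std::exp(-g / par.kT) * fpow[d + 1];
          }
          int pmax = std::min(a + 1 + par.maxloop, b - 2);
          for (int p = a + 1; p <= pmax; ++p) {
            if (!freeRun(a + 1, p - 1)) break;
            int s1 = p - a - 1;
            int qlo = std::max(p + 1, b - 1 - (par.maxloop - s1));
            for (int qq = b - 1; qq >= qlo; --qq) {
              if (!freeRun(qq + 1, b - 1)) break;
              double inner = QB(p, qq);
              if (inner <= 0.0) continue;
              double g = interiorE(s1, b - qq - 1, a, b, p, qq);
              if (g >= par.inf) continue;
              q += std::exp(-g / par.kT) * fpow[s1 + (b - qq - 1) + 2] * inner;
            }
          }
          double sm = 0.0;
          for (int m = a + 2; m <= b - 2; ++m)
            sm += QM(a + 1, m - 1) * QM1(m, b - 1);
          q += mlw * fpow[2] * sm;
        }
        QB(a, b) = q;
        double q1 = 0.0;
        if (unpairOK(b)) q1 += QM1(a, b - 1) * cf * f;
        q1 += QB(a, b) * bf;
        QM1(a, b) = q1;
        double qm = 0.0;
        if (unpairOK(b)) qm += QM(a, b - 1) * cf * f;
        double lead = 1.0;   // weight of unpaired run a..p-1, maintained incrementally
        for (int p = a; p <= b - 1; ++p) {
          double br = QB(p, b);
          if (br > 0.0) {
            br *= bf;
            if (lead > 0.0 && freeRun(a, p - 1)) qm += lead * br;
            if (p > a) qm += QM(a, p - 1) * br;
          }
          lead *= cf * f;
        }
        QM(a, b) = qm;
      }
    }
    haveQ = true;
  }

  // log of the (unscaled) conditional partition function of window (a,b)
  double logQwin(int a, int b) const {
    double v = Qb[(size_t)a * M + b];
    if (v <= 0.0) return R_NegInf;
    return std::log(v) - (b - a + 1) * (sigma / par.kT);
  }

  // -------- backtracking (MFE) --------
  void btEb(int a, int b, std::vector<std::pair<int,int> > &out) const {
    const double eps = 1e-7;
    double target = Eb[(size_t)a * M + b];
    if (target >= par.inf) stop("backtracking into an infeasible cell");
    out.push_back(std::make_pair(a, b));
    int d = b - a;
    if (freeRun(a + 1, b - 1) && std::fabs(hpLookup(d - 1) - target) <= eps)
      return;
    int pmax = std::min(a + 1 + par.maxloop, b - 2);
    for (int p = a + 1; p <= pmax; ++p) {
      if (!freeRun(a + 1, p - 1)) break;
      int s1 = p - a - 1;
      for (int q = p + 1; q <= b - 1; ++q) {
        int s2 = b - q - 1;
        if (s1 + s2 > par.maxloop) continue;
        if (!freeRun(q + 1, b - 1)) continue;
        double inner = getE(p, q);
        if (inner >= par.inf) continue;
        if (std::fabs(interiorE(s1, s2, a, b, p, q) + inner - target) <= eps) {
          btEb(p, q, out);
          return;
        }
      }
    }
    for (int m = a + 2; m <= b - 2; ++m) {
      double x = Em[(size_t)(a + 1) * M + (m - 1)] + Em1[(size_t)m * M + (b - 1)];
      if (x < par.inf && std::fabs(par.mlA + par.mlB + x - target) <= eps) {
        btEm(a + 1, m - 1, out);
        btEm1(m, b - 1, out);
        return;
      }
    }
    stop("MFE backtracking failed to reproduce a stored energy");
  }
  void btEm1(int a, int b, std::vector<std::pair<int,int> > &out) const {
    const double eps = 1e-7;
    int y = b;
    while (y > a + 0) {
      double target = Em1[(size_t)a * M + y];
      if (y > a && unpairOK(y) && Em1[(size_t)a * M + (y - 1)] < par.inf &&
          std::fabs(Em1[(size_t)a * M + (y - 1)] + par.mlC - target) <= eps) {
        --y;
        continue;
      }
      if (getE(a, y) < par.inf &&
          std::fabs(getE(a, y) + par.mlB - target) <= eps) {
        btEb(a, y, out);
        return;
      }
      stop("multiloop branch backtracking failed");
    }
    stop("multiloop branch backtracking failed");
  }
  void btEm(int a, int b, std::vector<std::pair<int,int> > &out) const {
    const double eps = 1e-7;
    int y = b;
    while (y > a) {
      double target = Em[(size_t)a * M + y];
      if (unpairOK(y) && Em[(size_t)a * M + (y - 1)] < par.inf &&
          std::fabs(Em[(size_t)a * M + (y - 1)] + par.mlC - target) <= eps) {
        --y;
        continue;
      }
      bool done = false;
      for (int p = a; p <= y - 1 && !done; ++p) {
        double br = getE(p, y);
        if (br >= par.inf) continue;
        br += par.mlB;
        if (freeRun(a, p - 1) &&
            std::fabs(par.mlC * (p - a) + br - target) <= eps) {
          btEb(p, y, out);
          return;
        }
        if (p > a && Em[(size_t)a * M + (p - 1)] < par.inf &&
            std::fabs(Em[(size_t)a * M + (p - 1)] + br - target) <= eps) {
          btEb(p, y, out);
          // remaining branches to the left
          int yy = p - 1;
          btEm(a, yy, out);
          return;
        }
      }
      stop("multiloop backtracking failed");
    }
    stop("multiloop backtracking failed");
  }
};

// [[Rcpp::export(name = ".cf_tables")]]
List cf_tables(IntegerVector codes, int n, List par, List rules,
               bool with_q = true) {
  FoldDP dp(codes, n, par, rules);
  dp.computeMFE();
  int M = dp.M;
  NumericMatrix eb(M, M), lq(M, M);
  std::fill(lq.begin(), lq.end(), R_NegInf);
  if (with_q) dp.computeQ();
  for (int a = 0; a < M; ++a)
    for (int b = a + 1; b < std::min(M, a + n); ++b) {
      eb(a, b) = dp.getE(a, b);
      if (with_q) lq(a, b) = dp.logQwin(a, b);
    }
  return List::create(_["Eb"] = eb, _["logQb"] = lq,
                      _["sigma"] = dp.sigma, _["circ_mfe"] = dp.circMFE());
}

// [[Rcpp::export(name = ".cf_backtrack")]]
List cf_backtrack(IntegerVector codes, int n, List par, List rules,
                  int a, int b) {
  FoldDP dp(codes, n, par, rules);
  dp.computeMFE();
  double e = dp.getE(a - 1, b - 1);
  if (e >= dp.par.inf)
    return List::create(_["pairs"] = IntegerMatrix(0, 2),
                        _["energy"] = NA_REAL, _["feasible"] = false);
  std::vector<std::pair<int,int> > prs;
  dp.btEb(a - 1, b - 1, prs);
  IntegerMatrix pm(prs.size(), 2);
  for (size_t r = 0; r < prs.size(); ++r) {
    pm(r, 0) = prs[r].first + 1;
    pm(r, 1) = prs[r].second + 1;
  }
  return List::create(_["pairs"] = pm, _["energy"] = e, _["feasible"] = true);
}

// [[Rcpp::export(name = ".cf_predict")]]
List cf_predict(IntegerVector codes, int n, List par, List rules,
                IntegerMatrix cand, int rule_mfe) {
  FoldDP dp(codes, n, par, rules);
  dp.computeMFE();
  dp.computeQ();
  int nc = cand.nrow();
  NumericVector lq(nc), en(nc);
  int best = -1;
  double bestval = R_PosInf;
  for (int r = 0; r < nc; ++r) {
    int i = cand(r, 0) - 1, j = cand(r, 1) - 1;
    double l1 = dp.logQwin(i, j), l2 = dp.logQwin(j, i + n);
    lq[r] = l1 + l2;
    double e = dp.getE(i, j) + dp.getE(j, i + n);
    en[r] = e >= dp.par.inf ? R_PosInf : e;
    double score = rule_mfe ? en[r] : -lq[r];   // -logQ ~ G/kT up to scale
    if (R_finite(score) && score < bestval - 1e-12) {
      bestval = score;
      best = r;
    }
  }
  if (best < 0)
    return List::create(_["feasible"] = false, _["logQ"] = lq,
                        _["energy"] = en);
  int i = cand(best, 0) - 1, j = cand(best, 1) - 1;
  std::vector<std::pair<int,int> > prs;
  dp.btEb(i, j, prs);
  dp.btEb(j, i + n, prs);
  // map doubled coords to circle (1-based), drop the duplicated closing pair
  std::vector<std::pair<int,int> > uniq;
  for (size_t r = 0; r < prs.size(); ++r) {
    int x = prs[r].first % n + 1, y = prs[r].second % n + 1;
    if (x > y) std::swap(x, y);
    bool seen = false;
    for (size_t t = 0; t < uniq.size(); ++t)
      if (uniq[t].first == x && uniq[t].second == y) { seen = true; break; }
    if (!seen) uniq.push_back(std::make_pair(x, y));
  }
  IntegerMatrix pm(uniq.size(), 2);
  for (size_t r = 0; r < uniq.size(); ++r) {
    pm(r, 0) = uniq[r].first;
    pm(r, 1) = uniq[r].second;
  }
  return List::create(_["feasible"] = true, _["best"] = best + 1,
                      _["logQ"] = lq, _["energy"] = en, _["pairs"] = pm,
                      _["mfe"] = en[best]);
}
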