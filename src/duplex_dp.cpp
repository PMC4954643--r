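#include <Rcpp.h>
using namespace Rcpp;

// Local antiparallel miRNA-site duplex alignment under an additive event
// scoring scheme.
//
// Sequences arrive integer-encoded (A=1, C=2, G=3, U=4, N=0); the site is
// already reversed so that index t runs along the site 3'->5' and pairing is
// (miRNA p, site t) with both indices increasing.
//
// Event grammar: the alignment is a sequence of events; first and last are
// PAIRs; PAIR positions are strictly increasing on both strands; between two
// PAIRs an internal loop consumes >=1 base and consists of one LOOP_OPEN
// followed by SYM (1 miRNA + 1 site base) and ASYM (1 base, either strand)
// extensions. PAIR at miRNA position 1 is legal only opposite A (m1A) and is
// scored by the single m1A weight; PAIRs at p>=2 require one of the six
// complementary pair types AU, UA, GC, CG, GU, UG. Loop events are indexed by
// the last consumed miRNA position (LOOP_OPEN and site-side ASYM do not
// consume a miRNA base).
//
// DP states per cell (p,t): M = best alignment ending with a PAIR at (p,t);
// L = best prefix ending inside a loop whose last consumed positions are
// (p,t). Ties are broken toward fewer events, then the 5'-most miRNA start,
// then the 5'-most site start (largest reversed t of the final PAIR handled
// at answer selection; within cells, the largest reversed start index).

namespace {

struct Cell {
  double score;
  int nev;     // events so far
  int mstart;  // miRNA position of the first PAIR
  int tstart;  // reversed site index of the first PAIR
  int choice;  // transition code, -1 = unreachable
  Cell() : score(R_NegInf), nev(0), mstart(0), tstart(0), choice(-1) {}
};

// choice codes for M: 0 fresh start, 1 from M[p-1][t-1], 2 from L[p-1][t-1]
// choice codes for L: 3 open+sym (M[p-1][t-1]), 4 open+asym_m (M[p-1][t]),
//                     5 open+asym_s (M[p][t-1]), 6 ext sym (L[p-1][t-1]),
//                     7 ext asym_m (L[p-1][t]), 8 ext asym_s (L[p][t-1])

inline int pair_type(int mb, int sb) {
  // 1 AU, 2 UA, 3 GC, 4 CG, 5 GU, 6 UG; 0 = not complementary
  if (mb == 1 && sb == 4) return 1;
  if (mb == 4 && sb == 1) return 2;
  if (mb == 3 && sb == 2) return 3;
  if (mb == 2 && sb == 3) return 4;
  if (mb == 3 && sb == 4) return 5;
  if (mb == 4 && sb == 3) return 6;
  return 0;
}

inline bool better(double sc, int nev, int mstart, int tstart, const Cell& c) {
  if (sc != c.score) return sc > c.score;
  if (nev != c.nev) return nev < c.nev;
  if (mstart != c.mstart) return mstart < c.mstart;
  return tstart > c.tstart;
}

}  // namespace

// [[Rcpp::export(name = ".duplex_dp")]]
List duplex_dp(IntegerVector mir, IntegerVector site_rev,
               NumericMatrix pair_w, double m1a, NumericVector open_w,
               NumericVector sym_w, NumericVector asym_w, NumericVector ind_w,
               int anchor_max_start) {
  const int P = mir.size();
  const int T = site_rev.size();
  std::vector<Cell> M((P + 1) * (T + 1)), L((P + 1) * (T + 1));
  auto at = [T](int p, int t) { return p * (T + 1) + t; };

  auto psc = [&](int p, int t, int& btype) -> double {
    int sb = site_rev[t - 1], mb = mir[p - 1];
    if (p == 1) {
      if (sb != 1) { btype = 0; return R_NegInf; }
      btype = 7;  // m1A pseudo-type
      return m1a + ind_w[0];
    }
    int b = pair_type(mb, sb);
    btype = b;
    if (b == 0) return R_NegInf;
    return pair_w(b - 1, p - 1) + ind_w[p - 1];
  };

  for (int p = 1; p <= P; ++p) {
    for (int t = 1; t <= T; ++t) {
      int bt;
      double ps = psc(p, t, bt);
      Cell& mc = M[at(p, t)];
      if (R_FINITE(ps)) {
        // fresh local start
        if (anchor_max_start <= 0 || p <= anchor_max_start) {
          if (better(ps, 1, p, t, mc)) {
            mc.score = ps; mc.nev = 1; mc.mstart = p; mc.tstart = t;
            mc.choice = 0;
          }
        }
        if (p >= 2 && t >= 2) {
          const Cell& pm = M[at(p - 1, t - 1)];
          if (pm.choice >= 0) {
            double sc = pm.score + ps;
            if (better(sc, pm.nev + 1, pm.mstart, pm.tstart, mc)) {
              mc.score = sc; mc.nev = pm.nev + 1; mc.mstart = pm.mstart;
              mc.tstart = pm.tstart; mc.choice = 1;
            }
          }
          const Cell& pl = L[at(p - 1, t - 1)];
          if (pl.choice >= 0) {
            double sc = pl.score + ps;
            if (better(sc, pl.nev + 1, pl.mstart, pl.tstart, mc)) {
              mc.score = sc; mc.nev = pl.nev + 1; mc.mstart = pl.mstart;
              mc.tstart = pl.tstart; mc.choice = 2;
            }
          }
        }
      }
      // L cell: loop prefix with last consumed positions (p,t)
      Cell& lc = L[at(p, t)];
      struct Cand { const Cell* src; double add; int nev_add; int code; };
      Cand cands[6];
      int nc = 0;
      if (p >= 2 && t >= 2) {
        const Cell& s = M[at(p - 1, t - 1)];
        if (s.choice >= 0)
          cands[nc++] = {&s, open_w[p - 2] + sym_w[p - 1], 2, 3};
      }
      if (p >= 2) {
        const Cell& s = M[at(p - 1, t)];
        if (s.choice >= 0)
          cands[nc++] = {&s, open_w[p - 2] + asym_w[p - 1], 2, 4};
      }
      if (t >= 2) {
        const Cell& s = M[at(p, t - 1)];
        if (s.choice >= 0)
          cands[nc++] = {&s, open_w[p - 1] + asym_w[p - 1], 2, 5};
      }
      if (p >= 2 && t >= 2) {
        const Cell& s = L[at(p - 1, t - 1)];
        if (s.choice >= 0) cands[nc++] = {&s, sym_w[p - 1], 1, 6};
      }
      if (p >= 2) {
        const Cell& s = L[at(p - 1, t)];
        if (s.choice >= 0) cands[nc++] = {&s, asym_w[p - 1], 1, 7};
      }
      if (t >= 2) {
        const Cell& s = L[at(p, t - 1)];
        if (s.choice >= 0) cands[nc++] = {&s, asym_w[p - 1], 1, 8};
      }
      for (int i = 0; i < nc; ++i) {
        double sc = cands[i].src->score + cands[i].add;
        int nev = cands[i].src->nev + cands[i].nev_add;
        if (better(sc, nev, cands[i].src->mstart, cands[i].src->tstart, lc)) {
          lc.score = sc; lc.nev = nev; lc.mstart = cands[i].src->mstart;
          lc.tstart = cands[i].src->tstart; lc.choice = cands[i].code;
        }
      }
    }
  }

  // answer: best M cell with score > 0, else empty alignment
  int bp = 0, bt = 0;
  Cell best;
  for (int p = 1; p <= P; ++p)
    for (int t = 1; t <= T; ++t) {
      const Cell& c = M[at(p, t)];
      if (c.choice >= 0 && c.score > 0 &&
          better(c.score, c.nev, c.mstart, c.tstart, best)) {
        best = c; bp = p; bt = t;
      }
    }
  if (bp == 0) {
    return List::create(_["score"] = 0.0,
                        _["events"] = IntegerMatrix(0, 4));
  }

  // traceback (emits events in reverse)
  std::vector<std::array<int, 4>> ev;  // code, p, t, pairtype
  int p = bp, t = bt, state = 0;  // 0 = in M, 1 = in L
  while (true) {
    if (state == 0) {
      const Cell& c = M[at(p, t)];
      int bt2;
      psc(p, t, bt2);
      ev.push_back({1, p, t, bt2});  // PAIR
      if (c.choice == 0) break;
      if (c.choice == 1) { --p; --t; state = 0; }
      else { --p; --t; state = 1; }
    } else {
      const Cell& c = L[at(p, t)];
      switch (c.choice) {
        case 3:  // open+sym from M[p-1][t-1]
          ev.push_back({3, p, t, 0});
          ev.push_back({2, p - 1, 0, 0});
          --p; --t; state = 0; break;
        case 4:
          ev.push_back({4, p, 0, 0});
          ev.push_back({2, p - 1, 0, 0});
          --p; state = 0; break;
        case 5:
          ev.push_back({5, p, t, 0});
          ev.push_back({2, p, 0, 0});
          --t; state = 0; break;
        case 6:
          ev.push_back({3, p, t, 0});
          --p; --t; break;
        case 7:
          ev.push_back({4, p, 0, 0});
          --p; break;
        case 8:
          ev.push_back({5, p, t, 0});
          --t; break;
        default:
          stop("corrupt traceback");
      }
    }
  }
  const int n = (int)ev.size();
  IntegerMatrix out(n, 4);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j) out(n - 1 - i, j) = ev[i][j];
  colnames(out) = CharacterVector::create("code", "p", "t", "pairtype");
  return List::create(_["score"] = best.score, _["events"] = out);
}
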