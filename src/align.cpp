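#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment engine over a precomputed match-score
// matrix S (n x m, S(i-1,j-1) = score of pairing residue i of seq1 with
// residue j of seq2).
//
// Semi-global convention: terminal gap columns (everything before the
// first MATCH column and after the last one) cost nothing; gap runs
// between matches are affine, go + k*ge for a run of length k (go, ge
// <= 0). An alignment's score is therefore the sum of its match scores
// plus the cost of its interior gap runs; the empty (all-gap) alignment
// scores 0.
//
// Forward state matrices ((n+1) x (m+1), -inf outside their domain):
//   Fm(i,j): best alignment prefix whose LAST match is (i, j)
//   Fx(i,j): prefix currently inside a charged delete run, residue i
//            just deleted at column j (a match precedes the run)
//   Fy(i,j): same for a charged insert run
// Backward state matrices:
//   Bm(i,j): best completion after a match at (i, j) (terminating is
//            free; any further gap opens pay go)
//   Bx(i,j): completion while inside a charged delete run that just
//            consumed residue i; must reach another match
//   By(i,j): same for an insert run
//
// Through-scores: T(i,j) = Fm(i,j) + Bm(i,j) is the best semi-global
// score among alignments containing edge (i,j) -- the Zuker quantity.

static const double NEG_INF = -1e100;

struct DPState {
  int n, m;
  double go, ge;
  std::vector<double> Fm, Fx, Fy, Bm, Bx, By;
  const NumericMatrix *S;
  inline int idx(int i, int j) const { return i * (m + 1) + j; }
  inline double s(int i, int j) const { return (*S)(i - 1, j - 1); }
};

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

static void fill_forward(DPState &st) {
  int n = st.n, m = st.m;
  double go = st.go, ge = st.ge;
  st.Fm.assign((n + 1) * (m + 1), NEG_INF);
  st.Fx.assign((n + 1) * (m + 1), NEG_INF);
  st.Fy.assign((n + 1) * (m + 1), NEG_INF);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int c = st.idx(i, j), d = st.idx(i - 1, j - 1);
      int u = st.idx(i - 1, j), l = st.idx(i, j - 1);
      // free leading overhang: a match may start the alignment (0 term)
      st.Fm[c] = st.s(i, j) +
        std::max(0.0, max3(st.Fm[d], st.Fx[d], st.Fy[d]));
      st.Fx[c] = ge + max3(st.Fm[u] + go, st.Fx[u], st.Fy[u] + go);
      st.Fy[c] = ge + max3(st.Fm[l] + go, st.Fy[l], st.Fx[l] + go);
    }
  }
}

static void fill_backward(DPState &st) {
  int n = st.n, m = st.m;
  double go = st.go, ge = st.ge;
  st.Bm.assign((n + 1) * (m + 1), NEG_INF);
  st.Bx.assign((n + 1) * (m + 1), NEG_INF);
  st.By.assign((n + 1) * (m + 1), NEG_INF);
  for (int i = n; i >= 0; --i) {
    for (int j = m; j >= 0; --j) {
      int c = st.idx(i, j);
      double mat = (i < n && j < m)
        ? st.s(i + 1, j + 1) + st.Bm[st.idx(i + 1, j + 1)] : NEG_INF;
      double dx = (i < n) ? st.Bx[st.idx(i + 1, j)] : NEG_INF;
      double iy = (j < m) ? st.By[st.idx(i, j + 1)] : NEG_INF;
      // from a match: terminate free, or pay an open for either gap
      st.Bm[c] = std::max(std::max(0.0, mat),
                          std::max(dx + go + ge, iy + go + ge));
      // inside a charged run: must reach another match eventually
      st.Bx[c] = max3(mat, dx + ge, iy + go + ge);
      st.By[c] = max3(mat, iy + ge, dx + go + ge);
    }
  }
}

static DPState make_state(const NumericMatrix &S, double go, double ge) {
  DPState st;
  st.n = S.nrow();
  st.m = S.ncol();
  st.go = go;
  st.ge = ge;
  st.S = &S;
  fill_forward(st);
  fill_backward(st);
  return st;
}

// Columns as (i, j) pairs with 0 standing for a gap.
typedef std::vector<std::pair<int, int> > Path;

// Backtrack the prefix ending with the MATCH at (i, j); emits columns in
// order, last column being (i, j). Tie-break: MATCH > DELETE > INSERT >
// free leading overhang.
static void trace_prefix(const DPState &st, int i, int j, Path &out) {
  std::vector<std::pair<int, int> > rev;
  int ci = i, cj = j, state = 0; // 0 = M, 1 = X, 2 = Y
  const double eps = 1e-9;
  for (;;) {
    if (state == 0) {
      rev.push_back(std::make_pair(ci, cj));
      double need = st.Fm[st.idx(ci, cj)] - st.s(ci, cj);
      int d = st.idx(ci - 1, cj - 1);
      if (ci > 1 && cj > 1 && std::abs(st.Fm[d] - need) < eps) state = 0;
      else if (ci > 1 && cj > 1 && std::abs(st.Fx[d] - need) < eps) state = 1;
      else if (ci > 1 && cj > 1 && std::abs(st.Fy[d] - need) < eps) state = 2;
      else { // free leading overhang covers the remaining residues
        for (int b = cj - 1; b >= 1; --b) rev.push_back(std::make_pair(0, b));
        for (int a = ci - 1; a >= 1; --a) rev.push_back(std::make_pair(a, 0));
        break;
      }
      --ci; --cj;
    } else if (state == 1) {
      rev.push_back(std::make_pair(ci, 0));
      double need = st.Fx[st.idx(ci, cj)] - st.ge;
      int u = st.idx(ci - 1, cj);
      if (std::abs(st.Fm[u] + st.go - need) < eps) state = 0;
      else if (std::abs(st.Fx[u] - need) < eps) state = 1;
      else state = 2;
      --ci;
    } else {
      rev.push_back(std::make_pair(0, cj));
      double need = st.Fy[st.idx(ci, cj)] - st.ge;
      int l = st.idx(ci, cj - 1);
      if (std::abs(st.Fm[l] + st.go - need) < eps) state = 0;
      else if (std::abs(st.Fy[l] - need) < eps) state = 2;
      else state = 1;
      --cj;
    }
  }
  for (int k = (int)rev.size() - 1; k >= 0; --k) out.push_back(rev[k]);
}

// Walk forward from the MATCH at (i, j) following the backward matrices.
static void trace_suffix(const DPState &st, int i, int j, Path &out) {
  int ci = i, cj = j, state = 0;
  const double eps = 1e-9;
  int n = st.n, m = st.m;
  for (;;) {
    int c = st.idx(ci, cj);
    double bval = (state == 0) ? st.Bm[c]
      : (state == 1) ? st.Bx[c] : st.By[c];
    double mat = (ci < n && cj < m)
      ? st.s(ci + 1, cj + 1) + st.Bm[st.idx(ci + 1, cj + 1)] : NEG_INF;
    double open = st.go + st.ge;
    double dx = (ci < n)
      ? st.Bx[st.idx(ci + 1, cj)] + (state == 1 ? st.ge : open) : NEG_INF;
    double iy = (cj < m)
      ? st.By[st.idx(ci, cj + 1)] + (state == 2 ? st.ge : open) : NEG_INF;
    if (std::abs(mat - bval) < eps) {
      out.push_back(std::make_pair(ci + 1, cj + 1));
      ++ci; ++cj; state = 0;
    } else if (std::abs(dx - bval) < eps) {
      out.push_back(std::make_pair(ci + 1, 0));
      ++ci; state = 1;
    } else if (std::abs(iy - bval) < eps) {
      out.push_back(std::make_pair(0, cj + 1));
      ++cj; state = 2;
    } else { // terminate: remaining residues form the free trailing overhang
      for (int r = ci + 1; r <= n; ++r) out.push_back(std::make_pair(r, 0));
      for (int cc = cj + 1; cc <= m; ++cc) out.push_back(std::make_pair(0, cc));
      return;
    }
  }
}

static IntegerMatrix path_to_matrix(const Path &p) {
  IntegerMatrix out(2, p.size());
  for (size_t k = 0; k < p.size(); ++k) {
    out(0, k) = p[k].first;
    out(1, k) = p[k].second;
  }
  return out;
}

static std::string path_key(const Path &p) {
  std::string key;
  key.reserve(p.size() * 8);
  char buf[32];
  for (size_t k = 0; k < p.size(); ++k) {
    snprintf(buf, sizeof(buf), "%d.%d;", p[k].first, p[k].second);
    key += buf;
  }
  return key;
}

// Best alignment through edge (i, j); realizes T(i,j) = Fm + Bm.
static Path through_edge_path(const DPState &st, int i, int j) {
  Path p;
  trace_prefix(st, i, j, p);
  trace_suffix(st, i, j, p);
  return p;
}

static Path staggered_path(int n, int m) {
  Path p;
  for (int r = 1; r <= n; ++r) p.push_back(std::make_pair(r, 0));
  for (int c = 1; c <= m; ++c) p.push_back(std::make_pair(0, c));
  return p;
}

// [[Rcpp::export]]
List cpp_semiglobal(NumericMatrix S, double go, double ge) {
  DPState st = make_state(S, go, ge);
  int n = st.n, m = st.m;
  double bestT = NEG_INF;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double t = st.Fm[st.idx(i, j)] + st.Bm[st.idx(i, j)];
      if (t > bestT + 1e-9) { bestT = t; bi = i; bj = j; }
    }
  double sopt = std::max(0.0, bestT);
  Path p = (bi > 0 && bestT > 0) ? through_edge_path(st, bi, bj)
                                 : staggered_path(n, m);
  return List::create(_["score"] = sopt, _["path"] = path_to_matrix(p));
}

// [[Rcpp::export]]
List cpp_zuker(NumericMatrix S, double go, double ge) {
  DPState st = make_state(S, go, ge);
  int n = st.n, m = st.m;
  NumericMatrix T(n, m), R(n, m);
  double sopt = 0.0;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double t = st.Fm[st.idx(i, j)] + st.Bm[st.idx(i, j)];
      T(i - 1, j - 1) = t;
      if (t > sopt) sopt = t;
    }
  // Exact best score avoiding edge (i,j). An alignment avoids it by
  // matching residue i elsewhere in the row, deleting it inside a
  // charged run, keeping all its matches strictly below/above row i
  // (residue i then sits in a free overhang), or being empty:
  //   S_avoid(i,j) = max( max_{j' != j} T(i,j'),
  //                       max_b Fx(i,b) + Bx(i,b),
  //                       max_{a<i,b} Fm(a,b),
  //                       max_{c>i,d} s(c,d) + Bm(c,d),  0 ).
  std::vector<double> below(n + 2, NEG_INF), above(n + 2, NEG_INF);
  for (int i = 1; i <= n; ++i) {
    double rm = NEG_INF, sm = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      rm = std::max(rm, st.Fm[st.idx(i, j)]);
      sm = std::max(sm, st.s(i, j) + st.Bm[st.idx(i, j)]);
    }
    below[i] = std::max(below[i - 1], rm); // best Fm over rows <= i
    above[i] = sm;                         // best first-match in row i
  }
  for (int i = n; i >= 1; --i) above[i] = std::max(above[i + 1], above[i]);
  for (int i = 1; i <= n; ++i) {
    double best = NEG_INF, second = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double t = T(i - 1, j - 1);
      if (t > best) { second = best; best = t; }
      else if (t > second) { second = t; }
    }
    double vdel = NEG_INF;
    for (int j = 0; j <= m; ++j) {
      double v = st.Fx[st.idx(i, j)] + st.Bx[st.idx(i, j)];
      if (v > vdel) vdel = v;
    }
    double off_row = std::max(std::max(vdel, 0.0),
                              std::max(below[i - 1], above[i + 1]));
    for (int j = 1; j <= m; ++j) {
      double t = T(i - 1, j - 1);
      double row_alt = (t >= best - 1e-12) ? second : best;
      R(i - 1, j - 1) = t - std::max(row_alt, off_row);
    }
  }
  return List::create(_["s_opt"] = sopt, _["through"] = T,
                      _["robustness"] = R);
}

// [[Rcpp::export]]
List cpp_pool(NumericMatrix S, double go, double ge, double threshold) {
  DPState st = make_state(S, go, ge);
  int n = st.n, m = st.m;
  double sopt = 0.0;
  std::map<std::string, std::pair<Path, double> > pool;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double t = st.Fm[st.idx(i, j)] + st.Bm[st.idx(i, j)];
      if (t > sopt) sopt = t;
      if (t >= threshold - 1e-9) {
        Path p = through_edge_path(st, i, j);
        pool[path_key(p)] = std::make_pair(p, t);
      }
    }
  }
  List paths(pool.size());
  NumericVector scores(pool.size());
  int k = 0;
  for (std::map<std::string, std::pair<Path, double> >::iterator it =
         pool.begin(); it != pool.end(); ++it, ++k) {
    paths[k] = path_to_matrix(it->second.first);
    scores[k] = it->second.second;
  }
  return List::create(_["s_opt"] = sopt, _["paths"] = paths,
                      _["scores"] = scores);
}

// Smith-Waterman local alignment with affine gaps; the alignment must
// start and end with a MATCH column.
// [[Rcpp::export]]
List cpp_local(NumericMatrix S, double go, double ge) {
  int n = S.nrow(), m = S.ncol();
  int W = m + 1;
  std::vector<double> Hm((n + 1) * (m + 1), NEG_INF),
    Hx((n + 1) * (m + 1), NEG_INF), Hy((n + 1) * (m + 1), NEG_INF);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int c = i * W + j, d = (i - 1) * W + (j - 1);
      int u = (i - 1) * W + j, l = i * W + (j - 1);
      double prev = std::max(0.0, max3(Hm[d], Hx[d], Hy[d]));
      Hm[c] = S(i - 1, j - 1) + prev;
      Hx[c] = ge + max3(Hm[u] + go, Hx[u], Hy[u] + go);
      Hy[c] = ge + max3(Hm[l] + go, Hy[l], Hx[l] + go);
      if (Hm[c] > best + 1e-9) { best = Hm[c]; bi = i; bj = j; }
    }
  }
  if (bi == 0) {
    return List::create(_["score"] = 0.0,
                        _["path"] = IntegerMatrix(2, 0),
                        _["bounds"] = IntegerVector::create(NA_INTEGER,
                          NA_INTEGER, NA_INTEGER, NA_INTEGER));
  }
  Path rev;
  int ci = bi, cj = bj, state = 0;
  const double eps = 1e-9;
  for (;;) {
    int c = ci * W + cj;
    if (state == 0) {
      rev.push_back(std::make_pair(ci, cj));
      double need = Hm[c] - S(ci - 1, cj - 1);
      int d = (ci - 1) * W + (cj - 1);
      if (need > -eps && need < eps) break; // fresh start: alignment begins
      if (std::abs(Hm[d] - need) < eps) state = 0;
      else if (std::abs(Hx[d] - need) < eps) state = 1;
      else state = 2;
      --ci; --cj;
    } else if (state == 1) {
      rev.push_back(std::make_pair(ci, 0));
      double need = Hx[c] - ge;
      int u = (ci - 1) * W + cj;
      if (std::abs(Hm[u] + go - need) < eps) state = 0;
      else if (std::abs(Hx[u] - need) < eps) state = 1;
      else state = 2;
      --ci;
    } else {
      rev.push_back(std::make_pair(0, cj));
      double need = Hy[c] - ge;
      int l = ci * W + (cj - 1);
      if (std::abs(Hm[l] + go - need) < eps) state = 0;
      else if (std::abs(Hy[l] - need) < eps) state = 2;
      else state = 1;
      --cj;
    }
  }
  Path p(rev.rbegin(), rev.rend());
  int si = p.front().first, sj = p.front().second;
  return List::create(_["score"] = best, _["path"] = path_to_matrix(p),
                      _["bounds"] = IntegerVector::create(si, sj, bi, bj));
}
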