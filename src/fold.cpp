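#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Residue codes used throughout: A=0, C=1, G=2, U=3, N=4, gap=5.

// [[Rcpp::export]]
IntegerMatrix cpp_nussinov_general(NumericMatrix S, int min_loop,
                                   double stack_bonus = 0.0) {
  // Maximum-weight nested pairing over an n x n score matrix, with an
  // optional bonus for directly stacked pairs ((i,j) over (i+1,j-1)).
  // S(i,j) = NA -> pair (i,j) disallowed. min_loop enforced here too.
  // Traceback prefers pairing the smallest i, then the smallest partner j,
  // then the stacked continuation.
  // W(i,j): best score on [i,j]; V(i,j): best score with (i,j) paired.
  const int n = S.nrow();
  const double EPS = 1e-9;
  const double NEG = -1e100;
  std::vector<std::vector<double> > W(n + 1, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<double> > V(n + 1, std::vector<double>(n + 1, NEG));
  #define WW(i, j) (((j) < (i)) ? 0.0 : W[i][j])
  if (n > 0) {
    for (int i = n - 1; i >= 0; --i) {
      for (int j = i; j < n; ++j) {
        if (j - i - 1 >= min_loop && !NumericMatrix::is_na(S(i, j))) {
          double inner = WW(i + 1, j - 1);
          if (V[i + 1][j - 1] > NEG / 2) {
            double st = V[i + 1][j - 1] + stack_bonus;
            if (st > inner) inner = st;
          }
          V[i][j] = S(i, j) + inner;
        }
        double best = (i + 1 <= j) ? W[i + 1][j] : 0.0; // i unpaired
        for (int l = i + min_loop + 1; l <= j; ++l) {
          if (V[i][l] <= NEG / 2) continue;
          double v = V[i][l] + WW(l + 1, j);
          if (v > best) best = v;
        }
        W[i][j] = best;
      }
    }
  }
  // traceback over (interval, state) items; state 0 = W, 1 = V
  std::vector<std::pair<int, int> > pairs;
  struct Item { int i, j, state; };
  std::vector<Item> stack;
  if (n > 0) stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    Item it = stack.back();
    stack.pop_back();
    int i = it.i, j = it.j;
    if (i >= j) continue;
    if (it.state == 1) {
      pairs.push_back(std::make_pair(i, j));
      double rest = V[i][j] - S(i, j);
      if (V[i + 1][j - 1] > NEG / 2 &&
          std::fabs(V[i + 1][j - 1] + stack_bonus - rest) < EPS) {
        stack.push_back({i + 1, j - 1, 1});
      } else if (i + 1 <= j - 1) {
        stack.push_back({i + 1, j - 1, 0});
      }
      continue;
    }
    double target = W[i][j];
    bool paired = false;
    for (int l = i + min_loop + 1; l <= j; ++l) {
      if (V[i][l] <= NEG / 2) continue;
      if (V[i][l] + WW(l + 1, j) >= target - EPS) {
        stack.push_back({i, l, 1});
        if (l + 1 <= j) stack.push_back({l + 1, j, 0});
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back({i + 1, j, 0});
  }
  #undef WW
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first;
    out(k, 1) = pairs[k].second;
  }
  out.attr("score") = (n > 0) ? W[0][n - 1] : 0.0;
  return out;
}

// [[Rcpp::export]]
List cpp_mccaskill(NumericMatrix Q, double scale) {
  // Inside-outside over the unambiguous grammar
  //   Z(i,j)  = Z(i,j-1) + sum_k Z(i,k-1) * Zb(k,j)
  //   Zb(k,j) = Q(k,j) * Z(k+1,j-1)
  // Q(k,j) = exp(-E(k,j)/kT) for admissible pairs, 0 otherwise
  // (caller bakes in canonical-pair, N and min_loop constraints).
  // All tables carry scale^-(span length) to avoid overflow; the scale
  // cancels exactly in P = Zb * Ob / Z(0,n-1).
  const int n = Q.nrow();
  NumericMatrix P(n, n);
  if (n == 0) return List::create(_["P"] = P, _["ok"] = true, _["logZ"] = 0.0);
  const double s = scale, s2 = scale * scale;
  std::vector<std::vector<double> > Z(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double> > Zb(n, std::vector<double>(n, 0.0));
  // z(i,j): scaled inside value; empty interval (j < i) == 1
  #define ZZ(i, j) (((j) < (i)) ? 1.0 : Z[i][j])
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double v = ZZ(i, j - 1) / s; // j unpaired
      for (int k = i; k < j; ++k) {
        double q = Q(k, j);
        if (q == 0.0) continue;
        double zb = (q / s2) * ZZ(k + 1, j - 1);
        Zb[k][j] = zb;
        v += ZZ(i, k - 1) * zb;
      }
      Z[i][j] = v;
    }
  }
  double Ztot = ZZ(0, n - 1);
  if (!std::isfinite(Ztot) || Ztot <= 0.0) {
    return List::create(_["P"] = P, _["ok"] = false, _["logZ"] = NA_REAL);
  }
  // outside
  std::vector<std::vector<double> > O(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double> > Ob(n, std::vector<double>(n, 0.0));
  O[0][n - 1] = 1.0;
  bool finite = true;
  for (int len = n; len >= 1; --len) {
    // push from Z-items of this length
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double o = O[i][j];
      if (o == 0.0) continue;
      if (j - 1 >= i) O[i][j - 1] += o / s;
      for (int k = i; k < j; ++k) {
        if (Q(k, j) == 0.0) continue;
        Ob[k][j] += o * ZZ(i, k - 1);
        if (k - 1 >= i) O[i][k - 1] += o * Zb[k][j];
      }
    }
    // push from Zb-items of this length
    for (int k = 0; k + len - 1 < n; ++k) {
      int j = k + len - 1;
      double ob = Ob[k][j];
      if (ob == 0.0) continue;
      if (k + 1 <= j - 1) O[k + 1][j - 1] += ob * (Q(k, j) / s2);
      if (!std::isfinite(ob)) finite = false;
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (Zb[i][j] == 0.0) continue;
      double p = Zb[i][j] * Ob[i][j] / Ztot;
      if (!std::isfinite(p)) finite = false;
      P(i, j) = p;
    }
  }
  #undef ZZ
  return List::create(_["P"] = P, _["ok"] = finite,
                      _["logZ"] = std::log(Ztot) + n * std::log(s));
}

static inline double pair_score_code(int a, int b, double gc, double au,
                                     double gu, double mism) {
  // a 5' residue, b 3' residue (codes A0 C1 G2 U3); N(4)+ never pairs
  if (a > 3 || b > 3) return mism;
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return gu;
  return mism;
}

// [[Rcpp::export]]
List cpp_duplex(IntegerVector leader, IntegerVector trailer,
                double sc_gc, double sc_au, double sc_gu,
                double sc_mismatch, double sc_gap) {
  // Local (Smith-Waterman style) alignment of leader 5'->3' against
  // trailer 3'->5'; diagonal steps score as intermolecular basepairs.
  const int n = leader.size(), m = trailer.size();
  // reverse trailer so both run left to right
  std::vector<int> r(m);
  for (int j = 0; j < m; ++j) r[j] = trailer[m - 1 - j];
  std::vector<std::vector<double> > H(n + 1, std::vector<double>(m + 1, 0.0));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H[i - 1][j - 1] +
        pair_score_code(leader[i - 1], r[j - 1], sc_gc, sc_au, sc_gu, sc_mismatch);
      double up = H[i - 1][j] + sc_gap;
      double left = H[i][j - 1] + sc_gap;
      double v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0.0) v = 0.0;
      H[i][j] = v;
      if (v > best + 1e-12) { best = v; bi = i; bj = j; }
    }
  }
  std::vector<int> lp, tp; // paired positions (canonical only)
  int i = bi, j = bj;
  const double EPS = 1e-9;
  while (i > 0 && j > 0 && H[i][j] > EPS) {
    double sc = pair_score_code(leader[i - 1], r[j - 1], sc_gc, sc_au, sc_gu,
                                sc_mismatch);
    if (std::fabs(H[i][j] - (H[i - 1][j - 1] + sc)) < EPS) {
      if (sc > 0) { lp.push_back(i - 1); tp.push_back(m - 1 - (j - 1)); }
      --i; --j;
    } else if (std::fabs(H[i][j] - (H[i - 1][j] + sc_gap)) < EPS) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(lp.begin(), lp.end());
  std::reverse(tp.begin(), tp.end());
  return List::create(_["score"] = best,
                      _["leader_pos"] = IntegerVector(lp.begin(), lp.end()),
                      _["trailer_pos"] = IntegerVector(tp.begin(), tp.end()),
                      _["leader_from"] = (bi > 0 && !lp.empty()) ? i : -1,
                      _["leader_to"] = (bi > 0 && !lp.empty()) ? (bi - 1) : -1);
}

// [[Rcpp::export]]
List cpp_profile_align(IntegerMatrix A, IntegerMatrix B, double match,
                       double mismatch, double gap_open, double gap_ext) {
  // Global affine-gap (Gotoh) alignment of two alignment profiles.
  // Column-vs-column score: mean over all row pairs of
  //   0 if either residue is N or a gap, match if equal, mismatch otherwise.
  // Returns 0-based column index paths with -1 marking an inserted gap.
  const int n = A.ncol(), m = B.ncol();
  const int ra = A.nrow(), rb = B.nrow();
  // per-column residue counts (A,C,G,U)
  std::vector<std::array<double, 4> > ca(n), cb(m);
  for (int j = 0; j < n; ++j) {
    ca[j] = {0, 0, 0, 0};
    for (int i = 0; i < ra; ++i) {
      int c = A(i, j);
      if (c >= 0 && c < 4) ca[j][c] += 1;
    }
  }
  for (int j = 0; j < m; ++j) {
    cb[j] = {0, 0, 0, 0};
    for (int i = 0; i < rb; ++i) {
      int c = B(i, j);
      if (c >= 0 && c < 4) cb[j][c] += 1;
    }
  }
  const double denom = (double)ra * (double)rb;
  const double NEG = -1e100;
  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double> > X(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double> > Y(n + 1, std::vector<double>(m + 1, NEG));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[i][0] = gap_open + (i - 1) * gap_ext; // columns of A against gaps
  for (int j = 1; j <= m; ++j) Y[0][j] = gap_open + (j - 1) * gap_ext;
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i > 0 && j > 0) {
        double sa = 0.0, sb = 0.0, seq = 0.0;
        for (int c = 0; c < 4; ++c) {
          sa += ca[i - 1][c];
          sb += cb[j - 1][c];
          seq += ca[i - 1][c] * cb[j - 1][c];
        }
        double s = (match * seq + mismatch * (sa * sb - seq)) / denom;
        double prev = std::max(M[i - 1][j - 1],
                               std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
        M[i][j] = prev + s;
      }
      if (i > 0) {
        double a = std::max(M[i - 1][j], Y[i - 1][j]) + gap_open;
        double b = X[i - 1][j] + gap_ext;
        if (!(i > 0 && j == 0)) X[i][j] = std::max(a, b);
      }
      if (j > 0) {
        double a = std::max(M[i][j - 1], X[i][j - 1]) + gap_open;
        double b = Y[i][j - 1] + gap_ext;
        if (!(j > 0 && i == 0)) Y[i][j] = std::max(a, b);
      }
    }
  }
  double sc = std::max(M[n][m], std::max(X[n][m], Y[n][m]));
  // traceback; prefer M, then X (gap in B), then Y
  std::vector<int> pa, pb;
  int i = n, j = m;
  int state; // 0 M, 1 X, 2 Y
  const double EPS = 1e-9;
  if (std::fabs(sc - M[n][m]) < EPS) state = 0;
  else if (std::fabs(sc - X[n][m]) < EPS) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(i - 1); pb.push_back(j - 1);
      double prev = M[i][j]; // == max(prev states) + s; recover which
      double sa = 0.0, sb = 0.0, seq = 0.0;
      for (int c = 0; c < 4; ++c) {
        sa += ca[i - 1][c]; sb += cb[j - 1][c];
        seq += ca[i - 1][c] * cb[j - 1][c];
      }
      double s = (match * seq + mismatch * (sa * sb - seq)) / denom;
      double want = prev - s;
      if (std::fabs(want - M[i - 1][j - 1]) < EPS) state = 0;
      else if (std::fabs(want - X[i - 1][j - 1]) < EPS) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      pa.push_back(i - 1); pb.push_back(-1);
      double want = X[i][j];
      if (std::fabs(want - (X[i - 1][j] + gap_ext)) < EPS &&
          X[i - 1][j] > NEG / 2) state = 1;
      else if (std::fabs(want - (M[i - 1][j] + gap_open)) < EPS) state = 0;
      else state = 2;
      --i;
    } else {
      pa.push_back(-1); pb.push_back(j - 1);
      double want = Y[i][j];
      if (std::fabs(want - (Y[i][j - 1] + gap_ext)) < EPS &&
          Y[i][j - 1] > NEG / 2) state = 2;
      else if (std::fabs(want - (M[i][j - 1] + gap_open)) < EPS) state = 0;
      else state = 1;
      --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = sc,
                      _["a_cols"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_cols"] = IntegerVector(pb.begin(), pb.end()));
}
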