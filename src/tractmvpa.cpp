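// Core numerical kernels: a compact SMO solver for the soft-margin C-SVC
// dual, a fused leave-one-out CV path for the SVM family (feature scoring,
// top-fraction selection, standardization, kernel evaluation and training all
// inside one call so permutation tests stay cheap), and the TFCE
// threshold-integration loop with union-find connected components.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SMO_TAU = 1e-12;

// Solve the C-SVC dual: min 1/2 a'Qa - e'a, 0 <= a <= C, y'a = 0, with
// Q_ij = y_i y_j K_ij, by maximal-violating-pair SMO. Returns dual
// coefficients y_i * alpha_i and the intercept b of f(x) = sum ya_i K(x_i, x) + b.
static void smo_solve(const std::vector<double>& K, const std::vector<double>& y,
                      int n, double C, double eps, int max_iter,
                      std::vector<double>& ya, double& b, bool& converged) {
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // working-set selection: maximal violating pair
    double m = -HUGE_VAL, M = HUGE_VAL;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < eps) { converged = true; break; }
    double Qii = K[i + n * i], Qjj = K[j + n * j];
    double Kij = K[i + n * j];
    double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      // Q_ij = y_i y_j K_ij = -K_ij here, so the dual curvature is
      // K_ii + K_jj - 2 K_ij in both branches
      double quad = Qii + Qjj - 2.0 * Kij;
      if (quad <= 0) quad = SMO_TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = Qii + Qjj - 2.0 * Kij;
      if (quad <= 0) quad = SMO_TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }
    double di = y[i] * (alpha[i] - ai_old), dj = y[j] * (alpha[j] - aj_old);
    // gradient update uses Q_ts = y_t y_s K_ts
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (K[t + n * i] * di + K[t + n * j] * dj);
  }
  // intercept from free support vectors, else midpoint of the violation bounds
  double bsum = 0.0; int nfree = 0;
  double m = -HUGE_VAL, M = HUGE_VAL;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (up && v > m) m = v;
    if (lo && v < M) M = v;
    if (alpha[t] > 0 && alpha[t] < C) { bsum += -y[t] * G[t]; ++nfree; }
  }
  b = nfree > 0 ? bsum / nfree : (m + M) / 2.0;
  ya.assign(n, 0.0);
  for (int t = 0; t < n; ++t) ya[t] = y[t] * alpha[t];
}

// kernel codes: 0 linear u.v ; 1 polynomial (gamma u.v + coef0)^degree ;
// 2 RBF exp(-gamma |u-v|^2)   (libsvm conventions)
static inline double kernel_from_parts(double dot, double d2, int kernel,
                                       double gamma, double degree, double coef0) {
  switch (kernel) {
    case 0: return dot;
    case 1: return std::pow(gamma * dot + coef0, degree);
    default: return std::exp(-gamma * d2);
  }
}

// [[Rcpp::export]]
List svm_fit_cpp(NumericMatrix X, NumericVector y, int kernel, double cost,
                 double gamma, double degree, double coef0,
                 double eps = 1e-5, int max_iter = 200000) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> K(n * n), yy(y.begin(), y.end());
  for (int a = 0; a < n; ++a)
    for (int bI = a; bI < n; ++bI) {
      double dot = 0, d2 = 0;
      for (int c = 0; c < p; ++c) {
        double u = X(a, c), v = X(bI, c);
        dot += u * v; d2 += (u - v) * (u - v);
      }
      double k = kernel_from_parts(dot, d2, kernel, gamma, degree, coef0);
      K[a + n * bI] = K[bI + n * a] = k;
    }
  std::vector<double> ya; double b; bool conv;
  smo_solve(K, yy, n, cost, eps, max_iter, ya, b, conv);
  return List::create(_["ya"] = NumericVector(ya.begin(), ya.end()),
                      _["b"] = b, _["converged"] = conv);
}

// [[Rcpp::export]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, NumericVector ya, double b,
                               NumericMatrix Xnew, int kernel, double gamma,
                               double degree, double coef0) {
  int n = Xtrain.nrow(), p = Xtrain.ncol(), m = Xnew.nrow();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double f = b;
    for (int t = 0; t < n; ++t) {
      if (ya[t] == 0) continue;
      double dot = 0, d2 = 0;
      for (int c = 0; c < p; ++c) {
        double u = Xtrain(t, c), v = Xnew(q, c);
        dot += u * v; d2 += (u - v) * (u - v);
      }
      f += ya[t] * kernel_from_parts(dot, d2, kernel, gamma, degree, coef0);
    }
    out[q] = f;
  }
  return out;
}

// Fused SVM leave-one-out CV over a (fraction x cost x gamma) grid.
// For each held-out subject: F-scores, top-fraction selection,
// standardization and training use the remaining subjects only.
// Returns a (grid x n) matrix of held-out decision scores, grid index
// running fraction-major, then cost, then gamma.
// [[Rcpp::export]]
NumericMatrix svm_loocv_cpp(NumericMatrix X, NumericVector y, int kernel,
                            NumericVector fractions, NumericVector costs,
                            NumericVector gammas, double degree, double coef0,
                            bool standardize, double eps = 1e-5,
                            int max_iter = 200000) {
  int n = X.nrow(), p = X.ncol();
  int nf = fractions.size(), nc = costs.size(), ng = gammas.size();
  NumericMatrix out(nf * nc * ng, n);
  int ntr = n - 1;
  std::vector<int> tr(ntr);
  std::vector<double> score(p), mu(p), sdv(p), ytr(ntr);
  std::vector<int> ord(p);
  std::vector<double> Z(ntr * p), ztest(p);

  for (int hold = 0; hold < n; ++hold) {
    int k2 = 0;
    for (int t = 0; t < n; ++t) if (t != hold) tr[k2++] = t;
    int npos = 0, nneg = 0;
    for (int t = 0; t < ntr; ++t) { ytr[t] = y[tr[t]]; if (ytr[t] > 0) ++npos; else ++nneg; }

    // per-voxel F-score on the training rows
    for (int c = 0; c < p; ++c) {
      double sp = 0, sn = 0, sp2 = 0, sn2 = 0;
      for (int t = 0; t < ntr; ++t) {
        double v = X(tr[t], c);
        if (ytr[t] > 0) { sp += v; sp2 += v * v; } else { sn += v; sn2 += v * v; }
      }
      double mp = sp / npos, mn = sn / nneg, mall = (sp + sn) / ntr;
      double vp = (sp2 - npos * mp * mp) / (npos - 1);
      double vn = (sn2 - nneg * mn * mn) / (nneg - 1);
      double num = (mp - mall) * (mp - mall) + (mn - mall) * (mn - mall);
      double den = vp + vn;
      score[c] = den > 0 ? num / den : (num > 0 ? HUGE_VAL : 0.0);
    }
    for (int c = 0; c < p; ++c) ord[c] = c;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int bI) { return score[a] > score[bI]; });

    for (int fi = 0; fi < nf; ++fi) {
      int k = (int)std::ceil(fractions[fi] * p);
      if (k < 1) k = 1; if (k > p) k = p;
      // standardization parameters from the training rows
      for (int cc = 0; cc < k; ++cc) {
        int c = ord[cc];
        double s = 0, s2 = 0;
        for (int t = 0; t < ntr; ++t) { double v = X(tr[t], c); s += v; s2 += v * v; }
        double m = s / ntr;
        double var = (s2 - ntr * m * m) / (ntr - 1);
        double sdev = var > 0 ? std::sqrt(var) : 1.0;
        if (!standardize) { m = 0.0; sdev = 1.0; }
        mu[cc] = m; sdv[cc] = sdev;
        for (int t = 0; t < ntr; ++t) Z[t + ntr * cc] = (X(tr[t], c) - m) / sdev;
        ztest[cc] = (X(hold, c) - m) / sdev;
      }
      // pairwise dot products / squared distances once per fraction
      std::vector<double> dot(ntr * ntr), d2;
      std::vector<double> dot_t(ntr), d2_t;
      bool need_d2 = (kernel == 2);
      if (need_d2) { d2.assign(ntr * ntr, 0.0); d2_t.assign(ntr, 0.0); }
      for (int a = 0; a < ntr; ++a)
        for (int bI = a; bI < ntr; ++bI) {
          double dd = 0, q2 = 0;
          for (int cc = 0; cc < k; ++cc) {
            double u = Z[a + ntr * cc], v = Z[bI + ntr * cc];
            dd += u * v; if (need_d2) q2 += (u - v) * (u - v);
          }
          dot[a + ntr * bI] = dot[bI + ntr * a] = dd;
          if (need_d2) d2[a + ntr * bI] = d2[bI + ntr * a] = q2;
        }
      for (int a = 0; a < ntr; ++a) {
        double dd = 0, q2 = 0;
        for (int cc = 0; cc < k; ++cc) {
          double u = Z[a + ntr * cc], v = ztest[cc];
          dd += u * v; if (need_d2) q2 += (u - v) * (u - v);
        }
        dot_t[a] = dd; if (need_d2) d2_t[a] = q2;
      }
      std::vector<double> K(ntr * ntr), ya;
      for (int ci = 0; ci < nc; ++ci)
        for (int gi = 0; gi < ng; ++gi) {
          double gam = gammas[gi];
          for (int a = 0; a < ntr * ntr; ++a)
            K[a] = kernel_from_parts(dot[a], need_d2 ? d2[a] : 0.0, kernel,
                                     gam, degree, coef0);
          double b; bool conv;
          smo_solve(K, ytr, ntr, costs[ci], eps, max_iter, ya, b, conv);
          double f = b;
          for (int t = 0; t < ntr; ++t)
            if (ya[t] != 0)
              f += ya[t] * kernel_from_parts(dot_t[t], need_d2 ? d2_t[t] : 0.0,
                                             kernel, gam, degree, coef0);
          out((fi * nc + ci) * ng + gi, hold) = f;
        }
    }
  }
  return out;
}

// ---- TFCE ----------------------------------------------------------------

struct UnionFind {
  std::vector<int> parent, size;
  UnionFind(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
  }
};

// TFCE for a non-negative map: out[v] = sum over thresholds h of
// extent(v, h)^E * h^H * dh, where extent is the size of v's connected
// suprathreshold (value >= h) cluster under the skeleton adjacency.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector values, IntegerVector from, IntegerVector to,
                       NumericVector thresholds, double E, double H, double dh) {
  int V = values.size(), m = from.size();
  NumericVector out(V);
  for (int s = 0; s < thresholds.size(); ++s) {
    double h = thresholds[s];
    UnionFind uf(V);
    for (int e = 0; e < m; ++e) {
      int a = from[e], b = to[e];
      if (values[a] >= h && values[b] >= h) uf.unite(a, b);
    }
    double hH = std::pow(h, H);
    for (int v = 0; v < V; ++v)
      if (values[v] >= h)
        out[v] += std::pow((double)uf.size[uf.find(v)], E) * hH * dh;
  }
  return out;
}
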