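// Compiled inner loops for the decoding pipeline.
//
// The decoding analyses fit on the order of 10^6-10^7 small linear SVMs
// (pseudo-trial counts n <= ~30, dimensions d <= ~306), one per
// (condition pair, time point, repetition, cross-validation fold).  The
// C-SVM dual is solved here with a dense SMO working-set solver on the
// precomputed linear Gram matrix; this is the same optimization problem
// libsvm solves, specialized to tiny dense problems.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------------------
// SMO solver for the C-SVM dual:
//   min_a 0.5 a' Q a - e' a ,  Q_ij = y_i y_j K_ij,  0 <= a <= C,  y'a = 0
// Maximal-violating-pair working-set selection; `b` is the intercept of the
// decision function f(x) = sum_i a_i y_i K(x_i, x) + b.
// One SMO optimization run on (a masked subset of) the problem.  `skip1`
// and `skip2` (-1 = none) exclude points from the working set entirely;
// their alpha must be 0 on entry (leave-one-out holdouts).
//
// The violation value v_t = -y_t * g_t is maintained directly (dv does not
// depend on y), and box-eligibility is carried as additive masks so the
// working-set scans vectorize.
static void smo_iterate(const mat& K, const vec& y, double C, vec& alpha,
                        vec& g, double& b, double tol, int max_iter,
                        int skip1 = -1, int skip2 = -1) {
  const int n = K.n_rows;
  const double NEG = -1e300, POS = 1e300;
  vec v(n), upm(n), lom(n);
  for (int t = 0; t < n; ++t) {
    v[t] = -y[t] * g[t];
    const bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    const bool lo = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    upm[t] = up ? 0.0 : NEG;
    lom[t] = lo ? 0.0 : POS;
  }
  if (skip1 >= 0) { upm[skip1] = NEG; lom[skip1] = POS; }
  if (skip2 >= 0) { upm[skip2] = NEG; lom[skip2] = POS; }
  const double* vp = v.memptr();
  const double* up_p = upm.memptr();
  const double* lo_p = lom.memptr();
  double vmax = NEG, vmin = POS;

  for (int it = 0; it < max_iter; ++it) {
    // vectorizable reduction first, index lookup second
    vmax = NEG; vmin = POS;
    for (int t = 0; t < n; ++t) {
      const double a1 = vp[t] + up_p[t];
      const double a2 = vp[t] + lo_p[t];
      vmax = (a1 > vmax) ? a1 : vmax;
      vmin = (a2 < vmin) ? a2 : vmin;
    }
    if (vmax <= NEG / 2 || vmin >= POS / 2 || vmax - vmin < tol) break;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      if (i < 0 && vp[t] + up_p[t] == vmax) i = t;
      if (j < 0 && vp[t] + lo_p[t] == vmin) j = t;
    }
    if (i < 0 || j < 0) break;
    const double* Ki = K.colptr(i);
    const double* Kj = K.colptr(j);

    double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
    if (quad < 1e-12) quad = 1e-12;
    double s = (vmax - vmin) / quad;
    const double cap_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    const double cap_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    s = std::min(s, std::min(cap_i, cap_j));
    if (s <= 0) break;

    const double dai = (y[i] > 0) ? s : -s; // alpha_i += y_i * s
    const double daj = (y[j] > 0) ? -s : s; // alpha_j -= y_j * s
    alpha[i] += dai;
    alpha[j] += daj;
    const double ci = y[i] * dai, cj = y[j] * daj;
    double* vw = v.memptr();
    for (int t = 0; t < n; ++t)
      vw[t] -= ci * Ki[t] + cj * Kj[t];
    for (int u : {i, j}) {
      const bool up = (y[u] > 0) ? (alpha[u] < C) : (alpha[u] > 0);
      const bool lo = (y[u] > 0) ? (alpha[u] > 0) : (alpha[u] < C);
      upm[u] = up ? 0.0 : NEG;
      lom[u] = lo ? 0.0 : POS;
    }
  }
  // restore the gradient (callers may reuse it) and set the intercept
  g = -(y % v);
  double hi = NEG, lo = POS;
  for (int t = 0; t < n; ++t) {
    const double a1 = vp[t] + up_p[t];
    const double a2 = vp[t] + lo_p[t];
    if (a1 > hi) hi = a1;
    if (a2 < lo) lo = a2;
  }
  if (hi > NEG / 2 && lo < POS / 2) b = 0.5 * (hi + lo);
  else if (hi > NEG / 2) b = hi;
  else if (lo < POS / 2) b = lo;
  else b = 0.0;
}

static void smo_solve(const mat& K, const vec& y, double C, vec& alpha,
                      double& b, double tol = 1e-3, int max_iter = 20000) {
  const int n = K.n_rows;
  alpha.zeros(n);
  vec g(n);
  g.fill(-1.0); // gradient of the dual objective at alpha = 0
  smo_iterate(K, y, C, alpha, g, b, tol, max_iter);
}

// Shared LOO engine on a precomputed Gram matrix with warm starts.
// alpha_full/g_full hold the full-data solution on entry (already
// optimized); returns the percent-correct over all 2G held-out items.
static double loo_folds_masked(const mat& Gram, const vec& y, int G, double C,
                               vec& alpha_full, vec& g_full,
                               vec& alpha_w, vec& g_w,
                               double tol, int max_iter) {
  const int n = 2 * G;
  int correct = 0;
  for (int f = 0; f < G; ++f) {
    const int hA = f, hB = G + f;
    const double aA = alpha_full[hA], aB = alpha_full[hB];
    // non-support holdouts leave the solution unchanged and are correct
    if (aA <= 0 && aB <= 0) {
      correct += 2;
      continue;
    }
    alpha_w = alpha_full;
    alpha_w[hA] = 0.0;
    alpha_w[hB] = 0.0;
    // gradient after removing the holdout alphas (rank-2 update)
    const double* GA = Gram.colptr(hA);
    const double* GB = Gram.colptr(hB);
    const double cA = y[hA] * aA, cB = y[hB] * aB;
    for (int t = 0; t < n; ++t)
      g_w[t] = g_full[t] - y[t] * (cA * GA[t] + cB * GB[t]);
    // repair the equality constraint: net class mass removed
    double D = aA - aB;
    for (int r = 0; r < n && std::abs(D) > 1e-12; ++r) {
      if (r == hA || r == hB) continue;
      double da = 0.0;
      if (D > 0 && y[r] > 0 && alpha_w[r] < C) da = std::min(D, C - alpha_w[r]);
      else if (D < 0 && y[r] < 0 && alpha_w[r] < C) da = std::min(-D, C - alpha_w[r]);
      if (da > 0) {
        alpha_w[r] += da;
        const double cy = y[r] * da;
        const double* Gr = Gram.colptr(r);
        for (int t = 0; t < n; ++t) g_w[t] += y[t] * cy * Gr[t];
        D += (D > 0) ? -da : da;
      }
    }
    double b = 0.0;
    smo_iterate(Gram, y, C, alpha_w, g_w, b, tol, max_iter, hA, hB);
    double fA = b, fB = b;
    for (int t = 0; t < n; ++t) {
      const double w = alpha_w[t] * y[t];
      fA += w * GA[t];
      fB += w * GB[t];
    }
    if (fA >= 0) ++correct;
    if (fB < 0) ++correct;
  }
  return 100.0 * correct / (2.0 * G);
}

// Leave-one-out accuracy on a precomputed Gram matrix.  Rows 0..G-1 are
// class A (y=+1), rows G..2G-1 class B (y=-1).  Each fold holds out one
// pseudo-trial per class jointly.  Decision ties (f = 0) go to class A.
static double loo_accuracy_gram(const mat& Gram, int G, double C,
                                double tol, int max_iter) {
  const int n = 2 * G;
  vec y(n);
  y.head(G).fill(1.0);
  y.tail(G).fill(-1.0);
  vec alpha_full(n, fill::zeros), g_full(n);
  g_full.fill(-1.0);
  double b_full = 0.0;
  smo_iterate(Gram, y, C, alpha_full, g_full, b_full, tol, max_iter);
  vec alpha_w(n), g_w(n);
  return loo_folds_masked(Gram, y, G, C, alpha_full, g_full, alpha_w, g_w,
                          tol, max_iter);
}

// Leave-one-out accuracy with per-fold channel z-scoring (training-fold
// mean/sd applied to train and held-out patterns).  X: n x d, first G rows
// class A.
static double loo_accuracy_zscore(const mat& X, int G, double C,
                                  double tol, int max_iter) {
  const int n = 2 * G, m = n - 2, d = X.n_cols;
  vec y(n);
  y.head(G).fill(1.0);
  y.tail(G).fill(-1.0);
  uvec idx(m);
  vec ysub(m), alpha;
  double b = 0.0;
  int correct = 0;
  for (int f = 0; f < G; ++f) {
    int p = 0;
    for (int t = 0; t < n; ++t)
      if (t != f && t != G + f) idx[p++] = t;
    mat Xtr = X.rows(idx);
    rowvec mu = mean(Xtr, 0);
    rowvec sd = stddev(Xtr, 0, 0);
    sd.transform([](double v) { return (v < 1e-12) ? 1.0 : v; });
    Xtr.each_row() -= mu;
    Xtr.each_row() /= sd;
    rowvec xA = (X.row(f) - mu) / sd;
    rowvec xB = (X.row(G + f) - mu) / sd;
    mat Ksub = Xtr * Xtr.t();
    for (int r = 0; r < m; ++r) ysub[r] = y[idx[r]];
    smo_solve(Ksub, ysub, C, alpha, b, tol, max_iter);
    vec w = Xtr.t() * (alpha % ysub);
    const double fA = dot(w, xA) + b;
    const double fB = dot(w, xB) + b;
    if (fA >= 0) ++correct;
    if (fB < 0) ++correct;
    (void)d;
  }
  return 100.0 * correct / (2.0 * G);
}

// Average groups of k trials into G pseudo-trials following a permutation.
// A: d x T x M cube; perm: 0-based trial order.
static cube pseudo_cube(const cube& A, const uvec& perm, int k, int G) {
  cube P(A.n_rows, A.n_cols, G, fill::zeros);
  for (int g = 0; g < G; ++g) {
    for (int j = 0; j < k; ++j) P.slice(g) += A.slice(perm[(uword)g * k + j]);
    P.slice(g) /= (double)k;
  }
  return P;
}

// Gather patterns at time index t as columns of a d x 2G matrix (class A
// pseudo-trials first); column-major copies are contiguous.
static void patterns_at(const cube& PA, const cube& PB, int t, mat& Xc) {
  const int G = PA.n_slices;
  for (int g = 0; g < G; ++g) {
    Xc.col(g) = PA.slice(g).col(t);
    Xc.col(G + g) = PB.slice(g).col(t);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_svm_train(const arma::mat& X, const arma::vec& y, double C) {
  mat K = X * X.t();
  vec alpha;
  double b = 0.0;
  smo_solve(K, y, C, alpha, b);
  vec w = X.t() * (alpha % y);
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("w") = w, Rcpp::Named("b") = b);
}

// [[Rcpp::export]]
double cpp_loo_accuracy(const arma::mat& Xa, const arma::mat& Xb, double C,
                        bool zscore) {
  const int G = std::min(Xa.n_rows, Xb.n_rows);
  mat X(2 * G, Xa.n_cols);
  X.rows(0, G - 1) = Xa.rows(0, G - 1);
  X.rows(G, 2 * G - 1) = Xb.rows(0, G - 1);
  if (zscore) return loo_accuracy_zscore(X, G, C, 1e-3, 20000);
  mat Gram = X * X.t();
  return loo_accuracy_gram(Gram, G, C, 1e-3, 20000);
}

// Time-resolved pairwise LOO decoding for one condition pair.
// A, B: d x T x M cubes of single trials; permA/permB: M x K 1-based
// permutation matrices (one column per repetition); k: subaverage size.
// Returns T x K accuracy (%) matrix, one column per repetition.
// [[Rcpp::export]]
arma::mat cpp_pair_course(const arma::cube& A, const arma::cube& B,
                          const arma::umat& permA, const arma::umat& permB,
                          int k, double C, bool zscore) {
  const int T = A.n_cols, K = permA.n_cols;
  const int G = std::min(A.n_slices, B.n_slices) / k;
  const int n = 2 * G;
  mat out(T, K);
  mat Xc(A.n_rows, 2 * G);

  vec y(n);
  y.head(G).fill(1.0);
  y.tail(G).fill(-1.0);

  for (int rep = 0; rep < K; ++rep) {
    cube PA = pseudo_cube(A, permA.col(rep) - 1, k, G);
    cube PB = pseudo_cube(B, permB.col(rep) - 1, k, G);
    if (zscore) {
      for (int t = 0; t < T; ++t) {
        patterns_at(PA, PB, t, Xc);
        out(t, rep) = loo_accuracy_zscore(Xc.t(), G, C, 1e-3, 20000);
      }
      continue;
    }
    // per-fold alpha carried across time points: the filtered signal
    // varies slowly, so each fold's previous solution is a near-optimal
    // warm start; gradients for all folds come from one batched product
    mat alphaF(n, G, fill::zeros); // column f: fold-f solution (holdouts 0)
    mat Gram(n, n), GF(n, G), Ya(n, G);
    vec alpha(n), g(n);
    double b = 0.0;
    for (int t = 0; t < T; ++t) {
      patterns_at(PA, PB, t, Xc);
      Gram = Xc.t() * Xc;
      Ya = alphaF.each_col() % y;
      GF = Gram * Ya;
      int correct = 0;
      for (int f = 0; f < G; ++f) {
        const int hA = f, hB = G + f;
        alpha = alphaF.col(f);
        g = y % GF.col(f) - 1.0;
        smo_iterate(Gram, y, C, alpha, g, b, 1e-3, 20000, hA, hB);
        alphaF.col(f) = alpha;
        const double* GA = Gram.colptr(hA);
        const double* GB = Gram.colptr(hB);
        double fA = b, fB = b;
        for (int u = 0; u < n; ++u) {
          const double w = alpha[u] * y[u];
          fA += w * GA[u];
          fB += w * GB[u];
        }
        if (fA >= 0) ++correct;
        if (fB < 0) ++correct;
      }
      out(t, rep) = 100.0 * correct / (2.0 * G);
    }
  }
  return out;
}

// Full 9-condition pairwise RDM course.  Per repetition, every condition is
// subaveraged once (partitions shared across pairs, as in the emulated
// analysis); LOO accuracy is then computed for each of the 36 pairs with
// per-fold warm starts across time.  conds: list of d x T x M cubes;
// perms: list of M x K 1-based permutation matrices.  Returns a T x 36
// matrix averaged over K (pairs in column-major (a,b) order, a < b).
// [[Rcpp::export]]
arma::mat cpp_rdm_course(Rcpp::List conds, Rcpp::List perms, int k, double C) {
  const int ncond = conds.size();
  std::vector<cube> cs(ncond);
  std::vector<umat> ps(ncond);
  for (int c = 0; c < ncond; ++c) {
    cs[c] = Rcpp::as<cube>(conds[c]);
    ps[c] = Rcpp::as<umat>(perms[c]);
  }
  const int T = cs[0].n_cols, K = ps[0].n_cols;
  int G = cs[0].n_slices / k;
  for (int c = 1; c < ncond; ++c)
    G = std::min(G, (int)cs[c].n_slices / k);
  const int n = 2 * G, npair = ncond * (ncond - 1) / 2;
  vec y(n);
  y.head(G).fill(1.0);
  y.tail(G).fill(-1.0);
  mat out(T, npair, fill::zeros);
  std::vector<cube> P(ncond);
  mat Xc(cs[0].n_rows, n);
  mat Gram(n, n), GF(n, G), Ya(n, G);
  vec alpha(n), g(n);
  for (int rep = 0; rep < K; ++rep) {
    for (int c = 0; c < ncond; ++c)
      P[c] = pseudo_cube(cs[c], ps[c].col(rep) - 1, k, G);
    int pr = 0;
    for (int a = 0; a < ncond - 1; ++a)
      for (int b = a + 1; b < ncond; ++b, ++pr) {
        mat alphaF(n, G, fill::zeros);
        double bint = 0.0;
        for (int t = 0; t < T; ++t) {
          patterns_at(P[a], P[b], t, Xc);
          Gram = Xc.t() * Xc;
          Ya = alphaF.each_col() % y;
          GF = Gram * Ya;
          int correct = 0;
          for (int f = 0; f < G; ++f) {
            alpha = alphaF.col(f);
            g = y % GF.col(f) - 1.0;
            smo_iterate(Gram, y, C, alpha, g, bint, 1e-3, 20000, f, G + f);
            alphaF.col(f) = alpha;
            const double* GA = Gram.colptr(f);
            const double* GB = Gram.colptr(G + f);
            double fA = bint, fB = bint;
            for (int u = 0; u < n; ++u) {
              const double w = alpha[u] * y[u];
              fA += w * GA[u];
              fB += w * GB[u];
            }
            if (fA >= 0) ++correct;
            if (fB < 0) ++correct;
          }
          out(t, pr) += 100.0 * correct / (2.0 * G);
        }
      }
  }
  return out / K;
}

// Cross-classification for one decoded factor: per repetition, each of the
// nine factorial cells is subaveraged once; for every held-out orthogonal
// level and decoded pair, classifiers train on the pseudo-trials of the two
// remaining levels and test on the held-out level's.  cells: list of 9
// d x T x M cubes indexed cell = (decoded - 1) * 3 + orth; perms: matching
// M x K permutations.  Returns a T x 9 matrix (combinations) averaged
// over K; combination index = (holdout - 1) * 3 + pair.
// [[Rcpp::export]]
arma::mat cpp_cross_factor(Rcpp::List cells, Rcpp::List perms, int k,
                           double C) {
  std::vector<cube> cs(9);
  std::vector<umat> ps(9);
  for (int c = 0; c < 9; ++c) {
    cs[c] = Rcpp::as<cube>(cells[c]);
    ps[c] = Rcpp::as<umat>(perms[c]);
  }
  const int T = cs[0].n_cols, K = ps[0].n_cols, d = cs[0].n_rows;
  int G = cs[0].n_slices / k;
  for (int c = 1; c < 9; ++c) G = std::min(G, (int)cs[c].n_slices / k);
  const int prs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
  const int ntr = 4 * G, nte = 2 * G;
  vec y(ntr);
  y.head(2 * G).fill(1.0);
  y.tail(2 * G).fill(-1.0);
  mat out(T, 9, fill::zeros);
  std::vector<cube> P(9);
  mat Xtr(d, ntr), Xte(d, nte);
  for (int rep = 0; rep < K; ++rep) {
    for (int c = 0; c < 9; ++c)
      P[c] = pseudo_cube(cs[c], ps[c].col(rep) - 1, k, G);
    int combo = 0;
    for (int h = 0; h < 3; ++h) {
      int tr_lv[2], p2 = 0;
      for (int o = 0; o < 3; ++o)
        if (o != h) tr_lv[p2++] = o;
      for (int pi = 0; pi < 3; ++pi, ++combo) {
        const int a = prs[pi][0], b = prs[pi][1];
        const cube& A1 = P[a * 3 + tr_lv[0]];
        const cube& A2 = P[a * 3 + tr_lv[1]];
        const cube& B1 = P[b * 3 + tr_lv[0]];
        const cube& B2 = P[b * 3 + tr_lv[1]];
        const cube& TA = P[a * 3 + h];
        const cube& TB = P[b * 3 + h];
        vec alpha_tr(ntr, fill::zeros), g_tr(ntr);
        double bint = 0.0;
        for (int t = 0; t < T; ++t) {
          for (int gidx = 0; gidx < G; ++gidx) {
            Xtr.col(gidx) = A1.slice(gidx).col(t);
            Xtr.col(G + gidx) = A2.slice(gidx).col(t);
            Xtr.col(2 * G + gidx) = B1.slice(gidx).col(t);
            Xtr.col(3 * G + gidx) = B2.slice(gidx).col(t);
            Xte.col(gidx) = TA.slice(gidx).col(t);
            Xte.col(G + gidx) = TB.slice(gidx).col(t);
          }
          mat Gram = Xtr.t() * Xtr;
          g_tr = y % (Gram * (y % alpha_tr)) - 1.0;
          smo_iterate(Gram, y, C, alpha_tr, g_tr, bint, 1e-3, 20000);
          vec w = Xtr * (alpha_tr % y);
          vec f = Xte.t() * w + bint;
          int correct = 0;
          for (int gidx = 0; gidx < G; ++gidx) {
            if (f[gidx] >= 0) ++correct;
            if (f[G + gidx] < 0) ++correct;
          }
          out(t, combo) += 100.0 * correct / (2.0 * G);
        }
      }
    }
  }
  return out / K;
}

// Cross-classification course for one train/test combination.  Training
// pseudo-trials are subaveraged within each orthogonal level separately
// (tA1/tA2 are the two training levels for class A), test pseudo-trials come
// from the held-out level.  Returns T x K accuracy matrix.
// [[Rcpp::export]]
arma::mat cpp_cross_course(const arma::cube& tA1, const arma::cube& tA2,
                           const arma::cube& tB1, const arma::cube& tB2,
                           const arma::cube& teA, const arma::cube& teB,
                           const arma::umat& pA1, const arma::umat& pA2,
                           const arma::umat& pB1, const arma::umat& pB2,
                           const arma::umat& pTA, const arma::umat& pTB,
                           int k, double C, bool zscore) {
  const int T = tA1.n_cols, K = pA1.n_cols, d = tA1.n_rows;
  const int G1 = tA1.n_slices / k;    // pseudo-trials per training level
  const int Gt = teA.n_slices / k;    // pseudo-trials per test class
  const int ntr = 4 * G1;
  vec y(ntr);
  y.head(2 * G1).fill(1.0);
  y.tail(2 * G1).fill(-1.0);
  mat out(T, K);
  mat Xtr(ntr, d);
  mat Xte(2 * Gt, d);
  for (int rep = 0; rep < K; ++rep) {
    cube PA1 = pseudo_cube(tA1, pA1.col(rep) - 1, k, G1);
    cube PA2 = pseudo_cube(tA2, pA2.col(rep) - 1, k, G1);
    cube PB1 = pseudo_cube(tB1, pB1.col(rep) - 1, k, G1);
    cube PB2 = pseudo_cube(tB2, pB2.col(rep) - 1, k, G1);
    cube QA = pseudo_cube(teA, pTA.col(rep) - 1, k, Gt);
    cube QB = pseudo_cube(teB, pTB.col(rep) - 1, k, Gt);
    vec alpha_tr(ntr, fill::zeros), g_tr(ntr);
    for (int t = 0; t < T; ++t) {
      for (int g = 0; g < G1; ++g)
        for (int c = 0; c < d; ++c) {
          Xtr(g, c) = PA1(c, t, g);
          Xtr(G1 + g, c) = PA2(c, t, g);
          Xtr(2 * G1 + g, c) = PB1(c, t, g);
          Xtr(3 * G1 + g, c) = PB2(c, t, g);
        }
      for (int g = 0; g < Gt; ++g)
        for (int c = 0; c < d; ++c) {
          Xte(g, c) = QA(c, t, g);
          Xte(Gt + g, c) = QB(c, t, g);
        }
      mat Xtr_t = Xtr, Xte_t = Xte;
      if (zscore) {
        rowvec mu = mean(Xtr_t, 0);
        rowvec sd = stddev(Xtr_t, 0, 0);
        sd.transform([](double v) { return (v < 1e-12) ? 1.0 : v; });
        Xtr_t.each_row() -= mu;
        Xtr_t.each_row() /= sd;
        Xte_t.each_row() -= mu;
        Xte_t.each_row() /= sd;
      }
      mat Gram = Xtr_t * Xtr_t.t();
      g_tr = y % (Gram * (y % alpha_tr)) - 1.0; // warm start from t - 1
      double b = 0.0;
      smo_iterate(Gram, y, C, alpha_tr, g_tr, b, 1e-3, 20000);
      const vec& alpha = alpha_tr;
      vec w = Xtr_t.t() * (alpha % y);
      vec f = Xte_t * w + b;
      int correct = 0;
      for (int g = 0; g < Gt; ++g) {
        if (f[g] >= 0) ++correct;
        if (f[Gt + g] < 0) ++correct;
      }
      out(t, rep) = 100.0 * correct / (2.0 * Gt);
    }
  }
  return out;
}

// Temporal generalization for one condition pair: train at t (LOO folds),
// test the held-out pseudo-trial pair at every t'.  Returns T x T accuracy
// (%) matrix averaged over K repetitions; rows index training time.
// [[Rcpp::export]]
arma::mat cpp_tempgen_course(const arma::cube& A, const arma::cube& B,
                             const arma::umat& permA, const arma::umat& permB,
                             int k, double C) {
  const int T = A.n_cols, K = permA.n_cols, d = A.n_rows;
  const int G = std::min(A.n_slices, B.n_slices) / k;
  const int n = 2 * G, m = n - 2;
  vec y(n);
  y.head(G).fill(1.0);
  y.tail(G).fill(-1.0);
  mat counts(T, T, fill::zeros);
  mat Xc(d, n), Ksub(m, m);
  vec ysub(m), alpha;
  uvec idx(m);
  for (int rep = 0; rep < K; ++rep) {
    cube PA = pseudo_cube(A, permA.col(rep) - 1, k, G);
    cube PB = pseudo_cube(B, permB.col(rep) - 1, k, G);
    for (int t = 0; t < T; ++t) {
      patterns_at(PA, PB, t, Xc);
      mat Gram = Xc.t() * Xc;
      for (int f = 0; f < G; ++f) {
        int p = 0;
        for (int u = 0; u < n; ++u)
          if (u != f && u != G + f) idx[p++] = u;
        for (int r = 0; r < m; ++r) {
          ysub[r] = y[idx[r]];
          for (int c = 0; c <= r; ++c) {
            Ksub(r, c) = Gram(idx[r], idx[c]);
            Ksub(c, r) = Ksub(r, c);
          }
        }
        double b = 0.0;
        smo_solve(Ksub, ysub, C, alpha, b, 1e-3, 20000);
        vec w(d, fill::zeros);
        for (int r = 0; r < m; ++r) {
          const double coef = alpha[r] * ysub[r];
          if (coef != 0.0) {
            const int u = idx[r];
            if (u < G) w += coef * vectorise(PA.slice(u).col(t));
            else w += coef * vectorise(PB.slice(u - G).col(t));
          }
        }
        rowvec fA = w.t() * PA.slice(f) + b;  // scores across all t'
        rowvec fB = w.t() * PB.slice(f) + b;
        for (int tp = 0; tp < T; ++tp) {
          if (fA[tp] >= 0) counts(t, tp) += 1.0;
          if (fB[tp] < 0) counts(t, tp) += 1.0;
        }
      }
    }
  }
  return counts * (100.0 / (2.0 * G * K));
}

// Zero-phase forward-backward IIR filtering along columns with odd
// (antisymmetric) edge reflection of length npad, as in standard filtfilt
// implementations.  Normalized coefficients, direct-form II transposed.
// [[Rcpp::export]]
arma::mat cpp_filtfilt_mat(const arma::mat& X, const arma::vec& bcoef,
                           const arma::vec& acoef, int npad) {
  const int n = X.n_rows, S = X.n_cols;
  const int ord = std::max(bcoef.n_elem, acoef.n_elem) - 1;
  vec b(ord + 1, fill::zeros), a(ord + 1, fill::zeros);
  for (uword i = 0; i < bcoef.n_elem; ++i) b[i] = bcoef[i] / acoef[0];
  for (uword i = 0; i < acoef.n_elem; ++i) a[i] = acoef[i] / acoef[0];
  if (npad >= n) npad = n - 1;
  const int ext = n + 2 * npad;
  mat out(n, S);
  vec x(ext);
  std::vector<double> z(ord);
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < npad; ++i)
      x[i] = 2.0 * X(0, s) - X(npad - i, s);
    for (int i = 0; i < n; ++i) x[npad + i] = X(i, s);
    for (int i = 0; i < npad; ++i)
      x[npad + n + i] = 2.0 * X(n - 1, s) - X(n - 2 - i, s);

    for (int pass = 0; pass < 2; ++pass) {
      std::fill(z.begin(), z.end(), 0.0);
      double* xp = x.memptr();
      for (int i = 0; i < ext; ++i) {
        const double xi = xp[i];
        const double yi = b[0] * xi + z[0];
        for (int j = 0; j < ord - 1; ++j)
          z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
        z[ord - 1] = b[ord] * xi - a[ord] * yi;
        xp[i] = yi;
      }
      x = reverse(x);
    }
    // two passes, each followed by a reversal: x is in forward order again
    for (int i = 0; i < n; ++i) out(i, s) = x[npad + i];
  }
  return out;
}

// Baseline correction + zero-phase filtering for a sensors x time x trials
// cube, in place (the caller owns the array and must not alias it): per
// trial and sensor, subtract the mean over the prestimulus columns, then
// forward-backward filter along time.  Each d x T slice stays
// cache-resident, avoiding large transposes.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_preprocess_cube(Rcpp::NumericVector dat_in,
                               const arma::uvec& pre_idx,
                               const arma::vec& bcoef, const arma::vec& acoef,
                               int npad) {
  Rcpp::IntegerVector dims = dat_in.attr("dim");
  cube dat(dat_in.begin(), dims[0], dims[1], dims[2], false, true);
  const int d = dat.n_rows, T = dat.n_cols, n = dat.n_slices;
  const int ord = std::max(bcoef.n_elem, acoef.n_elem) - 1;
  vec b(ord + 1, fill::zeros), a(ord + 1, fill::zeros);
  for (uword i = 0; i < bcoef.n_elem; ++i) b[i] = bcoef[i] / acoef[0];
  for (uword i = 0; i < acoef.n_elem; ++i) a[i] = acoef[i] / acoef[0];
  if (npad >= T) npad = T - 1;
  const int ext = T + 2 * npad;
  std::vector<double> x(ext), z(ord);
  const double npre = (double)pre_idx.n_elem;
  for (int s = 0; s < n; ++s) {
    mat& sl = const_cast<mat&>(dat.slice(s));
    // baseline per sensor
    vec bl(d, fill::zeros);
    for (uword pi = 0; pi < pre_idx.n_elem; ++pi) bl += sl.col(pre_idx[pi]);
    bl /= npre;
    sl.each_col() -= bl;
    // filter each sensor's time series
    for (int r = 0; r < d; ++r) {
      for (int i = 0; i < npad; ++i)
        x[i] = 2.0 * sl(r, 0) - sl(r, npad - i);
      for (int i = 0; i < T; ++i) x[npad + i] = sl(r, i);
      for (int i = 0; i < npad; ++i)
        x[npad + T + i] = 2.0 * sl(r, T - 1) - sl(r, T - 2 - i);
      for (int pass = 0; pass < 2; ++pass) {
        std::fill(z.begin(), z.end(), 0.0);
        for (int i = 0; i < ext; ++i) {
          const double xi = x[i];
          const double yi = b[0] * xi + z[0];
          for (int j = 0; j < ord - 1; ++j)
            z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
          z[ord - 1] = b[ord] * xi - a[ord] * yi;
          x[i] = yi;
        }
        std::reverse(x.begin(), x.end());
      }
      for (int i = 0; i < T; ++i) sl(r, i) = x[npad + i];
    }
  }
  return dat_in;
}

// Deterministic standard-normal draws: 64-bit Mersenne Twister feeding the
// 128-layer ziggurat of Marsaglia & Tsang (2000), independent of R's RNG
// stream; used for the bulk sensor noise where R-level generation would
// dominate run time.
namespace {
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    const double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
const ZigTables zig;

inline double zig_uni(std::mt19937_64& rng) {
  return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

double zig_norm(std::mt19937_64& rng) {
  const double r = 3.442619855899;
  for (;;) {
    const int32_t hz = (int32_t)(uint32_t)rng();
    const uint32_t iz = (uint32_t)hz & 127u;
    if ((uint32_t)std::abs(hz) < zig.kn[iz]) return hz * zig.wn[iz];
    if (iz == 0) { // tail
      double x, yv;
      do {
        x = -std::log(zig_uni(rng)) / r;
        yv = -std::log(zig_uni(rng));
      } while (yv + yv < x * x);
      return (hz > 0) ? r + x : -(r + x);
    }
    const double x = hz * zig.wn[iz];
    if (zig.fn[iz] + zig_uni(rng) * (zig.fn[iz - 1] - zig.fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}
} // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_randn(int n, int seed) {
  Rcpp::NumericVector out(n);
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  for (int i = 0; i < n; ++i) out[i] = zig_norm(rng);
  return out;
}
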