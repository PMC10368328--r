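// Ridge-penalized logistic regression engine for repeated-subsampling CV
// and recursive feature elimination.
//
// All fits run in the dual (sample) space: with n samples and p alignment
// columns, p >> n is the norm, so Newton steps are solved on the n x n
// Gram matrix of the standardized training features.  The intercept is a
// penalized pseudo-feature with value tau = 100; its effective penalty
// lambda / tau^2 is negligible relative to the feature penalty.
// During RFE the per-split Gram matrices are downdated by a rank-1 term
// when a column is eliminated, so a full path over hundreds of columns
// costs little more than a single cross-validation run per step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double TAU2 = 1e4;   // squared intercept pseudo-feature scale
static const double WMIN = 1e-10; // IRLS weight floor

// softplus, numerically stable
static inline double softplus(double x) {
  return (x > 0.0 ? x : 0.0) + std::log1p(std::exp(-std::fabs(x)));
}

static double objective(const vec& eta, const vec& y, double lambda, const vec& v) {
  double o = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) o += softplus(eta(i)) - y(i) * eta(i);
  return o + 0.5 * lambda * dot(v, eta);
}

// IRLS on the dual variables; Ka must include the intercept term (+TAU2).
// v is used as a warm start and overwritten with the solution.
static void irls_dual(const mat& Ka, const vec& y, double lambda,
                      int maxit, double tol, vec& v, vec& eta) {
  const uword n = y.n_elem;
  if (v.n_elem != n) v.zeros(n);
  eta = Ka * v;
  double obj = objective(eta, y, lambda, v);
  for (int it = 0; it < maxit; ++it) {
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec d = clamp(mu % (1.0 - mu), WMIN, 0.25);
    vec z = eta + (y - mu) / d;
    vec sd_ = sqrt(d);
    mat G = (sd_ * sd_.t()) % Ka;
    G.diag() += lambda;
    vec s;
    bool ok = solve(s, G, sd_ % z, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) { G.diag() += 1e-8; s = solve(G, sd_ % z); }
    vec v_new = sd_ % s;
    vec eta_new = Ka * v_new;
    double obj_new = objective(eta_new, y, lambda, v_new);
    // step halving toward the previous iterate if the penalized
    // deviance fails to decrease (rare; separable-ish extremes)
    double t = 1.0;
    int half = 0;
    while (obj_new > obj + 1e-12 && half < 20) {
      t *= 0.5;
      v_new = (1.0 - t) * v + t * (sd_ % s);
      eta_new = Ka * v_new;
      obj_new = objective(eta_new, y, lambda, v_new);
      ++half;
    }
    double delta = max(abs(eta_new - eta));
    v = v_new; eta = eta_new; obj = obj_new;
    if (delta < tol * (1.0 + max(abs(eta)))) break;
  }
}

// accuracy, auroc, precision, recall, f1 for positive class y==1,
// decision threshold eta > 0 (probability 0.5)
static void test_metrics(const vec& eta_te, const vec& y_te, double* out) {
  const uword n = eta_te.n_elem;
  double tp = 0, fp = 0, fn = 0, correct = 0;
  for (uword i = 0; i < n; ++i) {
    bool pred = eta_te(i) > 0.0;
    bool pos = y_te(i) > 0.5;
    if (pred == pos) ++correct;
    if (pred && pos) ++tp;
    if (pred && !pos) ++fp;
    if (!pred && pos) ++fn;
  }
  double acc = correct / double(n);
  double prec = (tp + fp > 0) ? tp / (tp + fp) : 0.0;
  double rec = (tp + fn > 0) ? tp / (tp + fn) : 0.0;
  double f1 = (prec + rec > 0) ? 2.0 * prec * rec / (prec + rec) : 0.0;
  // AUROC with midranks for ties
  uvec ord = sort_index(eta_te);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && eta_te(ord(j + 1)) == eta_te(ord(i))) ++j;
    double mid = 0.5 * double(i + j) + 1.0; // midrank, 1-based
    for (uword k = i; k <= j; ++k) ranks(ord(k)) = mid;
    i = j + 1;
  }
  double n1 = 0, n0 = 0, rsum = 0;
  for (uword k = 0; k < n; ++k) {
    if (y_te(k) > 0.5) { ++n1; rsum += ranks(k); } else { ++n0; }
  }
  double auroc = (n1 > 0 && n0 > 0)
    ? (rsum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0) : NA_REAL;
  out[0] = acc; out[1] = auroc; out[2] = prec; out[3] = rec; out[4] = f1;
}

// standardize the train block column-wise (population sd; constant
// columns get scale 1 and become all-zero), apply to the test block
static void standardize_split(const mat& X, const uvec& tr, const uvec& te,
                              mat& Xtr, mat& Xte) {
  Xtr = X.rows(tr);
  Xte = X.rows(te);
  rowvec m = mean(Xtr, 0);
  rowvec s = stddev(Xtr, 1, 0); // norm_type 1: divide by n
  s.elem(find(s == 0.0)).ones();
  Xtr.each_row() -= m; Xtr.each_row() /= s;
  Xte.each_row() -= m; Xte.each_row() /= s;
}

// [[Rcpp::export(name = ".cppFitRidge")]]
List cppFitRidge(const arma::mat& Xs, const arma::vec& y, double lambda,
                 int maxit, double tol) {
  // Xs: already standardized feature matrix
  mat Ka = Xs * Xs.t();
  Ka += TAU2;
  vec v, eta;
  irls_dual(Ka, y, lambda, maxit, tol, v, eta);
  vec w = Xs.t() * v;
  double b = TAU2 * accu(v);
  return List::create(_["coefficients"] = w, _["intercept"] = b,
                      _["linear_predictor"] = eta);
}

// [[Rcpp::export(name = ".cppCV")]]
List cppCV(const arma::mat& X, const arma::vec& y, const List& train,
           const List& test, double lambda, int maxit, double tol) {
  const int niter = train.size();
  const uword p = X.n_cols;
  mat metrics(niter, 5);
  vec absW(p, fill::zeros);
  uvec weakCount(p, fill::zeros);
  uvec te0 = as<uvec>(test[0]);
  const uword nte = te0.n_elem;
  imat preds(niter, nte);
  mat probs(niter, nte);
  for (int s = 0; s < niter; ++s) {
    uvec tr = as<uvec>(train[s]) - 1; // R 1-based -> 0-based
    uvec te = as<uvec>(test[s]) - 1;
    mat Xtr, Xte;
    standardize_split(X, tr, te, Xtr, Xte);
    mat Ka = Xtr * Xtr.t(); Ka += TAU2;
    vec v, eta;
    irls_dual(Ka, y(tr), lambda, maxit, tol, v, eta);
    vec w = Xtr.t() * v;
    absW += abs(w);
    if (p > 0) {
      // weakest feature of this fit (ties -> later column)
      uword wk = 0; double mn = std::fabs(w(0));
      for (uword j = 1; j < p; ++j)
        if (std::fabs(w(j)) <= mn) { mn = std::fabs(w(j)); wk = j; }
      weakCount(wk) += 1;
    }
    vec eta_te = Xte * w + TAU2 * accu(v);
    double out[5];
    test_metrics(eta_te, y(te), out);
    for (int k = 0; k < 5; ++k) metrics(s, k) = out[k];
    for (uword i = 0; i < nte; ++i) {
      preds(s, i) = eta_te(i) > 0.0 ? 1 : 0;
      probs(s, i) = 1.0 / (1.0 + std::exp(-eta_te(i)));
    }
  }
  return List::create(_["metrics"] = metrics,
                      _["meanAbsCoef"] = absW / double(niter),
                      _["weakCount"] = weakCount,
                      _["preds"] = preds, _["probs"] = probs);
}

// Full RFE path: repeated-subsampling CV at every active set, eliminating
// one column per step down to min_features.  The same splits are reused
// at every step; per-split Gram matrices are downdated in place.
// criterion: 0 = minimum mean |coefficient|, 1 = most often ranked weakest
// [[Rcpp::export(name = ".cppRFE")]]
List cppRFE(const arma::mat& X, const arma::vec& y, const List& train,
            const List& test, double lambda, int maxit, double tol,
            int min_features, int criterion) {
  const int niter = train.size();
  const int p = X.n_cols;
  const int nsteps = p - min_features + 1;
  std::vector<mat> Xtr(niter), Xte(niter), K(niter), C(niter);
  std::vector<vec> ytr(niter), yte(niter), vwarm(niter);
  for (int s = 0; s < niter; ++s) {
    uvec tr = as<uvec>(train[s]) - 1;
    uvec te = as<uvec>(test[s]) - 1;
    standardize_split(X, tr, te, Xtr[s], Xte[s]);
    K[s] = Xtr[s] * Xtr[s].t();
    C[s] = Xte[s] * Xtr[s].t();
    ytr[s] = y(tr); yte[s] = y(te);
  }
  std::vector<int> active(p);
  for (int j = 0; j < p; ++j) active[j] = j;
  mat stepMetrics(nsteps, 5);
  ivec nFeat(nsteps);
  ivec eliminated(nsteps); eliminated.fill(NA_INTEGER);
  for (int step = 0; step < nsteps; ++step) {
    const int pa = active.size();
    vec absW(pa, fill::zeros);
    vec weakCnt(pa, fill::zeros);
    rowvec msum(5, fill::zeros);
    int naur = 0; double aursum = 0.0;
    for (int s = 0; s < niter; ++s) {
      mat Ka = K[s]; Ka += TAU2;
      vec eta;
      irls_dual(Ka, ytr[s], lambda, maxit, tol, vwarm[s], eta);
      const vec& v = vwarm[s];
      // coefficients of the active columns only
      vec w(pa);
      for (int j = 0; j < pa; ++j) w(j) = dot(Xtr[s].col(active[j]), v);
      absW += abs(w);
      uword wk = 0; double mn = std::fabs(w(0));
      for (int j = 1; j < pa; ++j)
        if (std::fabs(w(j)) <= mn) { mn = std::fabs(w(j)); wk = j; }
      weakCnt(wk) += 1;
      vec eta_te = C[s] * v + TAU2 * accu(v);
      double out[5];
      test_metrics(eta_te, yte[s], out);
      msum(0) += out[0];
      if (!ISNAN(out[1])) { aursum += out[1]; ++naur; }
      msum(2) += out[2]; msum(3) += out[3]; msum(4) += out[4];
    }
    stepMetrics(step, 0) = msum(0) / niter;
    stepMetrics(step, 1) = naur > 0 ? aursum / naur : NA_REAL;
    stepMetrics(step, 2) = msum(2) / niter;
    stepMetrics(step, 3) = msum(3) / niter;
    stepMetrics(step, 4) = msum(4) / niter;
    nFeat(step) = pa;
    if (pa > min_features) {
      int elim = 0;
      if (criterion == 0) {
        double mn = absW(0);
        for (int j = 1; j < pa; ++j)
          if (absW(j) <= mn) { mn = absW(j); elim = j; } // ties -> later column
      } else {
        double mx = weakCnt(0);
        for (int j = 1; j < pa; ++j)
          if (weakCnt(j) >= mx) { mx = weakCnt(j); elim = j; }
      }
      int col = active[elim];
      for (int s = 0; s < niter; ++s) {
        K[s] -= Xtr[s].col(col) * Xtr[s].col(col).t();
        C[s] -= Xte[s].col(col) * Xtr[s].col(col).t();
      }
      eliminated(step) = col + 1; // back to 1-based
      active.erase(active.begin() + elim);
    }
    if (step % 25 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["stepMetrics"] = stepMetrics, _["nFeatures"] = nFeat,
                      _["eliminated"] = eliminated);
}
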