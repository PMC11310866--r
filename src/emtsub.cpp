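// Compiled numerical cores: Brunet multiplicative-update NMF, the multinomial
// sparse-group-lasso proximal (FISTA) solver, and a univariate logistic screen.
// Everything stochastic is initialized from the R side so that R's RNG governs
// reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double EPS_DEN = 1e-12;

static double kl_divergence(const arma::mat& V, const arma::mat& WH,
                            const arma::uvec& zero_idx) {
  arma::mat R = V / arma::clamp(WH, EPS_DEN, arma::datum::inf);
  R.elem(zero_idx).ones(); // 0 * log(0/x) := 0
  return arma::accu(V % arma::log(R)) - arma::accu(V) + arma::accu(WH);
}

// Brunet (generalized Kullback-Leibler) multiplicative updates.
// Stops when the sample connectivity (argmax over rows of H per column) is
// unchanged for conn_stop consecutive checks (every check_every iterations),
// or at max_iter. KL recorded every kl_every iterations plus at the end.
// [[Rcpp::export]]
List cpp_nmf_brunet(const arma::mat& V, arma::mat W, arma::mat H,
                    int max_iter, int check_every, int conn_stop,
                    int kl_every) {
  const arma::uvec zero_idx = arma::find(V == 0.0);
  std::vector<double> kl_trace;
  kl_trace.reserve(max_iter / std::max(1, kl_every) + 2);
  arma::urowvec conn_prev(V.n_cols, arma::fill::zeros);
  bool have_prev = false;
  int stable = 0, it = 0;
  bool conn_converged = false;

  for (it = 1; it <= max_iter; ++it) {
    // H update
    arma::mat WH = arma::clamp(W * H, EPS_DEN, arma::datum::inf);
    arma::mat Q = V / WH;
    arma::rowvec wsum = arma::sum(W, 0);
    wsum = arma::clamp(wsum, EPS_DEN, arma::datum::inf);
    H = H % (W.t() * Q);
    H.each_col() /= wsum.t();
    // W update
    WH = arma::clamp(W * H, EPS_DEN, arma::datum::inf);
    Q = V / WH;
    arma::colvec hsum = arma::sum(H, 1);
    hsum = arma::clamp(hsum, EPS_DEN, arma::datum::inf);
    W = W % (Q * H.t());
    W.each_row() /= hsum.t();

    if (kl_every > 0 && (it % kl_every == 0)) {
      kl_trace.push_back(kl_divergence(V, W * H, zero_idx));
    }
    if (it % check_every == 0) {
      arma::urowvec conn = arma::index_max(H, 0);
      if (have_prev && arma::all(conn == conn_prev)) {
        if (++stable >= conn_stop) { conn_converged = true; }
      } else {
        stable = 0;
      }
      conn_prev = conn;
      have_prev = true;
      if (conn_converged) break;
    }
  }
  int used = std::min(it, max_iter);
  if (kl_trace.empty() || (kl_every > 0 && used % kl_every != 0) ||
      conn_converged) {
    kl_trace.push_back(kl_divergence(V, W * H, zero_idx));
  }
  return List::create(_["W"] = W, _["H"] = H,
                      _["kl_trace"] = NumericVector(kl_trace.begin(), kl_trace.end()),
                      _["n_iter"] = used,
                      _["conn_converged"] = conn_converged);
}

static double softmax_loss(const arma::mat& Eta, const arma::mat& Y, arma::mat& P) {
  arma::vec m = arma::max(Eta, 1);
  arma::mat E = arma::exp(Eta.each_col() - m);
  arma::vec s = arma::sum(E, 1);
  P = E.each_col() / s;
  arma::vec ll = arma::sum(Y % Eta, 1) - m - arma::log(s);
  return -arma::mean(ll);
}

// Proximal operator of t*lambda*( alpha*|.|_1 + (1-alpha)*sqrt(K)*||row||_2 )
static void sgl_prox(arma::mat& B, double thr1, double thr2) {
  // entrywise soft threshold
  B = arma::sign(B) % arma::clamp(arma::abs(B) - thr1, 0.0, arma::datum::inf);
  // groupwise (row) soft threshold
  for (arma::uword g = 0; g < B.n_rows; ++g) {
    double nrm = arma::norm(B.row(g), 2);
    if (nrm <= thr2) B.row(g).zeros();
    else B.row(g) *= (1.0 - thr2 / nrm);
  }
}

// Multinomial sparse group lasso: -(1/n) loglik + lambda*(alpha*L1 +
// (1-alpha)*sqrt(K)*sum_g ||B_g||_2), one group per feature (row of B).
// FISTA with backtracking and objective-based momentum restart.
// [[Rcpp::export]]
List cpp_sgl_fit(const arma::mat& X, const arma::mat& Y, double lambda,
                 double alpha, arma::mat B, arma::rowvec b0,
                 int max_iter, double tol) {
  const arma::uword n = X.n_rows, K = Y.n_cols;
  const double sqrtK = std::sqrt((double)K);
  // Lipschitz bound for softmax gradient: 0.5 * smax([1 X])^2 / n
  arma::mat X1(n, X.n_cols + 1);
  X1.col(0).ones();
  X1.cols(1, X.n_cols) = X;
  double smax = arma::norm(X1, 2);
  double t0 = 1.0 / std::max(0.5 * smax * smax / (double)n, 1e-8);

  arma::mat Bm = B, Bprev = B, P;
  arma::rowvec b0m = b0, b0prev = b0;
  double tk = 1.0, t = t0;
  bool converged = false;
  int it = 0;
  double fprev_obj = arma::datum::inf;

  for (it = 1; it <= max_iter; ++it) {
    arma::mat Eta = X * Bm;
    Eta.each_row() += b0m;
    double fy = softmax_loss(Eta, Y, P);
    arma::mat E = (P - Y) / (double)n;
    arma::mat G = X.t() * E;
    arma::rowvec g0 = arma::sum(E, 0);

    arma::mat Bz; arma::rowvec b0z; double fz = 0.0;
    for (int bt = 0; bt < 60; ++bt) {
      Bz = Bm - t * G;
      sgl_prox(Bz, t * lambda * alpha, t * lambda * (1.0 - alpha) * sqrtK);
      b0z = b0m - t * g0;
      arma::mat Etaz = X * Bz;
      Etaz.each_row() += b0z;
      arma::mat Pz;
      fz = softmax_loss(Etaz, Y, Pz);
      double quad = fy + arma::accu(G % (Bz - Bm)) + arma::dot(g0, b0z - b0m) +
        (arma::accu(arma::square(Bz - Bm)) + arma::accu(arma::square(b0z - b0m))) / (2.0 * t);
      if (fz <= quad + 1e-12) break;
      t *= 0.5;
    }
    double dmax = std::max(arma::abs(Bz - B).max(),
                           arma::abs(b0z - b0).max());
    // momentum
    double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    double mom = (tk - 1.0) / tk1;
    Bm = Bz + mom * (Bz - B);
    b0m = b0z + mom * (b0z - b0);
    // objective-based restart
    double pen = lambda * (alpha * arma::accu(arma::abs(Bz)) +
                           (1.0 - alpha) * sqrtK *
                           arma::accu(arma::sqrt(arma::sum(arma::square(Bz), 1))));
    double obj = fz + pen;
    if (obj > fprev_obj + 1e-12) { tk1 = 1.0; Bm = Bz; b0m = b0z; }
    fprev_obj = std::min(fprev_obj, obj);
    tk = tk1;
    Bprev = B; b0prev = b0;
    B = Bz; b0 = b0z;
    if (dmax < tol) { converged = true; break; }
  }
  arma::mat Eta = X * B;
  Eta.each_row() += b0;
  double fv = softmax_loss(Eta, Y, P);
  double pen = lambda * (alpha * arma::accu(arma::abs(B)) +
                         (1.0 - alpha) * sqrtK *
                         arma::accu(arma::sqrt(arma::sum(arma::square(B), 1))));
  return List::create(_["B"] = B, _["b0"] = b0, _["n_iter"] = it,
                      _["converged"] = converged, _["objective"] = fv + pen,
                      _["loss"] = fv);
}

// Univariate logistic regression (intercept + one feature) per gene via Newton
// iterations; slope capped at +/-15 to tame perfect separation (flagged).
// Returns columns: slope, se, wald_p, separated(0/1).
// [[Rcpp::export]]
arma::mat cpp_ulogit(const arma::mat& X, const arma::vec& y, int max_iter) {
  const arma::uword p = X.n_rows, n = X.n_cols;
  arma::mat out(p, 4, arma::fill::zeros);
  const double ybar = arma::mean(y);
  const double a0 = std::log(std::max(ybar, 1e-8) / std::max(1.0 - ybar, 1e-8));
  for (arma::uword g = 0; g < p; ++g) {
    double a = a0, b = 0.0, S0 = 0, S1 = 0, S2 = 0, det = 1;
    for (int it = 0; it < max_iter; ++it) {
      double ga = 0, gb = 0;
      S0 = S1 = S2 = 0;
      for (arma::uword i = 0; i < n; ++i) {
        double x = X(g, i);
        double eta = a + b * x;
        if (eta > 30) eta = 30; else if (eta < -30) eta = -30;
        double mu = 1.0 / (1.0 + std::exp(-eta));
        double w = mu * (1.0 - mu) + 1e-10;
        double r = y(i) - mu;
        ga += r; gb += r * x;
        S0 += w; S1 += w * x; S2 += w * x * x;
      }
      det = S0 * S2 - S1 * S1;
      if (det < 1e-12) det = 1e-12;
      double da = (S2 * ga - S1 * gb) / det;
      double db = (-S1 * ga + S0 * gb) / det;
      a += da; b += db;
      if (b > 15) b = 15; else if (b < -15) b = -15;
      if (std::fabs(da) + std::fabs(db) < 1e-8) break;
    }
    double se = std::sqrt(S0 / det);
    double z = b / std::max(se, 1e-12);
    double pval = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
    bool separated = std::fabs(b) >= 15.0;
    // (near-)separation drives the Wald se to infinity (Hauck-Donner);
    // a clipped slope is treated as decisive and flagged
    if (separated) pval = 0.0;
    out(g, 0) = b; out(g, 1) = se; out(g, 2) = pval;
    out(g, 3) = separated ? 1.0 : 0.0;
  }
  return out;
}
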