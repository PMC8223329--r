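// FIML likelihood kernel for the SEM engine.
//
// The model is the usual LISREL-with-means parameterisation, with exogenous
// covariates conditioned on (fixed regressors):
//   eta = alpha + B eta + Gamma x + zeta,  zeta ~ N(0, Psi)
//   y   = nu + Lambda eta + eps,           eps  ~ N(0, Theta)
// giving, per row i,
//   mu_i  = nu + Lambda (I-B)^-1 (alpha + Gamma x_i)
//   Sigma = Lambda (I-B)^-1 Psi (I-B)^-T Lambda^T + Theta.
// The log-likelihood sums, over missingness patterns, the Gaussian
// log-density of each row's observed subvector.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static const double LOG2PI = 1.8378770664093454836;
static const double BIG_NLL = 1e12;

struct FilledModel {
  arma::mat Lambda, B, Psi, Theta, Gamma;
  arma::vec alpha, nu;
  bool ok;
};

static void fill_one(arma::mat& M, const Rcpp::List& fm, const arma::vec& theta) {
  arma::uvec idx = Rcpp::as<arma::uvec>(fm["idx"]);
  arma::uvec par = Rcpp::as<arma::uvec>(fm["par"]);
  for (arma::uword k = 0; k < idx.n_elem; ++k) M(idx(k)) = theta(par(k));
}

static FilledModel fill_model(const arma::vec& theta, const Rcpp::List& tmpl,
                              const Rcpp::List& fmap) {
  FilledModel m;
  m.Lambda = Rcpp::as<arma::mat>(tmpl["Lambda"]);
  m.B      = Rcpp::as<arma::mat>(tmpl["B"]);
  m.Psi    = Rcpp::as<arma::mat>(tmpl["Psi"]);
  m.Theta  = Rcpp::as<arma::mat>(tmpl["Theta"]);
  m.Gamma  = Rcpp::as<arma::mat>(tmpl["Gamma"]);
  arma::mat a = Rcpp::as<arma::mat>(tmpl["alpha"]);
  arma::mat n = Rcpp::as<arma::mat>(tmpl["nu"]);
  m.alpha = a.col(0);
  m.nu = n.col(0);
  fill_one(m.Lambda, fmap["Lambda"], theta);
  fill_one(m.B,      fmap["B"],      theta);
  fill_one(m.Psi,    fmap["Psi"],    theta);
  fill_one(m.Theta,  fmap["Theta"],  theta);
  fill_one(m.Gamma,  fmap["Gamma"],  theta);
  arma::mat am(m.alpha.memptr(), m.alpha.n_elem, 1, false, true);
  arma::mat nm(m.nu.memptr(), m.nu.n_elem, 1, false, true);
  fill_one(am, fmap["alpha"], theta);
  fill_one(nm, fmap["nu"], theta);
  m.ok = true;
  return m;
}

// Implied moments; returns false on singular (I - B).
static bool implied(const FilledModel& m, arma::mat& Sigma, arma::vec& mu0,
                    arma::mat& MG) {
  arma::uword nl = m.B.n_rows;
  arma::mat IB;
  if (!arma::inv(IB, arma::eye(nl, nl) - m.B)) return false;
  arma::mat M = m.Lambda * IB;
  Sigma = M * m.Psi * M.t() + m.Theta;
  mu0 = m.nu + M * m.alpha;
  if (m.Gamma.n_cols > 0) MG = M * m.Gamma;
  else MG.set_size(Sigma.n_rows, 0);
  return Sigma.is_finite() && mu0.is_finite();
}

// [[Rcpp::export]]
Rcpp::List fiml_implied_cpp(const arma::vec& theta, const Rcpp::List& tmpl,
                            const Rcpp::List& fmap) {
  FilledModel m = fill_model(theta, tmpl, fmap);
  arma::mat Sigma, MG; arma::vec mu0;
  bool ok = implied(m, Sigma, mu0, MG);
  return Rcpp::List::create(Rcpp::Named("ok") = ok,
                            Rcpp::Named("Sigma") = Sigma,
                            Rcpp::Named("mu") = mu0,
                            Rcpp::Named("MGamma") = MG,
                            Rcpp::Named("Lambda") = m.Lambda,
                            Rcpp::Named("B") = m.B,
                            Rcpp::Named("Psi") = m.Psi,
                            Rcpp::Named("Theta") = m.Theta,
                            Rcpp::Named("Gamma") = m.Gamma,
                            Rcpp::Named("alpha") = m.alpha,
                            Rcpp::Named("nu") = m.nu);
}

// patterns: list of list(rows = 0-based uvec, cols = 0-based uvec)
static double negll_core(const arma::vec& theta, const Rcpp::List& tmpl,
                         const Rcpp::List& fmap, const arma::mat& Y,
                         const arma::mat& X, const Rcpp::List& patterns,
                         bool casewise, arma::vec& cw) {
  FilledModel m = fill_model(theta, tmpl, fmap);
  arma::mat Sigma, MG; arma::vec mu0;
  if (!implied(m, Sigma, mu0, MG)) return BIG_NLL;
  const bool has_x = MG.n_cols > 0;
  double total = 0.0;
  if (casewise) cw.set_size(Y.n_rows);
  for (int pi = 0; pi < patterns.size(); ++pi) {
    Rcpp::List pat = patterns[pi];
    arma::uvec rows = Rcpp::as<arma::uvec>(pat["rows"]);
    arma::uvec cols = Rcpp::as<arma::uvec>(pat["cols"]);
    const arma::uword k = cols.n_elem;
    arma::mat S = Sigma(cols, cols);
    arma::mat R;
    if (!arma::chol(R, S)) return BIG_NLL;
    double logdet = 2.0 * arma::accu(arma::log(R.diag()));
    arma::mat Ry = Y(rows, cols);
    Ry.each_row() -= mu0(cols).t();
    if (has_x) Ry -= X.rows(rows) * MG.rows(cols).t();
    // quadratic forms via triangular solve: Z = R^-T Ry^T
    arma::mat Z = arma::solve(arma::trimatl(R.t()), Ry.t());
    arma::rowvec q = arma::sum(Z % Z, 0);
    double base = (double)k * LOG2PI + logdet;
    if (casewise) {
      for (arma::uword r = 0; r < rows.n_elem; ++r)
        cw(rows(r)) = -0.5 * (base + q(r));
    }
    total += -0.5 * ((double)rows.n_elem * base + arma::accu(q));
  }
  if (!std::isfinite(total)) return BIG_NLL;
  return -total;
}

// [[Rcpp::export]]
double fiml_negll_cpp(const arma::vec& theta, const Rcpp::List& tmpl,
                      const Rcpp::List& fmap, const arma::mat& Y,
                      const arma::mat& X, const Rcpp::List& patterns) {
  arma::vec cw;
  return negll_core(theta, tmpl, fmap, Y, X, patterns, false, cw);
}

// [[Rcpp::export]]
arma::vec fiml_casewise_cpp(const arma::vec& theta, const Rcpp::List& tmpl,
                            const Rcpp::List& fmap, const arma::mat& Y,
                            const arma::mat& X, const Rcpp::List& patterns) {
  arma::vec cw;
  double nll = negll_core(theta, tmpl, fmap, Y, X, patterns, true, cw);
  if (nll >= BIG_NLL) cw.fill(arma::datum::nan);
  return cw;
}

// Gaussian log-likelihood of data with missingness at fixed (mu, Sigma);
// used by the saturated-model EM and its oracle tests.
// [[Rcpp::export]]
double fiml_ll_moments_cpp(const arma::mat& Z, const arma::vec& mu,
                           const arma::mat& Sigma, const Rcpp::List& patterns) {
  double total = 0.0;
  for (int pi = 0; pi < patterns.size(); ++pi) {
    Rcpp::List pat = patterns[pi];
    arma::uvec rows = Rcpp::as<arma::uvec>(pat["rows"]);
    arma::uvec cols = Rcpp::as<arma::uvec>(pat["cols"]);
    arma::mat R;
    if (!arma::chol(R, Sigma(cols, cols))) return -arma::datum::inf;
    double logdet = 2.0 * arma::accu(arma::log(R.diag()));
    arma::mat Ry = Z(rows, cols);
    Ry.each_row() -= mu(cols).t();
    arma::mat W = arma::solve(arma::trimatl(R.t()), Ry.t());
    total += -0.5 * ((double)rows.n_elem *
                     ((double)cols.n_elem * LOG2PI + logdet) +
                     arma::accu(W % W));
  }
  return total;
}

// Analytic gradient of the FIML negative log-likelihood.
//
// Accumulates, over missingness patterns, the weight matrix
//   A = sum_p P_o' (Sigma_o^-1 C_p Sigma_o^-1 - n_p Sigma_o^-1) P_o
// (C_p the residual scatter), the mean-score vector u = sum Sigma_o^-1 r_i
// and the covariate-weighted score U = sum (Sigma_o^-1 r_i) x_i'.
// Structural derivatives then reduce to a handful of precomputed products
// per free-parameter cell.
// [[Rcpp::export]]
Rcpp::List fiml_negll_grad_cpp(const arma::vec& theta, const Rcpp::List& tmpl,
                               const Rcpp::List& fmap, const arma::mat& Y,
                               const arma::mat& X,
                               const Rcpp::List& patterns) {
  const int K = theta.n_elem;
  arma::vec grad(K, arma::fill::zeros);
  FilledModel m = fill_model(theta, tmpl, fmap);
  const arma::uword p = m.Lambda.n_rows, nl = m.Lambda.n_cols;
  const arma::uword q = m.Gamma.n_cols;
  arma::mat IB;
  if (!arma::inv(IB, arma::eye(nl, nl) - m.B))
    return Rcpp::List::create(Rcpp::Named("nll") = BIG_NLL,
                              Rcpp::Named("grad") = grad);
  arma::mat M = m.Lambda * IB;
  arma::mat Sigma = M * m.Psi * M.t() + m.Theta;
  arma::vec mu0 = m.nu + M * m.alpha;
  arma::mat MG;
  if (q > 0) MG = M * m.Gamma;

  double total = 0.0;
  arma::mat A(p, p, arma::fill::zeros);
  arma::vec u(p, arma::fill::zeros);
  arma::mat U(p, q, arma::fill::zeros);
  for (int pi = 0; pi < patterns.size(); ++pi) {
    Rcpp::List pat = patterns[pi];
    arma::uvec rows = Rcpp::as<arma::uvec>(pat["rows"]);
    arma::uvec cols = Rcpp::as<arma::uvec>(pat["cols"]);
    const arma::uword k = cols.n_elem;
    arma::mat S = Sigma(cols, cols);
    arma::mat R;
    if (!arma::chol(R, S))
      return Rcpp::List::create(Rcpp::Named("nll") = BIG_NLL,
                                Rcpp::Named("grad") = grad);
    double logdet = 2.0 * arma::accu(arma::log(R.diag()));
    arma::mat Ry = Y(rows, cols);
    Ry.each_row() -= mu0(cols).t();
    if (q > 0) Ry -= X.rows(rows) * MG.rows(cols).t();
    arma::mat Sinv = arma::inv_sympd(S);
    arma::mat SR = Ry * Sinv;                     // n_p x k, rows Sigma^-1 r_i
    total += -0.5 * ((double)rows.n_elem * ((double)k * LOG2PI + logdet) +
                     arma::accu(SR % Ry));
    arma::mat Ap = SR.t() * SR - (double)rows.n_elem * Sinv;
    A(cols, cols) += Ap;
    arma::vec up = arma::sum(SR, 0).t();
    u(cols) += up;
    if (q > 0) U.rows(cols) += SR.t() * X.rows(rows);
  }
  if (!std::isfinite(total))
    return Rcpp::List::create(Rcpp::Named("nll") = BIG_NLL,
                              Rcpp::Named("grad") = grad);

  // precomputed products for the structural chain rule
  arma::mat Q = IB * m.Psi * M.t();       // nl x p
  arma::mat Gpsi = M.t() * A * M;         // nl x nl
  arma::mat QA = Q * A;                   // nl x p
  arma::mat GB = QA * M;                  // nl x nl  (use GB(l, k))
  arma::vec Mu = M.t() * u;               // nl
  arma::vec IBa = IB * m.alpha;           // nl
  arma::mat Ggam, IBG;
  if (q > 0) { Ggam = M.t() * U; IBG = IB * m.Gamma; }

  const char* mats[7] = {"Lambda", "B", "Psi", "Theta", "Gamma", "alpha", "nu"};
  for (int mi = 0; mi < 7; ++mi) {
    Rcpp::List fm = fmap[mats[mi]];
    arma::uvec idx = Rcpp::as<arma::uvec>(fm["idx"]);
    arma::uvec par = Rcpp::as<arma::uvec>(fm["par"]);
    for (arma::uword c = 0; c < idx.n_elem; ++c) {
      arma::uword li = idx(c);
      double dll = 0.0;
      if (mi == 0) {            // Lambda cell (i, k), nrow p
        arma::uword i = li % p, k = li / p;
        dll = QA(k, i) + u(i) * IBa(k);
        if (q > 0) dll += arma::dot(U.row(i), IBG.row(k));
      } else if (mi == 1) {     // B cell (k, l), nrow nl
        arma::uword k = li % nl, l = li / nl;
        dll = GB(l, k) + Mu(k) * IBa(l);
        if (q > 0) dll += arma::dot(Ggam.row(k), IBG.row(l));
      } else if (mi == 2) {     // Psi cell (k, l)
        arma::uword k = li % nl, l = li / nl;
        dll = 0.5 * Gpsi(k, l);
      } else if (mi == 3) {     // Theta cell (i, j), nrow p
        dll = 0.5 * A(li % p, li / p);
      } else if (mi == 4) {     // Gamma cell (k, j), nrow nl
        dll = Ggam(li % nl, li / nl);
      } else if (mi == 5) {     // alpha k
        dll = Mu(li);
      } else {                  // nu i
        dll = u(li);
      }
      grad(par(c)) -= dll;
    }
  }
  return Rcpp::List::create(Rcpp::Named("nll") = -total,
                            Rcpp::Named("grad") = grad);
}
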