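#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Casewise (full-information) multivariate-normal discrepancy and its
// gradient, accumulated over missing-data patterns. Patterns carry
// sufficient statistics so cost is O(#patterns * k^3), independent of n.
//
// Each pattern g contributes, with o its observed index set,
//   n_g * (k log 2pi + log det S_oo) + tr(S_oo^-1 A_g),
// where A_g is the scatter of (y - mu) over the pattern's cases:
//   A_g = Syy - sumY mu_o' - mu_o sumY' + n_g mu_o mu_o'.
// The returned objective is -2 * loglik.
//
// Gradients (accumulated into full p x p / p coordinates):
//   dF/dSigma_oo = n_g W - W A_g W,   W = S_oo^-1
//   dF/dmu_o     = -2 W (sumY - n_g mu_o)

// [[Rcpp::export(name = ".fimlEvalCpp")]]
List fimlEvalCpp(const arma::vec& mu, const arma::mat& Sigma, List patterns,
                 bool wantGrad) {
  const int p = mu.n_elem;
  const double LOG2PI = std::log(2.0 * M_PI);
  double f = 0.0;
  arma::mat G(p, p, arma::fill::zeros);
  arma::vec gmu(p, arma::fill::zeros);
  bool ok = true;

  for (int g = 0; g < patterns.size(); ++g) {
    List pat = patterns[g];
    arma::uvec idx = as<arma::uvec>(pat["idx"]);  // 0-based observed indices
    double n = as<double>(pat["n"]);
    arma::vec sumY = as<arma::vec>(pat["sumY"]);
    arma::mat Syy = as<arma::mat>(pat["Syy"]);
    const int k = idx.n_elem;

    arma::mat Soo = Sigma.submat(idx, idx);
    arma::vec muo = mu.elem(idx);

    arma::mat L;
    if (!arma::chol(L, Soo, "lower")) { ok = false; break; }
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat W = arma::inv_sympd(Soo);

    arma::mat A = Syy - sumY * muo.t() - muo * sumY.t() + n * (muo * muo.t());
    f += n * (k * LOG2PI + logdet) + arma::trace(W * A);

    if (wantGrad) {
      arma::mat WA = W * A;
      arma::mat Gg = n * W - WA * W;
      G.submat(idx, idx) += Gg;
      gmu.elem(idx) += -2.0 * (W * (sumY - n * muo));
    }
  }

  if (!ok)
    return List::create(_["ok"] = false, _["f"] = R_PosInf);
  if (wantGrad)
    return List::create(_["ok"] = true, _["f"] = f, _["G"] = G,
                        _["gmu"] = gmu);
  return List::create(_["ok"] = true, _["f"] = f);
}

// One EM step for the saturated (unstructured) MVN model with missing
// data, using the same per-pattern sufficient statistics. Returns the
// expected-complete-data moments: sum over cases of E[y] and E[yy'].
// For pattern g with observed o / missing m:
//   E[y_m | y_o] = mu_m + S_mo W (y_o - mu_o)
//   Cov[y_m | y_o] = S_mm - S_mo W S_om
// Accumulation uses only pattern sums, never individual cases.

// [[Rcpp::export(name = ".emStepCpp")]]
List emStepCpp(const arma::vec& mu, const arma::mat& Sigma, List patterns) {
  const int p = mu.n_elem;
  arma::vec T1(p, arma::fill::zeros);
  arma::mat T2(p, p, arma::fill::zeros);
  double ntot = 0.0;

  for (int g = 0; g < patterns.size(); ++g) {
    List pat = patterns[g];
    arma::uvec o = as<arma::uvec>(pat["idx"]);
    arma::uvec m = as<arma::uvec>(pat["midx"]);
    double n = as<double>(pat["n"]);
    arma::vec sumY = as<arma::vec>(pat["sumY"]);
    arma::mat Syy = as<arma::mat>(pat["Syy"]);
    ntot += n;

    arma::mat W = arma::inv_sympd(Sigma.submat(o, o));
    T1.elem(o) += sumY;
    T2.submat(o, o) += Syy;

    if (m.n_elem > 0) {
      arma::vec muo = mu.elem(o), mum = mu.elem(m);
      arma::mat Smo = Sigma.submat(m, o);
      arma::mat B = Smo * W;  // regression of missing on observed
      // sums of conditional means: sum_i E[y_m] = n mum + B (sumY - n muo)
      arma::vec sumM = n * mum + B * (sumY - n * muo);
      T1.elem(m) += sumM;
      // sum_i E[y_m y_o'] = mum sumY' + B (Syy - sumY muo') - n mum muo'
      //                   + ... expand E[y_m|y_o] y_o'
      arma::mat crossMO =
          mum * sumY.t() + B * (Syy - sumY * muo.t() - muo * sumY.t() +
                                n * (muo * muo.t())) +
          (B * (sumY - n * muo)) * muo.t();
      T2.submat(m, o) += crossMO;
      T2.submat(o, m) += crossMO.t();
      // sum_i E[y_m y_m'] = n Cov_cond + sum_i E[y_m]E[y_m]'
      arma::mat Cond = Sigma.submat(m, m) - B * Smo.t();
      arma::vec d = sumY - n * muo;
      arma::mat S_EE = n * (mum * mum.t()) + mum * (B * d).t() +
                       (B * d) * mum.t() +
                       B *
                           (Syy - sumY * muo.t() - muo * sumY.t() +
                            n * (muo * muo.t())) *
                           B.t();
      T2.submat(m, m) += n * Cond + S_EE;
    }
  }
  return List::create(_["T1"] = T1, _["T2"] = T2, _["n"] = ntot);
}
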