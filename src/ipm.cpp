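// Core numerics for the time-varying IPM: kernel discretization (midpoint
// rule with truncate-and-renormalize eviction correction), power iteration
// for the stable structure, annual projection, and the composite
// size-structure + density log-likelihood. Parameter vector layout
// (0-based): 0-3 survival (int, size, time, size:time), 4-8 growth
// (int, size, time, size:time, sd), 9-12 fecundity (int, size, time,
// size:time), 13-15 offspring size (int, time, sd), 16-17 optional
// bounded-survival (beta1, beta2).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec linpred(const arma::vec& x, double t,
                                double a0, double a1, double a2, double a3) {
  return a0 + a1 * x + (a2 + a3 * x) * t;
}

// Build the discretized kernel K(i, j) ~ k(y_i, x_j, t) * h.
// [[Rcpp::export]]
arma::mat cpp_kernel(const arma::vec& theta, const arma::vec& nodes, double h,
                     double t, bool bounded, bool evict, double fec_cap) {
  const int n = nodes.n_elem;
  const double sd_g = theta(8), sd_o = theta(15);
  if (sd_g <= 0.0 || sd_o <= 0.0)
    stop("growth and offspring-size spreads must be > 0");
  const double lower = nodes(0) - h / 2.0;

  arma::vec s = 1.0 / (1.0 + arma::exp(-linpred(nodes, t, theta(0), theta(1),
                                                theta(2), theta(3))));
  if (bounded) s *= 1.0 / (1.0 + std::exp(theta(16) + theta(17) * t));

  arma::vec mu_g = linpred(nodes, t, theta(4), theta(5), theta(6), theta(7));
  arma::vec eta_f = linpred(nodes, t, theta(9), theta(10), theta(11), theta(12));
  eta_f.clamp(-arma::datum::inf, fec_cap);
  arma::vec f1 = arma::exp(eta_f);

  // growth transition, whole matrix at once: K0(i, j) = N(y_i; mu_j, sd) * h
  arma::mat K = arma::repmat(nodes, 1, n);
  K.each_row() -= mu_g.t();
  K = arma::exp(K % K * (-0.5 / (sd_g * sd_g))) *
      (h / (sd_g * std::sqrt(2.0 * M_PI)));
  for (int j = 0; j < n; ++j) {
    if (evict) {
      double mass = arma::accu(K.col(j));
      if (mass > 0.0) {
        K.col(j) *= s(j) / mass;
        continue;
      }
      // transition density entirely outside the mesh: survivors are kept
      // at the boundary cell nearest the (off-mesh) mean size
      int idx = (int)std::floor((mu_g(j) - lower) / h);
      idx = std::min(std::max(idx, 0), n - 1);
      K.col(j).zeros();
      K(idx, j) = s(j);
    } else {
      K.col(j) *= s(j);
    }
  }

  double mu_o = theta(13) + theta(14) * t;
  arma::vec f2 = arma::normpdf(nodes, mu_o, sd_o) * h;
  if (evict) {
    double mass = arma::accu(f2);
    if (mass > 0.0) {
      f2 /= mass;
    } else {
      int idx = (int)std::floor((mu_o - lower) / h);
      idx = std::min(std::max(idx, 0), n - 1);
      f2.zeros();
      f2(idx) = 1.0;
    }
  }
  K += f2 * f1.t();
  return K;
}

// Dominant eigenpair of a nonnegative kernel matrix by power iteration.
// Returns the structure as a density over log-size (quadrature = 1).
// [[Rcpp::export]]
List cpp_stable(const arma::mat& K, double h, double tol, int maxit) {
  const int n = K.n_rows;
  arma::vec v(n, arma::fill::ones);
  v /= (double)n;
  if (K.max() <= 0.0 && K.min() >= 0.0) {
    // null operator: every vector is an eigenvector with lambda = 0
    return List::create(_["values"] = v / (arma::accu(v) * h),
                        _["lambda"] = 0.0, _["residual"] = 0.0,
                        _["iterations"] = 0, _["converged"] = true);
  }
  double lambda = 0.0, delta = R_PosInf;
  int it = 0;
  bool conv = false;
  for (it = 1; it <= maxit; ++it) {
    arma::vec w = K * v;
    double tot = arma::accu(w);
    if (!std::isfinite(tot) || tot <= 0.0) {
      return List::create(_["values"] = v, _["lambda"] = NA_REAL,
                          _["residual"] = NA_REAL, _["iterations"] = it,
                          _["converged"] = false);
    }
    lambda = tot; // v has unit L1 mass
    w /= tot;
    delta = arma::abs(w - v).max();
    v = w;
    if (delta < tol) { conv = true; break; }
  }
  arma::vec nvec = v / (arma::accu(v) * h);
  double resid = arma::norm(K * nvec - lambda * nvec, 2) /
                 std::max(lambda, 1e-300);
  return List::create(_["values"] = nvec, _["lambda"] = lambda,
                      _["residual"] = resid, _["iterations"] = it,
                      _["converged"] = conv);
}

// Iterate the annual kernel from t0 over `horizon` years, starting from the
// stable structure at t0 scaled to init_density. Returns structures at
// every integer year t0..t0+horizon (columns) and the density series.
// [[Rcpp::export]]
List cpp_simulate(const arma::vec& theta, const arma::vec& nodes, double h,
                  double t0, int horizon, double init_density, bool bounded,
                  bool evict, double fec_cap, double tol, int maxit) {
  const int n = nodes.n_elem;
  arma::mat K0 = cpp_kernel(theta, nodes, h, t0, bounded, evict, fec_cap);
  List st = cpp_stable(K0, h, tol, maxit);
  if (!as<bool>(st["converged"]))
    return List::create(_["converged"] = false,
                        _["residual"] = st["residual"]);
  arma::vec v = as<arma::vec>(st["values"]) * init_density;
  arma::mat out(n, horizon + 1);
  arma::vec dens(horizon + 1);
  out.col(0) = v;
  dens(0) = arma::accu(v) * h;
  for (int k = 0; k < horizon; ++k) {
    arma::mat K = (k == 0) ? K0
      : cpp_kernel(theta, nodes, h, t0 + k, bounded, evict, fec_cap);
    v = K * v;
    out.col(k + 1) = v;
    dens(k + 1) = arma::accu(v) * h;
  }
  return List::create(_["structures"] = out, _["densities"] = dens,
                      _["lambda0"] = st["lambda"], _["converged"] = true);
}

// Composite log-likelihood l = l_n + w * l_d against an observed series.
// obs_years are absolute integer years (first = initialization time);
// cell_idx / ind_time are 0-based per-individual mesh-cell and
// observation-time indices; obs_dens are the observed densities.
// Returns (l, l_n, l_d); -Inf components flag non-viable parameters.
// [[Rcpp::export]]
NumericVector cpp_composite(const arma::vec& theta, const arma::vec& nodes,
                            double h, const arma::ivec& obs_years,
                            const arma::ivec& cell_idx,
                            const arma::ivec& ind_time,
                            const arma::vec& obs_dens, double w,
                            double sigma_d, double scale0, bool bounded,
                            bool evict, double fec_cap) {
  if (sigma_d <= 0.0) stop("sigma_d must be > 0");
  const int n = nodes.n_elem, T = obs_years.n_elem;
  const double neg_inf = R_NegInf;
  NumericVector bad = NumericVector::create(neg_inf, neg_inf, neg_inf);

  arma::mat K0 = cpp_kernel(theta, nodes, h, (double)obs_years(0), bounded,
                            evict, fec_cap);
  List st = cpp_stable(K0, h, 1e-10, 5000);
  if (!as<bool>(st["converged"])) return bad;
  arma::vec v = as<arma::vec>(st["values"]) * scale0;

  arma::mat at_obs(n, T);
  arma::vec pred(T);
  int ti = 0;
  for (int year = obs_years(0); year <= obs_years(T - 1); ++year) {
    if (year == obs_years(ti)) {
      at_obs.col(ti) = v;
      pred(ti) = arma::accu(v) * h;
      ++ti;
      if (ti == T) break;
    }
    arma::mat K = (year == obs_years(0)) ? K0
      : cpp_kernel(theta, nodes, h, (double)year, bounded, evict, fec_cap);
    v = K * v;
    if (!v.is_finite()) return bad;
  }

  double ln = 0.0;
  for (arma::uword i = 0; i < cell_idx.n_elem; ++i) {
    double p = at_obs(cell_idx(i), ind_time(i));
    double d = pred(ind_time(i));
    if (!(p > 0.0) || !(d > 0.0)) { ln = neg_inf; break; }
    ln += std::log(p) - std::log(d);
  }

  double ld = 0.0;
  const double s2 = sigma_d * sigma_d;
  for (int k = 0; k < T; ++k) {
    if (obs_dens(k) <= 0.0) continue; // outside lognormal support; skipped
    if (!(pred(k) > 0.0)) { ld = neg_inf; break; }
    double meanlog = std::log(pred(k)) - s2 / 2.0;
    double z = std::log(obs_dens(k)) - meanlog;
    ld += -std::log(obs_dens(k)) - std::log(sigma_d) -
          0.5 * std::log(2.0 * M_PI) - z * z / (2.0 * s2);
  }

  double l;
  if (!std::isfinite(ln)) l = neg_inf;
  else if (w == 0.0) l = ln;
  else if (!std::isfinite(ld)) l = neg_inf;
  else l = ln + w * ld;
  return NumericVector::create(l, ln, ld);
}
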