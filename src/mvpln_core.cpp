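// Core numerics for MVPLN mixture estimation.
//
// Conventions: an observation is an r x p matrix Y; its vectorization is
// vec(Y^T) (row-major order, cell (i,k) at position (i-1)*p + k, 1-based),
// under which the latent matrix-variate normal has covariance Phi (x) Omega.
// All per-observation variational quantities (xi r x p, Delta r x r,
// kappa p x p) are stored as cube slices, one slice per unit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec vt(const mat& X) { return vectorise(X.t()); }
static inline mat unvt(const vec& v, unsigned r, unsigned p) {
  return mat(const_cast<double*>(v.memptr()), p, r, true).t();
}

// Evidence lower bound contribution of one observation under one component.
// E-term uses exp(xi + log s + 0.5 * diag(Delta) diag(kappa)^T).
static double obs_elbo(const mat& Y, const mat& logs, double sumlg,
                       const mat& xi, const mat& Delta, const mat& kappa,
                       const mat& M, const mat& Phiinv, const mat& Omegainv,
                       double ldetPhi, double ldetOmega) {
  const double r = Y.n_rows, p = Y.n_cols;
  mat E = exp(xi + logs + 0.5 * (diagvec(Delta) * diagvec(kappa).t()));
  mat X = xi - M;
  double quad = trace(Phiinv * X * Omegainv * X.t());
  double ldetD, ldetK, sgn;
  log_det(ldetD, sgn, Delta);
  log_det(ldetK, sgn, kappa);
  return -accu(E) + accu((xi + logs) % Y) - sumlg
    - 0.5 * p * ldetPhi - 0.5 * r * ldetOmega
    - 0.5 * quad
    - 0.5 * trace(Phiinv * Delta) * trace(Omegainv * kappa)
    + 0.5 * p * ldetD + 0.5 * r * ldetK + 0.5 * r * p;
}

// One application of the fixed-point map for Delta (row covariance of q).
static mat delta_candidate(const mat& logs, const mat& xi, const mat& Delta,
                           const mat& kappa, const mat& Phiinv,
                           const mat& Omegainv) {
  const double p = kappa.n_rows;
  mat E = exp(xi + logs + 0.5 * (diagvec(Delta) * diagvec(kappa).t()));
  vec d = E * diagvec(kappa);               // d_i = sum_k E_ik kappa_kk
  mat bracket = diagmat(d) + Phiinv * trace(Omegainv * kappa);
  return p * inv_sympd(symmatu(bracket));
}

// Mirror map for kappa (column covariance of q).
static mat kappa_candidate(const mat& logs, const mat& xi, const mat& Delta,
                           const mat& kappa, const mat& Phiinv,
                           const mat& Omegainv) {
  const double r = Delta.n_rows;
  mat E = exp(xi + logs + 0.5 * (diagvec(Delta) * diagvec(kappa).t()));
  vec e = E.t() * diagvec(Delta);           // e_k = sum_i Delta_ii E_ik
  mat bracket = diagmat(e) + Omegainv * trace(Phiinv * Delta);
  return r * inv_sympd(symmatu(bracket));
}

// One damped Newton step on vec(xi^T); halves the step until the
// observation ELBO does not decrease. P = Phiinv (x) Omegainv.
static mat xi_candidate(const mat& Y, const mat& logs, double sumlg,
                        const mat& xi, const mat& Delta, const mat& kappa,
                        const mat& M, const mat& Phiinv, const mat& Omegainv,
                        const mat& P, double ldetPhi, double ldetOmega) {
  const unsigned r = Y.n_rows, p = Y.n_cols;
  mat E = exp(xi + logs + 0.5 * (diagvec(Delta) * diagvec(kappa).t()));
  vec g = vt(Y) - vt(E) - P * (vt(xi) - vt(M));
  if (!g.is_finite()) return xi;
  mat Hneg = diagmat(vt(E)) + P;            // minus the Hessian, SPD
  vec dir = solve(symmatu(Hneg), g, solve_opts::likely_sympd);
  double f0 = obs_elbo(Y, logs, sumlg, xi, Delta, kappa, M, Phiinv, Omegainv,
                       ldetPhi, ldetOmega);
  double t = 1.0;
  for (int h = 0; h < 30; ++h) {
    mat cand = unvt(vt(xi) + t * dir, r, p);
    double f1 = obs_elbo(Y, logs, sumlg, cand, Delta, kappa, M, Phiinv,
                         Omegainv, ldetPhi, ldetOmega);
    if (std::isfinite(f1) && f1 >= f0 - 1e-12) return cand;
    t *= 0.5;
  }
  return xi;
}

// Exported single-observation wrappers --------------------------------------

// [[Rcpp::export]]
double elbo_obs_cpp(const arma::mat& Y, const arma::mat& logs, double sumlg,
                    const arma::mat& xi, const arma::mat& Delta,
                    const arma::mat& kappa, const arma::mat& M,
                    const arma::mat& Phi, const arma::mat& Omega) {
  mat Phiinv = inv_sympd(symmatu(Phi)), Omegainv = inv_sympd(symmatu(Omega));
  double ldP = log_det_sympd(symmatu(Phi));
  double ldO = log_det_sympd(symmatu(Omega));
  return obs_elbo(Y, logs, sumlg, xi, Delta, kappa, M, Phiinv, Omegainv,
                  ldP, ldO);
}

// [[Rcpp::export]]
arma::mat update_delta_cpp(const arma::mat& logs, const arma::mat& xi,
                           const arma::mat& Delta, const arma::mat& kappa,
                           const arma::mat& Phi, const arma::mat& Omega) {
  mat Phiinv = inv_sympd(symmatu(Phi)), Omegainv = inv_sympd(symmatu(Omega));
  return delta_candidate(logs, xi, Delta, kappa, Phiinv, Omegainv);
}

// [[Rcpp::export]]
arma::mat update_kappa_cpp(const arma::mat& logs, const arma::mat& xi,
                           const arma::mat& Delta, const arma::mat& kappa,
                           const arma::mat& Phi, const arma::mat& Omega) {
  mat Phiinv = inv_sympd(symmatu(Phi)), Omegainv = inv_sympd(symmatu(Omega));
  return kappa_candidate(logs, xi, Delta, kappa, Phiinv, Omegainv);
}

// [[Rcpp::export]]
arma::mat update_xi_cpp(const arma::mat& Y, const arma::mat& logs,
                        double sumlg, const arma::mat& xi,
                        const arma::mat& Delta, const arma::mat& kappa,
                        const arma::mat& M, const arma::mat& Phi,
                        const arma::mat& Omega) {
  mat Phiinv = inv_sympd(symmatu(Phi)), Omegainv = inv_sympd(symmatu(Omega));
  mat P = kron(Phiinv, Omegainv);
  double ldP = log_det_sympd(symmatu(Phi));
  double ldO = log_det_sympd(symmatu(Omega));
  return xi_candidate(Y, logs, sumlg, xi, Delta, kappa, M, Phiinv, Omegainv,
                      P, ldP, ldO);
}

// Full pass over all observations for one component: evaluates the ELBO with
// the incoming state (used for responsibilities), then optionally applies one
// safeguarded Delta, kappa and xi update each. Returns updated state and the
// pre/post ELBO vectors. The safeguard comparisons use only the ELBO terms
// that the candidate actually changes; the assembled F matches obs_elbo.
// [[Rcpp::export]]
Rcpp::List vga_component_cpp(const arma::cube& Y, const arma::mat& logs,
                             const arma::vec& sumlg, const arma::mat& M,
                             const arma::mat& Phi, const arma::mat& Omega,
                             arma::cube xi, arma::cube Delta,
                             arma::cube kappa, bool do_update) {
  const unsigned N = Y.n_slices;
  const double r = Y.n_rows, p = Y.n_cols;
  mat Phiinv = inv_sympd(symmatu(Phi)), Omegainv = inv_sympd(symmatu(Omega));
  mat P = kron(Phiinv, Omegainv);
  double ldP = log_det_sympd(symmatu(Phi));
  double ldO = log_det_sympd(symmatu(Omega));
  const double const_g = -0.5 * p * ldP - 0.5 * r * ldO + 0.5 * r * p;
  double sgn;
  vec Fpre(N), Fpost(N);
  for (unsigned n = 0; n < N; ++n) {
    const mat& Yn = Y.slice(n);
    const double const_n = accu(logs % Yn) - sumlg(n) + const_g;
    mat xin = xi.slice(n), Dn = Delta.slice(n), Kn = kappa.slice(n);
    // cached ELBO pieces
    mat E = exp(xin + logs + 0.5 * (diagvec(Dn) * diagvec(Kn).t()));
    double sE = accu(E);
    double linY = accu(xin % Yn);
    mat X = xin - M;
    double quad = trace(Phiinv * X * Omegainv * X.t());
    double trPD = accu(Phiinv % Dn), trOK = accu(Omegainv % Kn);
    double ldD, ldK;
    log_det(ldD, sgn, Dn); log_det(ldK, sgn, Kn);
    double f = -sE + linY + const_n - 0.5 * quad - 0.5 * trPD * trOK
      + 0.5 * p * ldD + 0.5 * r * ldK;
    Fpre(n) = f;
    if (do_update) {
      // Delta fixed point; changes E, tr(Phiinv Delta), log|Delta|
      {
        vec dK = diagvec(Kn);
        vec d = E * dK;
        mat Dc = p * inv_sympd(symmatu(diagmat(d) + Phiinv * trOK));
        mat Ec = exp(xin + logs + 0.5 * (diagvec(Dc) * dK.t()));
        double sEc = accu(Ec), trPDc = accu(Phiinv % Dc);
        double ldDc; log_det(ldDc, sgn, Dc);
        double df = -(sEc - sE) - 0.5 * trOK * (trPDc - trPD)
          + 0.5 * p * (ldDc - ldD);
        if (std::isfinite(df) && df >= -1e-10) {
          Dn = Dc; E = Ec; sE = sEc; trPD = trPDc; ldD = ldDc; f += df;
        }
      }
      // kappa fixed point
      {
        vec dD = diagvec(Dn);
        vec e = E.t() * dD;
        mat Kc = r * inv_sympd(symmatu(diagmat(e) + Omegainv * trPD));
        mat Ec = exp(xin + logs + 0.5 * (dD * diagvec(Kc).t()));
        double sEc = accu(Ec), trOKc = accu(Omegainv % Kc);
        double ldKc; log_det(ldKc, sgn, Kc);
        double df = -(sEc - sE) - 0.5 * trPD * (trOKc - trOK)
          + 0.5 * r * (ldKc - ldK);
        if (std::isfinite(df) && df >= -1e-10) {
          Kn = Kc; E = Ec; sE = sEc; trOK = trOKc; ldK = ldKc; f += df;
        }
      }
      // xi Newton step with halving; changes E, linY, quad
      {
        vec g = vt(Yn) - vt(E) - P * (vt(xin) - vt(M));
        if (g.is_finite()) {
          mat Hneg = diagmat(vt(E)) + P;
          vec dir = solve(symmatu(Hneg), g, solve_opts::likely_sympd);
          mat half = 0.5 * (diagvec(Dn) * diagvec(Kn).t());
          double t = 1.0;
          for (int h = 0; h < 30; ++h) {
            mat xc = unvt(vt(xin) + t * dir, (unsigned)r, (unsigned)p);
            mat Ec = exp(xc + logs + half);
            double sEc = accu(Ec), linYc = accu(xc % Yn);
            mat Xc = xc - M;
            double quadc = trace(Phiinv * Xc * Omegainv * Xc.t());
            double df = -(sEc - sE) + (linYc - linY)
              - 0.5 * (quadc - quad);
            if (std::isfinite(df) && df >= -1e-12) {
              xin = xc; E = Ec; sE = sEc; linY = linYc; quad = quadc;
              f += df;
              break;
            }
            t *= 0.5;
          }
        }
      }
      xi.slice(n) = xin; Delta.slice(n) = Dn; kappa.slice(n) = Kn;
    }
    Fpost(n) = f;
  }
  return Rcpp::List::create(
    Rcpp::Named("Fpre") = Fpre, Rcpp::Named("Fpost") = Fpost,
    Rcpp::Named("xi") = xi, Rcpp::Named("Delta") = Delta,
    Rcpp::Named("kappa") = kappa);
}

// M-step accumulation for one component (weights z over units):
//   M     = sum_n z_n xi_n / n_g
//   Phi   = sum_n z_n [ (xi-M) Omega_old^-1 (xi-M)^T + Delta tr(Omega_old^-1 kappa) ] / (p n_g)
//   Omega = sum_n z_n [ kappa tr(Phi_new^-1 Delta) + (xi-M)^T Phi_new^-1 (xi-M) ] / (r n_g)
// [[Rcpp::export]]
Rcpp::List mstep_component_cpp(const arma::vec& z, const arma::cube& xi,
                               const arma::cube& Delta, const arma::cube& kappa,
                               const arma::mat& Omega_old) {
  const unsigned N = xi.n_slices, r = xi.n_rows, p = xi.n_cols;
  const double ng = accu(z);
  mat M(r, p, fill::zeros);
  for (unsigned n = 0; n < N; ++n) M += z(n) * xi.slice(n);
  M /= ng;
  mat Omoldinv = inv_sympd(symmatu(Omega_old));
  mat Phi(r, r, fill::zeros);
  for (unsigned n = 0; n < N; ++n) {
    mat X = xi.slice(n) - M;
    Phi += z(n) * (X * Omoldinv * X.t()
                   + Delta.slice(n) * trace(Omoldinv * kappa.slice(n)));
  }
  Phi = symmatu(Phi / (p * ng));
  // rank-deficient scatter (e.g. single observation with vanishing
  // variational covariances) takes a jitter path, mirroring ensure_spd()
  mat Phinv;
  if (!inv_sympd(Phinv, symmatu(Phi))) {
    Rcpp::warning("M-step Phi scatter near-singular; jittering diagonal");
    double jit = 1e-8 * trace(Phi) / r + 1e-12;
    for (int k = 0; k < 12; ++k) {
      Phi += jit * eye(r, r);
      if (inv_sympd(Phinv, symmatu(Phi))) break;
      jit *= 10.0;
    }
  }
  mat Omega(p, p, fill::zeros);
  for (unsigned n = 0; n < N; ++n) {
    mat X = xi.slice(n) - M;
    Omega += z(n) * (kappa.slice(n) * trace(Phinv * Delta.slice(n))
                     + X.t() * Phinv * X);
  }
  Omega = symmatu(Omega / (r * ng));
  return Rcpp::List::create(Rcpp::Named("M") = M, Rcpp::Named("Phi") = Phi,
                            Rcpp::Named("Omega") = Omega);
}

// Importance-sampled per-observation log marginal likelihood under one
// component, using the fitted variational posterior (covariances inflated
// by `infl`) as the proposal. Draws theta = xi + A Z B with A A' = infl *
// Delta and B'B = infl * kappa, so log q(theta) = const - ||Z||^2 / 2 and
// no solves are needed per draw. Uses R's RNG. Returns log( mean weight ).
// [[Rcpp::export]]
arma::vec is_loglik_cpp(const arma::cube& Y, const arma::mat& logs,
                        const arma::vec& sumlg, const arma::mat& M,
                        const arma::mat& Phi, const arma::mat& Omega,
                        const arma::cube& xi, const arma::cube& Delta,
                        const arma::cube& kappa, int m, double infl) {
  const unsigned N = Y.n_slices, r = Y.n_rows, p = Y.n_cols;
  mat Phiinv = inv_sympd(symmatu(Phi)), Omegainv = inv_sympd(symmatu(Omega));
  double ldP = log_det_sympd(symmatu(Phi));
  double ldO = log_det_sympd(symmatu(Omega));
  // the (2 pi)^{-d/2} factors of the prior and the proposal cancel in the
  // importance weight, so both constants omit them
  const double prior_const = -0.5 * p * ldP - 0.5 * r * ldO;
  const unsigned d = r * p;
  mat Pk = kron(Phiinv, Omegainv);              // precision of vec(theta^T)
  vec Mv = vt(M), logsv = vt(logs);
  vec out(N);
  mat Zm(d, m), TH(d, m), X(d, m), E(d, m);
  rowvec lw(m);
  Rcpp::RNGScope scope;
  for (unsigned n = 0; n < N; ++n) {
    vec Yv = vt(Y.slice(n));
    mat D = infl * Delta.slice(n), K = infl * kappa.slice(n);
    mat A = chol(symmatu(D), "lower"), B = chol(symmatu(K));
    double ldD = 2.0 * accu(log(A.diag())), ldK = 2.0 * accu(log(B.diag()));
    const double q_const = -0.5 * p * ldD - 0.5 * r * ldK;
    for (unsigned c = 0; c < d * (unsigned)m; ++c) Zm(c) = R::norm_rand();
    // vec(theta^T) = vec(xi^T) + (A (x) B^T) vec(Z^T); draws Zm are already
    // the vec(Z^T) coordinates, so the map is the Kronecker factor below
    TH = kron(A, B.t()) * Zm;
    TH.each_col() += vt(xi.slice(n));
    X = TH;
    X.each_col() -= Mv;
    E = TH;
    E.each_col() += logsv;
    lw = Yv.t() * E - sum(exp(E), 0) - 0.5 * sum(X % (Pk * X), 0)
      + 0.5 * sum(Zm % Zm, 0);
    lw += prior_const - q_const - sumlg(n);
    lw.replace(datum::nan, -datum::inf);
    double mx = lw.max();
    out(n) = std::isfinite(mx) ? mx + std::log(accu(exp(lw - mx)) / m)
                               : -datum::inf;
  }
  return out;
}

// Adaptive random-walk Metropolis sampler for the posterior of one latent
// log-rate matrix theta given counts Y, offsets s, and component parameters.
// Proposal scale adapts during burn-in toward the target acceptance rate.
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
Rcpp::List rwm_theta_cpp(const arma::mat& Y, const arma::mat& logs,
                         const arma::mat& M, const arma::mat& Phi,
                         const arma::mat& Omega, const arma::mat& theta0,
                         int B, int W, double target_accept,
                         bool keep_draws) {
  const unsigned r = Y.n_rows, p = Y.n_cols, d = r * p;
  mat Phiinv = inv_sympd(symmatu(Phi)), Omegainv = inv_sympd(symmatu(Omega));
  auto logpost = [&](const mat& th) {
    mat X = th - M;
    return accu(Y % (th + logs)) - accu(exp(th + logs))
      - 0.5 * trace(Phiinv * X * Omegainv * X.t());
  };
  mat th = theta0;
  double lp = logpost(th);
  // initial proposal scale from the Poisson curvature at the start value:
  // posterior sd per cell is roughly 1/sqrt(rate + prior precision)
  double curv = accu(exp(theta0 + logs)) / d + trace(kron(Phiinv, Omegainv)) / d;
  double lsig = std::log(2.38 / std::sqrt((double)d)) -
    0.5 * std::log(1.0 + curv);
  const int burn = B - W;
  int accepted = 0, acc_batch = 0, batch = 0;
  const int batch_size = 25;
  mat draws;
  if (keep_draws) draws.set_size(W, d);
  vec msum(d, fill::zeros);
  mat ssum(d, d, fill::zeros);
  Rcpp::RNGScope scope;
  for (int it = 0; it < B; ++it) {
    mat prop = th;
    double sig = std::exp(lsig);
    for (unsigned j = 0; j < d; ++j)
      prop(j / p, j % p) += sig * R::norm_rand();
    double lpp = logpost(prop);
    if (std::isfinite(lpp) && std::log(R::unif_rand()) < lpp - lp) {
      th = prop; lp = lpp; ++accepted; ++acc_batch;
    }
    if (it < burn && (it + 1) % batch_size == 0) {
      ++batch;
      double rate = (double)acc_batch / batch_size;
      double step = std::min(0.5, 2.0 / std::sqrt((double)batch));
      lsig += (rate > target_accept) ? step : -step;
      acc_batch = 0;
    }
    if (it >= burn) {
      vec v = vt(th);
      msum += v;
      ssum += v * v.t();
      if (keep_draws) draws.row(it - burn) = v.t();
    }
  }
  vec mbar = msum / W;
  mat S = ssum / W - mbar * mbar.t();   // centered second moment of vec(theta^T)
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("mean") = unvt(mbar, r, p),
    Rcpp::Named("S") = symmatu(S),
    Rcpp::Named("accept_rate") = (double)accepted / B,
    Rcpp::Named("W") = W);
  if (keep_draws) out["draws"] = draws;
  return out;
}
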