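# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no data files.

# small random SPD pair plus mean matrix, reproducible
toy_component <- function(r = 2, p = 3, seed = 42) {
  list(M = with_seed_test(seed, matrix(stats::rnorm(r * p), r, p)),
       Phi = random_spd(r, c(0.5, 2), seed = seed + 1),
       Omega = random_spd(p, c(0.5, 2), seed = seed + 2))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

ones_rp <- function(r, p) matrix(1, r, p)

# quadrature oracles for the 1x1 model: joint f(Y, theta) with offset s,
# prior N(m, v); returns log marginal, posterior mean and variance
quad_1x1 <- function(Y, s = 1, m = 0, v = 1) {
  lj <- function(th) -s * exp(th) + th * Y + Y * log(s) - lgamma(Y + 1) +
    stats::dnorm(th, m, sqrt(v), log = TRUE)
  marg <- stats::integrate(function(th) exp(lj(th)), -30, 30,
                           rel.tol = 1e-12)$value
  post <- function(th) exp(lj(th)) / marg
  pm <- stats::integrate(function(th) th * post(th), -30, 30,
                         rel.tol = 1e-10)$value
  pv <- stats::integrate(function(th) (th - pm)^2 * post(th), -30, 30,
                         rel.tol = 1e-10)$value
  list(logmarg = log(marg), mean = pm, var = pv, lj = lj)
}

# KL(q || posterior) by quadrature for the 1x1 model
quad_kl_1x1 <- function(Y, s, m, v, xi, sig2) {
  or <- quad_1x1(Y, s, m, v)
  f <- function(th) {
    lq <- stats::dnorm(th, xi, sqrt(sig2), log = TRUE)
    exp(lq) * (lq - or$lj(th) + or$logmarg)
  }
  stats::integrate(Vectorize(f), xi - 12 * sqrt(sig2), xi + 12 * sqrt(sig2),
                   rel.tol = 1e-10)$value
}

# numeric gradient of the observation ELBO w.r.t. a symmetric matrix slot
# ("Delta" or "kappa"), symmetrized central-difference perturbation
num_grad_sym <- function(slot, Y, offsets, xi, Delta, kappa, M, Phi, Omega,
                         h = 1e-5) {
  A <- if (slot == "Delta") Delta else kappa
  g <- matrix(0, nrow(A), ncol(A))
  fval <- function(Ap) {
    if (slot == "Delta")
      elbo_observation(Y, offsets, xi, Ap, kappa, M, Phi, Omega)
    else elbo_observation(Y, offsets, xi, Delta, Ap, M, Phi, Omega)
  }
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    Ap <- Am <- A
    Ap[i, j] <- Ap[i, j] + h
    Am[i, j] <- Am[i, j] - h
    if (i != j) {
      Ap[j, i] <- Ap[j, i] + h
      Am[j, i] <- Am[j, i] - h
    }
    g[i, j] <- (fval(Ap) - fval(Am)) / (2 * h)
  }
  g
}

num_grad_xi <- function(Y, offsets, xi, Delta, kappa, M, Phi, Omega,
                        h = 1e-5) {
  g <- matrix(0, nrow(xi), ncol(xi))
  for (i in seq_len(nrow(xi))) for (k in seq_len(ncol(xi))) {
    xp <- xm <- xi
    xp[i, k] <- xp[i, k] + h
    xm[i, k] <- xm[i, k] - h
    g[i, k] <- (elbo_observation(Y, offsets, xp, Delta, kappa, M, Phi,
                                 Omega) -
                elbo_observation(Y, offsets, xm, Delta, kappa, M, Phi,
                                 Omega)) / (2 * h)
  }
  g
}

# run the coordinate updates to (approximate) joint convergence for one
# observation; ends on Delta/kappa so their fixed points are current
converge_obs <- function(Y, offsets, xi, Delta, kappa, M, Phi, Omega,
                         iters = 2000) {
  for (i in seq_len(iters)) {
    Delta <- update_delta(Y, offsets, xi, Delta, kappa, M, Phi, Omega)
    kappa <- update_kappa(Y, offsets, xi, Delta, kappa, M, Phi, Omega)
    xi <- update_xi(Y, offsets, xi, Delta, kappa, M, Phi, Omega)
  }
  Delta <- update_delta(Y, offsets, xi, Delta, kappa, M, Phi, Omega)
  kappa <- update_kappa(Y, offsets, xi, Delta, kappa, M, Phi, Omega)
  list(xi = xi, Delta = Delta, kappa = kappa)
}

# small labeled dataset for fit tests
small_sim2 <- function(seed = 11, scale = 0.2) {
  simulate_mvpln_mixture(build_sim_design("sim2", seed = seed,
                                          scale = scale))
}

hard_z_test <- function(labels, G) {
  z <- matrix(0, length(labels), G)
  z[cbind(seq_along(labels), labels)] <- 1
  z
}

sample_labels <- function(N, G, seed = 123) {
  with_seed_test(seed, sample.int(G, N, replace = TRUE))
}
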