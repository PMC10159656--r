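# MCMC-EM estimation and the three-step hybrid estimator.
#
# The E-step expectation over each latent log-rate matrix is approximated by
# an adaptive random-walk Metropolis chain on vec(theta^T); retained draws
# give the posterior mean and the centered second moment needed by the
# M-step expectations. Responsibilities are evaluated by plugging the
# posterior mean into the Poisson x matrix-normal joint density.

#' Control settings for MCMC-based fits
#'
#' @param B total MCMC iterations per chain (default 2000).
#' @param W retained iterations after burn-in, \code{W < B} (default 1000).
#' @param n_chains number of chains per E-step expectation (default 1;
#'   chains are pooled).
#' @param target_accept Metropolis target acceptance rate; default 0.44 for
#'   scalar latent dimension and 0.234 otherwise.
#' @param max_iter maximum EM iterations (default 30).
#' @param tol relative convergence tolerance on the plug-in log-likelihood
#'   (default 1e-5).
#' @param n_kmeans k-means initialization runs (default 100).
#' @param seed integer seed (default 1).
#' @param rao_blackwell if \code{TRUE}, responsibilities average the joint
#'   density over retained draws instead of plugging in the posterior mean.
#' @param verbose print per-iteration progress.
#' @return A list of control settings.
#' @export
mcmc_control <- function(B = 2000, W = 1000, n_chains = 1,
                         target_accept = NULL, max_iter = 30, tol = 1e-5,
                         n_kmeans = 100, seed = 1, rao_blackwell = FALSE,
                         verbose = FALSE) {
  if (W >= B || W < 1) stop_validation("need 1 <= W < B")
  if (n_chains < 1) stop_validation("n_chains must be >= 1")
  list(B = B, W = W, n_chains = n_chains, target_accept = target_accept,
       max_iter = max_iter, tol = tol, n_kmeans = n_kmeans, seed = seed,
       rao_blackwell = rao_blackwell, verbose = verbose)
}

default_target_accept <- function(d) if (d == 1) 0.44 else 0.234

# Poisson x matrix-normal joint log density at a plug-in theta.
logjoint_obs <- function(Y, logs, th, cmp) {
  sum(-exp(th + logs) + (th + logs) * Y - lgamma(Y + 1)) +
    dmatnorm(th, cmp$M, cmp$Phi, cmp$Omega)
}

#' Sample the posterior of one latent log-rate matrix
#'
#' Draws from the posterior proportional to
#' \code{prod Poisson(Y_ik | exp(theta_ik + log s_ik)) x
#' matrix-normal(theta | M, Phi, Omega)} by adaptive random-walk Metropolis
#' on \code{vec(theta^T)}; the proposal scale adapts during burn-in toward
#' the target acceptance rate. Chains (if several) are pooled.
#'
#' @param Y \code{r x p} count matrix.
#' @param offsets \code{r x p} positive offset matrix.
#' @param params component parameters: list with \code{M}, \code{Phi},
#'   \code{Omega}.
#' @param config list from [mcmc_control()].
#' @param theta0 optional chain start (default: per-cell quasi-MLE
#'   \code{log((Y + 0.5) / s)}).
#' @param keep_draws if \code{TRUE}, return the retained draws
#'   (\code{W x rp}, rows are \code{vec(theta^T)}).
#' @return A list with \code{mean} (posterior mean matrix), \code{S}
#'   (centered second moment of \code{vec(theta^T)}), \code{accept_rate},
#'   \code{W} and optionally \code{draws}.
#' @export
sample_theta_posterior <- function(Y, offsets, params,
                                   config = mcmc_control(),
                                   theta0 = NULL, keep_draws = FALSE) {
  logs <- log(offsets)
  if (is.null(theta0)) theta0 <- log((Y + 0.5) / offsets)
  ta <- config$target_accept
  if (is.null(ta)) ta <- default_target_accept(length(Y))
  outs <- lapply(seq_len(config$n_chains), function(ch)
    rwm_theta_cpp(Y, logs, params$M, params$Phi, params$Omega, theta0,
                  config$B, config$W, ta, keep_draws))
  acc <- mean(vapply(outs, `[[`, 0, "accept_rate"))
  if (acc == 0)
    stop_numeric("Metropolis sampler failed: zero acceptance after adaptation")
  mean_pooled <- Reduce(`+`, lapply(outs, `[[`, "mean")) / length(outs)
  # pool centered moments around the pooled mean
  S <- Reduce(`+`, lapply(outs, function(o) {
    dv <- vec_transpose(o$mean - mean_pooled)
    o$S + tcrossprod(dv)
  })) / length(outs)
  res <- list(mean = mean_pooled, S = S, accept_rate = acc,
              W = config$W * config$n_chains)
  if (keep_draws)
    res$draws <- do.call(rbind, lapply(outs, `[[`, "draws"))
  res
}

# E[(theta - M) A (theta - M)^T] (r x r) and E[(theta - M)^T B (theta - M)]
# (p x p) from the posterior mean and the centered second moment S of
# vec(theta^T), index c = (i-1)p + k.
quad_expect_row <- function(mean_th, S, M, A) {
  r <- nrow(mean_th); p <- ncol(mean_th)
  X <- mean_th - M
  out <- X %*% A %*% t(X)
  S4 <- array(S, c(p, r, p, r))   # S4[k, i, l, j]
  for (i in seq_len(r)) for (j in seq_len(r))
    out[i, j] <- out[i, j] + sum(A * S4[, i, , j])
  out
}

quad_expect_col <- function(mean_th, S, M, B) {
  r <- nrow(mean_th); p <- ncol(mean_th)
  X <- mean_th - M
  out <- t(X) %*% B %*% X
  S4 <- array(S, c(p, r, p, r))
  for (k in seq_len(p)) for (l in seq_len(p))
    out[k, l] <- out[k, l] + sum(B * S4[k, , l, ])
  out
}

# M-step for one component from posterior means and centered moments.
mcmc_mstep_component <- function(zg, means, Ss, Omega_old, r, p) {
  ng <- sum(zg)
  if (ng < 1e-8) stop_numeric("degenerate component (n_g < 1e-8)")
  M <- Reduce(`+`, Map(function(w, m) w * m, zg, means)) / ng
  Omoldinv <- chol2inv(chol(Omega_old))
  Phi <- Reduce(`+`, Map(function(w, m, S)
    w * quad_expect_row(m, S, M, Omoldinv), zg, means, Ss)) / (p * ng)
  Phi <- ensure_spd(Phi, "Phi")
  Phinv <- chol2inv(chol(Phi))
  Omega <- Reduce(`+`, Map(function(w, m, S)
    w * quad_expect_col(m, S, M, Phinv), zg, means, Ss)) / (r * ng)
  list(M = M, Phi = Phi, Omega = ensure_spd(Omega, "Omega"))
}

#' Fit an MVPLN mixture by MCMC-EM
#'
#' Alternates a sampling E-step (posterior mean and second moment of each
#' latent log-rate matrix per unit and component; responsibilities from the
#' plug-in joint density at the posterior means) with the closed-form M-step
#' whose expectations are taken over the retained draws. Outer convergence
#' uses the relative change of the plug-in log-likelihood. Substantially
#' slower than [fit_vga()]; intended for posterior inference at moderate N.
#'
#' @param tensor a \code{count_tensor}.
#' @param offsets \code{r x p} positive offsets or \code{NULL} for ones.
#' @param G number of components.
#' @param control list from [mcmc_control()].
#' @return An object of class \code{mvpln_fit} (method \code{"mcmc"}) with
#'   sampler diagnostics in \code{$diagnostics}.
#' @export
fit_mcmc_em <- function(tensor, offsets = NULL, G, control = mcmc_control()) {
  d <- tensor_dims(tensor)
  offsets <- validate_offsets(offsets, tensor)
  control <- utils::modifyList(mcmc_control(), control)
  runs <- kmeans_runs(tensor, G, control$n_kmeans, control$seed)
  last_err <- NULL
  for (attempt in seq_len(min(3L, length(runs)))) {
    fit <- tryCatch(
      mcmc_em(tensor, offsets, G, control, runs[[attempt]]$cluster),
      mvpln_numeric_error = function(e) e)
    if (!inherits(fit, "error")) {
      fit$n_restarts <- attempt - 1L
      return(fit)
    }
    last_err <- fit
  }
  stop_numeric("MCMC-EM fit failed after restarts: ",
               conditionMessage(last_err))
}

mcmc_em <- function(tensor, offsets, G, control, init_labels) {
  d <- tensor_dims(tensor); N <- d$N; r <- d$r; p <- d$p
  logs <- log(offsets)
  Ymats <- lapply(seq_len(N), function(n) matrix(tensor$counts[n, , ], r, p))
  z <- hard_z(init_labels, G)

  theta_hat <- lapply(seq_len(G), function(g)
    lapply(Ymats, function(Y) log((Y + 0.5) / offsets)))
  tiny <- lapply(seq_len(N), function(n) diag(1e-4, r * p))
  comps <- lapply(seq_len(G), function(g)
    mcmc_mstep_component(z[, g], theta_hat[[g]], tiny, diag(p), r, p))
  pi_g <- pmax(colMeans(z), 1e-12); pi_g <- pi_g / sum(pi_g)

  trace <- numeric(0); converged <- FALSE; acc_all <- numeric(0)
  Smom <- vector("list", G)
  with_seed(control$seed, {
    for (it in seq_len(control$max_iter)) {
      lq <- matrix(0, N, G)
      for (g in seq_len(G)) {
        Smom[[g]] <- vector("list", N)
        for (n in seq_len(N)) {
          samp <- sample_theta_posterior(
            Ymats[[n]], offsets, comps[[g]],
            config = control, theta0 = theta_hat[[g]][[n]],
            keep_draws = control$rao_blackwell)
          theta_hat[[g]][[n]] <- samp$mean
          Smom[[g]][[n]] <- samp$S
          acc_all <- c(acc_all, samp$accept_rate)
          lq[n, g] <- if (control$rao_blackwell) {
            lvals <- apply(samp$draws, 1, function(v)
              logjoint_obs(Ymats[[n]], logs, inv_vec_transpose(v, r, p),
                           comps[[g]]))
            logsumexp(lvals) - log(length(lvals))
          } else logjoint_obs(Ymats[[n]], logs, samp$mean, comps[[g]])
        }
      }
      lw <- sweep(lq, 2, log(pi_g), "+")
      lse <- apply(lw, 1, logsumexp)
      z <- exp(lw - lse)
      proxy <- sum(lse)
      trace <- c(trace, proxy)
      if (control$verbose)
        message(sprintf("MCMC-EM iter %d: proxy %.4f", it, proxy))
      if (it > 2 &&
          abs(proxy - trace[it - 1]) / (abs(trace[it - 1]) + 1e-10) <
          control$tol) {
        converged <- TRUE
        break
      }
      ng <- colSums(z)
      if (any(ng < 1e-8))
        stop_numeric("degenerate component (effective size ~ 0)")
      pi_g <- ng / N
      comps <- lapply(seq_len(G), function(g)
        mcmc_mstep_component(z[, g], theta_hat[[g]], Smom[[g]],
                             comps[[g]]$Omega, r, p))
    }
  })

  comps <- lapply(comps, function(cm) {
    nf <- normalize_identifiability(cm$Phi, cm$Omega)
    list(M = cm$M, Phi = nf$Phi, Omega = nf$Omega)
  })
  loglik <- trace[length(trace)]
  K <- n_free_params(G, r, p, "mvpln")
  structure(list(method = "mcmc", G = G,
                 params = list(pi = pi_g, components = comps),
                 responsibilities = z, map_labels = map_classify(z),
                 elbo_trace = trace, loglik_proxy = loglik, K = K,
                 criteria = information_criteria(loglik, K, N, z),
                 converged = converged, n_iter = length(trace),
                 seed = control$seed, theta_hat = theta_hat,
                 diagnostics = list(accept_rate = mean(acc_all),
                                    W = control$W)),
            class = "mvpln_fit")
}

#' Control settings for the hybrid fit
#'
#' @param vga list from [vga_control()].
#' @param mcmc list from [mcmc_control()].
#' @param n_refine number of MCMC E-step / M-step refinement passes after
#'   the VGA fit (default 1).
#' @return A list of control settings.
#' @export
hybrid_control <- function(vga = vga_control(), mcmc = mcmc_control(),
                           n_refine = 1) {
  list(vga = vga, mcmc = mcmc, n_refine = n_refine)
}

#' Fit an MVPLN mixture by the hybrid VGA + MCMC approach
#'
#' Step 1 fits the model with [fit_vga()]; step 2 fixes hard memberships
#' from the VGA responsibilities; step 3 runs MCMC E-steps for the latent
#' log-rates conditional on those memberships, starting the chains at the
#' VGA variational means, and applies M-step(s) to obtain the final
#' parameter estimates. MAP labels are identical to the VGA labels by
#' construction; the criteria are computed from the plug-in classification
#' log-likelihood at the refined parameters.
#'
#' @param tensor a \code{count_tensor}.
#' @param offsets \code{r x p} positive offsets or \code{NULL} for ones.
#' @param G number of components.
#' @param control list from [hybrid_control()].
#' @return An object of class \code{mvpln_fit} (method \code{"hybrid"}).
#' @export
fit_hybrid <- function(tensor, offsets = NULL, G,
                       control = hybrid_control()) {
  d <- tensor_dims(tensor)
  offsets <- validate_offsets(offsets, tensor)
  control <- utils::modifyList(hybrid_control(), control)
  vfit <- fit_vga(tensor, offsets, G, control$vga)
  labels <- vfit$map_labels
  if (length(unique(labels)) < G)
    stop_numeric("hybrid refinement: VGA produced an empty MAP class")
  r <- d$r; p <- d$p
  logs <- log(offsets)
  Ymats <- lapply(seq_len(d$N), function(n)
    matrix(tensor$counts[n, , ], r, p))
  comps <- vfit$params$components
  pi_g <- tabulate(labels, G) / d$N
  acc_all <- numeric(0)
  theta_hat <- lapply(Ymats, function(Y) log((Y + 0.5) / offsets))
  with_seed(control$mcmc$seed, {
    for (pass in seq_len(control$n_refine)) {
      means <- vector("list", d$N); Ss <- vector("list", d$N)
      for (n in seq_len(d$N)) {
        g <- labels[n]
        th0 <- if (pass == 1) vfit$state[[g]]$xi[, , n] else theta_hat[[n]]
        if (r == 1 || p == 1) th0 <- matrix(th0, r, p)
        samp <- sample_theta_posterior(Ymats[[n]], offsets, comps[[g]],
                                       config = control$mcmc, theta0 = th0)
        means[[n]] <- samp$mean; Ss[[n]] <- samp$S
        acc_all <- c(acc_all, samp$accept_rate)
      }
      theta_hat <- means
      comps <- lapply(seq_len(G), function(g) {
        idx <- which(labels == g)
        mcmc_mstep_component(rep(1, length(idx)), means[idx], Ss[idx],
                             comps[[g]]$Omega, r, p)
      })
    }
  })
  loglik <- sum(vapply(seq_len(d$N), function(n)
    log(pi_g[labels[n]]) +
      logjoint_obs(Ymats[[n]], logs, theta_hat[[n]], comps[[labels[n]]]),
    0))
  comps <- lapply(comps, function(cm) {
    nf <- normalize_identifiability(cm$Phi, cm$Omega)
    list(M = cm$M, Phi = nf$Phi, Omega = nf$Omega)
  })
  K <- vfit$K
  structure(list(method = "hybrid", G = G,
                 params = list(pi = pi_g, components = comps),
                 responsibilities = vfit$responsibilities,
                 map_labels = labels,
                 elbo_trace = vfit$elbo_trace, loglik_proxy = loglik,
                 K = K,
                 criteria = information_criteria(loglik, K, d$N,
                                                 vfit$responsibilities),
                 converged = vfit$converged, n_iter = vfit$n_iter,
                 seed = control$vga$seed, vga_fit = vfit,
                 theta_hat = theta_hat,
                 diagnostics = list(accept_rate = mean(acc_all),
                                    W = control$mcmc$W)),
            class = "mvpln_fit")
}
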