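test_that("observation ELBO satisfies F = log f(Y) - KL by quadrature (1x1)", {
  cases <- expand.grid(Y = c(0, 1, 7), xi = c(-0.5, 0.4), sig = c(0.3, 1.2))
  for (i in seq_len(nrow(cases))) {
    Y <- matrix(cases$Y[i]); s <- matrix(1.3)
    xi <- matrix(cases$xi[i]); D <- matrix(cases$sig[i]); K <- matrix(0.8)
    M <- matrix(0.1); Phi <- matrix(1.4); Om <- matrix(0.7)
    F <- elbo_observation(Y, s, xi, D, K, M, Phi, Om)
    or <- quad_1x1(Y[1], s[1], M[1], Phi[1] * Om[1])
    kl <- quad_kl_1x1(Y[1], s[1], M[1], Phi[1] * Om[1], xi[1], D[1] * K[1])
    expect_equal(F, or$logmarg - kl, tolerance = 1e-6)
    # lower-bound property
    expect_lte(F, or$logmarg + 1e-10)
  }
})

test_that("observation ELBO is invariant under (c Delta, kappa / c)", {
  cmp <- toy_component(2, 3, seed = 31)
  Y <- with_seed_test(1, matrix(rpois(6, 15), 2, 3))
  s <- ones_rp(2, 3)
  xi <- log(Y + 0.5)
  D <- random_spd(2, c(0.2, 1), seed = 7)
  K <- random_spd(3, c(0.2, 1), seed = 8)
  f0 <- elbo_observation(Y, s, xi, D, K, cmp$M, cmp$Phi, cmp$Omega)
  for (c_ in c(0.2, 3, 17)) {
    expect_equal(elbo_observation(Y, s, xi, c_ * D, K / c_, cmp$M, cmp$Phi,
                                  cmp$Omega), f0, tolerance = 1e-10)
  }
})

test_that("coordinate updates are ELBO-stationary at their fixed points", {
  for (seed in 1:3) {
    cmp <- toy_component(2, 3, seed = 100 + seed)
    Y <- with_seed_test(seed, matrix(rpois(6, 30), 2, 3))
    s <- matrix(c(0.9, 1, 1.1, 1, 1.2, 0.8), 2, 3)
    st <- converge_obs(Y, s, log(Y + 0.5), diag(0.1, 2), diag(0.1, 3),
                       cmp$M, cmp$Phi, cmp$Omega)
    gD <- num_grad_sym("Delta", Y, s, st$xi, st$Delta, st$kappa,
                       cmp$M, cmp$Phi, cmp$Omega)
    gK <- num_grad_sym("kappa", Y, s, st$xi, st$Delta, st$kappa,
                       cmp$M, cmp$Phi, cmp$Omega)
    gx <- num_grad_xi(Y, s, st$xi, st$Delta, st$kappa, cmp$M, cmp$Phi,
                      cmp$Omega)
    expect_lt(max(abs(gD)), 1e-5)
    expect_lt(max(abs(gK)), 1e-5)
    expect_lt(max(abs(gx)), 1e-5)
    expect_true(is_spd(st$Delta))
    expect_true(is_spd(st$kappa))
  }
})

test_that("coordinate updates never decrease the observation ELBO", {
  for (seed in 1:10) {
    cmp <- toy_component(2, 3, seed = 300 + seed)
    Y <- with_seed_test(seed, matrix(rpois(6, exp(runif(6, 1, 4))), 2, 3))
    s <- ones_rp(2, 3)
    xi <- with_seed_test(seed + 1, log(Y + 0.5) + matrix(rnorm(6, 0, 0.3),
                                                         2, 3))
    D <- random_spd(2, c(0.05, 0.8), seed = seed)
    K <- random_spd(3, c(0.05, 0.8), seed = seed + 20)
    f0 <- elbo_observation(Y, s, xi, D, K, cmp$M, cmp$Phi, cmp$Omega)
    D1 <- update_delta(Y, s, xi, D, K, cmp$M, cmp$Phi, cmp$Omega)
    f1 <- elbo_observation(Y, s, xi, D1, K, cmp$M, cmp$Phi, cmp$Omega)
    expect_gte(f1, f0 - 1e-8)
    K1 <- update_kappa(Y, s, xi, D1, K, cmp$M, cmp$Phi, cmp$Omega)
    f2 <- elbo_observation(Y, s, xi, D1, K1, cmp$M, cmp$Phi, cmp$Omega)
    expect_gte(f2, f1 - 1e-8)
    x1 <- update_xi(Y, s, xi, D1, K1, cmp$M, cmp$Phi, cmp$Omega)
    f3 <- elbo_observation(Y, s, x1, D1, K1, cmp$M, cmp$Phi, cmp$Omega)
    expect_gte(f3, f2 - 1e-10)
  }
})

test_that("1x1 updates match direct scalar ELBO maximization", {
  Y <- matrix(3); s <- matrix(1)
  M <- matrix(0.2); Phi <- matrix(1.1); Om <- matrix(0.9)
  st <- converge_obs(Y, s, matrix(0), matrix(0.5), matrix(1), M, Phi, Om)
  # direct 2-D optimization over (xi, log sig2); kappa fixed at the
  # converged value exploits the (c Delta, kappa / c) flat direction
  obj <- function(par) -elbo_observation(Y, s, matrix(par[1]),
                                         matrix(exp(par[2])), st$kappa,
                                         M, Phi, Om)
  opt <- optim(c(0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(st$xi[1], opt$par[1], tolerance = 1e-3)
  expect_equal(st$Delta[1] * st$kappa[1], exp(opt$par[2]) * st$kappa[1],
               tolerance = 1e-3)
  # zero count with zero prior mean shrinks xi below 0
  st0 <- converge_obs(matrix(0), s, matrix(0), matrix(0.5), matrix(1),
                      matrix(0), matrix(1), matrix(1))
  expect_lt(st0$xi[1], 0)
})

test_that("converged xi approaches log(Y/s) under a weak prior", {
  Y <- matrix(c(120, 300, 80, 50, 600, 40), 2, 3)
  s <- matrix(c(1, 2, 0.5, 1, 1, 1), 2, 3)
  M <- matrix(0, 2, 3)
  st <- converge_obs(Y, s, log(Y + 0.5), diag(0.01, 2), diag(0.01, 3),
                     M, diag(100, 2), diag(100, 3))
  expect_equal(as.vector(st$xi), as.vector(log(Y / s)), tolerance = 1e-3)
})

test_that("responsibilities are a numerically safe softmax", {
  expect_equal(responsibilities_from_elbo(1, matrix(-5, 4, 1)),
               matrix(1, 4, 1))
  z <- responsibilities_from_elbo(c(0.5, 0.5), matrix(-1000, 3, 2))
  expect_equal(z, matrix(0.5, 3, 2))
  z2 <- responsibilities_from_elbo(c(0.5, 0.5),
                                   matrix(c(-1000, -1001), 1))
  expect_equal(as.vector(z2), c(plogis(1), plogis(-1)), tolerance = 1e-4)
  expect_equal(rowSums(z2), 1, tolerance = 1e-12)
})

test_that("one M-step recovers parameters from true latent states", {
  des <- build_sim_design("sim2", seed = 17)
  des$N <- 5000L
  dat <- simulate_mvpln_mixture(des, seed = 18)
  d <- dim(dat$tensor$counts)
  z <- matrix(0, d[1], 2)
  z[cbind(seq_len(d[1]), dat$labels)] <- 1
  # feed the true thetas as variational means with vanishing covariances
  state <- lapply(1:2, function(g)
    list(xi = dat$thetas,
         Delta = array(diag(1e-12, 2), c(2, 2, d[1])),
         kappa = array(diag(1e-12, 3), c(3, 3, d[1]))))
  old <- list(pi = c(0.5, 0.5),
              components = lapply(des$components, function(cm)
                list(M = cm$M * 0, Phi = diag(2), Omega = diag(3))))
  up <- mstep(dat$tensor, NULL, z, state, old)
  expect_equal(up$pi[1], 0.79, tolerance = 0.05)
  for (g in 1:2) {
    truth <- des$components[[g]]
    expect_equal(up$components[[g]]$M, truth$M, tolerance = 0.05)
    expect_lt(max(abs(kronecker(up$components[[g]]$Phi,
                                up$components[[g]]$Omega) -
                      kronecker(truth$Phi, truth$Omega))), 0.12)
  }
  # hard z, constant xi within component, vanishing Delta/kappa: M is the
  # component mean of xi
  stc <- lapply(1:2, function(g) {
    xi <- dat$thetas
    for (n in seq_len(d[1])) xi[, , n] <- des$components[[g]]$M
    list(xi = xi, Delta = array(diag(1e-12, 2), c(2, 2, d[1])),
         kappa = array(diag(1e-12, 3), c(3, 3, d[1])))
  })
  upc <- suppressWarnings(mstep(dat$tensor, NULL, z, stc, old))
  expect_equal(upc$components[[1]]$M, des$components[[1]]$M,
               tolerance = 1e-8)
  # degenerate component errors
  expect_error(mstep(dat$tensor, NULL, z * 0, state, old),
               class = "mvpln_numeric_error")
})

test_that("rank-deficient M-step scatter takes the jitter path with warning", {
  # two observations whose xi differ along a single row direction with
  # Delta = kappa = 0: the Phi scatter is rank one
  ct <- count_tensor(array(5L, c(2, 2, 3)))
  xi <- array(0, c(2, 3, 2))
  xi[1, , 2] <- c(1, 2, 3)   # second unit shifted in row 1 only
  state <- list(list(xi = xi, Delta = array(0, c(2, 2, 2)),
                     kappa = array(0, c(3, 3, 2))))
  old <- list(pi = 1, components = list(list(M = matrix(0, 2, 3),
                                             Phi = diag(2),
                                             Omega = diag(3))))
  w <- capture_warnings(res <- mstep(ct, NULL, matrix(1, 2, 1), state, old))
  expect_true(any(grepl("near-singular", w)))
  expect_true(is_spd(res$components[[1]]$Phi))
  expect_true(is_spd(res$components[[1]]$Omega))
})

test_that("k-means initialization separates, degenerates and reproduces", {
  dat <- small_sim2(seed = 23, scale = 0.15)
  z <- init_kmeans(dat$tensor, 2, n_runs = 20, seed = 3)
  expect_equal(adjusted_rand_index(map_classify(z), dat$labels), 1)
  z1 <- init_kmeans(dat$tensor, 1, seed = 3)
  expect_equal(as.vector(z1), rep(1, nrow(z1)))
  expect_identical(init_kmeans(dat$tensor, 3, n_runs = 10, seed = 5),
                   init_kmeans(dat$tensor, 3, n_runs = 10, seed = 5))
  tiny <- count_tensor(array(1L, c(2, 1, 2)))
  expect_error(init_kmeans(tiny, 5), class = "mvpln_validation_error")
})

test_that("fit_vga clusters sim2-style data perfectly and is well-formed", {
  dat <- small_sim2(seed = 29, scale = 0.25)
  fit <- fit_vga(dat$tensor, G = 2, control = vga_control(seed = 1))
  expect_s3_class(fit, "mvpln_fit")
  expect_equal(adjusted_rand_index(fit$map_labels, dat$labels), 1)
  # monotone ELBO trace (1e-6 relative slack)
  dtr <- diff(fit$elbo_trace)
  expect_true(all(dtr > -1e-6 * abs(fit$elbo_trace[-length(fit$elbo_trace)])))
  # responsibilities valid, labels = row argmax, no NaN anywhere
  expect_equal(rowSums(fit$responsibilities), rep(1, nrow(fit$responsibilities)),
               tolerance = 1e-12)
  expect_identical(fit$map_labels, map_classify(fit$responsibilities))
  expect_false(anyNA(fit$responsibilities))
  expect_true(all(is.finite(fit$elbo_trace)))
  # identifiability constraint applied
  for (cm in fit$params$components) expect_equal(cm$Phi[1, 1], 1)
  expect_identical(fit$K, n_free_params(2, 2, 3, "mvpln"))
  # determinism
  fit2 <- fit_vga(dat$tensor, G = 2, control = vga_control(seed = 1))
  expect_identical(fit$map_labels, fit2$map_labels)
  expect_equal(fit$loglik_proxy, fit2$loglik_proxy, tolerance = 1e-12)
})

test_that("fit_vga with G = 1 has no mixture dynamics and stays monotone", {
  des <- build_sim_design("sim1", seed = 41, scale = 0.1)
  dat <- simulate_mvpln_mixture(des)
  fit <- fit_vga(dat$tensor, G = 1, control = vga_control(seed = 1))
  expect_identical(fit$params$pi, 1)
  expect_true(all(fit$responsibilities == 1))
  expect_true(all(diff(fit$elbo_trace) > -1e-6 * abs(fit$elbo_trace[-1])))
})

test_that("fit_vga recovers sim2 parameters within sampling error", {
  # mean estimated pi_1 over seeds within 3 MC SE of 0.79
  pis <- c(); Merr <- c()
  n_seeds <- 6
  for (seed in seq_len(n_seeds)) {
    des <- build_sim_design("sim2", seed = 50, scale = 0.5)
    dat <- simulate_mvpln_mixture(des, seed = 60 + seed)
    fit <- fit_vga(dat$tensor, G = 2, control = vga_control(seed = 1))
    pis <- c(pis, max(fit$params$pi))
  }
  se <- sqrt(0.79 * 0.21 / (500 * n_seeds))
  expect_lt(abs(mean(pis) - 0.79), 3 * se + 0.01)
})
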