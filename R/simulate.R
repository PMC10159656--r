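# Synthetic three-way count data: MVPLN mixtures, independent Poisson and
# negative binomial competitor mixtures, random SPD covariance factors, and
# the six benchmark simulation designs.

#' Random symmetric positive-definite matrix
#'
#' Eigenvalues are sampled uniformly in \code{eig_range} and rotated by a
#' random orthogonal basis, so the condition number is bounded by
#' \code{max(eig_range) / min(eig_range)}. With \code{diagonal_only = TRUE} a
#' diagonal positive matrix is returned (off-diagonals exactly zero).
#'
#' @param dim matrix dimension, >= 1.
#' @param eig_range length-2 positive vector of eigenvalue bounds; the
#'   default \code{c(1, 3)} gives moderate correlation strength.
#' @param diagonal_only if \code{TRUE}, return a diagonal matrix.
#' @param seed optional integer seed; \code{NULL} uses the current RNG
#'   stream.
#' @return A \code{dim x dim} SPD matrix.
#' @export
random_spd <- function(dim, eig_range = c(1, 3), diagonal_only = FALSE,
                       seed = NULL) {
  if (dim < 1) stop_validation("dim must be >= 1")
  if (any(eig_range <= 0) || eig_range[2] < eig_range[1])
    stop_validation("eig_range must be positive and increasing")
  with_seed(seed, {
    ev <- stats::runif(dim, eig_range[1], eig_range[2])
    if (diagonal_only || dim == 1) return(diag(ev, dim))
    qr_ <- qr(matrix(stats::rnorm(dim * dim), dim))
    Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))), dim)
    A <- Q %*% diag(ev, dim) %*% t(Q)
    (A + t(A)) / 2
  })
}

# Sequentially draw G mean matrices with cells uniform on log_range,
# accepting each candidate only if its Euclidean (log-scale) distance to
# every previous mean is >= d_min.
draw_separated_means <- function(G, r, p, log_range, d_min) {
  means <- vector("list", G)
  for (g in seq_len(G)) {
    ok <- FALSE
    for (try in seq_len(20000L)) {
      cand <- matrix(stats::runif(r * p, log_range[1], log_range[2]), r, p)
      if (g == 1 || all(vapply(means[seq_len(g - 1)], function(m)
        sqrt(sum((m - cand)^2)), 0) >= d_min)) {
        means[[g]] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop_numeric("could not place ", G,
                          " component means at separation ", d_min)
  }
  means
}

# Per-design generator settings for the six benchmark designs. Mean matrices
# live in log-space [log 10, log 500] (counts roughly 10..500, RNA-seq-like);
# multi-component designs enforce a minimum mean separation of 3 log units;
# covariance factors have eigenvalues in [0.25, 0.75] (within-cluster
# biological-scale log variance). See the methods vignette for rationale.
.design_mean_log_range <- c(log(10), log(500))
.design_min_sep <- 3.0
.design_cov_eig <- c(0.25, 0.75)

#' Build one of the six benchmark simulation designs
#'
#' Returns a fully specified generator for the named design: sim1 (MVPLN,
#' G = 1, N = 1000), sim2 (MVPLN, G = 2, pi1 = 0.79, N = 1000), sim3 (MVPLN,
#' G = 2, pi1 = 0.6, N = 1000, diagonal covariance factors), sim4
#' (independent Poisson mixture, G = 2, pi1 = 0.45, N = 1000, six cells
#' analyzed as 2 x 3), sim5 (independent negative binomial mixture, G = 2,
#' pi1 = 0.79, N = 2000), sim6 (MVPLN, G = 8, equal proportions,
#' N = 1500). Component parameters are drawn reproducibly from \code{seed}.
#'
#' @param which design name, one of \code{"sim1"} .. \code{"sim6"}.
#' @param seed integer seed controlling the component parameter draws.
#' @param scale factor in (0, 1] applied to N (replicate counts are scaled
#'   by callers such as [make_fixtures()]).
#' @return An object of class \code{sim_design}: a list with \code{name},
#'   \code{N}, \code{r}, \code{p}, \code{G}, \code{pi}, \code{family},
#'   \code{components}, \code{seed}.
#' @export
build_sim_design <- function(which = c("sim1", "sim2", "sim3", "sim4",
                                       "sim5", "sim6"),
                             seed = 1, scale = 1) {
  which <- match.arg(which)
  if (scale <= 0 || scale > 1) stop_validation("scale must be in (0, 1]")
  spec <- switch(which,
    sim1 = list(N = 1000, G = 1, pi = 1, family = "mvpln", diag = FALSE),
    sim2 = list(N = 1000, G = 2, pi = c(0.79, 0.21), family = "mvpln",
                diag = FALSE),
    sim3 = list(N = 1000, G = 2, pi = c(0.6, 0.4), family = "mvpln",
                diag = TRUE),
    sim4 = list(N = 1000, G = 2, pi = c(0.45, 0.55),
                family = "indep_poisson", diag = FALSE),
    sim5 = list(N = 2000, G = 2, pi = c(0.79, 0.21),
                family = "indep_negbin", diag = FALSE),
    sim6 = list(N = 1500, G = 8, pi = rep(0.125, 8), family = "mvpln",
                diag = FALSE))
  r <- 2L; p <- 3L
  comps <- with_seed(seed, {
    means <- draw_separated_means(spec$G, r, p, .design_mean_log_range,
                                  if (spec$G > 1) .design_min_sep else 0)
    lapply(seq_len(spec$G), function(g) {
      if (spec$family == "mvpln") {
        Phi <- random_spd(r, .design_cov_eig, diagonal_only = spec$diag)
        Omega <- random_spd(p, .design_cov_eig, diagonal_only = spec$diag)
        nf <- normalize_identifiability(Phi, Omega)
        list(M = means[[g]], Phi = nf$Phi, Omega = nf$Omega)
      } else if (spec$family == "indep_poisson") {
        list(lambda = exp(means[[g]]))
      } else {
        list(mu = exp(means[[g]]),
             size = matrix(stats::runif(r * p, 2, 10), r, p))
      }
    })
  })
  structure(list(name = which,
                 N = as.integer(max(spec$G, round(spec$N * scale))),
                 r = r, p = p, G = as.integer(spec$G), pi = spec$pi,
                 family = spec$family, components = comps, seed = seed),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("sim_design '%s': family %s, N = %d, r = %d, p = %d, G = %d\n",
              x$name, x$family, x$N, x$r, x$p, x$G))
  cat("pi:", paste(signif(x$pi, 3), collapse = ", "), "\n")
  invisible(x)
}

validate_design <- function(design, family) {
  if (!inherits(design, "sim_design")) stop_validation("not a sim_design")
  if (!design$family %in% family)
    stop_validation("design family must be one of: ",
                    paste(family, collapse = ", "))
  if (abs(sum(design$pi) - 1) > 1e-8)
    stop_validation("mixing proportions must sum to 1")
  if (design$N < design$G) stop_validation("N must be >= G")
  invisible(design)
}

#' Simulate from an MVPLN mixture
#'
#' For each unit a component is drawn from the mixing proportions, a latent
#' log-rate matrix theta from the component's matrix-variate normal (via
#' \code{M + A Z B} with \code{A A' = Phi}, \code{B' B = Omega}, \code{Z}
#' iid standard normal), and each count from
#' \code{Poisson(exp(theta + log s))}.
#'
#' @param design a \code{sim_design} with \code{family = "mvpln"}.
#' @param offsets optional \code{r x p} positive offset matrix (default all
#'   ones, so closed-form moments apply directly).
#' @param seed integer seed (defaults to the design's seed).
#' @return A \code{labeled_dataset}: list with \code{tensor},
#'   \code{offsets}, \code{labels} (true components), \code{thetas}
#'   (\code{r x p x N} latent draws) and \code{design}.
#' @export
simulate_mvpln_mixture <- function(design, offsets = NULL,
                                   seed = design$seed) {
  validate_design(design, "mvpln")
  N <- design$N; r <- design$r; p <- design$p
  if (is.null(offsets)) offsets <- matrix(1, r, p)
  if (!all(dim(offsets) == c(r, p)) || any(offsets <= 0))
    stop_validation("offsets must be a positive r x p matrix")
  logs <- log(offsets)
  with_seed(seed, {
    labels <- sample.int(design$G, N, replace = TRUE, prob = design$pi)
    chA <- lapply(design$components, function(cm) t(chol(cm$Phi)))
    chB <- lapply(design$components, function(cm) chol(cm$Omega))
    thetas <- array(0, c(r, p, N))
    counts <- array(0L, c(N, r, p))
    for (n in seq_len(N)) {
      g <- labels[n]
      Z <- matrix(stats::rnorm(r * p), r, p)
      th <- design$components[[g]]$M + chA[[g]] %*% Z %*% chB[[g]]
      thetas[, , n] <- th
      counts[n, , ] <- stats::rpois(r * p, exp(th + logs))
    }
    structure(list(tensor = count_tensor(counts), offsets = offsets,
                   labels = labels, thetas = thetas, design = design),
              class = "labeled_dataset")
  })
}

#' Simulate from an independent Poisson or negative binomial mixture
#'
#' Competitor generators: counts are drawn independently per cell from the
#' stated univariate family (cell-wise rates, plus size parameters for the
#' negative binomial) and arranged as \code{r x p} matrices. Offsets are all
#' ones.
#'
#' @param design a \code{sim_design} with family \code{"indep_poisson"} or
#'   \code{"indep_negbin"}.
#' @param seed integer seed (defaults to the design's seed).
#' @return A \code{labeled_dataset} (without latent \code{thetas}).
#' @export
simulate_competitor_mixture <- function(design, seed = design$seed) {
  validate_design(design, c("indep_poisson", "indep_negbin"))
  N <- design$N; r <- design$r; p <- design$p
  for (cm in design$components) {
    if (design$family == "indep_poisson" && any(cm$lambda <= 0))
      stop_validation("Poisson rates must be positive")
    if (design$family == "indep_negbin" &&
        (any(cm$mu <= 0) || any(cm$size <= 0)))
      stop_validation("negative binomial means and dispersions must be positive")
  }
  with_seed(seed, {
    labels <- sample.int(design$G, N, replace = TRUE, prob = design$pi)
    counts <- array(0L, c(N, r, p))
    for (n in seq_len(N)) {
      cm <- design$components[[labels[n]]]
      counts[n, , ] <- if (design$family == "indep_poisson")
        stats::rpois(r * p, cm$lambda)
      else stats::rnbinom(r * p, mu = cm$mu, size = cm$size)
    }
    structure(list(tensor = count_tensor(counts),
                   offsets = matrix(1, r, p), labels = labels,
                   thetas = NULL, design = design),
              class = "labeled_dataset")
  })
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %s design '%s', N = %d, G = %d\n",
              x$design$family, x$design$name, x$design$N, x$design$G))
  print(table(labels = x$labels))
  invisible(x)
}
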