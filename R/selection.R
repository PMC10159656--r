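# Information criteria, MAP classification, adjusted Rand index, and the
# G-sweep model-selection driver.

#' Information criteria for a fitted mixture
#'
#' Computes \code{AIC = -2 loglik + 2K}, \code{AIC3 = -2 loglik + 3K},
#' \code{BIC = 2 loglik - K log N} and
#' \code{ICL = BIC + 2 sum_n sum_g MAP(z_ng) log z_ng}, where \code{MAP(.)}
#' is the one-hot maximum a posteriori indicator. The values are stored
#' exactly in these printed forms: AIC and AIC3 are minimize-form, BIC and
#' ICL are maximize-form (see \code{attr(, "direction")}). ICL <= BIC
#' always, with equality iff the responsibilities are hard.
#'
#' @param loglik maximized log-likelihood (or its surrogate: the converged
#'   aggregate ELBO for VGA fits, the plug-in log-likelihood for MCMC fits).
#' @param K number of free parameters.
#' @param N number of observations.
#' @param z \code{N x G} responsibility matrix.
#' @return Named numeric vector with elements AIC, BIC, AIC3, ICL and a
#'   \code{direction} attribute.
#' @export
information_criteria <- function(loglik, K, N, z) {
  if (N < 1) stop_validation("N must be >= 1")
  if (K < 0) stop_validation("K must be >= 0")
  z <- as.matrix(z)
  map <- map_classify(z)
  zmap <- z[cbind(seq_len(nrow(z)), map)]
  ent <- sum(ifelse(zmap > 0, log(zmap), 0))
  bic <- 2 * loglik - K * log(N)
  out <- c(AIC = -2 * loglik + 2 * K,
           BIC = bic,
           AIC3 = -2 * loglik + 3 * K,
           ICL = bic + 2 * ent)
  attr(out, "direction") <- c(AIC = "min", BIC = "max", AIC3 = "min",
                              ICL = "max")
  out
}

#' Maximum a posteriori classification
#'
#' Row-argmax of the responsibility matrix; ties are broken toward the
#' lowest component index.
#'
#' @param z \code{N x G} responsibility matrix.
#' @return Integer vector of labels in \code{1..G}.
#' @export
map_classify <- function(z) {
  z <- as.matrix(z)
  max.col(z, ties.method = "first")
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions, from
#' the contingency table. Equals 1 for identical partitions (up to
#' relabeling) and has expected value 0 under independent random labeling.
#' When the adjustment denominator is zero (e.g. both partitions are the
#' single-cluster partition) the partitions coincide and 1 is returned.
#'
#' @param a,b label vectors of equal length (>= 2).
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_validation("label vectors differ in length")
  if (length(a) < 2) stop_validation("need at least 2 items")
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

#' Fit a range of G and select by information criteria
#'
#' Fits every G in \code{G_range} with the chosen method under a shared
#' seeding policy, collects all four criteria, and reports the winning G
#' per criterion (minimum for AIC/AIC3, maximum for BIC/ICL; ties resolved
#' toward smaller G). A fit that fails is recorded and excluded without
#' aborting the sweep.
#'
#' @param tensor a \code{count_tensor}.
#' @param offsets \code{r x p} positive offsets or \code{NULL} for ones.
#' @param G_range integer vector of component counts to fit.
#' @param method \code{"vga"}, \code{"mcmc"} or \code{"hybrid"}.
#' @param control control list for the chosen method.
#' @return A list with \code{report} (one row per fitted G: criteria, K,
#'   loglik proxy), \code{fits} (every successful fit, named by G),
#'   \code{best} (named list: the winning G per criterion), \code{errors}
#'   (messages for failed G).
#' @examples
#' \donttest{
#' dat <- simulate_mvpln_mixture(build_sim_design("sim2", scale = 0.2))
#' sel <- select_model(dat$tensor, G_range = 1:3)
#' sel$best$BIC
#' }
#' @export
select_model <- function(tensor, offsets = NULL, G_range,
                         method = c("vga", "mcmc", "hybrid"),
                         control = NULL) {
  method <- match.arg(method)
  G_range <- sort(unique(as.integer(G_range)))
  if (!length(G_range)) stop_validation("G_range must be non-empty")
  if (is.null(control))
    control <- switch(method, vga = vga_control(), mcmc = mcmc_control(),
                      hybrid = hybrid_control())
  fits <- list(); errors <- list()
  for (G in G_range) {
    fit <- tryCatch(
      switch(method,
             vga = fit_vga(tensor, offsets, G, control),
             mcmc = fit_mcmc_em(tensor, offsets, G, control),
             hybrid = fit_hybrid(tensor, offsets, G, control)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      errors[[as.character(G)]] <- conditionMessage(fit)
    } else {
      fits[[as.character(G)]] <- fit
    }
  }
  if (!length(fits)) stop_numeric("all fits in the G sweep failed")
  report <- do.call(rbind, lapply(fits, function(f)
    data.frame(G = f$G, K = f$K, loglik_proxy = f$loglik_proxy,
               AIC = f$criteria[["AIC"]], BIC = f$criteria[["BIC"]],
               AIC3 = f$criteria[["AIC3"]], ICL = f$criteria[["ICL"]],
               converged = f$converged)))
  rownames(report) <- NULL
  pick <- function(values, dir) {
    # ties toward smaller G; report is ordered by increasing G
    idx <- if (dir == "min") which(values == min(values))
    else which(values == max(values))
    report$G[idx[1]]
  }
  best <- list(AIC = pick(report$AIC, "min"),
               BIC = pick(report$BIC, "max"),
               AIC3 = pick(report$AIC3, "min"),
               ICL = pick(report$ICL, "max"))
  structure(list(report = report, fits = fits, best = best,
                 errors = errors, method = method),
            class = "mvpln_selection")
}

#' @export
print.mvpln_selection <- function(x, ...) {
  cat(sprintf("mvpln_selection (%s): %d fits\n", x$method,
              nrow(x$report)))
  print(x$report, row.names = FALSE)
  cat("chosen G -> AIC:", x$best$AIC, "| BIC:", x$best$BIC,
      "| AIC3:", x$best$AIC3, "| ICL:", x$best$ICL, "\n")
  if (length(x$errors))
    cat("failed G:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
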