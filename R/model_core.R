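# MVPLN data model: vectorization convention, matrix-variate normal density,
# closed-form moments, free-parameter counts, identifiability normalization,
# complete-data log-likelihood.

#' Row-major vectorization (vec of the transpose)
#'
#' Places element \code{(i, k)} of an \code{r x p} matrix at position
#' \code{(i - 1) * p + k}. Under this convention the covariance of the
#' vectorized matrix-variate normal is the Kronecker product
#' \code{Phi \%x\% Omega}.
#'
#' @param X an \code{r x p} matrix.
#' @return A numeric vector of length \code{r * p}.
#' @seealso [inv_vec_transpose()]
#' @export
vec_transpose <- function(X) {
  if (!is.matrix(X)) stop_validation("X must be a matrix")
  as.vector(t(X))
}

#' Inverse of the row-major vectorization
#'
#' @param v numeric vector of length \code{r * p}.
#' @param r,p target dimensions.
#' @return The \code{r x p} matrix with \code{vec_transpose(out) == v}.
#' @export
inv_vec_transpose <- function(v, r, p) {
  if (length(v) != r * p) stop_validation("length(v) must equal r * p")
  matrix(v, nrow = r, ncol = p, byrow = TRUE)
}

#' Matrix-variate normal log density
#'
#' Density of an \code{r x p} matrix \code{X} with mean matrix \code{M}, row
#' (occasion) covariance \code{Phi} and column (variable) covariance
#' \code{Omega}. Equals the \code{rp}-dimensional multivariate normal log
#' density of \code{vec_transpose(X)} with mean \code{vec_transpose(M)} and
#' covariance \code{Phi \%x\% Omega}; computed via separate Cholesky factors,
#' never forming the Kronecker product.
#'
#' @param X,M \code{r x p} matrices.
#' @param Phi \code{r x r} symmetric positive-definite matrix.
#' @param Omega \code{p x p} symmetric positive-definite matrix.
#' @param log if \code{TRUE} (default) return the log density.
#' @return A scalar (log) density.
#' @export
dmatnorm <- function(X, M, Phi, Omega, log = TRUE) {
  r <- nrow(X); p <- ncol(X)
  if (!identical(dim(M), dim(X)))
    stop_validation("M must have the same dimensions as X")
  Phi <- ensure_spd(Phi, "Phi"); Omega <- ensure_spd(Omega, "Omega")
  cP <- chol(Phi); cO <- chol(Omega)
  ldPhi <- 2 * sum(log(diag(cP))); ldOmega <- 2 * sum(log(diag(cO)))
  # tr(Phi^-1 X0 Omega^-1 X0^T) with X0 = X - M via triangular solves
  X0 <- X - M
  A <- backsolve(cP, X0, transpose = TRUE)     # cP^-T X0
  B <- backsolve(cO, t(A), transpose = TRUE)   # cO^-T X0^T cP^-1
  quad <- sum(B * B)
  out <- -0.5 * r * p * log(2 * pi) - 0.5 * p * ldPhi - 0.5 * r * ldOmega -
    0.5 * quad
  if (log) out else exp(out)
}

#' Unconditional moments of the MVPLN distribution
#'
#' With latent log-rates theta ~ matrix-normal(M, Phi, Omega) and counts
#' conditionally Poisson(exp(theta)) (unit offsets), each cell has
#' mean \code{m_ik = exp(M_ik + Phi_ii Omega_kk / 2)} and variance
#' \code{m_ik + m_ik^2 (exp(Phi_ii Omega_kk) - 1)}: counts are overdispersed
#' whenever the latent variance is positive.
#'
#' @param M \code{r x p} latent mean matrix.
#' @param Phi,Omega SPD covariance factors.
#' @return A list with \code{r x p} matrices \code{mean} and \code{variance}.
#' @export
mvpln_moments <- function(M, Phi, Omega) {
  Phi <- ensure_spd(Phi, "Phi"); Omega <- ensure_spd(Omega, "Omega")
  v <- outer(diag(Phi), diag(Omega))
  m <- exp(M + v / 2)
  list(mean = m, variance = m + m^2 * (exp(v) - 1))
}

#' Number of free parameters of the mixture model
#'
#' For a G-component mixture on \code{r x p} matrices the matrix-variate
#' (Kronecker-structured) model has
#' \code{K = (G - 1) + G r p + G [r (r + 1) + p (p + 1)] / 2} free
#' parameters, against \code{(G - 1) + G r p + G rp (rp + 1) / 2} for the
#' unstructured vectorized (MPLN) model.
#'
#' @param G,r,p positive integers.
#' @param family \code{"mvpln"} (Kronecker-structured covariance) or
#'   \code{"mpln"} (unstructured \code{rp x rp} covariance).
#' @return Integer count of free parameters.
#' @export
n_free_params <- function(G, r, p, family = c("mvpln", "mpln")) {
  family <- match.arg(family)
  if (any(c(G, r, p) < 1) || any(c(G, r, p) != round(c(G, r, p))))
    stop_validation("G, r, p must be positive integers")
  base <- (G - 1) + G * r * p
  if (family == "mvpln") base + G * (r * (r + 1) + p * (p + 1)) / 2
  else base + G * (r * p) * (r * p + 1) / 2
}

#' Identifiability normalization of the covariance factors
#'
#' \code{Phi} and \code{Omega} are only identified up to a reciprocal positive
#' scaling; the constraint adopted here fixes the first diagonal element of
#' \code{Phi} to 1 by dividing \code{Phi} and multiplying \code{Omega} by
#' \code{Phi[1, 1]}. The Kronecker product \code{Phi \%x\% Omega} is exactly
#' preserved.
#'
#' @param Phi,Omega SPD covariance factors.
#' @return A list with normalized \code{Phi} and \code{Omega}.
#' @export
normalize_identifiability <- function(Phi, Omega) {
  if (!is.matrix(Phi) || Phi[1, 1] <= 0)
    stop_numeric("Phi[1, 1] must be strictly positive")
  c1 <- Phi[1, 1]
  list(Phi = Phi / c1, Omega = Omega * c1)
}

#' Complete-data log-likelihood of the MVPLN mixture
#'
#' Evaluates the complete-data log-likelihood at given (hard or soft)
#' memberships \code{z} and latent log-rate matrices: mixing-proportion term,
#' conditional Poisson terms with offsets, log-factorial term, and the
#' matrix-variate normal terms with their trace quadratic form. Invariant
#' under [normalize_identifiability()] of any component.
#'
#' @param tensor a \code{count_tensor}.
#' @param offsets \code{r x p} positive matrix (or \code{NULL} for ones).
#' @param params mixture parameters: a list with \code{pi} (length-G vector)
#'   and \code{components}, a G-list of lists with \code{M}, \code{Phi},
#'   \code{Omega}.
#' @param z \code{N x G} membership matrix; rows must sum to 1.
#' @param thetas latent log-rates: either an \code{r x p x N} array (shared
#'   across components, e.g. the true draws) or a G-list of such arrays (one
#'   latent matrix per unit and component).
#' @return The scalar complete-data log-likelihood.
#' @export
complete_data_loglik <- function(tensor, offsets, params, z, thetas) {
  d <- tensor_dims(tensor)
  offsets <- validate_offsets(offsets, tensor)
  G <- length(params$pi)
  if (!is.matrix(z) || nrow(z) != d$N || ncol(z) != G)
    stop_validation("z must be an N x G matrix")
  if (max(abs(rowSums(z) - 1)) > 1e-8)
    stop_validation("rows of z must sum to 1")
  shared <- !is.list(thetas)
  if (shared && !identical(dim(thetas), c(d$r, d$p, d$N)))
    stop_validation("thetas array must have dimensions r x p x N")
  logs <- log(offsets)
  ll <- sum(colSums(z) * log(params$pi))
  for (g in seq_len(G)) {
    cmp <- params$components[[g]]
    th_g <- if (shared) thetas else thetas[[g]]
    for (n in seq_len(d$N)) {
      w <- z[n, g]
      if (w == 0) next
      th <- th_g[, , n, drop = TRUE]
      if (d$r == 1 || d$p == 1) th <- matrix(th, d$r, d$p)
      Y <- matrix(tensor$counts[n, , ], d$r, d$p)
      pois <- sum(-exp(th + logs) + (th + logs) * Y - lgamma(Y + 1))
      ll <- ll + w * (pois + dmatnorm(th, cmp$M, cmp$Phi, cmp$Omega))
    }
  }
  ll
}
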