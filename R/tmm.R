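# Trimmed mean of M-values library-size normalization (simplified
# re-derivation, not a bit-exact clone of edgeR's calcNormFactors).

#' Compute library-size offsets by trimmed mean of M-values
#'
#' Flattens the tensor to a genes x samples matrix (one sample per
#' (occasion, variable) cell), picks as reference the sample whose
#' upper-quartile proportion is closest to the mean upper quartile, trims 30
#' percent of M-values (log-fold changes) and 5 percent of A-values (average
#' abundances) on each side, and scales each library by 2 to the
#' precision-weighted mean of the retained M-values. Effective library sizes
#' are rescaled to geometric mean 1 and returned as an \code{r x p} offset
#' matrix.
#'
#' @param tensor a \code{count_tensor}.
#' @param trim_M,trim_A two-sided trim fractions for M- and A-values.
#' @return An \code{r x p} matrix of strictly positive offsets with
#'   geometric mean 1.
#' @export
compute_offsets_tmm <- function(tensor, trim_M = 0.3, trim_A = 0.05) {
  d <- tensor_dims(tensor)
  Ymat <- flatten_tensor(tensor)            # N x (r*p), genes x samples
  lib <- colSums(Ymat)
  if (any(lib == 0))
    stop_numeric("sample column(s) with all-zero counts: ",
                 paste(colnames(Ymat)[lib == 0], collapse = ", "))
  prop <- sweep(Ymat, 2, lib, "/")
  uq <- apply(prop, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  factors <- vapply(seq_along(lib), function(j) {
    if (j == ref) return(1)
    pj <- prop[, j]; pr <- prop[, ref]
    keep <- pj > 0 & pr > 0
    if (!any(keep)) return(1)
    M <- log2(pj[keep] / pr[keep])
    A <- 0.5 * log2(pj[keep] * pr[keep])
    # asymptotic precision weights (delta-method variance of M)
    w <- 1 / ((lib[j] - Ymat[keep, j]) / (lib[j] * Ymat[keep, j]) +
              (lib[ref] - Ymat[keep, ref]) / (lib[ref] * Ymat[keep, ref]))
    if (max(abs(M)) < 1e-6) return(1)
    loM <- stats::quantile(M, trim_M); hiM <- stats::quantile(M, 1 - trim_M)
    loA <- stats::quantile(A, trim_A); hiA <- stats::quantile(A, 1 - trim_A)
    sel <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(sel) || sum(w[sel]) == 0) return(1)
    2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  }, 0)
  eff <- lib * factors
  eff <- eff / exp(mean(log(eff)))
  inv_vec_transpose(eff, d$r, d$p)
}
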