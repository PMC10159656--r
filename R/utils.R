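# Internal helpers: condition classes, RNG scoping, SPD guards.

stop_validation <- function(...) {
  stop(structure(class = c("mvpln_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("mvpln_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. Seeds are kept below 2^31.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Validate symmetric positive definiteness; near-singular matrices are
# jittered on the diagonal (1e-8 * trace/dim) with a warning.
ensure_spd <- function(A, label = "matrix", rel_tol = 1e-10) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop_validation(label, " must be a square matrix")
  A <- (A + t(A)) / 2
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0 || min(ev) < -1e-6 * max(abs(ev)))
    stop_numeric(label, " is not positive definite")
  if (min(ev) <= rel_tol * max(ev)) {
    jit <- 1e-8 * sum(diag(A)) / nrow(A) + 1e-12 - min(min(ev), 0)
    warning(sprintf("%s near-singular (min eig %.3e); jittering diagonal by %.3e",
                    label, min(ev), jit))
    A <- A + diag(jit, nrow(A))
  }
  A
}

is_spd <- function(A, rel_tol = 1e-10) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) return(FALSE)
  if (max(abs(A - t(A))) > 1e-8 * (1 + max(abs(A)))) return(FALSE)
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > rel_tol * max(ev) && max(ev) > 0
}

is_count <- function(x) is.numeric(x) && all(is.finite(x)) &&
  all(x >= 0) && all(abs(x - round(x)) < 1e-8)
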