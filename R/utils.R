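# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L) # force RNG initialisation so we have a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Dirichlet draw via normalised gamma variates; rows of the result are the draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, ncol = k, byrow = TRUE)
  # guard against all-zero rows (possible for very small shape parameters)
  zero <- rowSums(x) == 0
  while (any(zero)) {
    x[zero, ] <- matrix(rgamma(sum(zero) * k, shape = alpha, rate = 1),
                        nrow = sum(zero), byrow = TRUE)
    zero <- rowSums(x) == 0
  }
  x / rowSums(x)
}

# Stable key for an unordered disease-gene pair table.
pair_keys <- function(disease, gene) paste(disease, gene, sep = "\r")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)
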