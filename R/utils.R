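#' Gauss-Hermite quadrature nodes and weights
#'
#' Nodes and weights for \eqn{\int f(x) e^{-x^2} dx \approx \sum_k w_k f(x_k)},
#' computed by the Golub-Welsch eigenvalue method on the Jacobi matrix of the
#' Hermite recurrence.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`, each length `n`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = sqrt(pi) * e$vectors[1, idx]^2)
}

# Harmonic (Fourier) design matrix on the time-of-day covariate:
# columns 1, cos(2*pi*k*zt/cycle), sin(2*pi*k*zt/cycle) for k = 1..K.
trig_design <- function(zt, K, cycle = 24) {
  X <- matrix(1, length(zt), 1 + 2 * K)
  for (k in seq_len(K)) {
    w <- 2 * pi * k * zt / cycle
    X[, 2 * k]     <- cos(w)
    X[, 2 * k + 1] <- sin(w)
  }
  X
}

# Centered running mean with window w bins; partial windows at the edges use
# the available points (keeps a constant series exactly constant).
running_mean <- function(x, w) {
  n <- length(x)
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Deterministic child seed derivation (keeps results < 2^31 and independent
# across stages without consuming the caller's RNG stream).
child_seed <- function(seed, salt) {
  (as.integer(seed) * 7919L + as.integer(salt) * 104729L) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
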