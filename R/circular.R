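#' Circular summary statistics of a phase sample
#'
#' Computes the mean direction \eqn{\mu}, mean resultant length
#' \eqn{\bar R}, circular standard deviation \eqn{\sqrt{-2\ln\bar R}}
#' (radians), the maximum-likelihood Von Mises concentration \eqn{\kappa}
#' (inversion of \eqn{A(\kappa) = I_1/I_0 = \bar R}, Newton-refined), the
#' circular median (minimizer of mean arc distance, candidates at the data
#' points), and the phase-coherence measure `1 / circular SD`. A fully
#' coherent sample (`Rbar == 1`) gets `coherence = Inf` with
#' `degenerate = TRUE`.
#'
#' @param phases radians (any real; reduced mod `2*pi`).
#' @return object of class `circular_summary`: list with `n`, `mu`, `Rbar`,
#'   `circ_sd`, `kappa`, `median`, `coherence`, `degenerate`.
#' @export
circular_summary <- function(phases) {
  phases <- as.numeric(phases) %% (2 * pi)
  n <- length(phases)
  if (n < 2) stop("need at least 2 phases")
  C <- mean(cos(phases)); S <- mean(sin(phases))
  Rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C) %% (2 * pi)
  degenerate <- Rbar > 1 - 1e-12
  circ_sd <- if (degenerate) 0 else sqrt(-2 * log(max(Rbar, 1e-300)))
  kappa <- kappa_ml(Rbar)
  med <- circ_median(phases)
  coherence <- if (degenerate) Inf else if (Rbar < 1e-12) 0 else 1 / circ_sd
  structure(list(n = n, mu = mu, Rbar = Rbar, circ_sd = circ_sd,
                 kappa = kappa, median = med, coherence = coherence,
                 degenerate = degenerate),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "circular_summary: n=%d, mu=%.3f rad, median=%.3f rad, Rbar=%.3f, SD=%.3f rad, kappa=%.3f, coherence=%s\n",
    x$n, x$mu, x$median, x$Rbar, x$circ_sd, x$kappa,
    if (is.infinite(x$coherence)) "Inf (degenerate)" else
      sprintf("%.3f", x$coherence)))
  invisible(x)
}

#' Maximum-likelihood Von Mises concentration from the resultant length
#'
#' Standard three-regime series approximation (Fisher-style) followed by
#' Newton steps on \eqn{A(\kappa) = \bar R} using exact Bessel ratios.
#'
#' @param Rbar mean resultant length in `[0, 1]`.
#' @return kappa estimate (`0` for `Rbar = 0`, `Inf` for `Rbar = 1`).
#' @export
kappa_ml <- function(Rbar) {
  if (Rbar <= 0) return(0)
  if (Rbar >= 1 - 1e-12) return(Inf)
  k <- if (Rbar < 0.53) 2 * Rbar + Rbar^3 + 5 * Rbar^5 / 6
  else if (Rbar < 0.85) -0.4 + 1.39 * Rbar + 0.43 / (1 - Rbar)
  else 1 / (Rbar^3 - 4 * Rbar^2 + 3 * Rbar)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  for (i in 1:5) {
    a <- A(k)
    dA <- 1 - a / k - a^2
    if (!is.finite(dA) || dA <= 0) break
    k <- max(k - (a - Rbar) / dA, 1e-8)
  }
  k
}

# Circular median: data-point candidate minimizing the mean arc distance;
# ties broken by the smallest angle.
circ_median <- function(phases) {
  phases <- phases %% (2 * pi)
  d <- vapply(phases, function(th)
    mean(pi - abs(pi - abs(phases - th))), 0)
  cand <- sort(phases[d <= min(d) + 1e-12])
  cand[1]
}

# Circular mean of a (small) phase sample; NA-safe
circ_mean <- function(phases) {
  phases <- phases[is.finite(phases)]
  if (!length(phases)) return(NA_real_)
  atan2(mean(sin(phases)), mean(cos(phases))) %% (2 * pi)
}

#' Von Mises cumulative distribution function
#'
#' CDF on the branch starting at `mu - pi`, from the Fourier-Bessel series of
#' the density.
#'
#' @param q angles (radians).
#' @param mu mean direction.
#' @param kappa concentration.
#' @param terms number of series terms; by default grows with `kappa`
#'   (the Bessel ratios `I_j/I_0` decay like `(kappa/2)^j / j!`).
#' @return probabilities in `[0, 1]`.
#' @export
pvonmises <- function(q, mu = 0, kappa = 1, terms = NULL) {
  th <- (q - mu + pi) %% (2 * pi) - pi    # in (-pi, pi]
  if (kappa < 1e-10) return((th + pi) / (2 * pi))
  if (is.null(terms)) terms <- min(200L, max(20L, ceiling(2 * kappa + 20)))
  j <- seq_len(terms)
  bj <- vapply(j, function(k) besselI(kappa, k, expon.scaled = TRUE), 0) /
    besselI(kappa, 0, expon.scaled = TRUE)
  F <- (th + pi) / (2 * pi) +
    (sin(outer(th, j)) %*% (bj / j)) / pi
  pmin(pmax(drop(F), 0), 1)
}

# Watson U^2 statistic of angles against VonMises(mu, kappa)
watson_u2_stat <- function(phases, mu, kappa) {
  z <- sort(pvonmises(phases, mu, kappa))
  n <- length(z)
  i <- seq_len(n)
  sum((z - (2 * i - 1) / (2 * n))^2) - n * (mean(z) - 0.5)^2 + 1 / (12 * n)
}

fit_vonmises <- function(phases) {
  C <- mean(cos(phases)); S <- mean(sin(phases))
  Rbar <- sqrt(C^2 + S^2)
  list(mu = atan2(S, C) %% (2 * pi), kappa = kappa_ml(Rbar), Rbar = Rbar)
}

#' Watson goodness-of-fit test against the Von Mises distribution
#'
#' Computes Watson's \eqn{U^2} of the sample against the Von Mises
#' distribution with estimated \eqn{(\mu, \kappa)}; the p-value comes from a
#' parametric bootstrap (refit and recompute \eqn{U^2} on each bootstrap
#' sample), which sidesteps printed critical-value tables.
#'
#' @param phases radians.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return object of class `circ_test`: list with `test`, `statistic`,
#'   `p_value`, `n`, `degenerate`.
#' @export
watson_gof <- function(phases, B = 1000, seed = 1) {
  phases <- as.numeric(phases) %% (2 * pi)
  n <- length(phases)
  if (n < 10) warning("n < 10: Watson test is underpowered")
  f <- fit_vonmises(phases)
  if (f$Rbar > 1 - 1e-12 || !is.finite(f$kappa)) {
    return(structure(list(test = "watson_gof", statistic = NA_real_,
                          p_value = NA_real_, n = n, degenerate = TRUE),
                     class = "circ_test"))
  }
  u2 <- watson_u2_stat(phases, f$mu, f$kappa)
  set.seed(seed)
  u2b <- vapply(seq_len(B), function(b) {
    x <- rvonmises(n, f$mu, f$kappa)
    fb <- fit_vonmises(x)
    watson_u2_stat(x, fb$mu, fb$kappa)
  }, 0)
  structure(list(test = "watson_gof", statistic = u2,
                 p_value = (1 + sum(u2b >= u2)) / (B + 1), n = n,
                 degenerate = FALSE),
            class = "circ_test")
}

#' @export
print.circ_test <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g, p=%.4g (n=%s)%s\n", x$test,
              x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (isTRUE(x$degenerate)) " [degenerate sample]" else ""))
  invisible(x)
}

#' Two-sample test for equal Von Mises concentrations
#'
#' Concentration-homogeneity test with the three variance-stabilizing
#' transforms chosen by the weighted pooled mean resultant length
#' \eqn{\bar R_w = (n_1 \bar R_1 + n_2 \bar R_2)/N}:
#' \itemize{
#'   \item \eqn{\bar R_w < 0.45}: \eqn{g_1(x) = \arcsin(x \sqrt{3/8})}
#'     applied to \eqn{2\bar R_j}, normal reference with variance
#'     \eqn{3/4 (1/(n_1-4) + 1/(n_2-4))};
#'   \item \eqn{0.45 \le \bar R_w \le 0.70}: \eqn{g_2(x) =
#'     \mathrm{asinh}((x - 1.089)/0.258)}, scale 0.893, dfs \eqn{n_j - 3};
#'   \item \eqn{\bar R_w > 0.70}: dispersion ratio
#'     \eqn{F = \frac{(n_1 - R_1)/(n_1 - 1)}{(n_2 - R_2)/(n_2 - 1)}} against
#'     \eqn{F_{n_1-1, n_2-1}}.
#' }
#' All p-values are two-sided.
#'
#' @param a,b phase samples (radians).
#' @return `circ_test` with fields `test`, `statistic`, `p_value`, `regime`,
#'   `n`.
#' @export
equal_kappa_test <- function(a, b) {
  a <- as.numeric(a) %% (2 * pi); b <- as.numeric(b) %% (2 * pi)
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 5, n2 >= 5)
  fa <- fit_vonmises(a); fb <- fit_vonmises(b)
  Rw <- (n1 * fa$Rbar + n2 * fb$Rbar) / (n1 + n2)
  if (Rw < 0.45) {
    g <- function(x) asin(pmin(x * sqrt(3 / 8), 1))
    z <- (g(2 * fa$Rbar) - g(2 * fb$Rbar)) /
      sqrt(3 / 4 * (1 / (n1 - 4) + 1 / (n2 - 4)))
    p <- 2 * stats::pnorm(-abs(z)); stat <- z; regime <- "low"
  } else if (Rw <= 0.70) {
    g <- function(x) asinh((x - 1.089) / 0.258)
    z <- (g(fa$Rbar) - g(fb$Rbar)) /
      (0.893 * sqrt(1 / (n1 - 3) + 1 / (n2 - 3)))
    p <- 2 * stats::pnorm(-abs(z)); stat <- z; regime <- "mid"
  } else {
    d1 <- (n1 - n1 * fa$Rbar) / (n1 - 1)
    d2 <- (n2 - n2 * fb$Rbar) / (n2 - 1)
    f <- d1 / d2
    pf1 <- stats::pf(f, n1 - 1, n2 - 1)
    p <- 2 * min(pf1, 1 - pf1); stat <- f; regime <- "high"
  }
  structure(list(test = "equal_kappa", statistic = stat, p_value = min(p, 1),
                 regime = regime, n = c(n1, n2)),
            class = "circ_test")
}

#' Pairwise equal-concentration tests with Bonferroni adjustment
#'
#' Applies [equal_kappa_test()] to every pair of groups and adjusts p-values
#' by Bonferroni over the number of pairs actually tested. Groups below the
#' minimum size are skipped with a notice.
#'
#' @param groups named list of phase samples (radians), one per genotype.
#' @param min_n minimum group size (default 5).
#' @return data.frame: group1, group2, regime, statistic, p_value,
#'   p_adjusted.
#' @export
equal_kappa_pairwise <- function(groups, min_n = 5) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  keep <- vapply(groups, length, 0L) >= min_n
  if (any(!keep))
    message("skipping groups below n=", min_n, ": ",
            paste(names(groups)[!keep], collapse = ", "))
  groups <- groups[keep]
  if (length(groups) < 2) stop("fewer than 2 groups of sufficient size")
  pairs <- utils::combn(names(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    tt <- equal_kappa_test(groups[[g1]], groups[[g2]])
    data.frame(group1 = g1, group2 = g2, regime = tt$regime,
               statistic = tt$statistic, p_value = tt$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(out$p_value * nrow(out), 1)
  out
}
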