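#' Bootstrap mean difference with percentile 95% confidence interval
#'
#' Estimation-statistics summary of a two-group comparison: the difference
#' of means `mean(b) - mean(a)` with a percentile bootstrap confidence
#' interval (each group resampled with replacement `n_boot` times).
#' Deterministic under `seed`.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `effect_size`: `mean_a`, `mean_b`, `difference`,
#'   `ci_low`, `ci_high`, `n_a`, `n_b`, `n_boot`, `seed`.
#' @export
bootstrap_mean_diff <- function(a, b, n_boot = 5000, seed = 1, conf = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  stopifnot(all(is.finite(a)), all(is.finite(b)), n_boot >= 100)
  set.seed(seed)
  na <- length(a); nb <- length(b)
  ma <- matrix(sample(a, na * n_boot, replace = TRUE), na)
  mb <- matrix(sample(b, nb * n_boot, replace = TRUE), nb)
  diffs <- colMeans(mb) - colMeans(ma)
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(diffs, c(alpha, 1 - alpha), type = 7))
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 difference = mean(b) - mean(a),
                 ci_low = ci[1], ci_high = ci[2],
                 n_a = na, n_b = nb, n_boot = n_boot, seed = seed,
                 conf = conf),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("mean difference %.4g [%.0f%% bootstrap CI %.4g, %.4g] (n=%d vs %d, B=%d)\n",
              x$difference, 100 * x$conf, x$ci_low, x$ci_high,
              x$n_a, x$n_b, x$n_boot))
  invisible(x)
}
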