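#' Bin a luminescence trace into wider intervals
#'
#' Mean counts-per-second per `bin`-minute time window (windows are aligned
#' to the record start, so a 4-min trace binned at 30 min alternates between
#' 8- and 7-sample windows). A trailing window that extends past the end of
#' the record is dropped.
#'
#' @param raw a [luc_series()].
#' @param bin output bin width in minutes (`>=` the resolution).
#' @return a [luc_series()] at the new resolution.
#' @export
bin_luminescence <- function(raw, bin = 30) {
  stopifnot(inherits(raw, "luc_series"))
  if (bin < raw$resolution)
    stop("bin must be at least the resolution (", raw$resolution, " min)")
  rel_h <- raw$t - raw$t[1]
  idx <- floor(rel_h * 60 / bin + 1e-9)
  span_end <- rel_h[length(rel_h)] + raw$resolution / 60
  n_full <- floor(span_end * 60 / bin + 1e-9)
  if (n_full < 1) stop("record shorter than one bin")
  keep <- idx < n_full
  m <- as.numeric(tapply(raw$cps[keep], idx[keep], mean))
  out <- luc_series(m, bin, sample_id = raw$sample_id,
                    genotype = raw$genotype, t0_h = raw$t[1])
  attr(out, "truth") <- attr(raw, "truth")
  out
}

#' Detrend a decaying luminescence trace
#'
#' Two transparent steps standing in for vendor decay normalization:
#' (1) fit \eqn{A e^{-t/\lambda}} by least squares on the log of a 24-h
#' running mean of the signal (the running mean averages out the circadian
#' oscillation, and for a pure exponential only rescales it, so the decay
#' rate is recovered exactly) and divide by the fitted trend; (2) subtract a
#' 24-h centered moving average so the result oscillates around zero.
#' Non-positive values entering the log step trigger an offset-shift
#' fallback with a warning.
#'
#' @param series a [luc_series()] covering at least 2 days.
#' @return a [luc_series()]-like object (field `cps` holds the detrended
#'   arbitrary units, possibly negative) with attribute `decay` =
#'   `list(A, lambda)`.
#' @export
detrend_luminescence <- function(series) {
  stopifnot(inherits(series, "luc_series"))
  t <- series$t - series$t[1]
  x <- series$cps
  if (max(t) < 48) stop("need at least 2 days of data")
  w <- as.integer(round(24 * 60 / series$resolution))
  s <- running_mean(x, w)
  if (any(s <= 0)) {
    warning("non-positive smoothed values: applying offset shift before log")
    s <- s - min(s) + 1e-6 * max(abs(s))
  }
  # fit only where the running-mean window is complete: for a pure
  # exponential the interior running mean is an exact constant multiple of
  # the trend, so the decay rate is recovered exactly
  interior <- seq_len(length(x)) > w / 2 & seq_len(length(x)) <= length(x) - w / 2
  if (sum(interior) < 10) interior <- rep(TRUE, length(x))
  fit <- lm(log(s[interior]) ~ t[interior])
  A <- exp(coef(fit)[1]); lambda <- -1 / coef(fit)[2]
  trend <- exp(coef(fit)[1] + coef(fit)[2] * t)
  y <- x / trend
  y <- y - running_mean(y, w)
  out <- series
  out$cps <- y
  attr(out, "decay") <- list(A = unname(A), lambda = unname(lambda))
  attr(out, "detrended") <- TRUE
  out
}

# Continuous Morlet wavelet transform power on a log-spaced period grid.
# Torrence & Compo normalization (unit energy per scale), FFT implementation.
cwt_morlet_power <- function(x, dt_h, periods, omega0 = 6) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^ceiling(log2(n * 2))
  xp <- c(x, rep(0, npad - n))
  xf <- fft(xp)
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt_h)
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods / fourier_factor
  P <- matrix(NA_real_, length(periods), n)
  norm0 <- pi^(-0.25)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- norm0 * sqrt(2 * pi * s / dt_h) *
      exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    w <- stats::mvfft(matrix(xf * psi, ncol = 1), inverse = TRUE)[seq_len(n), 1] / npad
    P[j, ] <- Mod(w)^2
  }
  list(power = P, scales = scales, coi_efold = sqrt(2) * scales)
}

#' Time-resolved period estimation by Morlet wavelet ridge
#'
#' Continuous Morlet transform (central frequency 6) over a log-spaced
#' period grid (64 voices) inside the analysis band; the ridge is the
#' power-maximizing period at each time point, with scales whose cone of
#' influence reaches past the nearer record edge excluded. The summary
#' period is the median over ridge points.
#'
#' @param detrended a detrended [luc_series()] (see
#'   [detrend_luminescence()]).
#' @param band admissible periods in hours (default `c(16, 32)`).
#' @param voices grid size (default 64).
#' @param omega0 Morlet central frequency (default 6).
#' @return object of class `wavelet_result`: list with `sample_id`, `ridge`
#'   (data.frame `t`, `period`), `median_period`, `band`, `no_signal`.
#' @export
wavelet_period <- function(detrended, band = c(16, 32), voices = 64,
                           omega0 = 6) {
  stopifnot(inherits(detrended, "luc_series"), band[1] > 0, band[2] > band[1])
  x <- detrended$cps
  dt_h <- detrended$resolution / 60
  n <- length(x)
  if (n * dt_h < 3 * band[2])
    stop("record must cover at least 3x the longest band period")
  if (all(abs(x - mean(x)) < 1e-14)) {
    return(structure(list(sample_id = detrended$sample_id,
                          ridge = data.frame(t = numeric(), period = numeric()),
                          median_period = NA_real_, band = band,
                          no_signal = TRUE),
                     class = "wavelet_result"))
  }
  periods <- exp(seq(log(band[1]), log(band[2]), length.out = voices))
  cw <- cwt_morlet_power(x, dt_h, periods, omega0)
  tt <- detrended$t - detrended$t[1]
  edge <- pmin(tt, max(tt) - tt)             # distance to nearer edge (h)
  # a time point contributes to the ridge only when every scale in the band
  # lies inside its cone of influence there, so the argmax is never forced
  # onto the short-period fallback near the record edges
  valid_t <- edge >= max(cw$coi_efold)
  ridge <- rep(NA_real_, n)
  for (i in which(valid_t))
    ridge[i] <- periods[which.max(cw$power[, i])]
  keep <- is.finite(ridge)
  structure(list(sample_id = detrended$sample_id,
                 ridge = data.frame(t = detrended$t[keep],
                                    period = ridge[keep]),
                 median_period = if (any(keep)) median(ridge[keep]) else NA_real_,
                 band = band, no_signal = FALSE),
            class = "wavelet_result")
}

#' @export
print.wavelet_result <- function(x, ...) {
  cat(sprintf("wavelet_result '%s': median period %s h over %d ridge points (band %g-%g h)%s\n",
              x$sample_id,
              if (is.na(x$median_period)) "NA" else sprintf("%.2f", x$median_period),
              nrow(x$ridge), x$band[1], x$band[2],
              if (x$no_signal) " [no signal]" else ""))
  invisible(x)
}

#' Read a luminescence CSV (t_minutes, cps)
#'
#' @param path CSV with columns `t_minutes` and `cps`.
#' @param sample_id,genotype identifiers.
#' @return a [luc_series()].
#' @export
read_luc_csv <- function(path, sample_id = basename(path),
                         genotype = "unknown") {
  d <- utils::read.csv(path)
  stopifnot(all(c("t_minutes", "cps") %in% names(d)))
  steps <- diff(d$t_minutes)
  if (length(steps) && any(abs(steps - steps[1]) > 1e-6))
    stop("non-uniform sampling in ", path)
  luc_series(d$cps, steps[1], sample_id = sample_id, genotype = genotype,
             t0_h = d$t_minutes[1] / 60)
}
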