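# Second-order Butterworth low-pass coefficients via the bilinear transform.
# Wn is the cutoff as a fraction of the Nyquist frequency.
butter2_lowpass <- function(Wn) {
  stopifnot(Wn > 0, Wn < 1)
  K <- tan(pi * Wn / 2)
  den <- 1 + sqrt(2) * K + K^2
  list(b = c(K^2, 2 * K^2, K^2) / den,
       a = c(1, 2 * (K^2 - 1) / den, (1 - sqrt(2) * K + K^2) / den))
}

iir_filter <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    acc <- b[1] * x[t]
    if (t > 1) acc <- acc + b[2] * x[t - 1] - a[2] * y[t - 1]
    if (t > 2) acc <- acc + b[3] * x[t - 2] - a[3] * y[t - 2]
    y[t] <- acc
  }
  y
}

# Zero-phase filtering on a circular (daily) record: filter the tripled
# series forward and backward, keep the middle copy. Circular extension is
# natural for one day of a periodic signal and avoids edge transients.
filtfilt_circular <- function(b, a, x) {
  n <- length(x)
  xx <- rep(x, 3)
  y <- iir_filter(b, a, xx)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(n + 1):(2 * n)]
}

#' Activity-peak phase of one free-running day
#'
#' Low-pass filters one DD day's counts (zero-phase second-order Butterworth,
#' default cutoff period 4 h, circular edge handling) and returns the
#' circadian time of the filtered maximum as an angle
#' \eqn{\theta = 2\pi \, \mathrm{zt}/24} (bin midpoints). Rhythmicity
#' screening is the caller's responsibility: arrhythmic flies must not enter
#' phase statistics.
#'
#' @param series annotated [activity_series()] with DD days.
#' @param day DD day index (1 = first full day of constant darkness).
#' @param cutoff_h low-pass cutoff period in hours.
#' @param smoother `"butterworth"` (default) or `"none"` (raw argmax);
#'   exposed so alternative peak strategies can be swapped in.
#' @return phase in radians `[0, 2*pi)`, or `NA` for an all-zero day.
#' @export
daily_peak_phase <- function(series, day, cutoff_h = 4,
                             smoother = c("butterworth", "none")) {
  smoother <- match.arg(smoother)
  dd <- dd_day(series)
  idx <- which(!is.na(dd) & dd == day)
  bw_h <- series$bin_width / 60
  if (length(idx) != round(24 / bw_h))
    stop("DD day ", day, " not fully recorded")
  x <- series$counts[idx]
  if (all(x == 0)) return(NA_real_)
  if (smoother == "butterworth") {
    fs <- 1 / bw_h                       # samples per hour
    co <- butter2_lowpass((1 / cutoff_h) / (fs / 2))
    x <- filtfilt_circular(co$b, co$a, x)
  }
  zt_mid <- series$zt[idx] + bw_h / 2
  (2 * pi * zt_mid[which.max(x)] / 24) %% (2 * pi)
}

#' Per-fly free-running phase from DD days 2 and 3
#'
#' Circular mean of the daily peak phases of the second and third full days
#' in constant darkness. If one day is missing (all-zero) the other is used
#' and the result flagged; if both are missing the fly is excluded
#' (`NA` phase).
#'
#' @param series annotated [activity_series()].
#' @param days DD day indices (default `c(2, 3)`).
#' @param ... passed to [daily_peak_phase()].
#' @return one-row data.frame: fly_id, genotype, phase (radians or NA),
#'   n_days (days that contributed).
#' @export
fly_phase <- function(series, days = c(2, 3), ...) {
  ph <- vapply(days, function(d) daily_peak_phase(series, d, ...), 0)
  ok <- is.finite(ph)
  phase <- if (any(ok)) circ_mean(ph[ok]) else NA_real_
  data.frame(fly_id = series$fly_id, genotype = series$genotype,
             phase = phase, n_days = sum(ok))
}

#' Phase sample of a cohort, excluding arrhythmic flies
#'
#' @param series_set list of annotated [activity_series()].
#' @param rhythm data.frame from [classify_rhythmicity()] (or NULL to skip
#'   the exclusion, for simulated data of known rhythmicity).
#' @param days DD day indices (default DD2 and DD3).
#' @param ... passed to [daily_peak_phase()].
#' @return data.frame: fly_id, genotype, phase, n_days; arrhythmic and
#'   phase-less flies are dropped.
#' @export
phase_table <- function(series_set, rhythm = NULL, days = c(2, 3), ...) {
  if (!is.null(rhythm)) {
    keep <- rhythm$fly_id[rhythm$rhythmic]
    series_set <- Filter(function(s) s$fly_id %in% keep, series_set)
  }
  if (!length(series_set)) return(data.frame(fly_id = character(),
                                             genotype = character(),
                                             phase = numeric(),
                                             n_days = integer()))
  out <- do.call(rbind, lapply(series_set, fly_phase, days = days, ...))
  out[is.finite(out$phase), , drop = FALSE]
}
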