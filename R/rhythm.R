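#' Autocorrelogram of an activity series
#'
#' Mean-subtracted, biased-normalized autocorrelation (the standard
#' correlogram: denominator `N`, so values shrink toward zero at long lags)
#' at every bin lag up to `max_lag` hours.
#'
#' @param series an [activity_series()] (typically the DD segment).
#' @param max_lag maximum lag in hours; defaults to half the record, capped
#'   at 60 h.
#' @return data.frame with `lag_h` and `acf`, plus attribute `N` (series
#'   length in bins).
#' @export
autocorrelogram <- function(series, max_lag = NULL) {
  x <- series$counts
  bw_h <- series$bin_width / 60
  N <- length(x)
  if (var(x) == 0) stop("zero-variance error: constant series")
  half <- N * bw_h / 2
  if (is.null(max_lag)) max_lag <- min(60, half)
  if (max_lag > half + 1e-9) stop("max_lag exceeds half the record")
  nl <- as.integer(floor(max_lag / bw_h))
  ac <- acf(x, lag.max = nl, plot = FALSE, demean = TRUE,
            type = "correlation")$acf[, 1, 1]
  out <- data.frame(lag_h = (0:nl) * bw_h, acf = ac)
  attr(out, "N") <- N
  out
}

# Parabolic (3-point) interpolation around a local maximum; returns the
# refined (x, y) using the neighbouring grid points.
parabolic_peak <- function(lag, val, k) {
  if (k <= 1 || k >= length(lag)) return(c(lag[k], val[k]))
  y1 <- val[k - 1]; y2 <- val[k]; y3 <- val[k + 1]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < 1e-15) return(c(lag[k], val[k]))
  d <- 0.5 * (y1 - y3) / denom
  d <- max(min(d, 1), -1)
  h <- lag[2] - lag[1]
  c(lag[k] + d * h, y2 - 0.25 * (y1 - y3) * d)
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Rhythmicity statistics from a correlogram
#'
#' The free-running period `tau` is the parabolic-interpolated lag of the
#' highest correlogram peak in the circadian range; the rhythm index RI is
#' the interpolated height of the third correlogram peak (counting lag 0),
#' i.e. the local maximum near lag `2*tau`; the rhythmic strength
#' RS = RI / (2/sqrt(N)) scales RI by the 95% confidence line of a white
#' correlogram. A fly is rhythmic when a circadian peak exists and
#' RS >= `rs_threshold`.
#'
#' @param correlogram output of [autocorrelogram()] covering at least
#'   `2 * period_range[2]` hours of lag.
#' @param N series length in bins (defaults to the correlogram attribute).
#' @param rs_threshold RS cutoff (default 1.5; 1.0 is the lenient option).
#' @param period_range admissible circadian periods in hours.
#' @return one-row data.frame: period, RI, RS, rhythmic, reason.
#' @export
rhythm_stats <- function(correlogram, N = attr(correlogram, "N"),
                         rs_threshold = 1.5, period_range = c(18, 30)) {
  lag <- correlogram$lag_h; v <- correlogram$acf
  if (max(lag) < 2 * period_range[1])
    stop("correlogram must cover at least two putative cycles")
  cand <- local_maxima(v)
  cand <- cand[lag[cand] >= period_range[1] & lag[cand] <= period_range[2]]
  arr <- function(reason) data.frame(period = NA_real_, RI = NA_real_,
                                     RS = NA_real_, rhythmic = FALSE,
                                     reason = reason)
  if (!length(cand)) return(arr("no_circadian_peak"))
  k <- cand[which.max(v[cand])]
  # localize the period on the unbiased-corrected correlogram: the biased
  # estimator's (1 - k/N) envelope drags the interpolated peak to shorter
  # lags; heights (RI, RS) stay on the biased scale
  bw <- lag[2] - lag[1]
  vu <- v * N / pmax(N - lag / bw, 1)
  pk <- parabolic_peak(lag, vu, k)
  tau <- pk[1]
  # third peak (counting lag 0): local maximum nearest 2*tau
  win <- which(lag >= 2 * tau - 2 & lag <= 2 * tau + 2)
  if (!length(win)) return(arr("second_cycle_outside_correlogram"))
  cand2 <- intersect(local_maxima(v), win)
  k2 <- if (length(cand2)) cand2[which.max(v[cand2])] else win[which.max(v[win])]
  ri <- parabolic_peak(lag, v, k2)[2]
  rs <- ri / (2 / sqrt(N))
  rhythmic <- rs >= rs_threshold
  # arrhythmic flies carry no period (they are excluded downstream anyway)
  data.frame(period = if (rhythmic) tau else NA_real_, RI = ri, RS = rs,
             rhythmic = rhythmic,
             reason = if (rhythmic) "ok" else "below_rs_threshold")
}

#' Classify a cohort as rhythmic or arrhythmic in DD
#'
#' Runs [autocorrelogram()] + [rhythm_stats()] on the DD segment of every
#' fly. Arrhythmic flies carry a missing period and are excluded from phase
#' analysis downstream.
#'
#' @param series_set list of annotated [activity_series()].
#' @param rs_threshold,period_range passed to [rhythm_stats()].
#' @param max_lag passed to [autocorrelogram()].
#' @return data.frame: fly_id, genotype, period, RI, RS, rhythmic, reason.
#' @export
classify_rhythmicity <- function(series_set, rs_threshold = 1.5,
                                 period_range = c(18, 30), max_lag = NULL) {
  if (inherits(series_set, "activity_series")) series_set <- list(series_set)
  rows <- lapply(series_set, function(s) {
    dd <- if (!is.null(s$segment)) series_slice(s, s$segment == "DD") else s
    res <- tryCatch({
      ac <- autocorrelogram(dd, max_lag)
      rhythm_stats(ac, rs_threshold = rs_threshold,
                   period_range = period_range)
    }, error = function(e) data.frame(period = NA_real_, RI = NA_real_,
                                      RS = NA_real_, rhythmic = FALSE,
                                      reason = conditionMessage(e)))
    cbind(data.frame(fly_id = s$fly_id, genotype = s$genotype), res)
  })
  do.call(rbind, rows)
}

#' Genotype-level rhythmicity summary
#'
#' @param rhythm data.frame from [classify_rhythmicity()].
#' @return per genotype: n, percent_rhythmic, mean period +/- SEM and mean
#'   RS +/- SEM over rhythmic flies.
#' @export
rhythm_summary <- function(rhythm) {
  do.call(rbind, lapply(split(rhythm, rhythm$genotype), function(g) {
    r <- g[g$rhythmic, , drop = FALSE]
    sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    data.frame(genotype = g$genotype[1], n = nrow(g),
               percent_rhythmic = 100 * mean(g$rhythmic),
               period_mean = if (nrow(r)) mean(r$period) else NA_real_,
               period_sem = sem(r$period),
               rs_mean = if (nrow(r)) mean(r$RS) else NA_real_,
               rs_sem = sem(r$RS))
  }))
}
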