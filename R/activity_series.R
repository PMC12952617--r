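#' Photoperiod description of a recording
#'
#' Describes the light regime of an experiment: clock times of lights-on and
#' lights-off, the number of recorded light:dark (LD) and constant-darkness
#' (DD) days, and how many of each are used for analysis. A 12:12 LD cycle
#' with lights-on at 08:00 and at least 3 LD + 5 DD analysis days is the
#' standard design this package targets.
#'
#' @param lights_on,lights_off clock times in hours (`0 <= t < 24`), unequal.
#' @param n_ld_days,n_dd_days recorded full days in each segment.
#' @param ld_analysis_days,dd_analysis_days days entering the analysis
#'   (defaults 3 LD, 5 DD); must not exceed the recorded counts.
#' @return an object of class `photo_regime`.
#' @export
photo_regime <- function(lights_on = 8, lights_off = 20,
                         n_ld_days = 4, n_dd_days = 5,
                         ld_analysis_days = 3, dd_analysis_days = 5) {
  stopifnot(lights_on >= 0, lights_on < 24, lights_off >= 0, lights_off < 24)
  if (lights_on == lights_off)
    stop("lights_on and lights_off must differ")
  if (ld_analysis_days > n_ld_days || dd_analysis_days > n_dd_days)
    stop("analysis day counts must not exceed recorded day counts")
  structure(list(lights_on = lights_on, lights_off = lights_off,
                 n_ld_days = n_ld_days, n_dd_days = n_dd_days,
                 ld_analysis_days = ld_analysis_days,
                 dd_analysis_days = dd_analysis_days,
                 photoperiod = (lights_off - lights_on) %% 24),
            class = "photo_regime")
}

#' @export
print.photo_regime <- function(x, ...) {
  cat(sprintf("photo_regime: lights %02.0f:00-%02.0f:00 (%g h photoperiod), %d LD + %d DD days (analyze %d + %d)\n",
              x$lights_on, x$lights_off, x$photoperiod,
              x$n_ld_days, x$n_dd_days,
              x$ld_analysis_days, x$dd_analysis_days))
  invisible(x)
}

#' One fly's binned activity record
#'
#' Container for a single fly's binned beam-crossing counts. Light-regime
#' annotation (`light`, `zt`, `segment`, `day`) is attached by
#' [annotate_regime()].
#'
#' @param counts non-negative integer counts per bin.
#' @param bin_width bin width in minutes.
#' @param t0 POSIXct timestamp of the first bin start.
#' @param fly_id,genotype identifiers.
#' @return an object of class `activity_series`.
#' @export
activity_series <- function(counts, bin_width, t0, fly_id = "fly",
                            genotype = "unknown") {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!inherits(t0, "POSIXct")) stop("t0 must be POSIXct")
  structure(list(fly_id = fly_id, genotype = genotype,
                 bin_width = bin_width, t0 = t0, counts = counts,
                 light = NULL, zt = NULL, segment = NULL, day = NULL),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("activity_series '%s' (%s): %d bins of %g min%s\n",
              x$fly_id, x$genotype, length(x$counts), x$bin_width,
              if (is.null(x$segment)) " (unannotated)" else
                sprintf(", %d LD / %d DD bins", sum(x$segment == "LD"),
                        sum(x$segment == "DD"))))
  invisible(x)
}

#' @export
as.data.frame.activity_series <- function(x, ...) {
  n <- length(x$counts)
  data.frame(fly_id = x$fly_id, genotype = x$genotype,
             t = x$t0 + (seq_len(n) - 1) * x$bin_width * 60,
             zt = x$zt %||% rep(NA_real_, n),
             segment = x$segment %||% rep(NA_character_, n),
             light = x$light %||% rep(NA_character_, n),
             count = x$counts)
}

# Hours elapsed since the reference lights-on for each bin start.
abs_zt <- function(series, regime) {
  lt <- as.POSIXlt(series$t0)
  clock0 <- lt$hour + lt$min / 60 + lt$sec / 3600
  phase0 <- (clock0 - regime$lights_on) %% 24
  phase0 + (seq_along(series$counts) - 1) * series$bin_width / 60
}

#' Annotate an activity series with its light regime
#'
#' Populates the `light`, `zt` (Zeitgeber time in LD; circadian time anchored
#' to the last actual lights-on and projected forward in 24-h cycles in DD),
#' `segment` (LD/DD) and `day` (cycle index from the first lights-on) fields.
#' `zt = 0` at lights-on; in a 12:12 cycle `light == "L"` for `zt` in
#' `[0, 12)` during LD, and `"D"` for every DD bin.
#'
#' @param series an [activity_series()].
#' @param regime a [photo_regime()].
#' @return the annotated series (regime stored as attribute `regime`).
#' @export
annotate_regime <- function(series, regime) {
  stopifnot(inherits(series, "activity_series"), inherits(regime, "photo_regime"))
  az <- abs_zt(series, regime)
  span_h <- az[length(az)] + series$bin_width / 60
  need_h <- (regime$n_ld_days + regime$n_dd_days) * 24
  if (span_h < need_h)
    stop(sprintf("coverage error: series spans %.1f h but regime declares %.1f h",
                 span_h, need_h))
  series$zt <- az %% 24
  series$day <- floor(az / 24) + 1L
  series$segment <- ifelse(series$day <= regime$n_ld_days, "LD", "DD")
  series$light <- ifelse(series$segment == "LD" & series$zt < regime$photoperiod,
                         "L", "D")
  attr(series, "regime") <- regime
  series
}

# DD day index (1-based; NA in LD)
dd_day <- function(series) {
  regime <- attr(series, "regime")
  if (is.null(regime)) stop("series is not annotated")
  ifelse(series$segment == "DD", series$day - regime$n_ld_days, NA_integer_)
}

# Subset bins of an annotated series (keeps annotation; bins need not stay
# contiguous, callers own that invariant).
series_slice <- function(series, idx) {
  out <- series
  out$counts <- series$counts[idx]
  for (f in c("light", "zt", "segment", "day"))
    if (!is.null(series[[f]])) out[[f]] <- series[[f]][idx]
  out
}
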