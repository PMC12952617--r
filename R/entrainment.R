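#' Activity sums in the 6-h windows flanking a light transition
#'
#' Sums the counts in the 6 hours before (`[t - 6h, t)`) and after
#' (`[t, t + 6h)`, by bin start) a lights-on or lights-off transition on one
#' LD day. With `startle_correction = TRUE` the first bin after the
#' transition is excluded from the after-window, removing the reflexive
#' startle response to the light change.
#'
#' @param series an annotated [activity_series()].
#' @param transition `"lights_on"` or `"lights_off"`.
#' @param day LD day index (1-based from the first recorded cycle).
#' @param startle_correction drop the first post-transition bin.
#' @param window_h half-window in hours (6 by default).
#' @return named numeric `c(before_sum, after_sum)`.
#' @export
window_sums <- function(series, transition = c("lights_on", "lights_off"),
                        day, startle_correction = FALSE, window_h = 6) {
  transition <- match.arg(transition)
  regime <- attr(series, "regime")
  if (is.null(regime)) stop("series must be annotated with annotate_regime()")
  az <- abs_zt(series, regime)
  zt_tr <- if (transition == "lights_on") 0 else regime$photoperiod
  T_tr <- (day - 1) * 24 + zt_tr
  bw_h <- series$bin_width / 60
  before <- which(az >= T_tr - window_h - 1e-9 & az < T_tr - 1e-9)
  after <- which(az >= T_tr - 1e-9 & az < T_tr + window_h - 1e-9)
  n_expect <- as.integer(round(window_h / bw_h))
  if (length(before) != n_expect || length(after) != n_expect)
    stop(sprintf("coverage error: %s window of day %d truncated by the recording edge",
                 transition, day))
  if (startle_correction) after <- after[-1]
  c(before_sum = sum(series$counts[before]),
    after_sum = sum(series$counts[after]))
}

#' Entrainment index
#'
#' EI = before / (before + after): the fraction of the activity in the 12 h
#' flanking a light transition that falls in the 6 h preceding it. Flies with
#' no activity in either window get `NA` and are excluded from percentages.
#' A fly counts as entrained when EI exceeds 0.75 strictly.
#'
#' @param before_sum,after_sum window sums from [window_sums()].
#' @return EI in `[0, 1]`, or `NA` when both sums are zero.
#' @export
entrainment_index <- function(before_sum, after_sum) {
  if (any(before_sum < 0) || any(after_sum < 0))
    stop("contract error: negative window sums")
  tot <- before_sum + after_sum
  ifelse(tot > 0, before_sum / tot, NA_real_)
}

#' Per-fly, per-day EI table
#'
#' Computes the EI of every fly at both transitions on each LD analysis day
#' (the last `regime$ld_analysis_days` recorded LD days). Lights-on windows
#' need the preceding evening, so the first recorded day is only usable for
#' lights-off.
#'
#' @param series_set list of annotated [activity_series()].
#' @param startle_correction passed to [window_sums()].
#' @param days LD day indices to analyze; defaults to the last
#'   `ld_analysis_days` recorded LD days.
#' @return data.frame: fly_id, genotype, transition, day, before_sum,
#'   after_sum, ei.
#' @export
ei_table <- function(series_set, startle_correction = TRUE, days = NULL) {
  if (inherits(series_set, "activity_series")) series_set <- list(series_set)
  regime <- attr(series_set[[1]], "regime")
  if (is.null(regime)) stop("series must be annotated")
  if (is.null(days))
    days <- seq(regime$n_ld_days - regime$ld_analysis_days + 1, regime$n_ld_days)
  rows <- list()
  for (s in series_set) {
    for (tr in c("lights_on", "lights_off")) {
      for (d in days) {
        if (tr == "lights_on" && d == 1) next  # no recorded evening before day 1
        ws <- window_sums(s, tr, d, startle_correction)
        rows[[length(rows) + 1]] <- data.frame(
          fly_id = s$fly_id, genotype = s$genotype, transition = tr, day = d,
          before_sum = ws[["before_sum"]], after_sum = ws[["after_sum"]],
          ei = entrainment_index(ws[["before_sum"]], ws[["after_sum"]]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Fraction of entrained flies per transition
#'
#' Averages each fly's daily EIs per transition over the analysis days, then
#' thresholds at EI > 0.75 (strict). Flies whose EI is undefined on every day
#' are excluded from the denominator.
#'
#' @param ei_df output of [ei_table()].
#' @param threshold entrainment threshold (default 0.75, strict inequality).
#' @return data.frame per transition (and genotype when several are present):
#'   n_entrained, n_total, percent, mean_ei, sd_ei.
#' @export
percent_entrained <- function(ei_df, threshold = 0.75) {
  if (is.null(ei_df) || !nrow(ei_df)) stop("empty EI table")
  agg <- stats::aggregate(ei ~ fly_id + genotype + transition, data = ei_df,
                          FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  agg <- agg[is.finite(agg$ei), , drop = FALSE]
  if (!nrow(agg)) stop("no fly with a defined EI")
  out <- do.call(rbind, lapply(split(agg, list(agg$genotype, agg$transition),
                                     drop = TRUE), function(g) {
    data.frame(genotype = g$genotype[1], transition = g$transition[1],
               n_entrained = sum(g$ei > threshold), n_total = nrow(g),
               percent = 100 * mean(g$ei > threshold),
               mean_ei = mean(g$ei), sd_ei = sd(g$ei))
  }))
  rownames(out) <- NULL
  out
}
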