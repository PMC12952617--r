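#' Model-implied occupancy of the active state over the day
#'
#' Builds the per-bin transition matrices of one 24-h cycle at the fly's
#' posterior-mode intercepts and returns, for every cycle position `k`, the
#' periodically stationary distribution: the solution of
#' \eqn{\delta_k = \delta_k \Gamma_k \Gamma_{k+1} \cdots \Gamma_{k+C-1}},
#' \eqn{\sum \delta_k = 1}. This is the model-implied probability of being in
#' the active state as a function of time of day. Successive positions are
#' propagated exactly via \eqn{\delta_{k+1} = \delta_k \Gamma_k}.
#'
#' @param fit an `hmm_fit` from [fit_hmm()], or an [hmm_spec()] (then `u`
#'   must be supplied directly).
#' @param fly_id fly whose intercepts to use (ignored when `u` is given).
#' @param u optional explicit intercept pair, overriding `fly_id`.
#' @return object of class `occupancy_curve`: data.frame with `zt` (hours,
#'   one cycle) and `p_active`, plus attributes `fly_id`.
#' @export
occupancy_curve <- function(fit, fly_id = NULL, u = NULL) {
  spec <- if (inherits(fit, "hmm_fit")) fit$spec else fit
  stopifnot(inherits(spec, "hmm_spec"))
  if (is.null(u)) {
    if (inherits(fit, "hmm_fit") && !is.null(fly_id)) {
      if (!fly_id %in% rownames(fit$u_hat)) stop("unknown fly: ", fly_id)
      u <- fit$u_hat[fly_id, ]
    } else u <- c(0, 0)
  }
  ncyc <- as.integer(round(spec$cycle * 60 / spec$bin_width))
  zt <- (seq_len(ncyc) - 1) * spec$bin_width / 60
  X <- trig_design(zt, spec$K, spec$cycle)
  eps <- 1e-6
  p12 <- plogis(drop(X %*% spec$beta12) + u[1])
  p21 <- plogis(drop(X %*% spec$beta21) + u[2])
  if (any(p12 <= 0 | p12 >= 1 | p21 <= 0 | p21 >= 1)) {
    warning("switching probabilities at 0/1; clipping")
    p12 <- pmin(pmax(p12, eps), 1 - eps)
    p21 <- pmin(pmax(p21, eps), 1 - eps)
  }
  delta <- matrix(0, ncyc, 2)
  delta[1, ] <- C_stationary(p12, p21)
  for (k in seq_len(ncyc - 1)) {
    d <- delta[k, ]
    delta[k + 1, ] <- c(d[1] * (1 - p12[k]) + d[2] * p21[k],
                        d[1] * p12[k] + d[2] * (1 - p21[k]))
  }
  out <- data.frame(zt = zt, p_active = delta[, 2])
  attr(out, "fly_id") <- fly_id %||% "population"
  class(out) <- c("occupancy_curve", "data.frame")
  out
}

#' Occupancy curves for every fitted fly
#'
#' @param fit an `hmm_fit`.
#' @param genotype label attached to the output rows.
#' @return long data.frame: fly_id, genotype, zt, p_active.
#' @export
occupancy_curves <- function(fit, genotype = "unknown") {
  ids <- rownames(fit$u_hat)
  do.call(rbind, lapply(ids, function(id) {
    oc <- occupancy_curve(fit, id)
    data.frame(fly_id = id, genotype = genotype, zt = oc$zt,
               p_active = oc$p_active)
  }))
}

# argmax of `value` over grid points whose zt lies within +/- half_window of
# center (circular); ties broken to the earliest time.
peak_in_window <- function(zt, value, center, half_window = 3, cycle = 24) {
  d <- abs((zt - center + cycle / 2) %% cycle - cycle / 2)
  idx <- which(d <= half_window + 1e-9)
  if (!length(idx)) stop("empty peak window")
  idx[which.max(value[idx])]
}

#' Between-individual SD of active-state occupancy at the peaks
#'
#' Peak times (morning and evening) are the argmax of the control genotype's
#' population-mean occupancy curve within +/- 3 h of lights-on and lights-off
#' (projected transitions in DD); the statistic is the between-fly SD of
#' `p_active` at those grid points, per genotype.
#'
#' @param curves long data.frame from [occupancy_curves()] (possibly several
#'   genotypes row-bound).
#' @param control_genotype name of the control genotype present in `curves`.
#' @param regime a [photo_regime()] (for the transition times).
#' @param segment `"LD"` or `"DD"` label attached to the output.
#' @return data.frame: genotype, segment, peak, peak_time, sd (proportion
#'   scale), n.
#' @export
occupancy_sd_at_peaks <- function(curves, control_genotype, regime,
                                  segment = "LD") {
  stopifnot(control_genotype %in% curves$genotype)
  ctrl <- curves[curves$genotype == control_genotype, ]
  mean_curve <- stats::aggregate(p_active ~ zt, data = ctrl, FUN = mean)
  mean_curve <- mean_curve[order(mean_curve$zt), ]
  if (max(mean_curve$p_active) - min(mean_curve$p_active) < 1e-12)
    warning("flat control curve; peak ties broken to earliest time")
  peaks <- c(morning = 0, evening = regime$photoperiod)
  rows <- list()
  for (p in names(peaks)) {
    k <- peak_in_window(mean_curve$zt, mean_curve$p_active, peaks[[p]])
    pt <- mean_curve$zt[k]
    for (g in unique(curves$genotype)) {
      sub <- curves[curves$genotype == g & abs(curves$zt - pt) < 1e-9, ]
      if (nrow(sub) < 2) stop("need >= 2 flies per genotype: ", g)
      rows[[length(rows) + 1]] <- data.frame(
        genotype = g, segment = segment, peak = p, peak_time = pt,
        sd = sd(sub$p_active), n = nrow(sub))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
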