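# Shared fixtures and independent oracles. Everything is generated in code;
# no binary data.

std_regime <- function(n_ld = 4, n_dd = 5)
  photo_regime(lights_on = 8, lights_off = 20, n_ld_days = n_ld,
               n_dd_days = n_dd, ld_analysis_days = min(3, n_ld),
               dd_analysis_days = n_dd)

t0_utc <- function(h = 8) as.POSIXct(sprintf("2024-01-01 %02d:00:00", h),
                                     tz = "UTC")

# counts -> annotated 30-min series spanning the regime
make_series <- function(counts, regime = std_regime(), bin_width = 30,
                        fly_id = "f1", genotype = "g") {
  s <- activity_series(counts, bin_width, t0_utc(regime$lights_on),
                       fly_id = fly_id, genotype = genotype)
  annotate_regime(s, regime)
}

# Independent oracle: HMM likelihood by explicit enumeration of all state
# paths (vectorized over the 2^T paths). Initial distribution from the
# eigen-decomposed product of one cycle of transition matrices.
brute_force_loglik <- function(counts, zt, spec, u = c(0, 0), bin_h = 0.5) {
  T <- length(counts)
  X <- circavar:::trig_design(zt, spec$K)
  p12 <- plogis(drop(X %*% spec$beta12) + u[1])
  p21 <- plogis(drop(X %*% spec$beta21) + u[2])
  ncyc <- as.integer(24 / bin_h)
  ztc <- (zt[1] + (seq_len(ncyc) - 1) * bin_h) %% 24
  Xc <- circavar:::trig_design(ztc, spec$K)
  q12 <- plogis(drop(Xc %*% spec$beta12) + u[1])
  q21 <- plogis(drop(Xc %*% spec$beta21) + u[2])
  M <- diag(2)
  for (k in seq_len(ncyc))
    M <- M %*% matrix(c(1 - q12[k], q12[k], q21[k], 1 - q21[k]), 2, 2,
                      byrow = TRUE)
  delta <- c(M[2, 1], M[1, 2]) / (M[1, 2] + M[2, 1])
  ld <- cbind(dnbinom(counts, size = spec$emissions$phi[1],
                      mu = spec$emissions$mu[1]),
              dnbinom(counts, size = spec$emissions$phi[2],
                      mu = spec$emissions$mu[2]))
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  pr <- delta[paths[, 1]] * ld[cbind(1, paths[, 1])]
  if (T > 1) for (t in 2:T) {
    G <- rbind(c(1 - p12[t - 1], p12[t - 1]), c(p21[t - 1], 1 - p21[t - 1]))
    pr <- pr * G[cbind(paths[, t - 1], paths[, t])] * ld[cbind(t, paths[, t])]
  }
  log(sum(pr))
}

# circular helpers for tests
circ_diff <- function(a, b) atan2(sin(a - b), cos(a - b))
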