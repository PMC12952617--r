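base_spec <- function(sigma_u = 0, K = 1,
                      beta12 = c(-2.5, 1, 0), beta21 = c(-1.5, 0, 0))
  hmm_spec(nb_params(c(0.5, 12), c(2, 5), "LD"), beta12, beta21,
           sigma_u = sigma_u, bin_width = 30)

short_series <- function(counts, offset = 0) {
  reg <- std_regime()
  s <- make_series(rep(0L, 9 * 48), reg)
  s <- circavar:::series_slice(s, offset + seq_along(counts))
  s$counts <- as.numeric(counts)
  s
}

test_that("forward log-likelihood equals brute-force path enumeration", {
  set.seed(13)
  spec <- base_spec()
  for (i in 1:25) {
    T <- sample(1:10, 1)
    x <- rnbinom(T, size = 2, mu = 3)
    u <- rnorm(2, 0, 0.7)
    off <- sample(0:150, 1)
    s <- short_series(x, off)
    f <- hmm_loglik(s, spec, u)
    b <- brute_force_loglik(x, s$zt, spec, u)
    expect_equal(f, b, tolerance = 1e-12)
  }
})

test_that("single-bin likelihood is the closed-form state mixture", {
  spec <- base_spec()
  s <- short_series(4)
  oc <- occupancy_curve(spec)                 # stationary at zt = 0
  delta <- c(1 - oc$p_active[1], oc$p_active[1])
  manual <- log(sum(delta * dnbinom(4, size = spec$emissions$phi,
                                    mu = spec$emissions$mu)))
  expect_equal(hmm_loglik(s, spec), manual, tolerance = 1e-12)
})

test_that("with identical emissions the transitions drop out", {
  em <- nb_params(c(5, 5 + 1e-12), c(3, 3), "LD")
  x <- c(2, 7, 4, 0, 9)
  s <- short_series(x)
  for (b12 in list(c(-2, 1, 0), c(0.3, -1, 2))) {
    spec <- hmm_spec(em, b12, c(-1, 0.5, -0.5), bin_width = 30)
    expect_equal(hmm_loglik(s, spec),
                 sum(dnbinom(x, size = 3, mu = 5, log = TRUE)),
                 tolerance = 1e-6)
  }
})

test_that("likelihood contributions are additive over duplicated flies", {
  set.seed(2)
  sim <- simulate_activity(sim_params(n_flies = 2, sigma_u = 0.5),
                           std_regime(), seed = 14)
  ser <- lapply(sim$series_set, function(s)
    circavar:::series_slice(s, s$segment == "LD"))
  spec0 <- list(K = 2, cycle = 24, bin_width = 30); class(spec0) <- "hmm_spec"
  em <- nb_params(c(0.5, 25), c(2, 10), "LD")
  tb <- circavar:::common_time_base(ser, spec0)
  X <- circavar:::trig_design(tb$zt, 2); Xc <- circavar:::trig_design(tb$ztc, 2)
  ddl <- lapply(ser, function(s) circavar:::emission_dens(s$counts, em))
  dl <- lapply(ddl, `[[`, "dens"); ls_ <- vapply(ddl, `[[`, 0, "logscale")
  gh <- gauss_hermite(7)
  par <- c(-4, 1, 0, 2, -3, -2, 0, 0, 3, 0, log(0.5))
  one <- circavar:::marginal_nll(par, dl, ls_, X, Xc, 5, gh)
  two <- circavar:::marginal_nll(par, c(dl, dl), c(ls_, ls_), X, Xc, 5, gh)
  expect_equal(two, 2 * one, tolerance = 1e-10)
})

test_that("occupancy has the closed form under constant switching", {
  em <- nb_params(c(0.5, 12), c(2, 5), "LD")
  spec <- hmm_spec(em, c(qlogis(0.3), 0, 0), c(qlogis(0.1), 0, 0))
  oc <- occupancy_curve(spec)
  expect_equal(nrow(oc), 48)
  expect_lt(max(abs(oc$p_active - 0.75)), 1e-12)
})

test_that("occupancy matches the explicit 48-matrix eigenvector oracle", {
  set.seed(31)
  for (i in 1:5) {
    beta12 <- c(rnorm(1, -2, 0.5), rnorm(2, 0, 1))
    beta21 <- c(rnorm(1, -1.5, 0.5), rnorm(2, 0, 1))
    u <- rnorm(2, 0, 0.8)
    spec <- base_spec(K = 1, beta12 = beta12, beta21 = beta21)
    oc <- occupancy_curve(spec, u = u)
    zt <- oc$zt
    X <- circavar:::trig_design(zt, 1)
    p12 <- plogis(drop(X %*% beta12) + u[1])
    p21 <- plogis(drop(X %*% beta21) + u[2])
    G <- lapply(1:48, function(k)
      rbind(c(1 - p12[k], p12[k]), c(p21[k], 1 - p21[k])))
    for (k in c(1, 17, 48)) {
      M <- Reduce(`%*%`, G[c(k:48, seq_len(k - 1))[1:48]])
      e <- eigen(t(M))
      v <- Re(e$vectors[, which.min(abs(e$values - 1))])
      v <- v / sum(v)
      expect_equal(oc$p_active[k], v[2], tolerance = 1e-10)
    }
    expect_true(all(oc$p_active >= 0 & oc$p_active <= 1))
  }
})

test_that("between-fly occupancy SD reduces to the two-point case", {
  curves <- data.frame(
    fly_id = rep(c("a", "b"), each = 48), genotype = "g",
    zt = rep((0:47) / 2, 2), p_active = rep(c(0.6, 0.8), each = 48))
  # a control with a mild peak at zt 0 to define peak times
  ctrl <- data.frame(fly_id = "c", genotype = "ctrl", zt = (0:47) / 2,
                     p_active = 0.5 + 0.1 * cos(2 * pi * (0:47) / 48))
  ctrl2 <- ctrl; ctrl2$fly_id <- "c2"
  vs <- occupancy_sd_at_peaks(rbind(curves, ctrl, ctrl2), "ctrl",
                              std_regime())
  g <- vs[vs$genotype == "g", ]
  expect_equal(g$sd, rep(sd(c(0.6, 0.8)), 2), tolerance = 1e-12)
  expect_equal(g$sd[1], 0.14142136, tolerance = 1e-6)
  # identical flies: SD exactly 0
  ctrl_sd <- vs[vs$genotype == "ctrl", "sd"]
  expect_equal(ctrl_sd, c(0, 0))
})

test_that("fit_emissions recovers a degenerate two-state truth in order", {
  set.seed(6)
  p <- sim_params(n_flies = 8, mu = c(6, 6 + 1e-9), phi = c(3, 3),
                  sigma_u = 0, kappa_phase = Inf, tau_sd = 0, startle = 0)
  sim <- simulate_activity(p, std_regime(2, 0), seed = 8)
  em <- fit_emissions(sim$series_set, "LD", K = 1, n_restarts = 2, seed = 1)
  expect_lte(em$mu[1], em$mu[2])
  expect_equal(em$mu[1], em$mu[2], tolerance = 0.35)
  expect_equal(mean(em$mu), 6, tolerance = 0.1)
})

test_that("sigma_u = 0 truth yields a boundary fit", {
  p <- sim_params(n_flies = 25, mu = c(0.5, 12), phi = c(2, 5),
                  beta12 = c(-2.5, 1, 0), beta21 = c(-1.5, 0, 0),
                  sigma_u = 0, kappa_phase = Inf, tau_sd = 0, startle = 0)
  sim <- simulate_activity(p, std_regime(4, 0), seed = 16)
  em <- nb_params(c(0.5, 12), c(2, 5), "LD")
  fit <- fit_hmm(sim$series_set, em, K = 1, n_restarts = 2, seed = 2)
  expect_lt(fit$spec$sigma_u, 0.1)
})

test_that("flat control curves trigger the tie-break warning", {
  flat <- do.call(rbind, lapply(c("a", "b"), function(id)
    data.frame(fly_id = id, genotype = "ctrl", zt = (0:47) / 2,
               p_active = 0.4)))
  expect_warning(occupancy_sd_at_peaks(flat, "ctrl", std_regime()), "flat")
})
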