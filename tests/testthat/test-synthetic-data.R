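test_that("simulation is bit-identical under the same seed", {
  p <- sim_params(n_flies = 3)
  reg <- std_regime()
  a <- simulate_activity(p, reg, seed = 5)
  b <- simulate_activity(p, reg, seed = 5)
  expect_identical(lapply(a$series_set, `[[`, "counts"),
                   lapply(b$series_set, `[[`, "counts"))
  expect_identical(a$true_states, b$true_states)
  expect_identical(a$true_intercepts, b$true_intercepts)
  c <- simulate_activity(p, reg, seed = 6)
  expect_false(identical(lapply(a$series_set, `[[`, "counts"),
                         lapply(c$series_set, `[[`, "counts")))
})

test_that("degenerate parameters are rejected", {
  expect_error(sim_params(sigma_u = -0.1), "sigma_u")
  expect_error(sim_params(kappa_phase = -1), "kappa_phase")
  expect_error(sim_params(mu = c(5, 2)))
  expect_error(simulate_activity(sim_params(), std_regime()), "seed")
})

test_that("no heterogeneity means identical switching curves across flies", {
  p <- sim_params(n_flies = 4, sigma_u = 0, kappa_phase = Inf, tau_sd = 0)
  sim <- simulate_activity(p, std_regime(), seed = 1)
  expect_true(all(sim$true_intercepts == 0))
  expect_true(all(sim$true_phases == 0))
  expect_equal(sim$true_periods, rep(p$tau_free, 4))
})

test_that("identical emission states give iid negative-binomial counts", {
  # mu1 = mu2, phi1 = phi2: the state process is irrelevant; check moments
  # against the closed form at n*T = 1e5 (needs mu2 > mu1, so use the raw
  # negative-binomial sampler through a two-state chain with equal mus via
  # an epsilon gap)
  mu <- 6; phi <- 3
  p <- sim_params(n_flies = 90, mu = c(mu, mu + 1e-9), phi = c(phi, phi),
                  startle = 0, sigma_u = 0, kappa_phase = Inf, tau_sd = 0)
  reg <- photo_regime(8, 20, 4, 20, 3, 20)   # 1152 bins/fly
  sim <- simulate_activity(p, reg, seed = 2)
  x <- unlist(lapply(sim$series_set, `[[`, "counts"))
  expect_gt(length(x), 1e5 - 1)
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(var(x), mu + mu^2 / phi, tolerance = 0.05)
})

test_that("dwell times are geometric under constant switching probabilities", {
  p12 <- 0.3; p21 <- 0.2
  p <- sim_params(n_flies = 20, beta12 = c(qlogis(p12), 0, 0),
                  beta21 = c(qlogis(p21), 0, 0), sigma_u = 0,
                  kappa_phase = Inf, tau_sd = 0, startle = 0)
  sim <- simulate_activity(p, std_regime(), seed = 3)
  runs <- unlist(lapply(sim$true_states, function(s) {
    r <- rle(s); r$lengths[r$values == 2][-1]   # active dwells, drop first
  }))
  expect_equal(mean(runs), 1 / p21, tolerance = 0.05)
  # geometric: sd ~= sqrt(1-p)/p
  expect_equal(sd(runs), sqrt(1 - p21) / p21, tolerance = 0.1)
})

test_that("simulated active fractions match the analytic occupancy curve", {
  p <- sim_params(n_flies = 150, sigma_u = 0, kappa_phase = Inf, tau_sd = 0,
                  startle = 0)
  sim <- simulate_activity(p, std_regime(), seed = 5)
  states <- do.call(rbind, sim$true_states)
  ld <- seq_len(4 * 48)
  zt <- sim$series_set[[1]]$zt[ld]
  frac <- tapply(colMeans(states[, ld] == 2), zt, mean)
  oc <- occupancy_curve(hmm_spec(nb_params(p$mu, p$phi, "LD"),
                                 p$beta12, p$beta21))
  expect_lt(max(abs(frac[as.character(oc$zt)] - oc$p_active)), 0.06)
})

test_that("startle spikes land exactly in the first post-transition bin", {
  p0 <- sim_params(n_flies = 5, startle = 0)
  p1 <- sim_params(n_flies = 5, startle = 50)
  reg <- std_regime()
  a <- simulate_activity(p0, reg, seed = 9)
  b <- simulate_activity(p1, reg, seed = 9)
  for (i in 1:5) {
    d <- b$series_set[[i]]$counts - a$series_set[[i]]$counts
    lt <- a$series_set[[i]]$light
    trans <- which(lt[-1] != lt[-length(lt)]) + 1L
    expect_true(all(d[trans] == 50))
    expect_true(all(d[-trans] == 0))
  }
})

test_that("luciferase simulation obeys its contract", {
  expect_error(simulate_luciferase(modulation = 1), "contract")
  a <- simulate_luciferase(seed = 4)
  b <- simulate_luciferase(seed = 4)
  expect_identical(a$cps, b$cps)
  # m = 0: pure decay; detrended residual vanishes
  d <- detrend_luminescence(bin_luminescence(
    simulate_luciferase(modulation = 0, noise_sd = 0, seed = 1), 30))
  expect_lt(max(abs(d$cps)), 1e-6)
})

test_that("intensity simulation hits its stated means", {
  s <- simulate_intensity(10, 15, sd = 1, n_a = 50, n_b = 50, seed = 8)
  # SE of the difference is sqrt(2/50) ~ 0.2; allow 3 sigma
  expect_lt(abs((mean(s$b) - mean(s$a)) - 5), 0.6)
  expect_warning(simulate_intensity(0, 0, 1, 1, 5, seed = 1), "size 1")
})
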