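#' Negative-binomial emission parameters
#'
#' Mean/dispersion parameterization with variance \eqn{\mu + \mu^2/\phi};
#' state 1 is "inactive", state 2 "active", ordered so that
#' `mu[1] < mu[2]`.
#'
#' @param mu length-2 means (counts/bin).
#' @param phi length-2 dispersions (`> 0`).
#' @param segment `"LD"` or `"DD"` (emissions are estimated separately).
#' @return object of class `nb_params`.
#' @export
nb_params <- function(mu, phi, segment = c("LD", "DD")) {
  segment <- match.arg(segment)
  stopifnot(length(mu) == 2, length(phi) == 2, all(phi > 0), all(mu >= 0))
  o <- order(mu)
  structure(list(mu = mu[o], phi = phi[o], segment = segment),
            class = "nb_params")
}

#' Specification of the periodic two-state activity HMM
#'
#' A two-state hidden Markov model for binned activity counts. The two
#' switching probabilities are logit-linear in `K` harmonics of time of day
#' (24-h cycle); per-fly random intercepts with common SD `sigma_u` act on
#' both switching logits; emissions are negative binomial per state.
#'
#' @param emissions an [nb_params()].
#' @param beta12,beta21 switching-logit coefficients, length `1 + 2K` each
#'   (inactive->active and active->inactive).
#' @param sigma_u random-intercept SD (`>= 0`).
#' @param bin_width bin width in minutes.
#' @param cycle cycle length in hours (24).
#' @return object of class `hmm_spec`.
#' @export
hmm_spec <- function(emissions, beta12, beta21, sigma_u = 0, bin_width = 30,
                     cycle = 24) {
  stopifnot(inherits(emissions, "nb_params"), sigma_u >= 0,
            length(beta12) == length(beta21), length(beta12) %% 2 == 1)
  structure(list(emissions = emissions, beta12 = beta12, beta21 = beta21,
                 K = (length(beta12) - 1) %/% 2, sigma_u = sigma_u,
                 bin_width = bin_width, cycle = cycle),
            class = "hmm_spec")
}

# Rescaled per-bin emission densities: each row of `dens` is
# exp(logdens - rowmax); `logscale` collects the removed constants. Keeps the
# C++ forward loop free of exp() without risking underflow.
emission_dens <- function(counts, emissions) {
  ld1 <- dnbinom(counts, size = emissions$phi[1], mu = emissions$mu[1], log = TRUE)
  ld2 <- dnbinom(counts, size = emissions$phi[2], mu = emissions$mu[2], log = TRUE)
  m <- pmax(ld1, ld2)
  list(dens = cbind(exp(ld1 - m), exp(ld2 - m)), logscale = sum(m))
}

# Shared time-base check; returns the observed zt vector and one full cycle
# of zt values starting at the first bin's phase (for the stationary init).
common_time_base <- function(series_set, spec) {
  zt <- series_set[[1]]$zt
  if (is.null(zt)) stop("series must be annotated")
  for (s in series_set)
    if (length(s$zt) != length(zt) || max(abs(s$zt - zt)) > 1e-9)
      stop("all series must share one time base")
  ncyc <- as.integer(round(spec$cycle * 60 / spec$bin_width))
  ztc <- (zt[1] + (seq_len(ncyc) - 1) * spec$bin_width / 60) %% spec$cycle
  list(zt = zt, ncyc = ncyc, ztc = ztc)
}

#' Conditional log-likelihood of one series under the periodic HMM
#'
#' Scaled forward recursion with time-varying transition matrices; the
#' initial distribution is the periodically stationary distribution at the
#' series' first bin (left eigenvector of the ordered product of one cycle of
#' transition matrices). `u` holds the fly's random intercepts on the two
#' switching logits.
#'
#' @param series annotated [activity_series()].
#' @param spec an [hmm_spec()].
#' @param u numeric length 2, random intercepts `(u12, u21)`.
#' @return log-likelihood (scalar); `-Inf` with a warning on underflow.
#' @export
hmm_loglik <- function(series, spec, u = c(0, 0)) {
  stopifnot(inherits(series, "activity_series"), inherits(spec, "hmm_spec"))
  tb <- common_time_base(list(series), spec)
  X <- trig_design(tb$zt, spec$K, spec$cycle)
  Xc <- trig_design(tb$ztc, spec$K, spec$cycle)
  dd <- emission_dens(series$counts, spec$emissions)
  ll <- C_cond_ll(dd$dens, dd$logscale,
                  drop(X %*% spec$beta12), drop(X %*% spec$beta21),
                  drop(Xc %*% spec$beta12), drop(Xc %*% spec$beta21),
                  u[1], u[2])
  if (!is.finite(ll)) warning("likelihood underflow: returning -Inf")
  ll
}

# Negative marginal log-likelihood for a parameter vector; densities fixed.
marginal_nll <- function(par, dens_list, logscales, X, Xc, npar_beta, gh,
                         estimate_sigma = TRUE) {
  nb <- npar_beta
  beta12 <- par[seq_len(nb)]
  beta21 <- par[nb + seq_len(nb)]
  sigma <- if (estimate_sigma) exp(par[2 * nb + 1]) else 0
  gh_use <- if (sigma > 0) gh else list(nodes = 0, weights = sqrt(pi))
  v <- C_marginal_nll(dens_list, logscales,
                      drop(X %*% beta12), drop(X %*% beta21),
                      drop(Xc %*% beta12), drop(Xc %*% beta21),
                      sigma, gh_use$nodes, gh_use$weights)
  if (!is.finite(v)) 1e10 else v
}

optim_restarts <- function(par0, fn, n_restarts, seed, scale = 0.5, ...) {
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    p0 <- if (r == 1) par0 else par0 + rnorm(length(par0), 0, scale)
    fit <- tryCatch(
      optim(p0, fn, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10), ...),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("fit error: no restart converged")
  best
}

#' Estimate emission parameters on control flies
#'
#' Maximizes the full HMM likelihood (random-intercept SD fixed at zero, `K`
#' harmonics active) over the emission and transition parameters on the
#' pooled control flies of one light segment, and returns the emission
#' component. State labels are fixed by construction (`mu` of the active
#' state is the inactive mean plus a positive offset). The full transition
#' fit is kept in attribute `transition_fit`.
#'
#' @param control_series list of annotated control [activity_series()],
#'   already restricted to the segment of interest.
#' @param segment `"LD"` or `"DD"` label stored on the result.
#' @param K number of harmonics (default 2).
#' @param bin_width bin width in minutes.
#' @param n_restarts random restarts for the optimizer.
#' @param seed integer seed (restart perturbations).
#' @return an [nb_params()] with attribute `transition_fit`
#'   (`list(beta12, beta21, logLik, convergence)`).
#' @export
fit_emissions <- function(control_series, segment = c("LD", "DD"), K = 2,
                          bin_width = 30, n_restarts = 5, seed = 1) {
  segment <- match.arg(segment)
  stopifnot(length(control_series) >= 1)
  spec0 <- list(K = K, cycle = 24, bin_width = bin_width)
  class(spec0) <- "hmm_spec"
  tb <- common_time_base(control_series, spec0)
  X <- trig_design(tb$zt, K)
  Xc <- trig_design(tb$ztc, K)
  counts_list <- lapply(control_series, `[[`, "counts")
  allx <- unlist(counts_list)
  ux <- sort(unique(allx))               # NB densities evaluated once per value
  idx_list <- lapply(counts_list, match, table = ux)
  nb <- 1 + 2 * K
  # moment-style initial values: low vs high activity split
  q <- quantile(allx, c(0.5, 0.9))
  mu1_0 <- max(mean(allx[allx <= q[1]]), 0.05)
  mu2_0 <- max(mean(allx[allx >= q[2]]), mu1_0 * 2 + 0.5)
  par0 <- c(log(mu1_0), log(mu2_0 - mu1_0), log(1), log(1),
            c(qlogis(0.1), rep(0, nb - 1)), c(qlogis(0.1), rep(0, nb - 1)))
  nll <- function(par) {
    mu1 <- exp(par[1]); mu2 <- mu1 + exp(par[2])
    phi <- exp(par[3:4])
    if (!all(is.finite(c(mu1, mu2, phi))) || mu2 > 1e6) return(1e10)
    ld1 <- dnbinom(ux, size = phi[1], mu = mu1, log = TRUE)
    ld2 <- dnbinom(ux, size = phi[2], mu = mu2, log = TRUE)
    m <- pmax(ld1, ld2)
    d1 <- exp(ld1 - m); d2 <- exp(ld2 - m)
    dens_list <- lapply(idx_list, function(ix) cbind(d1[ix], d2[ix]))
    logscales <- vapply(idx_list, function(ix) sum(m[ix]), 0)
    marginal_nll(par[-(1:4)], dens_list, logscales, X, Xc, nb, NULL,
                 estimate_sigma = FALSE)
  }
  best <- optim_restarts(par0, nll, n_restarts, seed, scale = 0.3)
  mu1 <- exp(best$par[1]); mu2 <- mu1 + exp(best$par[2])
  out <- nb_params(c(mu1, mu2), exp(best$par[3:4]), segment)
  attr(out, "transition_fit") <- list(
    beta12 = best$par[4 + seq_len(nb)],
    beta21 = best$par[4 + nb + seq_len(nb)],
    logLik = -best$value, convergence = best$convergence)
  out
}

#' Fit the random-intercept periodic HMM with frozen emissions
#'
#' Maximizes the marginal likelihood
#' \deqn{\sum_i \log \iint L_i(u_{12}, u_{21}) \phi(u; \sigma_u) \, du}
#' over the transition coefficients and `sigma_u` (log-parameterized), with
#' the double integral approximated by non-adaptive Gauss-Hermite quadrature
#' (`gh_nodes` per dimension). Emissions are frozen (estimated on controls
#' via [fit_emissions()]), which keeps state meaning comparable across
#' genotypes. Posterior-mode intercepts are obtained per fly by a 2-D
#' optimization at the MLE.
#'
#' @param series_set list of annotated [activity_series()] sharing one time
#'   base (one light segment).
#' @param emissions frozen [nb_params()].
#' @param K harmonics on each switching logit (default 2).
#' @param gh_nodes Gauss-Hermite nodes per dimension (default 7).
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @param sigma_init initial value for `sigma_u`.
#' @return object of class `hmm_fit`: `spec` (an [hmm_spec()] at the MLE),
#'   `logLik`, `u_hat` (n x 2, rownames = fly ids), `boundary` (TRUE when
#'   `sigma_u` collapsed below 1e-4), `convergence`, `seed`.
#' @export
fit_hmm <- function(series_set, emissions, K = 2, gh_nodes = 7,
                    n_restarts = 5, seed = 1, sigma_init = 0.5) {
  stopifnot(inherits(emissions, "nb_params"), length(series_set) >= 1)
  spec0 <- list(K = K, cycle = 24, bin_width = series_set[[1]]$bin_width)
  class(spec0) <- "hmm_spec"
  tb <- common_time_base(series_set, spec0)
  X <- trig_design(tb$zt, K)
  Xc <- trig_design(tb$ztc, K)
  ddl <- lapply(series_set, function(s) emission_dens(s$counts, emissions))
  dens_list <- lapply(ddl, `[[`, "dens")
  logscales <- vapply(ddl, `[[`, 0, "logscale")
  gh <- gauss_hermite(gh_nodes)
  nb <- 1 + 2 * K
  tf <- attr(emissions, "transition_fit")
  b12_0 <- if (!is.null(tf) && length(tf$beta12) == nb) tf$beta12 else
    c(qlogis(0.1), rep(0, nb - 1))
  b21_0 <- if (!is.null(tf) && length(tf$beta21) == nb) tf$beta21 else
    c(qlogis(0.15), rep(0, nb - 1))
  par0 <- c(b12_0, b21_0, log(sigma_init))
  nll <- function(par) marginal_nll(par, dens_list, logscales, X, Xc, nb, gh)
  best <- optim_restarts(par0, nll, n_restarts, seed, scale = 0.4)
  beta12 <- best$par[seq_len(nb)]
  beta21 <- best$par[nb + seq_len(nb)]
  sigma <- exp(best$par[2 * nb + 1])
  boundary <- sigma < 1e-4
  spec <- hmm_spec(emissions, beta12, beta21, sigma_u = sigma,
                   bin_width = spec0$bin_width)
  eta12 <- drop(X %*% beta12); eta21 <- drop(X %*% beta21)
  eta12c <- drop(Xc %*% beta12); eta21c <- drop(Xc %*% beta21)
  u_hat <- matrix(0, length(series_set), 2,
                  dimnames = list(vapply(series_set, `[[`, "", "fly_id"),
                                  c("u12", "u21")))
  if (!boundary) {
    for (i in seq_along(series_set)) {
      post <- function(u)
        -(C_cond_ll(dens_list[[i]], logscales[i], eta12, eta21,
                    eta12c, eta21c, u[1], u[2]) +
            sum(dnorm(u, 0, sigma, log = TRUE)))
      u_hat[i, ] <- optim(c(0, 0), post, method = "BFGS",
                          control = list(maxit = 200))$par
    }
  }
  structure(list(spec = spec, logLik = -best$value, u_hat = u_hat,
                 boundary = boundary, convergence = best$convergence,
                 n_flies = length(series_set), seed = seed),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("hmm_fit: %d flies, K=%d harmonics, sigma_u=%.3f%s, logLik=%.1f\n",
              x$n_flies, x$spec$K, x$spec$sigma_u,
              if (x$boundary) " (boundary)" else "", x$logLik))
  invisible(x)
}
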