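---
title: "circavar: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circavar: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
fits, the estimators it uses, the places where the method was genuinely
open and a choice had to be made, and what a green test suite does and does
not establish.

# The problem

A population of flies can have a perfectly normal *average* circadian
phenotype — normal free-running period, normal percent rhythmic, normal
mean activity profile — while individuals diverge from one another: each
fly is active at its own times, or drifts to its own free-running phase.
Detecting that *inter-individual variability* requires statistics defined
at the level of the individual and then summarized as dispersion across
individuals. `circavar` implements four such instruments: the entrainment
index, a random-intercept hidden Markov model of activity, circular
phase-coherence statistics, and rhythmicity scoring, plus wavelet period
estimation for bioluminescence reporters and bootstrap estimation
statistics for staining intensities.

# Data model

Activity arrives as per-minute beam-crossing counts in the common
DAM2/DAMSystem3 text dialect (42 tab-separated columns; counts in columns
11–42). Counts are summed into analysis bins — **30 min by default**. The
source protocols do not state the activity bin width; 30 min matches the
luminescence binning used alongside and standard actogram practice, and
every stage takes the width as a parameter. Each bin is annotated with
Zeitgeber time (`zt = 0` at lights-on), light flag, and segment (LD or DD).
In DD, circadian time is anchored to the last actual lights-on and
projected forward in 24-h cycles, so "morning" and "evening" remain
well-defined. Missing minutes are an error by default; zero-filling is an
explicit option (`fill_gaps = TRUE`), because silent imputation corrupts
count statistics.

# Entrainment index

For a transition at time $t$ (lights-on or lights-off) on one LD day,

$$\mathrm{EI} = \frac{\sum_{[t-6h,\,t)} x}{\sum_{[t-6h,\,t)} x + \sum_{[t,\,t+6h)} x},$$

computed on bin starts. A fly is *synchronized* when $\mathrm{EI} > 0.75$,
strictly — 0.75 itself does not count. Open details resolved here:

- **Startle correction.** The underlying protocol corrects for the
  reflexive startle response to a light change but does not say how. We
  exclude exactly the first post-transition bin from the after-window
  (`startle_correction = TRUE`). This is minimal, auditable, and provably
  makes EI invariant to any activity added solely to that bin.
- **Aggregation over days.** One EI per fly per transition is obtained by
  averaging the daily EIs over the LD analysis days (the last three
  recorded LD days by default) and thresholding the average. Whether the
  original analysis averaged over days or pooled counts is unstated;
  day-averaging is the simplest choice consistent with one value per fly.
- Flies with zero activity in both windows have undefined EI and are
  excluded from the percentage denominator.

# The periodic two-state HMM

Binned counts $x_{i,t}$ of fly $i$ are modelled as a 2-state hidden Markov
chain (state 1 inactive, state 2 active) with negative-binomial emissions
parameterized by mean and dispersion, $\mathrm{Var} = \mu_j + \mu_j^2/\phi_j$,
and time-varying switching probabilities

$$\mathrm{logit}\,\gamma^{12}_i(t) = \beta^{12}_0 + \sum_{k=1}^{K}
  \left(a^{12}_k \cos\tfrac{2\pi k t}{24} + b^{12}_k \sin\tfrac{2\pi k t}{24}\right) + u^{12}_i,$$

and symmetrically for $\gamma^{21}$. The random intercepts
$u^{12}_i, u^{21}_i \sim N(0, \sigma_u^2)$ are independent with a single
shared $\sigma_u$ (parsimony; the shared-variance restriction is part of
the model definition). Choices the model description leaves open, and how
they were resolved:

- **Harmonic order `K = 2` by default.** "A function of time of day" needs
  a basis; two harmonics capture the bimodal crepuscular day with 10
  transition parameters total. `K` is an argument everywhere.
- **Link: logit.** Standard, unconstrained, and the natural scale for
  Gaussian intercepts.
- **Initial distribution = periodically stationary law at the first bin**
  — the left eigenvector of the ordered product of one cycle of transition
  matrices. This is consistent with the occupancy construct below and adds
  no free parameter.
- **Quadrature.** The marginal likelihood integrates $(u^{12}, u^{21})$ by
  non-adaptive Gauss–Hermite quadrature with 7 nodes per dimension (49
  points). Deterministic, smooth in the parameters, and accurate for the
  unimodal integrands that arise here.
- **Optimization.** BFGS on unconstrained transforms ($\log \sigma_u$,
  $\log$ dispersions, raw logit coefficients), with seeded random restarts.
  $\hat\sigma_u < 10^{-4}$ is reported as a boundary fit, not an error.
- **Label order** is fixed structurally: the active mean is parameterized
  as the inactive mean plus a positive offset, so there is no label
  switching to resolve.
- **Control-frozen emissions.** Emission parameters are estimated on the
  control genotype only (full likelihood with $\sigma_u = 0$), separately
  for LD and DD, and then frozen when fitting the other genotypes. This
  keeps the meaning of "active" identical across genotypes — the entire
  point of comparing their occupancy statistics.

The forward algorithm runs in C++ with pre-exponentiated, row-rescaled
emission densities and lazy renormalization, making a 100-fly fit a matter
of seconds. Its correctness is pinned by a brute-force path-enumeration
oracle on series of length ≤ 10 (relative error < 1e-10).

## Occupancy and the variability statistic

For each fly, using its posterior-mode intercepts $\hat u_i$, the 48
per-bin transition matrices of one cycle give the periodically stationary
distribution at every cycle position:
$\delta_k = \delta_k \Gamma_k \Gamma_{k+1} \cdots \Gamma_{k+47}$. The
active coordinate of $\delta_k$ is the model-implied probability of being
active at that time of day. Successive positions obey
$\delta_{k+1} = \delta_k \Gamma_k$, which is how the curve is computed
(the eigen construction is kept as a test oracle). Peak times are the
argmax of the **control** population-mean curve within ±3 h of lights-on
(morning) and lights-off (evening), projected transitions in DD; the
variability statistic is the between-fly SD of $p_{\mathrm{active}}$ at
those grid points, reported on the proportion scale. Whether the original
occupancy statistic used the periodically stationary law or smoothed state
probabilities is unstated; the stationary law is the construct tested
here, and it is what the simulator/estimator consistency property checks.

# Phase coherence in DD

Per fly, the daily activity peak on DD days 2 and 3 is extracted by
zero-phase second-order Butterworth low-pass filtering (cutoff period 4 h)
of the day's 48 bins with circular edge handling, then taking the argmax
(bin midpoints); the fly's phase is the circular mean of the two daily
phases, $\theta = 2\pi\,\mathrm{zt}/24$. The original toolbox's peak
algorithm is unstated; the smoother is exposed as a strategy option
(`smoother = "none"` gives the raw argmax) so alternatives can be swapped
without touching the statistics. Arrhythmic flies are excluded before any
phase is computed — the pipeline enforces this globally.

Group-level statistics: mean direction $\mu$, resultant length $\bar R$,
circular SD $= \sqrt{-2\ln\bar R}$, ML concentration $\hat\kappa$
($A(\kappa)=\bar R$ inverted by the standard three-regime approximation
plus Newton steps on exact Bessel ratios), circular median (candidate data
points, minimal mean arc distance), and **coherence $= 1/\mathrm{SD}$**. A
fully coherent sample ($\bar R = 1$) reports coherence as a flagged
infinity rather than a capped number: plots may cap, data do not.

- **Watson's $U^2$** against the fitted Von Mises uses parametric-bootstrap
  p-values (refit + recompute per bootstrap sample, B = 1000, seeded)
  instead of printed critical-value tables; type-I error calibrates to
  5% ± 2 points in the acceptance suite.
- **Equal-concentration tests** use the classical three-regime
  variance-stabilizing construction selected by the weighted pooled
  resultant length (< 0.45, 0.45–0.70, > 0.70); two-sided p-values,
  Bonferroni across pairs. Note the low-$\bar R$ transform
  $g_1(2\bar R) = \arcsin(2\bar R\sqrt{3/8})$ has asymptotic variance
  $3/(4(n-4))$ — we verified this empirically (printed versions of the
  constant differ across secondary sources) and the mid/high regimes
  calibrate at nominal level, while the low regime is mildly conservative
  (~2–3% at $\kappa = 0.6$), a known property of the transform.

# Rhythmicity

A functional substitute for the external toolbox the original analysis
delegated to (whose exact criterion is unpublished): the mean-subtracted,
biased-normalized autocorrelogram of the DD counts up to 60 h lag. The
period $\tau$ is the parabolic-interpolated lag of the highest correlogram
peak in 18–30 h — localized on the *unbiased-corrected* correlogram
($\times N/(N-k)$), because the biased estimator's triangular envelope
otherwise drags the interpolated peak to shorter lags. The rhythm index RI
is the height (biased scale) of the third correlogram peak, i.e. the local
maximum near lag $2\tau$; rhythmic strength $\mathrm{RS} =
\mathrm{RI}/(2/\sqrt N)$ scales RI by the white-noise 95% line, and a fly
is rhythmic iff a circadian peak exists and $\mathrm{RS} \ge 1.5$ (the
conventional cutoff; 1.0 is available). Arrhythmic flies carry a missing
period. For a noiseless 24-h cosine over 5 days of 30-min bins the closed
form gives $\mathrm{RI} = (1 - 96/240) = 0.6$ and $\mathrm{RS} = 4.65$ —
the test suite pins both. A Lomb–Scargle cross-check was considered and
dropped: the correlogram peak with parabolic interpolation already meets
the ±0.25 h recovery tolerance and one estimator is easier to audit.

# Bioluminescence wavelet analysis

Raw counts-per-second traces (4-min resolution) are binned to 30 min by
time window, detrended in two transparent steps — divide by
$A e^{-t/\lambda}$ fitted by least squares on the log of a 24-h running
mean (fitted on interior points only, where the running mean of an
exponential is an exact constant multiple of it), then subtract a 24-h
centered moving average — and analyzed with a continuous Morlet transform
($\omega_0 = 6$, the standard time/frequency trade-off) on a 64-point
log-spaced period grid in 16–32 h. The ridge is the power-maximizing
period per time point. **Cone-of-influence policy:** a time point
contributes to the ridge only when *every* scale in the band lies inside
its cone of influence there ($\sqrt 2\, s$ e-folding). The laxer
per-scale exclusion was tried first and rejected: near the record edges it
forces the argmax onto the shortest admissible period and corrupts the
ridge ends. The summary period is the median over ridge points. The
original scripts' wavelet parameters are not published; these defaults are
labelled substitutes and all are arguments.

# Estimation statistics

Two-group mean differences are reported with a percentile bootstrap 95% CI
(group-wise resampling, B = 5000, seeded). BCa was considered; at the
sample sizes involved (n ≈ 10–30 per group) the difference is immaterial
and the percentile interval is the simplest reproducible choice. Coverage
calibrates to 95% ± 2 points over 500 null experiments in the acceptance
suite.

# The synthetic world

`simulate_activity()` is the generative mirror of the fitted model plus
the three field artifacts the analysis must survive: startle spikes (a
fixed extra count in exactly the first bin after each light transition —
giving the EI startle correction something concrete to remove), per-fly
phase dispersal (a Von Mises-distributed circular shift of the harmonic
covariate), and per-fly period dispersal in DD (a time dilation of the
covariate clock, LD stays locked to the Zeitgeber). Truth (states,
intercepts, phases, periods) is returned alongside the series, and
identical seeds reproduce datasets bit-exactly.

Default parameters were chosen **once** to make the default cohort behave
like a well-entrained control strain, and are not revisited: emissions
0.5/25 counts per 30-min bin (dispersions 2/10), activation peaked 3.5 h
before each transition (second harmonic, amplitude 4, intercept −4) with a
first-harmonic bias making the evening bout dominant, deactivation peaked
at the transitions (amplitude 3, intercept −2), $\sigma_u = 0.3$,
$\kappa_{\mathrm{phase}} = 50$, $\tau = 23.8 \pm 0.2$ h, startle 20
counts. Under these defaults a 30-fly cohort shows mean EI ≈ 0.85–0.95
with ~80–100% synchronized (mornings weaker than evenings, as in real
control data), ~90% rhythmic at RS ≥ 1.5, and a ~23.8 h free-running
period. "Mutant-like" cohorts are obtained by raising $\sigma_u$ and/or
lowering $\kappa_{\mathrm{phase}}$.

What the generator does **not** emulate — and hence what a green test does
not establish: mortality and age effects, sex differences, sleep
micro-architecture beyond the 2-state process, light masking beyond a
constant dark-bin multiplier, and inter-day non-stationarity other than
free-running drift. Two consequences worth knowing:

- Single-day peak extraction on the stochastic bout process carries ~1 h
  of intrinsic jitter even at high signal-to-noise; per-fly phases are
  accurate to that level, not to one bin. The phase-recovery test asserts
  tracking well beyond the noise floor (correlation > 0.8 with the true
  offsets), not sub-bin accuracy.
- With a symmetric crepuscular profile the peak-picker can alternate
  between the morning and evening bouts (12 h apart), deflating measured
  coherence. The default world makes the evening bout dominant for this
  reason; strongly bimodal genotypes would need a peak-window strategy
  (the `smoother`/strategy hook exists for that).

# Numerics, seeds, degenerate inputs

- Every stochastic routine takes an explicit seed; the pipeline derives
  stage seeds deterministically from the master seed (`child_seed()`), so
  whole reports are byte-reproducible.
- Switching probabilities exactly at 0/1 in the occupancy construction are
  clipped to $[10^{-6}, 1-10^{-6}]$ with a warning; likelihood underflow
  returns $-\infty$ (conditional) or a large penalty (inside the
  optimizer).
- Degenerate circular samples: $\bar R = 1$ flags coherence infinite;
  $\bar R = 0$ gives $\kappa = 0$; Watson's test refuses the degenerate
  repeated-value sample with a flag rather than a fake p-value.
- Flat control occupancy curves break peak ties to the earliest time with
  a warning; constant activity series are a zero-variance error in the
  correlogram.
- The acceptance suite scales the heaviest stated designs only where the
  statement allows it ("scaled replicates"): bootstrap coverage uses
  B = 1000 per experiment (the criterion fixes the number of experiments,
  not B), and the variability-ordering criterion runs its 20 replicates at
  the stated 100 flies with single-restart fits.

# Known limitations

- The equal-concentration low-$\bar R$ regime is mildly conservative; for
  strongly dispersed groups the mid/high regimes (where the source data
  live) are the calibrated ones.
- The rhythmicity module is an explicitly labelled substitute for an
  unpublished toolbox criterion; absolute RS values are comparable within
  this package only.
- The wavelet ridge discards ~44 h at each record edge under the strict
  cone-of-influence policy; records shorter than ~4 days yield few ridge
  points.
- EI day-aggregation and the startle-exclusion width are decisions, not
  reproductions; both are isolated behind arguments.
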