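# circavar

Quantifying **inter-individual variability in circadian locomotor
behaviour** of *Drosophila* from beam-crossing recordings (TriKinetics
DAM2-style monitors), with companion tools for bioluminescence period
estimation and estimation statistics.

Classical circadian summaries (mean activity profiles, percent rhythmic,
period) can look normal while a population is falling apart *between*
individuals: every fly keeps a clock, but each one runs at its own phase, or
drifts in and out of the active state at its own times. `circavar`
implements the quantitative machinery for detecting exactly that kind of
phenotype:

- **Entrainment Index (EI).** For each light transition, the fraction of
  activity in the 6 h before the transition relative to the 12 h flanking
  it: `EI = before / (before + after)`, with an optional startle correction
  that drops the first post-transition bin. A fly is *synchronized* when
  `EI > 0.75` (strict).
- **Periodic 2-state hidden Markov model.** Binned counts arise from an
  inactive/active chain with negative-binomial emissions (variance
  `mu + mu^2/phi`), switching probabilities
  `logit γ12(t) = β0 + Σ_k a_k cos(2πkt/24) + b_k sin(2πkt/24) + u12`
  (same for `γ21`), and per-fly random intercepts
  `u12, u21 ~ N(0, σ_u²)` with one shared `σ_u`. Emissions are estimated on
  the control genotype only and then frozen for all genotypes, so the
  meaning of "active" is comparable between groups. The marginal likelihood
  integrates the intercepts by 7×7 Gauss–Hermite quadrature; the forward
  algorithm runs in C++.
- **Model-implied occupancy.** For every fly, the periodically stationary
  distribution `δ_k = δ_k Γ_k Γ_{k+1} … Γ_{k+C-1}` gives the probability of
  being active as a function of time of day; the **between-fly SD of
  occupancy at the morning and evening peaks** (peak times from the control
  mean curve) is the headline variability statistic.
- **Phase coherence.** Per-fly activity-peak phases on the second and third
  days of constant darkness (arrhythmic flies excluded), summarized by the
  circular mean/median, resultant length `R̄`, circular
  `SD = sqrt(-2 ln R̄)`, ML Von Mises concentration `κ`, and coherence
  `1/SD`; Watson's goodness-of-fit test (parametric bootstrap p-values) and
  pairwise equal-`κ` tests with Bonferroni adjustment.
- **Rhythmicity.** Autocorrelogram-based: period from the circadian
  correlogram peak (parabolic interpolation), rhythm index RI = height of
  the third correlogram peak (lag ≈ 2τ), rhythmic strength
  `RS = RI / (2/sqrt(N))`, rhythmic ⇔ `RS ≥ 1.5`.
- **Bioluminescence.** 30-min binning, exponential-decay normalization plus
  24-h moving-average detrending, and Morlet (ω0 = 6) continuous-wavelet
  ridge period estimation in a 16–32 h band with cone-of-influence
  exclusion.
- **Estimation statistics.** Two-group mean difference with a percentile
  bootstrap 95% CI.
- **Synthetic data.** A seeded generator (`sim_params()`,
  `simulate_activity()`, `simulate_luciferase()`, `simulate_intensity()`)
  produces cohorts with known states, intercepts, phases and periods, so
  every stage is testable without external recordings.

## Worked example

Simulate a control-like cohort against a "variable" genotype (larger
random-intercept SD, dispersed phases) and run both analysis arms:

```r
library(circavar)
regime <- photo_regime(lights_on = 8, lights_off = 20,
                       n_ld_days = 4, n_dd_days = 5)
cfg <- analysis_config(
  genotypes = list(
    iso = sim_params(n_flies = 20, genotype = "iso"),
    hsp = sim_params(n_flies = 20, sigma_u = 1.2, kappa_phase = 1,
                     genotype = "hsp")),
  control = "iso", regime = regime, seed = 42, n_restarts = 1)
ld <- run_ld_analysis(cfg)
ld$entrained
#>   genotype transition n_entrained n_total percent mean_ei  sd_ei
#> 1      hsp lights_off           6      20      30   0.575 0.2718
#> 2      iso lights_off          20      20     100   0.965 0.0156
#> 3      hsp  lights_on           4      20      20   0.458 0.2827
#> 4      iso  lights_on          14      20      70   0.801 0.1534
ld$hmm$variability
#>   genotype segment    peak peak_time    sd  n
#> 1      iso      LD morning        22 0.041 20
#> 2      hsp      LD morning        22 0.101 20
#> 3      iso      LD evening         9 0.021 20
#> 4      hsp      LD evening         9 0.131 20
```

The control concentrates its activity ahead of both transitions (mean EI
0.97/0.80, 100%/70% synchronized) while the variable genotype does not —
and the between-fly SD of active-state occupancy at both peaks is 2–6×
larger in the variable genotype, even though its *average* rhythmicity is
untouched:

```r
dd <- run_dd_analysis(cfg)
dd$rhythm_summary
#>     genotype  n percent_rhythmic period_mean period_sem rs_mean rs_sem
#> hsp      hsp 20               80        23.8      0.109    2.24 0.0937
#> iso      iso 20               80        23.8      0.099    2.30 0.1213
```

Phase coherence on clean Von Mises samples (n = 60 each):

```r
set.seed(7)
tight <- rvonmises(60, mu = pi, kappa = 8)
loose <- rvonmises(60, mu = pi, kappa = 1)
circular_summary(tight)
#> circular_summary: n=60, mu=3.186 rad, median=3.239 rad, Rbar=0.928,
#>   SD=0.387 rad, kappa=7.204, coherence=2.582
circular_summary(loose)
#> circular_summary: n=60, mu=2.787 rad, median=2.850 rad, Rbar=0.430,
#>   SD=1.299 rad, kappa=0.955, coherence=0.770
equal_kappa_test(tight, loose)
#> equal_kappa: statistic=6.437, p=1.215e-10 (n=60/60)
```

Bioluminescence period estimation and estimation statistics:

```r
luc <- simulate_luciferase(period = 23.6, modulation = 0.3, noise_sd = 20,
                           duration = 9, seed = 2)
wavelet_period(detrend_luminescence(bin_luminescence(luc, 30)))
#> wavelet_result 'luc_seed2': median period 23.52 h over 256 ridge points
#>   (band 16-32 h)

s <- simulate_intensity(100, 120, sd = 15, n_a = 12, n_b = 12, seed = 3)
bootstrap_mean_diff(s$a, s$b, n_boot = 5000, seed = 11)
#> mean difference 17.95 [95% bootstrap CI 8.91, 27.52] (n=12 vs 12, B=5000)
```

## Command line

A thin CLI is installed under `exec/`:

```sh
circavar run --config analysis.json --out results/
circavar ei --dam Monitor1.txt --channels 1,2,3 --lights-on 8 --lights-off 20
circavar rhythm --dam Monitor1.txt --channels 1,2,3 --rs-threshold 1.5
circavar wavelet --in sample.csv --band 16,32 --bin 30
circavar esdiff --a a.csv --b b.csv --boot 5000 --seed 11
```

Configs are JSON (see `read_analysis_config()` for the layout).

## Documentation

The methods vignette (`vignettes/circavar-methods.Rmd`) describes the
model, the estimation choices, what the synthetic generator does and does
not emulate, and known limitations.
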