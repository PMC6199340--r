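# autoshift

Screening multivariate time series for **long-lived changes in
autodependency** — the lag-1 serial dependence of each variable on itself.
In affect research this quantity is emotional inertia, and sustained shifts
in it are conjectured to precede critical events such as relapse into
depression; analogous shifts mark epileptic seizures in EEG and volcanic
eruptions in seismic signals. `autoshift` is for analysts of intensive
longitudinal data (experience sampling, physiological monitoring) who need
to ask: *did the autocorrelation of this system change somewhere, and
when?*

Two complementary detectors are implemented, both targeting the
piecewise-stationary diagonal VAR(1) model
`X_i = α + diag(φ) X_{i-1} + ε_i`, `ε_i ~ MVN(0, Σ)`:

* **KCP-AR** — kernel change point detection applied to *running
  autocorrelations*. A window slides across the series; within each
  window the lag-1 autocorrelation of every variable is computed; the
  derived series is segmented by exact dynamic-programming minimization of
  a Gaussian-kernel variance criterion `R̂_min,K`. The number of change
  points is decided by a variance-drop permutation test (reshuffling the
  raw series and recomputing everything) followed by a penalty grid search
  over the coefficient `C` in
  `pen_K = C · v_max · (K+1)/w · [1 + log(w/(K+1))]`.
* **Regime-switching AR(1)** — maximum-likelihood estimation of the same
  observation equation with a hidden first-order Markov chain over the
  autoregression vector `φ^r` (intercepts fixed at zero, innovation
  covariance shared, by default). The exact filtered likelihood is
  maximized by ECM with multistart; the number of regimes is chosen by AIC
  and BIC, and occasions are assigned to regimes by their posterior
  probabilities.

A phase-structured simulator (`simulate_phase_var1()`, `toy_design()`,
`study_grid()`, `null_design()`) and an evaluation harness
(`rand_index()`, `run_study()`, `summarize_study()`) support power and
type-I-error studies of both detectors.

## Worked example

Three variables, three phases of 100 occasions, per-variable
autocorrelation 0 → 0.5 → 0 (true change points at t = 101 and 201):

```r
library(autoshift)

sim <- simulate_phase_var1(toy_design(), seed = 11)
fit <- kcp_ar(sim, window = 25, kmax = 10, n_perm = 500, seed = 11)
fit
#> KCP-AR change point analysis
#>   windows: 276 (size 25)   permutations: 500
#>   variance-drop test: statistic = 0.1333, p = 0.003992
#>   selected K = 2; change points at t = 110, 208
```

The permutation test rejects (p ≈ 0.004), the grid search keeps K = 2, and
the detected change points land within ten occasions of the truth. The
auxiliary per-phase autocorrelations recover the generating levels
(≈ 0 / 0.5 / 0):

```r
tidy(fit)
#> # A tibble: 9 × 5
#>   phase start   end variable autocorrelation
#> 1     1     1   109 X1               -0.180
#> 4     2   110   207 X1                0.524
#> 5     2   110   207 X2                0.564
#> 7     3   208   300 X1               -0.0320
#> ...
```

The regime-switching route reaches the same conclusion — two regimes, with
`φ` near 0 in one and near 0.5 in the other:

```r
sel <- select_regimes(sim, regimes = 1:3, seed = 11)
sel
#> Regime number selection
#>   regimes   loglik n_params     aic     bic converged
#> 1       1 -1299.59        9 2617.19 2650.49      TRUE
#> 2       2 -1267.69       14 2563.39 2615.19      TRUE
#> 3       3 -1265.23       21 2572.47 2650.18      TRUE
#> AIC chooses R = 2; BIC chooses R = 2

round(sel$best_aic$phi, 2)
#>         X1   X2   X3
#> [1,] -0.09 0.02 0.05
#> [2,]  0.58 0.59 0.57
```

`autoplot()` methods draw the running autocorrelations with detected
change points, posterior regime paths, and AIC/BIC curves; `glance()`
returns one-row fit summaries. For experience-sampling data with missed
beeps and overnight gaps, preprocess with `lag1_filter()` and
`winsorize_3sd()` before analysis. A thin command-line wrapper lives at
`inst/cli/autoshift.R` (`simulate`, `preprocess`, `kcp-ar`, `rsar`,
`study` subcommands).

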