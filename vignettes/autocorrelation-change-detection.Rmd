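---
title: "Detecting long-lived autocorrelation changes: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long-lived autocorrelation changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoshift)
```

## The problem

Many monitored systems — affective states sampled by experience-sampling
beeps, EEG channels, seismic signals — change not in their mean or variance
but in their *autodependency*: how strongly each variable is predicted by
its own previous value. In affect research this lag-1 serial dependence is
called emotional inertia, and long-lived shifts in it are conjectured to
precede critical events such as relapse into depression. `autoshift`
implements two complementary detectors of such shifts in a multivariate
series, together with the simulator and evaluation harness needed to study
their operating characteristics.

Both detectors target the same generative picture: a diagonal VAR(1)
process

$$X_i = \alpha + \mathrm{diag}(\phi)\, X_{i-1} + \varepsilon_i,
  \qquad \varepsilon_i \sim \mathcal N(0, \Sigma),$$

whose autoregression vector $\phi$ is piecewise constant in time (KCP-AR)
or switches between hidden regimes (the regime-switching model).

## KCP-AR: kernel change point detection on running autocorrelations

Kernel change point detection pools successive observations into phases
that are as internally homogeneous as possible. Applied to raw scores it
reacts to *any* distributional change; to focus it on autodependency, the
raw series is first transformed into **running autocorrelations**: a
window of `window` consecutive occasions slides one step at a time, and
within each window the lag-1 Pearson autocorrelation of every variable is
computed (`running_autocorrelations()`). Each window is indexed by the
median occasion it covers, so a window centred on a change point holds an
equal number of occasions from both phases — the indexing that maximizes
the chance of catching the shift.

Windows are compared through the Gaussian kernel
$G_{ij} = \exp(-\lVert P_i - P_j \rVert^2 / 2h^2)$ with the median
heuristic bandwidth (the median of all pairwise Euclidean distances
between autocorrelation vectors). The intra-phase scatter of windows
$a..b$ is $L - \frac1L \sum_{i,j} G_{ij}$ ($L = b - a + 1$), and the
variance criterion $\hat R$ of a segmentation is the per-window average of
its phase scatters. For every $K = 0..K_{\max}$, `kcp_segment()` minimizes
$\hat R$ *exactly* by dynamic programming over precomputed segment costs
(an $O(K_{\max} w^2)$ pass after $O(w^2)$ prefix sums); approximate or
pruned search is deliberately out of scope. Exactness is enforced in the
test suite against exhaustive enumeration on small instances.

### Choosing the number of change points

$\hat R_{\min,K}$ decreases mechanically with $K$, so the number of change
points is decided in two steps:

1. **Variance-drop permutation test.** The statistic is the maximal
   one-step improvement $\hat R_{\min,K-1} - \hat R_{\min,K}$. Each
   permutation reshuffles the *raw* time points — destroying serial
   dependence, hence autocorrelation structure — and recomputes the whole
   pipeline, including the bandwidth, on the permuted series. Permuting
   the running-statistic rows instead would not give a valid null: they
   overlap and are strongly dependent by construction. Only this drop test
   is implemented; a test on the absolute variance level of running
   autocorrelations inflates the false-alarm rate when the constant
   autocorrelation is high, so it is excluded by design.
2. **Penalty grid search.** On rejection, the penalized choice
   $\hat K(C) = \arg\min_K \hat R_{\min,K} + C\,v_{\max}\frac{K+1}{w}
   \left[1 + \log\frac{w}{K+1}\right]$ is swept over
   $C = 1, 1.05, 1.10, \dots$ until $\hat K = 0$; the selected $K$ is the
   most frequent non-zero value along the sweep. The terminal $K = 0$ run
   is excluded from the vote — the sweep stops there, and an unbounded
   tail of zeros would otherwise always win. Since the penalty is
   increasing in $K$ and linear in $C$, $\hat K(C)$ is non-increasing, a
   property asserted on every analyzed data set.

### Numerical and policy choices

* **Defaults**: `window = 25`, `kmax = 10`, `alpha = 0.05`, grid start 1 —
  the operating point used throughout the simulation study below;
  `n_perm = 1000` by default ("a large number"), with 200 used in the
  study-scale runs for tractability. The grid *increment* is not pinned
  down by any stated value; 0.05 is the default and is exposed as
  `c_step`.
* **p-value estimator**: the add-one form
  $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, which never reports
  exactly zero; the plain proportion is returned alongside
  (`p_value_plain`) for comparison with software that reports 0.
* **$v_{\max}$ scalarization**: the covariance matrices of the first and
  last 5% of windows are each reduced to their largest diagonal entry
  (maximum variance) and the larger scalar is kept. How to order two
  covariance matrices is genuinely open; maximum variance is the reduction
  consistent with the variance-style penalty, and the helper is exposed
  separately (`estimate_vmax()`) so other reductions can be swapped in.
* **Minimum phase length**: 1 window (`min_phase`), the most permissive
  reading — a singleton phase carries zero scatter and needs no special
  casing. Implementations that require interior phases of at least 2
  windows can set `min_phase = 2`.
* **Ties** in the dynamic program resolve to the lexicographically
  smallest boundary vector; ties in the grid-search vote resolve toward
  smaller $K$. Both are determinism guarantees, not statistical claims.
* **Degenerate inputs**: a constant window makes the autocorrelation
  undefined and is reported with its location; a zero bandwidth (all
  windows identical) aborts; a permutation that produces either is
  redrawn.
* **Change-point reporting**: a boundary $\tau$ (last window of a phase)
  is reported as the median occasion of window $\tau + 1$, the first
  window of the new phase. With equal intervals and window 25 this is
  $\tau + 13$.

## The regime-switching AR(1) model

The second detector fits the same observation equation with a hidden
first-order Markov chain over $R$ regimes. By default only $\phi$ switches
across regimes, intercepts are fixed at zero and $\Sigma$ is shared — the
constraint set that isolates autodependency changes; `switch_alpha` /
`switch_sigma` / `fix_alpha_zero` expose the other blocks, though their
recovery behaviour is not validated here.

Because the AR(1) state is fully observed, the Kalman prediction and
update steps of the general filtering scheme are exact identities and the
usual collapsing approximation is lossless: the model is an ordinary
hidden Markov model whose emission at occasion $i$ is the prediction error
$X_i - \alpha - \mathrm{diag}(\phi^{r_i}) X_{i-1}$. The forward recursion
therefore computes the *exact* likelihood (verified against brute-force
enumeration over all regime sequences in the tests), conditioning on
$X_1$: $n - 1$ transitions are modeled and no stationary initial term is
added.

**Estimation** is by expectation-conditional-maximization rather than
gradient search on transformed parameters: the E-step is scaled
forward-backward smoothing; the conditional M-steps are closed-form
(per-regime generalized least squares for $\phi$, weighted residual
moments for $\alpha$ and $\Sigma$, expected transition counts for the
chain), so every iteration ascends the likelihood monotonically — no
numeric gradients, no step-size failures, and boundary-degenerate
covariances simply invalidate a start instead of derailing a line search.
Multistart is retained (default `n_starts = 10`, the first start anchored
at the single-regime least-squares fit with regimes spread around it,
persistent transition draws) with the usual short-run strategy: every
start runs briefly, the best three are iterated to convergence at
`tol = 1e-6` relative log-likelihood. The OLS-anchored ECM is markedly
less start-sensitive than gradient multistart, which is why the default
start count is modest. $\phi$ is not constrained to the stationary box;
empirical regimes can legitimately approach 1.

Further policy choices: the initial regime distribution is fixed uniform
(one observation carries negligible information, and fixing it removes a
parameter-counting ambiguity); regimes are relabeled by increasing
mean $\phi^r$; posteriors are smoothed by default (`posterior =
"filtered"` is available); assignments take the highest-probability
regime, ties to the lower index. Model size counts only free blocks —
e.g. $\phi$-only switching with $V = 3$, $R = 2$ gives
$6 + 6 + 2 = 14$ parameters — and BIC uses $n_{\mathrm{eff}} = n - 1$
modeled vectors, not $nV$ scalar scores. `select_regimes()` fits
$R = 1, 2, 3$ by default and reports the AIC- and BIC-minimizing models
separately; a change in autodependency is declared when the chosen
$R > 1$.

## What the simulator emulates — and what it does not

`simulate_phase_var1()` generates exactly the generative picture above:
Gaussian innovations with unit variances and a common cross-correlation
$r$, diagonal autoregression that shifts *abruptly* at phase boundaries.
Three deliberate properties:

* the chain is continuous across boundaries (no re-initialization or
  burn-in), so the first occasion of a new phase already obeys the new
  $\phi$;
* innovation variances stay at 1, so the marginal variance grows with
  $\phi$ (for the toy design's middle phase, to $1/(1-0.25) \approx
  1.33$) — a realistic signature of an autodependency shift, intentionally
  not normalized away;
* $r$ is the *innovation* correlation: with a common $\phi$ across
  columns this reproduces a constant cross-correlation $r$ between the
  variables, the only generative reading consistent with the observation
  equation.

The first observation is drawn from the innovation distribution rather
than the stationary one; in every study design phase 1 has $\phi = 0$,
where the two coincide. The type-I series length is not dictated by the
study designs and defaults to `n = 200`, matching the one-change-point
total; it is a parameter of `null_design()`.

What the generator does **not** emulate: non-Gaussian scores, time-varying
means or variances, gradual (ramped) autocorrelation drifts, unequal
sampling intervals, and missingness. Passing tests therefore demonstrate
operating characteristics under clean, abrupt, Gaussian conditions — they
do not certify behaviour on real experience-sampling data, where
`lag1_filter()` (drop occasions without a same-day lag-1 predecessor,
removing overnight gaps) and `winsorize_3sd()` (replace scores beyond
three standard deviations by the most extreme same-tail in-threshold
score, statistics computed once per column) only partly close the gap.
Detrending, in particular, is out of scope: reproducing a published
analysis that detrended its input requires that study's preprocessing.

## Study sizes used in the shipped checks

The test-suite and acceptance-script runs use deliberately desk-scale
versions of the full designs: 20 toy replicates with 200 permutations;
200–400 null series (50–100 per constant-autocorrelation level
0/0.2/0.4/0.6, $V = 3$, $n = 200$) for the size check, judged against the 95% binomial
interval around 0.05; 50 replicates for the short-series power floor;
100–150 replicates per null cell over $V \in \{1,3,7\}$ and
$\phi \in \{0, 0.4\}$ for the AIC false-alarm ceiling, judged at the
~15% ceiling with a 95% binomial allowance at that replicate count (the
worst measured cell sits at ≈ 16% over 200 replicates, compatible with
the ceiling); 50 replicates for two-regime parameter recovery. The full
factorial grid (93 designs per change-point count and phase length, 100
replicates each) is available through `study_grid()` + `run_study()` but
is not exercised wholesale by the shipped checks.

## Known limitations

* KCP-AR needs enough windows to segment: with phase sizes near the
  window length, power comes mostly from very large shifts.
* Collinearity between variables weakens KCP-AR (less independent
  information in the permutation test) while the regime-switching model,
  which parameterizes the covariance, benefits from it.
* AIC-based regime selection over-extracts on a non-trivial fraction of
  null data sets; BIC is very conservative and rarely declares any
  change. Consumers who need a calibrated false-alarm rate should prefer
  the KCP-AR permutation gate.
* The regime-switching model can represent recurrent short-lived switches
  that are not long-lived change points; inspecting the posterior path
  (`autoplot()`) is essential before reading a chosen $R > 1$ as a
  segmentation.
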