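---
title: "Monitoring high-dimensional biomarker streams with hdspc"
author: "hdspc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring high-dimensional biomarker streams with hdspc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdspc)
```

## The monitoring problem

A patient stream produces one multi-analyte observation per time step — here
a panel of 46 blood indicators (analytes, general chemicals, tumor markers).
We want an online alarm: as soon as the incoming observations stop looking
like the in-control reference population, flag the stream.  Two features of
such data defeat classical multivariate control charts: the dimension `p`
(46) far exceeds any workable subgroup size, and the indicators are mostly
non-normal (a Jarque–Bera screen on the motivating panel rejects normality
for about 80% of the columns).  `hdspc` implements a chart built for exactly
this regime and a dimension-reduction comparator to benchmark it against.

## The D-ELEWMA chart

Each monitored step looks at the most recent sliding window of `D`
observations (`D` = 6–10 in practice, so `D` is far below `p`).  On the
window, an empirical-likelihood (EL) ratio statistic tests whether the
window is centred at the in-control mean `mu0`.  Plain EL fails when
`p/n > 1/2` because the sample convex hull almost never contains `mu0`; the
statistic therefore appends two *virtual points* on the line through the
window mean and `mu0`,

\[
x_{n+1} = \mu_0 - a_n(\bar x - \mu_0),\qquad
x_{n+2} = \mu_0 + (2 + a_n)(\bar x - \mu_0),
\]

with anchor scale
\(a_n = l_n \big/ \{\lVert \bar x - \mu_0\rVert^2 +
k_n (\gamma'(\bar x - \mu_0))^2\}^{1/2}\).
The augmented problem is always feasible, needs no covariance inverse, and
its log-likelihood ratio \(W = -2\log R(\mu_0, k_n)\) has a closed form in
the single scalar \(\xi_n = (n+2)/(1+a_n)\) (implemented in
`el_logratio_closed()`; \(W(0)=0\), \(W\sim\xi^2/2\) for small \(\xi\), and
\(W\to\infty\) as \(\xi\to n+2\)).  The standardized window statistic is

\[
Q \;=\; \{2\,\widehat{tr}(\Omega^2)\}^{-1/2}
\Big\{\tfrac{2 n l_n^2}{(n+2)^2}\, W - \widehat{tr}(\Omega)\Big\},
\qquad
\Omega = \Sigma^{1/2}\,(I_p + k_n\gamma\gamma')\,\Sigma^{1/2}.
\]

`Q` is then smoothed by an EWMA,
\(T_t = (1-\lambda)T_{t-1} + \lambda Q_t\), and an alarm is raised the first
time \(T_t\) exceeds the calibrated upper limit `L1`.

### Tuning constants

* `l_n = n^{5/4} log n`, `k_n = sqrt(p / log p)`,
  `gamma = (1,...,1)'/sqrt(p)` — the recommended defaults, produced by
  `default_el_params(n, p)`.  All logarithms are natural; a different base
  would only rescale `l_n`, which the Monte-Carlo limit calibration absorbs.
* `lambda` (unitless, in (0,1), default 0.05): small values favour small
  sustained shifts, larger values favour large abrupt shifts.  The study
  grid uses 0.05/0.1/0.2.
* `D` (observations, default 10): the window size, and also the EL sample
  size `n`.

### Numerical choices

* **Trace estimators.**  `tr(Omega)` and `tr(Omega^2)` reduce to
  `tr(Sigma)`, `gamma' Sigma gamma`, `tr(Sigma^2)` and
  `gamma' Sigma^2 gamma`.  The default (`mode = "bias_corrected"`) replaces
  `tr(Sigma^2)` by the unbiased
  \(\frac{(n-1)^2}{(n-2)(n+1)}[tr(S^2) - tr(S)^2/(n-1)]\), which matters at
  `n = D = 10 << p = 46` where the plug-in `tr(S^2)` is strongly biased
  upward; the remaining terms are plugged in.  A pure plug-in mode is kept
  for cross-checks.  Other estimator choices shift the calibrated limit
  slightly but not the achieved ARL, which is what the chart is calibrated
  to.
* **Degenerate window mean.**  When `xbar == mu0` exactly, the anchor is
  infinite; the implementation takes the continuous limit
  (`a_n = Inf`, `xi = 0`, `W = 0`) rather than erroring mid-stream.
* **Guards.**  The first logarithm's argument in the closed form reaches 0
  at `xi = n+2`; it is clamped at `1e-300` and the domain is checked.  `xi`
  is computed from the exact rational form `(n+2)/(1+a_n)` to avoid
  cancellation at large `a_n`.
* **EWMA seed.**  The in-control mean of `Q` is negative (at `xbar = mu0`
  the statistic is `-tr(Omega)/sqrt(2 tr(Omega^2)) < 0`), so an upper limit
  calibrated to a 370-step false-alarm rate can itself be negative.  Seeding
  the EWMA at 0 would then alarm immediately.  `T0` therefore defaults to
  the Monte-Carlo in-control mean of `Q` (estimated during calibration and
  reported as `ic_stat_mean`); `T0 = 0` remains selectable.
* **Diagnostic solver.**  `el_reduced_numeric()` solves the augmented EL
  program restricted to equal weights on the original points numerically;
  the test suite confirms it reproduces the closed form to 1e-6, which
  supports using the closed form as the production path.
* **Compiled inner loop.**  The per-window statistic sequence is computed in
  C++ with rank-two sliding updates of the window cross-product matrix
  (rebuilt every 1024 steps to stop floating-point drift); a pure-R engine
  (`engine = "r"`) is kept and the two are asserted to agree.

### Run-length conventions

The first statistic is emitted once the first `D` observations have
arrived, and run lengths count emitted statistics, not raw observations.
Under this convention a fully shifted stream already has a fully shifted
first window, which is what makes out-of-control ARLs below 2 attainable
for large shifts.  Whether warm-up observations should be counted is a
genuine ambiguity of windowed charts; the convention here is fixed and
documented, and all comparisons use it consistently for both charts.

## The MSEWMA comparator

The comparator reduces the panel to 6 selected features (the package treats
the selection — AFP, CEA, HE4, CA19-9, LYM%, CO2CP on the motivating panel
— as configuration data; feature selection itself is out of scope) and runs
a windowed spatial-sign EWMA chart: Phase-I estimation of
\((\theta_0, A_0)\) with \(A_0'A_0 = p^{-1}tr(\Sigma_0)\Sigma_0^{-1}\),
window-averaged spatial signs

\[
v_i = \frac1D \sum_{j=1}^{D}
\frac{A_0(x_{ij}-\theta_0)}{\lVert A_0(x_{ij}-\theta_0)\rVert},
\]

the vector EWMA \(w_i = (1-\lambda)w_{i-1} + \lambda v_i\) seeded at
\(w_0 = 0\), and the quadratic statistic
\(S_i = \frac{2-\lambda}{\lambda}\, p\, w_i'w_i\) against an upper limit
`L2`.  The symmetric (spectral) root is used for `A_0`; any other root
differs by an orthogonal rotation and leaves `S` unchanged (asserted in the
tests).  Rows that coincide with \(\theta_0\) contribute a zero sign vector
with a warning.  The window averaging follows the sliding-window alignment
of the D-ELEWMA chart exactly, so run lengths are directly comparable.

## Control-limit calibration

`find_control_limit()` estimates the limit attaining a nominal in-control
ARL (370 throughout, i.e. a 0.27% false-alarm rate per step):

* one bank of seeded replications is drawn once; every candidate limit is
  evaluated on the same bank (common random numbers), making the estimated
  ARL exactly non-decreasing in the limit and the whole search
  deterministic given the seed;
* the initial guess is the empirical `1 - 1/ARL0` quantile of the pooled
  statistic values, expanded geometrically into a bracket and refined by
  bisection;
* replication trajectories are extended lazily (doubling) only when a
  candidate limit has not been crossed, up to the cap (20,000 steps by
  default); runs still uncrossed at the cap enter at the cap value and are
  reported as censored, and calibration aborts if more than 1% of runs are
  censored at the returned limit;
* the reference convention is 10,000 replications; 2,000 is used as the
  desk scale here (Monte-Carlo standard error of the achieved ARL around
  370/sqrt(2000) ~ 8), and the study grid uses 500.

The printed control limits of any particular implementation depend on
conventions the chart definition leaves open (trace estimators, EWMA seed,
standardization of the stream); the achieved in-control ARL is the
calibration target and is what the acceptance checks verify, via
independent re-estimation at the returned limit.

## The synthetic stream generator

The generator emulates the simulation design of the motivating study:

* **In-control law.**  Independent coordinates drawn from the packaged
  clinical reference ranges (46 indicators; the CA72-4 marker is excluded,
  matching the preprocessing that removes it for >60% missingness).  The
  range `[lower, upper]` is interpreted as mean `(lower+upper)/2` and, by
  default, sd `(upper-lower)/6` (the "range rule": about 99.7% coverage of
  the reference interval).  A `four_sigma` variant (width/4) and a uniform-
  on-range variant are provided, since the source material states only that
  in-control data come from the normal ranges.
* **Monitoring scale.**  Standardized (z-score) by default: shift sizes of
  0.3/0.5/0.8 are only meaningful in sd units (a raw 0.8-unit shift of a
  platelet count would be invisible).  For normal in-control laws the
  standardized stream is exactly iid N(0, I).
* **Shifts.**  After the change point `tau`, each designated coordinate
  receives an independent per-observation draw from
  Normal(`delta`, `shift_sd^2`) with `shift_sd = 1` by default, read from
  the stated "shifts with mean magnitudes 0.3/0.5/0.8 and variances of 1";
  a deterministic shift (`shift_sd = 0`) is available for sensitivity
  analysis.  Whether such shifts should be redrawn per observation or once
  per replication is ambiguous in the source; per-observation is the
  default and the deterministic mode brackets the other reading.
* **Shifted coordinates.**  The default study set is
  {1, 4, 11, 12, 16, 20, 29, 36, 42, 46} of the 46 indicators, and 3 of the
  6 monitored MSEWMA features (AFP, CA19-9, CO2CP — positions 1, 4, 6 of
  the feature list).  Under the exchangeable standardized in-control model
  the identity of the coordinates is statistically immaterial; only their
  counts (10 of 46, and 3 of 6) matter.
* **Determinism.**  Rows are generated in time order from consecutive RNG
  draws (R's default Mersenne-Twister), so streams sharing a seed agree
  row-for-row on common prefixes across lengths; shift noise uses a
  separate substream so in-control draws are bitwise independent of the
  shift configuration.

What the generator does **not** emulate: cross-correlation between
indicators (real analytes are correlated), heavy tails and skewness (real
panels fail normality screens), missingness, and covariates such as age or
menopausal status.  Passing tests on synthetic streams therefore validate
the chart mechanics and the calibration loop, not clinical performance on
real panels; the preprocessing and monitoring entry points accept real CSV
data for that purpose.

## Problem sizes and what the checks compute

The package's own acceptance checks run at desk scale, chosen to keep the
full suite within a coffee break on one core: calibration closure for
D-ELEWMA (p = 46, D = 10, lambda in {0.05, 0.2}) and MSEWMA (p = 6,
D = 10, lambda = 0.2) at 2,000 replications, verified by independent
re-estimation within 3 Monte-Carlo standard errors of 370; out-of-control
spot checks at 1,000 replications; and the full
{chart} x {D = 6, 8, 10} x {lambda = 0.05, 0.1, 0.2} x
{delta = 0.3, 0.5, 0.8} grid at 500 replications, asserting that the
out-of-control ARL is non-increasing in the shift size within overlapping
95% Monte-Carlo intervals and that the D-ELEWMA chart beats the comparator
in every D = 10 cell.  `scripts/acceptance.R` re-runs the two calibration
closures from scratch and writes the re-estimated in-control ARLs as JSON.

## Known limitations

* The exact trace estimators behind the published statistic are not fully
  specified; the bias-corrected default is a documented choice, and printed
  control limits shift slightly under other choices (the achieved ARL does
  not).
* Monte-Carlo calibration at 2,000 replications carries ~2% standard error
  on the achieved ARL; archival-quality limits should use 10,000 or more.
* The MSEWMA comparator assumes a nonsingular Phase-I covariance with
  `m > p` history rows; no regularized variant is provided.
* Real-data alarm positions depend on the external patient CSV, which is
  not packaged; the CLI (`inst/scripts/hdspc`) provides the exact commands
  to reproduce them given that file.
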