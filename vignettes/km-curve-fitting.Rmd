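---
title: "Fitting survival curves to summary Kaplan-Meier data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting survival curves to summary Kaplan-Meier data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmrecon)
```

## The problem

Economic evaluations of health technologies need the *mean* time patients
spend in health states — mean overall survival, mean progression-free
survival — together with the uncertainty of those means. When only a
published Kaplan-Meier graph is available, the common practice of fitting
a Weibull by least squares on the curve, or by regressing
$\log(-\log S(t))$ on $\log t$, has two weaknesses: every part of the
curve is weighted equally although the tail rests on a handful of
patients, and neither method yields a defensible standard error.

`kmrecon` instead *estimates the individual patient data* (IPD) behind the
graph and fits parametric models to that estimate by maximum likelihood.
The inputs are exactly what a journal prints: survival probabilities read
off the curve on a regular grid, and the numbers of patients at risk
reported beneath it.

## Step 1 — reconstructing the individual patient data

Write $S(t)$ for the Kaplan-Meier survival probability and $R(t)$ for the
number at risk at reporting times $t_0 < t_1 < \dots < t_{max}$. Within
one reporting interval, assuming censoring occurs at a constant rate (so
that on average half the interval's censorships happen before any given
event), the product-limit construction links the unknown event count $D$
and censorship count $C$ to the observed quantities:

$$S(t+1) = S(t)\,\frac{R(t) - C/2 - D}{R(t) - C/2},
  \qquad R(t+1) = R(t) - C - D .$$

Solving gives closed forms
$$D = \bigl(R(t)+R(t+1)\bigr)\frac{S(t)-S(t+1)}{S(t)+S(t+1)}, \qquad
  C = \frac{2\bigl(S(t+1)R(t)-S(t)R(t+1)\bigr)}{S(t)+S(t+1)},$$
which satisfy $D + C = R(t) - R(t+1)$ identically — the reconstruction
conserves patients by construction (`reconstruct_level1()`).

Reporting intervals are long (typically only 5–12 at-risk numbers are
printed), so the survival readings at the interval's midpoint and quarter
points are used to refine the estimate. With the midpoint reading, the
same constant-censoring assumption gives a three-equations-in-three-
unknowns system whose solution splits the interval's events into its two
halves (`reconstruct_level2()`); applying the identical algebra inside
each half with the reconstructed midpoint at-risk count
$R(t+\tfrac12) = R(t) - D(t,t+\tfrac12) - C/2$ yields quarter-interval
event counts, with the first and third quarters obtained by differencing
and the censorships split equally over the four quarters
(`reconstruct_level3()`, the default). The quarter totals need not equal
the coarser estimates — they use strictly more information — but every
level reproduces the reported $S$ and $R$ exactly when the balance
equations are run forward, a property the test suite asserts to $10^{-9}$.

Counts are kept as real numbers: the equations rarely produce integers,
the likelihood below accepts fractional exponents naturally, and rounding
would destroy the round-trip identity.

### Cleaning

Real readings are noisy, and the closed forms can then return slightly
negative counts. `clean_counts()` clips negatives to zero and removes the
same mass from the other counts of the same reporting interval — first
from the companion count of the same sub-interval, then proportionally —
so conservation still holds. Negative values no larger than $10^{-6}$ are
treated as floating-point noise and fixed silently; anything larger is
reported, and an adjustment exceeding 10% of the interval's at-risk count
(configurable) raises an error, since input that inconsistent points to a
digitisation mistake the user should fix rather than have silently
repaired. For the same reason increasing $S$ or increasing $R$ is rejected
outright. If the curve reaches zero inside an interval, censoring there is
unidentifiable; all remaining patients are assigned as events apportioned
by the drop in $S$, which keeps the bookkeeping exact and avoids 0/0 in
the closed forms.

## Step 2 — interval-censored maximum likelihood

Given quarter-interval counts $D_k$, $C_k$ on $[a_k, b_k)$ and the
residual $R(t_{max})$ patients still at risk at the last reporting time,
the log-likelihood of a parametric survivor function $S(\cdot;\theta)$ is

$$\ell(\theta) = R(t_{max})\log S(t_{max})
 + \sum_k D_k \log\bigl[S(a_k) - S(b_k)\bigr]
 + \sum_k C_k \log S\!\left(\tfrac{a_k+b_k}{2}\right).$$

Events are treated as interval censored — we know only the quarter
interval in which they fell — while censorships are placed at the
sub-interval midpoint. (A variant that places events at the midpoint and
uses the density there is available behind
`fit_mle(..., events = "midpoint")` purely for benchmarking; it fits
worse, especially under decreasing hazard.) Terms with zero count
contribute nothing regardless of their log argument; survival differences
are floored at $10^{-300}$, and any floored term with positive count marks
the evaluation as $-\infty$.

Four families are provided: Weibull in the rate parameterisation
$S(t) = e^{-\lambda t^\gamma}$ (the natural choice in this field, with
mean $(1/\lambda)^{1/\gamma}\Gamma(1+1/\gamma)$), the exponential as its
$\gamma = 1$ special case, the log-logistic $S(t) = 1/(1+\lambda
t^\gamma)$ (mean by numeric integration, divergent for shape $\le 1$),
and the log-normal. Families are compared by
$-2\log\hat L + \alpha q$ with $\alpha = 2$ by default; ties go to fewer
parameters.

### Numerical choices

* Optimisation runs on $\log$-transformed parameters (positivity for
  free, and the likelihood is much better conditioned under heavy
  censoring) with BFGS and a Nelder-Mead fallback, multi-started from a
  regression-style fit to the survival curve implied by the counts and
  from a crude moment match, then polished at tight tolerance.
* The covariance of the estimates is the inverse of the numerically
  differentiated Hessian (central differences via `stats::optimHess`) at
  the optimum, mapped to the natural $(\lambda, \gamma)$ scale by the
  delta method because downstream parameter simulation operates on that
  scale.
* Probabilistic-sensitivity draws are $\hat\Lambda + \mathbf{C}z$ with
  $\mathbf{C}$ the lower Cholesky factor of that covariance. Draws
  falling outside the parameter domain are rejected and redrawn (up to
  100-fold oversampling, count reported): truncating instead would bias
  the simulated means. The standard error of the mean survival time is
  the standard deviation of the means across 10,000 draws by default.
* The two-arm fit shares $\gamma$ across arms with arm-specific rates,
  so the hazard ratio is the rate ratio at every time; its confidence
  interval comes from the log-scale covariance of the joint fit.

## The trial simulator

`trial_spec()`/`simulate_trial()` emulate the setting these summaries
come from: patients recruited at a constant rate over a 10-unit window,
administratively censored at the calendar cutoff (so follow-up is
uniform between 0 and the window), Weibull event times, and optionally an
independent exponential drop-out process with mean time 5 — i.e.
non-informative censoring at constant hazard. Default reporting follows
conservative publication practice: at-risk numbers at 0, 2, ..., 10 and
survival readings every 0.5 units (four per reporting interval). At-risk
numbers are counted as patients with observed time strictly greater than
the reporting time, and the Kaplan-Meier curve is read right-continuously
with the last value carried beyond the final observation.

`run_scenario()` replicates trials (replicate seed = base seed +
replicate index, so any replicate can be reproduced in isolation),
estimates the mean survival time with each requested method — the
quarter-interval reconstruction with interval-censored MLE, its coarser
and midpoint variants, the full-IPD MLE, least squares, and log-log
regression — and reports mean/median estimates, bias, mean and median
absolute error, MSE, the failure fraction, and relative efficiency,
defined as MSE(IPD fit)/MSE(method) about the true mean. Failed fits are
excluded from summaries but counted; estimates are never winsorised,
however extreme.

What the simulator does *not* emulate: digitisation error in reading the
curve (readings are exact Kaplan-Meier values), informative or
time-varying drop-out, covariate structure, and discrete event-time
recording. Passing simulation tests therefore demonstrate correctness of
the method under clean summary data, not robustness to sloppy
digitisation.

The test suite exercises these scenarios at 500–1,000 replicates with
100–500 patients, which makes the Monte-Carlo error of mean-type summaries
a few percent while keeping a full run in the low minutes; the
`scripts/acceptance.R` driver uses the same sizes.

## Small-sample behaviour and limitations

* With decreasing hazard ($\gamma < 1$) a large share of events occurs
  very early, and the event times *inside* the first half-unit interval
  carry much of the sample's information about $\gamma$. That information
  is simply absent from the summary, so in a small trial (100 patients)
  the interval-censored likelihood is occasionally almost flat in
  $\gamma$: in a percent or so of replicates the maximiser settles at a
  much smaller shape than the full-data fit would, and because the
  Weibull mean grows super-exponentially in $1/\gamma$, those few
  replicates dominate the mean bias and the MSE of the summary-based
  estimate. The bulk of the sampling distribution tracks the full-IPD
  MLE closely (the central quantiles of $\hat\gamma$ nearly coincide),
  but MSE-based comparisons at $n = 100$ under decreasing hazard are
  tail-driven and should be read with that in mind. With 500 patients the
  effect disappears.
* The reconstruction assumes censoring is constant *within* each
  reporting interval; strongly clustered censoring inside an interval
  biases the split of losses between events and censorships.
* Reconstruction requires the numbers at risk; graphs published without
  them are out of scope.
* No covariate adjustment and no multi-event correlation: those genuinely
  need the IPD.
* The reported uncertainty treats the reconstructed counts as known, so
  standard errors are very slightly understated.
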