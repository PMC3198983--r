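# kmrecon

Parametric survival curves fitted to *summary* Kaplan-Meier data.

Cost-effectiveness models of health technologies are driven by **mean**
survival times (overall survival, progression-free survival, ...), which
must usually be extrapolated from a parametric survival model. Individual
patient data (IPD) are rarely released, so analysts commonly fit Weibull
curves to the published Kaplan-Meier graph by least squares or by
regressing `log(-log S(t))` on `log t`. Both approaches weight the highly
uncertain tail of the curve as strongly as its well-populated start and
give no usable uncertainty estimate.

`kmrecon` implements a more statistically principled route:

1. **Reconstruct** the IPD underlying the published graph. From the
   survival probabilities `S(t)` read at four points per risk-reporting
   interval and the numbers at risk `R(t)` printed beneath the graph, the
   numbers of events `D` and censorships `C` in each quarter-interval are
   recovered by solving the Kaplan-Meier balance equations under the
   assumption of constant within-interval censoring; for one reporting
   interval

   `D = (R(t) + R(t+1)) (S(t) - S(t+1)) / (S(t) + S(t+1))`,
   `C = 2 (S(t+1) R(t) - S(t) R(t+1)) / (S(t) + S(t+1))`,

   refined to half- and quarter-intervals using the intermediate readings.

2. **Fit** a parametric distribution (Weibull `S(t) = exp(-λ t^γ)`,
   exponential, log-logistic or log-normal) to the reconstructed counts by
   maximising the interval-censored likelihood

   `L(λ, γ) = S(t_max)^R(t_max) · ∏_k [S(a_k) - S(b_k)]^{D_k} · S(m_k)^{C_k}`,

   where `[a_k, b_k)` are the quarter-intervals and `m_k` their midpoints.
   Model choice is by AIC; the fit reports the parameter covariance and its
   Cholesky factor, so probabilistic sensitivity analysis can draw
   parameters as `Λ̂ + Cz`, and the standard error of the mean survival
   time `(1/λ)^{1/γ} Γ(1 + 1/γ)` follows by parameter simulation. A
   two-arm proportional-hazards fit with shared shape yields a hazard
   ratio `λ_b / λ_a` as a validity check against the published one.

The package also contains the traditional least-squares and regression
fits, a full-IPD maximum-likelihood benchmark, and a Monte-Carlo trial
simulator (`run_scenario()`) that measures bias, absolute error and
relative efficiency of all methods under realistic recruitment and
censoring.

## Worked example

A small synthetic trial arm (200 patients, Weibull with `λ = 0.2`,
`γ = 0.8`, uniform recruitment over 15 months, drop-out with mean 8
months) summarised the way a journal would print it ships with the
package:

```r
library(kmrecon)
grid <- system.file("extdata", "synthetic_km_grid.csv", package = "kmrecon")
risk <- system.file("extdata", "synthetic_km_risk.csv", package = "kmrecon")

summ <- read_km_summary(grid, risk)
counts <- reconstruct_ipd(summ)       # Step 1: estimated events/censorships
head(as.data.frame(counts), 4)
#>  start  end   events censorships n_at_risk_start report_interval
#>   0.00 0.75 28.43181    17.32132       200.00000               1
#>   0.75 1.50 16.20036    17.32132       154.24687               1
#>   1.50 2.25 18.00581    17.32132       120.72519               1
#>   2.25 3.00 10.07674    17.32132        85.39806               1

report <- run_pipeline(run_config(grid, risk, seed = 42))  # Steps 1 + 2
report
#> Model comparison:
#>       family  loglik npar criterion
#>      weibull -289.77    2    583.53
#>  exponential -291.28    1    584.55
#>    lognormal -291.17    2    586.35
#>  loglogistic -291.49    2    586.99
#>
#> Selected model:
#> Parametric survival fit: weibull
#>        estimate       se
#> lambda  0.20166 0.030934
#> gamma   0.85506 0.080532
#> logLik: -289.77   AIC: 583.53
#> mean survival time: 7.0511
#> SE of mean survival (parameter simulation): 1.3035
```

The reconstruction turns the six reported at-risk numbers and twenty-one
survival readings into fractional event/censorship counts per
0.75-month interval; the AIC table compares the four families; and the
selected Weibull recovers the generating parameters (`0.20`, `0.86`
against the true `0.2`, `0.8`) together with a mean survival estimate and
its simulation-based standard error — the two numbers a cost-effectiveness
model needs.

A thin command-line wrapper around the same functions is provided at
`inst/cli/kmrecon.R` with `reconstruct`, `fit`, `pipeline` and `simulate`
subcommands.

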