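# riskmle

Structural estimation and model judging for risky lottery choice.

## The problem

Theories of decision making under risk — expected utility (EUT) and
rank-dependent utility (RDU) — are deterministic, but estimating risk
preferences from observed lottery choices requires an assumption about the
*stochastic* part of choice, and that assumption is not innocuous: the same
data can imply risk aversion under one error story and risk seeking under
another. `riskmle` is for experimental and behavioral economists who elicit
risk preferences with multiple price lists and want to (a) estimate
structural preference parameters under explicit, comparable stochastic
assumptions and (b) judge which combination of preference functional and
error specification the data actually support, in-sample and out-of-sample.

## Models

Utility of money is CRRA, `u(x) = x^(1-r)/(1-r)`. Three preference
functionals are crossed with five error specifications (15 models):

- **EUT**: `V = Σ p_i u(x_i)`; parameters `(r, μ)`.
- **RDU**: probabilities replaced by rank-dependent decision weights built
  from the inverse-S weighting function
  `w(p) = p^γ / (p^γ + (1-p)^γ)^(1/γ)`; `γ = 1` collapses RDU to EUT.
  Parameters `(r, γ, μ)`.
- **Mixture**: each *choice* is EUT with probability `π_EUT` and RDU
  otherwise; the record likelihood is `π·L_EUT + (1-π)·L_RDU`. Parameters
  `(r_EUT, r_RDU, γ, μ, π_EUT)`.

Error specifications (P(choose B) from option values `V_A, V_B`):

| code | specification |
|------|---------------|
| FP / FL | Fechner (strong utility): `F((V_B - V_A)/μ)`, probit / logit link |
| CP / CL | contextual utility: Fechner index further divided by `ν`, the pair's prize-utility range |
| LUCE | strict utility: `V_B^(1/μ) / (V_A^(1/μ) + V_B^(1/μ))`, equivalently a logit on log-values |

Indifferent responses enter as a 50/50 mixture of the two choice likelihoods
(exactly `ln 0.5` per record). Estimation is maximum likelihood with
multi-start BFGS; inference is cluster-robust (sandwich over subject
clusters, delta method to the natural scale). The judging battery covers
AIC/BIC, Vuong and Clarke non-nested tests, and leave-one-subject-out
cross-validated out-of-sample log-likelihood (OSLLF).

## Worked example

The package ships the two-scale Holt–Laury design (10 rows, payouts ×1 and
×5; 20 choices per subject). `hl_table()` reproduces the design table with
expected values and the implied relative-risk-aversion intervals:

```r
library(riskmle)
hl_table()[, c("row", "p_high", "ev_a", "ev_b", "ev_diff", "rra_lower", "rra_upper")]
#>    row p_high ev_a  ev_b ev_diff rra_lower rra_upper
#> 1    1    0.1 1.64 0.475   1.165      -Inf     -1.71
#> 2    2    0.2 1.68 0.850   0.830     -1.71     -0.95
#> 3    3    0.3 1.72 1.225   0.495     -0.95     -0.49
#> 4    4    0.4 1.76 1.600   0.160     -0.49     -0.14
#> 5    5    0.5 1.80 1.975  -0.175     -0.14      0.15
#> 6    6    0.6 1.84 2.350  -0.510      0.15      0.41
#> 7    7    0.7 1.88 2.725  -0.845      0.41      0.68
#> 8    8    0.8 1.92 3.100  -1.180      0.68      0.97
#> 9    9    0.9 1.96 3.475  -1.515      0.97      1.37
#> 10  10    1.0 2.00 3.850  -1.850      1.37       Inf
```

A subject switching from A to B at row `k` reveals `r` in
`(rra_lower[k], rra_upper[k])`; row 10 is a dominance/comprehension check.

Simulate 84 subjects from the built-in mixture contextual-probit truth and
refit the generating model:

```r
sim <- simulate_choices(risk_truth("MIX", "CP"), seed = 42)
fit <- riskfit(sim, "MIX", "CP")
summary(fit)
#> MIX preference functional with CP error
#> 1680 records in 84 subject clusters; cluster-robust SEs
#>        estimate std_error ci_lower ci_upper
#> r_eut    0.4888    0.0475   0.3958   0.5819
#> r_rdu   -0.3372    0.1599  -0.6506  -0.0239
#> gamma    0.3773    0.0391   0.3007   0.4538
#> mu       0.1134    0.0104   0.0930   0.1339
#> pi_eut   0.4930    0.0857   0.3250   0.6609
#> log-likelihood -664.154  AIC 1338.307  BIC 1365.440
#> Wald tests:
#>   gamma = 1                    W =  254.006  df = 1  p = 0.0000
#>   pi_eut = 1 (collapse to EUT) W =   35.010  df = 1  p = 0.0000
#>   pi_eut = 0 (collapse to RDU) W =   33.096  df = 1  p = 0.0000
#>   pi_eut = 0 & gamma = 1       W =  297.734  df = 2  p = 0.0000
```

The coefficient block reads like the usual structural-estimates table: the
EUT-consistent share of choices is `pi_eut` (here about half, with the
simulation truth 0.316 inside the interval), `gamma` well below 1 means
small probabilities are over-weighted and large ones under-weighted within
the RDU component, and the Wald panel shows the mixture collapses neither to
pure EUT nor to pure RDU, and that probability weighting is significant.

Judge competing models (here a small grid, without the expensive
cross-validation):

```r
rpt <- selection_battery(sim, functionals = c("EUT", "MIX"),
                         errors = c("FP", "CP"), osllf = FALSE)
rpt$criteria[, c("functional", "error", "k", "logLik", "AIC", "BIC")]
```

`print(rpt)` renders the criteria grid with best-model flags, the pairwise
Vuong tests (positive statistics favor the row model) and the two-direction
exact Clarke sign tests, including a report of intransitive Clarke cycles
when they occur. `osllf_cv(fit)` computes the leave-one-subject-out
out-of-sample log-likelihood for a single fit. `recovery_study()` wraps the
simulate–fit loop into a Monte Carlo parameter-recovery report (bias, RMSE,
CI coverage per parameter).

File-based pipelines (`cmd_simulate()`, `cmd_fit()`, `cmd_judge()`) write
choice CSVs, truth/fit JSONs, criteria and test tables, plus a manifest
sufficient to reproduce the run.

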