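---
title: "Estimating and judging stochastic models of risky choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and judging stochastic models of risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskmle)
```

## The problem

Theories of decision making under risk — expected utility (EUT) and its
rank-dependent generalization (RDU) — are deterministic, but observed lottery
choices are not: the same subject facing the same pair twice may choose
differently. Estimating structural risk preferences therefore requires a
*stochastic choice model* layered on top of the deterministic theory, and the
choice of that layer is consequential: the same data can imply risk aversion
under one error specification and risk seeking under another. `riskmle`
implements the full pipeline for confronting this problem: structural maximum
likelihood estimation of EUT, RDU, and a choice-level EUT/RDU mixture under
five stochastic error specifications, followed by a battery of in-sample and
out-of-sample criteria for judging which model to believe.

## The choice task

Data come from a multiple price list (MPL) in the Holt–Laury format: ten
ordered rows, each offering a "safe" lottery A \((p, 2.00; 1-p, 1.60)\)
against a "risky" lottery B \((p, 3.85; 1-p, 0.10)\), with \(p = k/10\) in
row \(k\). Row 10 is degenerate (the high prize is certain) and screens for
comprehension, since B dominates there for every risk attitude. The package's
default registry contains two such lists: the baseline (`scale = 1`) and one
with every payout multiplied by five, giving 20 choices per subject.
`hl_table()` reproduces the printed design table: expected values, their
differences, and the implied coefficient-of-relative-risk-aversion interval
revealed by the row at which a subject switches from A to B.

Interval endpoints are the roots of \(EU_A(r) = EU_B(r)\) per row. Two
numerical points matter here:

* Root-finding uses the *normalized* CRRA utility
  \(u(x) = (x^{1-r} - 1)/(1 - r)\) (with \(\ln x\) at \(r = 1\)). It is an
  affine transformation of the plain form for each fixed \(r\), so it
  preserves the sign of every expected-utility difference, but unlike the
  plain form it is continuous through \(r = 1\), letting the bisection cross
  that point (row 9's root is 1.368). Bracketed bisection runs on
  \(r \in [-5, 5]\) with tolerance `1e-10`.
* Reported endpoints are rounded half-away-from-zero to two decimals, the
  convention that reproduces the printed table on rows 1–3 and 6–9. The
  row-4 root is \(-0.1426\) and the row-5 root \(+0.1464\); tables in the
  tradition of the original price list print this risk-neutral interval as a
  symmetric \((-0.15, 0.15)\) or variants thereof. The package reports the
  computed roots and does not force agreement with any single printed cell.

## Preference functionals

Utility of money is CRRA, \(u(x) = x^{1-r}/(1-r)\), with \(r\) the relative
risk aversion coefficient (\(r = 0\) neutral, \(r > 0\) averse, \(r < 0\)
loving). The likelihood uses this literal form exclusively — the normalized
variant rescales utility *differences* by \(1/(1-r)\) relative to the literal
one and is therefore not interchangeable inside error specifications that
normalize by something else (contextual utility) or not at all. Because the
literal form degenerates at \(r = 1\), the optimizer's search region excludes
a `1e-6` band around it (estimates never land there in practice; the
likelihood is continuous up to that band from both sides).

Under EUT a lottery is worth \(\sum_i p_i u(x_i)\). Under RDU the
probabilities are replaced by decision weights built from the inverse-S
weighting function
\(w(p) = p^{\gamma} / (p^{\gamma} + (1-p)^{\gamma})^{1/\gamma}\): with
outcomes ranked best to worst, the weight on the best outcome of a two-outcome
lottery is \(w(p_{best})\) and the worst receives the remainder. The
implementation generalizes to \(n\) outcomes through differences of \(w\) at
the decumulative probabilities, with tied prizes merged before ranking; only
the two-outcome case is exercised by the price-list design. At
\(\gamma = 1\), \(w\) is the identity and RDU collapses to EUT — the Wald
test of \(\gamma = 1\) is the test of no probability weighting.

The mixture functional assumes two data-generating processes coexist: each
*choice* (not each subject) is EUT-consistent with probability
\(\pi_{EUT}\) and RDU-consistent otherwise, so a record's likelihood is
\(\pi_{EUT} L_{EUT} + (1 - \pi_{EUT}) L_{RDU}\), mixed before the logarithm.
The subject-level alternative (each subject wholly one type) is a different
model and is out of scope, though the simulator offers a subject-level
class-assignment switch as a diagnostic of how much the distinction matters.

## Stochastic error specifications

Five specifications map the pair of option values \((V_A, V_B)\) to
\(P(\text{choose } B)\):

* **FP / FL** — Fechner (strong utility): \(P(B) = F((V_B - V_A)/\mu)\) with
  \(F\) the standard normal or logistic distribution function and
  \(\mu > 0\) a noise scale.
* **CP / CL** — contextual utility (moderate utility): the Fechner index is
  further divided by \(\nu\), the utility range over all four prizes in the
  pair at the current \(r\). \(\nu\) changes from pair to pair, so this is a
  pair-specific heteroskedasticity correction; the rescaled index always
  lies in \([-1, 1]\). \(\nu\) is computed from unweighted prize utilities —
  it is defined over prizes, so probability weighting never enters it.
* **LUCE** — strict utility: \(P(B) = V_B^{1/\mu} / (V_A^{1/\mu} +
  V_B^{1/\mu})\), which requires strictly positive option values. Since
  dividing by \(1 - r\) cancels in the ratio when \(1 - r > 0\), the package
  evaluates the ratio with the positive kernel \(u(x) = x^{1-r}\) and
  restricts \(r < 1\) (enforced as \(r \le 0.999\) in estimation). This
  restriction is the package's own resolution of the positivity requirement;
  all plausible strict-utility estimates on this design satisfy it
  comfortably. The ratio is algebraically a logit on
  \((\ln V_B - \ln V_A)/\mu\) — the classic result that every strict binary
  utility model is also a strong one — and the implementation computes it in
  that form for numerical stability (the identity is verified to `1e-12` in
  the tests).

An expressed indifference is modelled as a 50/50 mixture of the two choice
likelihoods, hence contributes exactly \(\ln 0.5\) for a binary pair: it
carries no information about any parameter, and the tests verify end-to-end
that adding or stripping indifferent records moves no estimate.

Probabilities are clipped to \([10^{-12}, 1 - 10^{-12}]\) before logs; the
number of clipped values at the optimum is recorded in the fit's convergence
diagnostics.

## Estimation

`riskfit()` maximizes the likelihood on an unconstrained internal scale:
\(\mu = e^{m}\), \(\gamma = e^{g}\), \(\pi_{EUT} = \text{logistic}(q)\),
\(r\) free (and \(r = 0.999 - e^{s}\) under the Luce error). This keeps every
iterate interior and makes the delta-method map to the reporting scale a
diagonal Jacobian.

The likelihood of a price-list dataset depends on the data only through the
count of each (pair, response) combination, so the objective is evaluated as
a dense count-weighted sum over at most 20 × 3 cells — this is what makes the
Monte Carlo studies below affordable.

Starting values come from a fixed grid (\(r \in \{-1, -0.5, 0, 0.5, 0.9\}\),
\(\gamma \in \{0.5, 1, 2\}\), \(\mu \in \{0.1, 0.5, 1\}\),
\(\pi \in \{0.2, 0.5, 0.8\}\), restricted to the functional's free
parameters). Every grid point is screened by its log-likelihood and a subset
is polished with BFGS; polished starts are required to be mutually distant on
the internal scale so that several basins of attraction are explored rather
than five near-copies of the best cell. The defaults (5 EUT, 10 RDU, 32
mixture starts) were chosen because, on mixture test problems, 32 diverse
starts reproduced the optimum found by polishing all 675 grid points exactly,
at a fraction of the cost. The best local optimum wins; ties within `1e-6`
go to the earliest start, and a final restart from the winner polishes
stalled line searches. Mixture likelihoods on this design are genuinely
multimodal (see *Limitations*), which is why the refinement budget is
deliberately generous; a practical cross-check, also wired into
`selection_battery()`, is that probit and logit links should give similar
risk coefficients — a large discrepancy is a symptom of a local maximum.

Inference is cluster-robust: subjects make 20 choices each, so scores are
summed within subject before the outer product, giving the sandwich
\(A^{-1} B A^{-1}\) with \(A\) the observed information (central
finite-difference Hessian, step \(10^{-5}(1 + |\theta|)\)) and \(B\) the
cluster-sum score covariance scaled by \(C/(C-1)\). With singleton clusters
this reduces to the ordinary heteroskedasticity-robust estimator with factor
\(n/(n-1)\). Wald tests are quadratic forms against \(\chi^2\) with rank
degrees of freedom; single-constraint p-values are thus the normal-reference
ones. Restrictions that pin the mixing probability to 0 or 1 sit on the
boundary of the parameter space, where the \(\chi^2\) reference is
nonstandard — the tests are reported in the conventional form with an
explicit flag, mirroring how such panels are usually printed.

## Judging the models

* **Information criteria**: \(AIC = 2k - 2\log L\),
  \(BIC = k \ln n - 2\log L\) with \(n\) the number of choice records (1680
  for the default design — the convention that regenerates the printed
  criteria of the emulated study exactly).
* **Vuong test**: per-record log-likelihood ratios \(m_i\);
  statistic \(\sum m_i / (\sqrt{n}\, s_m)\), one-sided upper-tail normal
  p-value, positive values favoring the first model. The default uses the
  maximum-likelihood standard deviation at the individual-choice level,
  matching the observation indexing of the test's definition; an
  unbiased-variance option and a cluster-aggregated option (per-subject sums)
  exist because the clustering treatment is not pinned down in the tradition
  this follows. No dimension correction is applied by default —
  within-functional comparisons have equal \(k\), so it would vanish there
  anyway — but AIC- and BIC-style corrections are available for
  unequal-dimension comparisons.
* **Clarke test**: an exact binomial sign test on the \(m_i\), both one-sided
  directions reported; ties (zero to within `1e-12`) are dropped and the
  effective sample size reported, with no continuity correction. Pairwise
  sign tests need not be transitive, so the battery searches for strict
  preference cycles and prints them when present.
* **Out-of-sample log-likelihood (OSLLF)**: grouped cross-validation leaving
  one subject (their 20 choices) out at a time, refitting, and scoring the
  held-out subject at the refitted estimates. Refits warm-start at the
  full-sample estimate with the multi-start schedule as fallback;
  non-converged refits are flagged and reported, and are included in the
  total unless excluded explicitly.

EUT, RDU and the mixture are nested in each other by construction
(\(\gamma = 1\), \(\pi = 1\), \(\pi = 0\)), so the non-nested tests are run
between error specifications within a functional, and the nesting hypotheses
are handled by the Wald panel instead.

## Synthetic data

No subject-level dataset accompanies the study this package emulates, so the
simulator is a first-class component: it forward-generates responses for
`n_subjects` (default 84, the emulated sample) facing both price lists (20
choices), from any functional/error/parameter truth. Built-in presets carry
the published point estimates for all 15 model combinations; the default
truth is the mixture contextual-probit preset
(\(r_{EUT} = 0.409\), \(r_{RDU} = -0.291\), \(\gamma = 0.391\),
\(\mu = 0.106\), \(\pi_{EUT} = 0.316\)), the specification that won the
published model comparison. Mixture records draw their latent class per
choice, matching the estimator's assumption. Indifference is injected
exogenously at a configurable rate (default 0, as the empirical rate is
unreported): the likelihood gives indifferent responses no parametric
content, so modelling them structurally would add nothing testable.

What the simulator deliberately does *not* emulate: heterogeneity of \(r\)
or \(\mu\) across subjects (every simulated subject shares the truth
parameters, so within-subject clustering arises only through the mixture's
class draws), order and session effects, and payout-scale effects beyond the
mechanical prize scaling. Passing recovery tests therefore certify the
estimator against its own assumptions — they do not certify that real
subjects satisfy those assumptions, and cluster-robust intervals on real
data will typically be wider than on data simulated this way.

`recovery_study()` wraps the simulate–fit loop and reports per-parameter
bias, Monte Carlo standard errors, RMSE, and coverage of the cluster-robust
95% intervals, with convergence failures counted rather than hidden.

## Problem sizes used by the shipped tests

The package's own test suite runs the recovery and selection studies at 50
replications of the full 84 × 20 design — enough for Monte Carlo standard
errors a few times smaller than the effects being checked while keeping the
suite comfortably below typical continuous-integration budgets — and smaller
subject counts (6–30) for unit-level checks where only correctness, not
sampling precision, is at stake.

## Limitations

The central known limitation is the identifiability of the mixture under
contextual utility at the emulated design size. CRRA is homothetic, so the
contextual normalization makes choice probabilities identical across the two
payout scales; the design then carries effectively ten distinct response
probabilities from which five mixture parameters must be inferred. At 84
subjects the likelihood is multimodal, and in roughly one replication in ten
the *global* maximum is a degenerate mode (step-like weighting with
\(\gamma\) in the tens, or a drifting \(r_{EUT}\) with \(\pi_{EUT}\) near
zero) rather than the truth-basin mode. The package reports the global
maximum it finds — pruning modes the model itself does not rule out would be
misleading — so mixture-CP Monte Carlo summaries at this size show biased
means and 95% intervals covering at roughly 70–80% rather than the nominal
rate, while EUT recoveries are clean at the same size. Users fitting mixture
models on single datasets of this size should treat boundary flags, the
probit/logit cross-check, and implausibly extreme \(\gamma\) as signs that
the sample does not separate the two processes, and should prefer the
judging battery over any single fit.

Other limitations: no loss-domain lotteries, no alternative weighting
families, no trembles or random-preference error models, no subject-level
mixture, no covariates on parameters, and no Bayesian or hierarchical
estimation.
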