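---
title: "Randomization-based inference for generalized MCP-Mod: models, tests and design choices"
author: "MCPModRand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization-based inference for generalized MCP-Mod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MCPModRand)
```

## The problem

Phase II dose-finding trials ask whether there is any dose-response signal
at all before modeling its shape. The generalized MCP-Mod methodology
answers this with a multiple-contrast test: a set of M candidate
dose-response shapes is fixed in advance, each shape is turned into an
optimal contrast vector over the k dose groups, and the test statistic is
the maximum of the standardized contrasts of the estimated group means.
With a binary endpoint and a small trial, two things go wrong with the
standard (population-based, asymptotic) version of this test:

* **Separation.** With dose-specific intercepts, a dose group in which
  every patient fails (or every patient succeeds) makes that intercept's
  maximum-likelihood estimate infinite. In the motivating design — n = 49,
  a 1:2:2:2 allocation over placebo and 10/25/100 mg, success probability
  around 20% under the null — the placebo arm has only 7 patients and is
  outcome-pure in roughly one trial out of five.
* **Asymptotics.** The multivariate-normal reference distribution of the
  max-contrast statistic is an n-to-infinity approximation; at n = 49 the
  population-based test is conservative (type-I error near 3% at a nominal
  10%), and enrollment-time trends distort it further.

The package implements both remedies studied for this setting:
Firth-penalized estimation, whose estimates always exist, and Monte-Carlo
randomization tests, which replace the asymptotic reference by the exact
distribution of the statistic under re-randomization and are valid in
finite samples under the strong null that no patient's outcome depends on
their assignment.

## Estimation

The working model is a GLM with linear predictor
`eta_i = delta_{Z_i} + x_i' beta` (one intercept per dose group plus
covariate effects). Three fitting routes are provided by `fitGlm()`:

* `method = "mle"` for the binomial family is iteratively reweighted least
  squares exactly as in `glm.fit` (same starting values, same relative
  deviance criterion of 1e-8, maxit 25). Under separation the estimates do
  not exist; the last iterate is returned, flagged, because the simulation
  studies must reflect what standard software reports in practice.
* `method = "firth"` maximizes the Jeffreys-penalized likelihood
  `l(theta) + log det I(theta) / 2` by penalized scoring with
  step-halving; convergence requires the penalized score below 1e-6 and a
  step below 1e-8, with at most 100 iterations. The covariance is the
  inverse penalized information at the optimum. Tests verify the optimum
  against an independent BFGS maximization of the same penalized
  likelihood written in plain R.
* The gaussian family reduces to ordinary least squares under either
  method label (the Jeffreys penalty does not involve the mean parameters
  there).

Group means are reported population-averaged: `mu_j = delta_j + xbar'
beta`, with covariance `L V L'` for `L = [I | 1 xbar']`.

**Separation detection** is exact, not heuristic: complete separation is
the LP feasibility of `(2y_i - 1) x_i' b >= 1`, and quasicomplete
separation the feasibility of `(2y_i - 1) x_i' b >= 0` with a strictly
positive total margin (equivalent, for a full-rank design, to a nonzero
direction of recession of the likelihood). The LPs are solved by a small
dense two-phase simplex with Bland's rule, written for this package since
no linear-programming backend is part of its dependency set; the verdicts
are tested against exhaustive oracles on intercept-only designs and
against a closed-form rule for the dose-intercept + single-covariate
design. A divergence heuristic is deliberately not used. For the
dose-intercept + one-covariate design, `fitGlm()` first applies an exact
O(n) necessary condition and only then runs the LP, which keeps the n =
490 simulations cheap.

**Which separation event has ~18% probability?** The published frequency
of "complete separation" in this design (about 18% at n = 49, 3.4% at
n = 98, 0 at n = 490) does not correspond to strict complete separation of
the whole design, which is nearly impossible once a continuous covariate
is present (measured below 0.1%), nor to separation of any kind (about
27%). It matches, both analytically — `(1 - E[gamma])^7 = 0.180` for the
null success probabilities — and in simulation, the probability that the
MLE of the *placebo-arm intercept* does not exist, i.e. that the smallest
arm is outcome-pure. `separationFrequency()` therefore reports that event
by default, decided exactly by the direction-of-recession LP
(`coefMleInfinite()`), with the strict events available via its `event`
argument.

## The five tests

Writing `muHat_Z` and `S_Z` for the population-average group means and
covariance under assignment sequence Z, and `c_1, ..., c_M` for the
optimal contrasts, the two statistics are

* **S1 (model-based):** `max_m c_m' muHat_Z / sqrt(c_m' S_Z c_m)`, with
  the GLM refitted for every sequence;
* **S2 (residual-based):** fit the covariate-only model once, take
  residuals `r_i = y_i - g(alphahat + x_i' betahat)`, and compute
  `max_m c_m' rbar_Z / sqrt(sum_j c_{m,j}^2 s_j^2 / n_j)` from per-arm
  residual means and variances (variances use the n-1 divisor).

The optimal contrast for standardized shape means `mu0` under covariance S
is `c ~ S^{-1}(mu0 - 1 (1'S^{-1}mu0)/(1'S^{-1}1))`, normalized to unit
Euclidean norm and oriented so `c'mu0 > 0`. Contrasts are invariant to
location/scale changes of the shape, so candidate shapes are stored
standardized.

The **population-based test** (test 1) refers the observed S1 to the
distribution of the maximum of M standard normals with correlation
`R_{mm'} = c_m'S c_{m'} / sqrt(c_m'S c_m c_{m'}'S c_{m'})`, integrating
the multivariate normal tail (quasi-Monte-Carlo, absolute tolerance 1e-5,
run under a fixed internal RNG state so that p-values are deterministic).
The normal rather than t reference is used, consistent with the
large-sample generalized MCP-Mod test for non-gaussian families.

The **randomization tests** (tests 2-5: S1 or S2, each with ML or Firth
estimation) redraw `nrand` sequences from the trial's own randomization
distribution, recompute the statistic with outcomes held fixed, and report
the tie-inclusive plain Monte-Carlo p-value `#(S(Z_l) >= S(Z_obs))/nrand`
— exactly the printed estimator, with no +1 correction; the corrected
estimator is available but off by default. Exactness under the strong null
holds for any statistic, which the tests verify by full enumeration on
small reference sets.

### Design choices that were genuinely open

* **Contrasts for the randomization statistics.** For S2 the contrasts
  come from the per-arm sample sizes by construction. For S1 either
  design-stage contrasts (group-size weighted) or contrasts recomputed
  from each draw's estimated covariance are defensible; published
  operating characteristics for this design are reproduced by the
  design-stage choice (e.g. test 4 power under RA within Monte-Carlo error
  of the published 86.7%), while per-draw recomputation runs 2-4
  percentage points lower, so design-stage contrasts are the default and
  `recomputeContrasts = TRUE` the option. Validity is unaffected either
  way; only power is at stake.
* **Complete-randomization draws that empty an arm.** The statistic must
  assign a value to every support point. When a drawn CR sequence leaves
  an arm empty, the statistic is computed on the arms present, with
  contrasts re-derived on the reduced grid; at n = 490, where CR is
  actually used, empty arms essentially never occur.
* **Degenerate S2 variances.** If every residual in an arm is identical,
  the denominator vanishes; such a draw scores +Inf when its numerator is
  positive and -Inf otherwise. With binary data at n >= 49 this is a
  measure-zero corner.
* **Ties in the p-value.** Ties count toward rejection-unfavorable
  evidence (the `>=` in the estimator), exactly as printed.

## The binary-endpoint study

`binaryScenario()` + `generateTrial()` emulate the motivating Phase II
trial: an Emax dose-response truth on the logit scale with ED50 = 10,
calibrated in closed form through the placebo and top-dose success
probabilities (`calibrateEmaxTruth()`; p0 = 0.2, pTop = 0.8 gives theta0 =
-1.39 and theta1 = 3.05); one standard-normal covariate entering the
linear predictor with coefficient 0.6, chosen so its discriminative AUC in
the control group is 0.66 (`covariateAuc()` checks this by quadrature);
and an optional linear time trend `t_i = 0.4 i/n - 0.2` added on the
probability scale with clipping to [0, 1]. Success probability parameters
are interpreted at covariate zero, exactly as the generating formulas
prescribe; the marginal placebo rate is slightly above p0 (about 0.217)
by the convexity of the inverse logit below one half — this is a property
of the generator, not recalibrated away.

The scenario grid (n in {49, 98, 490} x {RA, PBD, CR at 490 only} x trend
in {no, yes}) ships as a YAML config
(`system.file("extdata/table1_scenarios.yaml", package = "MCPModRand")`),
with top-dose probabilities 0.8 / 0.61 / 0.364 taken as given inputs — the
external design calculation that equalized asymptotic power across sample
sizes is out of scope. CR is restricted to n = 490 because at smaller
sizes the probability of a nearly empty placebo arm is material.

**Candidate set.** The five default shapes (`defaultCandidateSet()`) are
two Emax models (ED50 10 and 35), two sigmoid Emax models (ED50 25 with
Hill 3; ED50 60 with Hill 5) and one non-monotone beta model (delta1 =
1.5, delta2 = 3, scaling constant 120, maximum near 40 mg). The exact
parameters behind the published study's candidate shapes are not
recoverable; these were fixed once to span the same qualitative range
(steep/shallow monotone increase plus one umbrella shape, with the
truth-matching Emax among them) and operating characteristics have mild
(±2 percentage points) sensitivity to this choice. The beta model's
scaling constant is configurable for other dose ranges, and the log-linear
family uses offset c = 1 so it is finite at placebo.

**Seeds.** The harness derives one seed per replicate from the master
seed, and every test sees the same simulated trials; sampling runs through
R's RNG (including the compiled samplers), so a master seed makes the
whole grid bit-reproducible regardless of worker count.

## The continuous-endpoint potential-outcomes study

`generatePotentialOutcomes()` builds a complete n x k table of month-12
outcomes — every patient carries an outcome under every dose — from a
**synthetic stand-in** curve model (`curveModel()`): individual Emax
curves with ED50 = 150 micrograms on the (0, 100, 200, 400, 1000)
microgram grid, a baseline visual-acuity-like score carried over with
slope 0.9, between-patient random effects on intercept (sd 6 letters) and
maximal effect (12 +/- 5 letters), residual noise (sd 4), and truncation
of all outcomes to the 0-70 ETDRS letter range. The pharmacometric model
that generated the published table is external and unpublished in the
source; the stand-in's parameters are configuration chosen to give a
strong drug effect at n = 50 and realistic score ranges, and exact powers
from that study are deliberately not reproduction targets — only the
qualitative contrasts are: the baseline covariate adds roughly ten points
of power, randomization tests hold the 10% level under the sharp null for
both RA and PBD, and sorting patients by baseline (a positive time trend)
breaks the population-based test's calibration under PBD while the
randomization test remains exact. The *direction* of that miscalibration
depends on the generating table: with this package's Gaussian
random-effects stand-in the sorted sharp-null table deflates the PBD
population test severely (type-I near 2% at a nominal 10%, consistent
with the deflation the binary-endpoint study shows under PBD with a time
trend), whereas the original pharmacometric table produced inflation.
The reproducible invariant — and the one the acceptance tests assert — is
exactness of the randomization test versus miscalibration of the
population test.

Draws are quasi-random by default: a Richtmyer sequence (point l,
dimension j equals the fractional part of `l sqrt(p_j)` for the j-th
prime), mapped through inverse CDFs — one dimension for the baseline, two
for the random effects, one per dose for the residuals — so the table is a
deterministic low-discrepancy sample from the model. Scenario 2 sorts
patients by baseline; scenario 3 replaces every row by its placebo value
(the sharp null). The flat candidate shape is excluded from contrast
construction (a constant shape admits no contrast) and enters only as a
data-generating possibility.

## Numerical choices

* Exact reference-set counts use base-1e6 big-natural arithmetic with
  factorials assembled from prime factorizations, so no big-integer
  division is ever needed; `format()` prints all digits. For the
  motivating design the counts are 630^7 (about 3.9e19) for PBD and
  49!/(7! 14!^3) (about 1.8e26) for RA. For CR the package implements
  |R| = k^n; the worked example in the source prints 7^49 instead, which
  conflicts with its own formula (k = 4 arms), so the CR count is
  documented here and excluded from numerical comparisons.
* Near-singular information matrices (separated ML fits) fall back to a
  symmetric pseudo-inverse; the population test adds a 1e-10 relative
  ridge before contrast construction so the statistic stays defined, which
  reproduces the intended behavior of reporting a (meaningless but
  finite) p-value for separated ML fits.
* The S1 randomization loop warm-starts each draw's Firth fit from the
  observed-sequence solution; tests confirm warm and cold starts reach the
  same optimum to 1e-6.
* Monte-Carlo profile defaults follow the source study (nsim = 10000,
  nrand = 1000, one-sided alpha = 0.1); the documented reduced profile
  (nsim = 2000, nrand = 500) is used for the expensive Firth-refit cells
  in the acceptance script and for desk-scale smoke runs. The problem
  sizes used by the test suite are smaller still (hundreds of replicates)
  and are chosen to keep each property detectable within Monte-Carlo
  error.

## What passing tests do and do not show

The synthetic generator reproduces the *design* of the motivating trial —
block structure, allocation, covariate strength, trend shape — but real
trials have covariates with unknown distributions, non-Emax truths,
informative enrollment, and missing data, none of which are emulated.
Exactness of the randomization tests under the strong null is a theorem
and the tests verify the implementation, not the assumption: under
effect heterogeneity the strong null is a stronger statement than "no
average effect". Operating-characteristic agreement with the published
study is within Monte-Carlo error plus a documented candidate-set
tolerance for power cells; type-I error of randomization tests is
contrast-free and reproduces tightly.

## Known limitations

* Covariate-adaptive, response-adaptive, biased-coin and urn designs are
  out of scope; only CR, RA and PBD are implemented.
* The dose-response *estimation* step of MCP-Mod (model fitting and model
  averaging after a significant test) is intentionally absent.
* Exact logistic regression and data-augmentation remedies for separation
  are not provided; Firth's method is the supported remedy.
* The continuous-endpoint study's generating model is a documented
  synthetic stand-in, not the published pharmacometric model.
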