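---
title: "Multistage incidence models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage incidence models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it fits, the
synthetic cohorts it simulates, and the numerical decisions behind
both. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The multistep model family

If disease onset requires `k` rare, independent steps, each with a
small per-year probability, the age-specific incidence is proportional
to `t^(k-1)` for ages at which every per-step cumulative risk is still
small. On the scale the package fits on — `y = log(incidence)`,
`x = log(age) - log(30)` (natural logs; the offset makes the intercept
the log rate at age 30 rather than at the meaningless age 1) — the five
models are:

| model | mean function | parameters |
|---|---|---|
| linear | `y = slope·x + c` | slope (= k−1), c, σ_res |
| broken stick | two slopes joined continuously at `x = bp` | slope1, slope2, bp, level, σ_res |
| sex (intercept) | broken stick + per-sex vertical offset | + level_female, level_male |
| sex (full) | per-sex slopes, shared breakpoint | + 4 slopes |
| beta | `I = α·u^(k−1)·(1−βt)`, `u = t/30` | α, k, β, σ_res |
| susceptibility | `I = α·u^(k−1) / [1 + ((1−C)/C)·e^{Λ(t)}]` | α, k, C, σ_res |

with `Λ(t) = (30α/10⁵)·u^k/k` the cumulative per-person onset hazard
implied by `α` (rates are per 100,000 person-years throughout, so the
10⁵ conversion is part of the model, not a display choice — omitting it
mis-scales the depletion term by five orders of magnitude and makes `C`
unrecoverable).

The susceptibility denominator arises from pool depletion: with
susceptible onset density `f` and cdf `F`, observed incidence per
person still at risk is `C·f/(1−C·F)`, which for the power-law hazard
collapses to the expression above. It is nonnegative for all ages,
reduces exactly to the plain power law at `C = 1`, behaves as
`C·α·u^(k−1)` for small `t`, and decays to zero as the pool empties —
the four properties the implementation is tested against. The beta
model is deliberately not clipped at zero: its sign change past
`t = 1/β` is its documented structural flaw, and the tests assert it.

`α` is parameterized at the 30-year reference age (age enters as
`t/30`). Two reasons: it matches the `log(30)` offset of the linear
family, and it puts `log α` on a unit scale where an informative prior
is meaningful — at the raw `t^k` scale the rate constant for a
realistic disease is around `e^{-23}`, which no sensible shared prior
block could cover.

### Likelihood

All models share one likelihood convention (a prerequisite for
comparing them by Bayes factors):

```
y_i ~ Normal(mu_i, sqrt(sigma_y_i^2 + sigma_res^2))
```

where `sigma_y_i` is the measurement SD of the log incidence derived
from each bin's 95% interval under a symmetric-on-log-scale normal
approximation, `sigma_y = (log ci_high − log ci_low)/(2·1.96)`, and
`sigma_res` is a residual scale absorbing model misfit. This makes
`sigma_y` invariant to the incidence unit, and it is isolated in
`to_loglog()` so a different uncertainty model can replace it in one
place. Nonlinear models evaluate their mean on the log scale; a
nonpositive beta-model prediction at an observed age has likelihood
zero rather than being silently clipped.

Zero-incidence bins cannot be log-transformed and are never patched
with pseudo-counts (which would bias the slope); `to_loglog()` refuses
them and `drop_zero_incidence()` removes them with a warning. Ages
below the offset age are excluded with a warning. The linear family is
conventionally fitted on ages 30–80, the nonlinear family on the full
range, because the power law demonstrably breaks above ~80 — that
break is the very thing the nonlinear family models.

### Priors

One explicit block (`default_priors()`), stored verbatim in every fit:
slopes ~ Normal(6, 3); intercept levels ~ Normal(0, 3) on the
log-per-100,000 scale; breakpoint ~ Uniform over the central 80% of
the observed `x` range; `σ_res` ~ half-Normal(0, 1); `k` ~ Normal(7, 3)
truncated at 1; `log α` ~ Normal(0, 5); `C` ~ Beta(2, 20);
`β` ~ half-Normal(0, 0.02)/yr. They are informative but moderately
tight, centred on values typical of multistage-incidence applications.
Because marginal likelihoods are prior-sensitive, reported Bayes
factors should be read at the level of their evidence category
(moderate/strong/decisive), not digit-for-digit.

## 2. Posterior computation

Fits run on an unconstrained scale: breakpoints and `C` by (ranged)
logit, `k` by `1 + exp(u)`, and — after less happy experiments with
`log` — the scale parameters `σ_res` and `β` by the *folded*
parameterization `σ = |v|` (Jacobian constant ½; the half-normal prior
on `σ` becomes exactly Normal(0, sd) on `v`). A log-transformed scale
parameter whose posterior piles up at zero leaves the sampler a flat
unbounded tail to wander in; folding removes the boundary entirely and
was the single largest mixing improvement in development.

The two-segment models anchor their level parameter at the median of
the observed `x`, not at `x = 0`: when the data carry only one slope
the breakpoint is weakly identified, and an extrapolated `x = 0`
intercept then sits on an identifiability ridge with slope1 and the
breakpoint (chains visibly stick). The level at an interior point is
always pinned by data. The conventional intercepts at `x = 0` are
reported as derived posterior columns (`intercept1`,
`intercept_female`, `intercept_male`); in a single-slope data set
their wide intervals are a faithful statement of what is not
identified, not a convergence problem.

The sampler is an adaptive Metropolis scheme: during warmup, a
Haario-style running covariance (restarted mid-warmup to shed the
initial transient) with Robbins–Monro scale tuning toward 30%
acceptance; after warmup the proposal is frozen and the kernel mixes
four moves — the adapted random walk (60%), a small-scale random walk
for stiff ridges (15%), an independence proposal from the
warmup-estimated Gaussian (15%), and a heavy-tailed single-coordinate
move (10%) that traverses funnel-like directions. Default policy: 4
chains, 2,000 warmup + 2,000 retained draws each; convergence requires
rank-normalized split-R̂ < 1.01 on the constrained (reported) scale for
every parameter; on failure the fit retries with doubled draws, up to
two escalations, and is otherwise flagged — never silently accepted.
Summaries are the posterior median and the 2.5%/97.5% quantiles.
Identical seed and data give bit-identical draws; chain seeds are
derived independently, so results do not depend on chain order.

## 3. Evidence, Bayes factors, R²

The log marginal likelihood is estimated by iterative optimal bridge
sampling between the posterior draws and a moment-matched multivariate
normal proposal, on the unconstrained scale (the Jacobians are part of
the density, so the evidence equals the constrained-scale evidence).
Two implementation details matter and are oracle-tested:

* folded coordinates make the `v`-posterior symmetric and potentially
  bimodal; evidence is therefore computed on the positive half-space
  with `+log 2` per folded coordinate, restoring unimodality for the
  proposal;
* proposal draws falling outside the support contribute zero to the
  bridge numerator but stay in the draw count — excluding them biases
  the evidence upward by the excluded mass (a bug the quadrature
  oracle caught during development).

Monte-Carlo error is estimated by bootstrap over both draw sets, and
each fit's evidence is derived deterministically from the fit's own
seed, so `BF(a,b)·BF(b,a) = 1` holds exactly and the pairwise BF table
is transitive by construction. The estimator is cross-checked against
a conjugate closed form, tensor-grid quadrature (feasible to 3
parameters), and a semi-analytic oracle that marginalizes slope and
intercept in closed form conditional on `σ_res`. Evidence categories:
BF in [3, 10) moderate, [10, 100) strong, ≥ 100 decisive; BF < 1 is
reported as support for the other model. Evidence is refused, not
approximated, for non-converged fits and for fits whose data
fingerprints differ.

Bayesian R² is the predictive variance decomposition
`Var(pred)/(Var(pred) + Var(resid))` using the per-point posterior
median predictions; it is bounded in [0, 1) and is reported as a
goodness-of-fit descriptor only — model selection runs on Bayes
factors.

## 4. The synthetic-cohort generator

`cohort_spec()`/`simulate_cohort()` generate individual onset ages:
each individual is assigned a subgroup by mixture weight, is
susceptible with probability `C`, and (if susceptible) draws step
durations at sex-multiplied, optionally `(1 − βt)`-attenuated rates;
onset is the sum of durations (sequential) or the last completion
(any-order), censored at `max_age`. `incidence_from_onsets()` converts
onsets to an incidence table with exact person-time integration
(individuals leave the risk set at onset; non-susceptibles contribute
until `max_age`) and Poisson (Garwood) 95% intervals — the real data's
intervals come from an upstream estimation model the package does not
reproduce, and Garwood is the standard exactly-computable stand-in.
`hazard_closed_form()`/`survival_closed_form()` provide the Erlang,
hypoexponential, parallel-system and power-law forms as analytic
oracles for the simulator tests.

Two generative laws, and why both exist:

* `law = "exponential"` draws literal exponential step clocks. Its
  hazard is `∝ t^(k-1)` only while every `rate·t ≪ 1` — the regime of
  the heuristic argument — and in that regime lifetime risk is tiny.
  A mathematical consequence worth stating plainly: *no* literal
  `k`-step exponential process can show a clean `t^(k-1)` power law
  *and* appreciable cumulative risk, because depletion requires
  `(λt)^k/k! ≈ 1`, i.e. `λt ≈ (k!)^{1/k} ≈ 3.8` for `k = 8`, which
  bends the local log-log slope to `k − 1 − λt`.
* `law = "power_law"` therefore uses the limiting form itself,
  `h(t) = (∏rates)·t^(k-1)/(k-1)!`, as the exact onset hazard (a
  Weibull process). This is the generative counterpart of the fitted
  phenomenological models, and the regime a fitted susceptible
  fraction of ~10% implies (susceptibles' lifetime conversion well
  above one half). Susceptible-fraction recovery is tested under this
  law.

In the deep rare-event regime the expected number of onsets between
ages 30 and 80 for a 2-million cohort at `k = 8`, rate 0.004/yr is of
order 10⁻², so no direct simulation can estimate the slope there.
`simulate_cohort(rate_boost = m)` implements importance sampling:
durations are drawn at `m`-fold rates and each individual carries the
exact likelihood ratio (density ratio for observed onsets; survival
ratio at the censoring age for censored individuals). Weighted event
and person-time sums are unbiased for the target rates, and
`incidence_from_onsets()` takes Garwood intervals on the effective
count `(Σw)²/Σw²`. The simulator-vs-theory acceptance check runs the
stated 2×10⁶ cohort with `rate_boost = 10`; the estimand and the
cohort's generative parameters are untouched by the boost.

Reproducibility contract: one root seed; assignment and step-duration
streams are derived separately and laid out per individual, so growing
`n_individuals` extends an existing cohort without reshuffling it.

### The reference cohort and what it does not emulate

The default `cohort_spec()` describes the package's reference
population: a 10%/90% mixture of 6- and 8-step subgroups under the
power-law hazard (per-step rates 0.0402 and 0.042/yr, chosen so the
subgroup hazards cross near age 45 and incidence peaks in the 80s),
female rates 0.94× male (an intercept shift of `k·log 0.94 ≈ −0.5` at
`k = 8`), a 10% susceptible fraction, 1-year bins over ages 30–100,
and 2×10⁵ individuals per sex. These were chosen once to emulate a
PD-like national data set and are not tuned thereafter.

What passing tests on this generator do *not* show about real data:
the mixture's slope change is gradual (subgroup hazards cross smoothly),
not a literal kink, so broken-stick parameters on reference-cohort data
are attenuated relative to a two-segment truth; parameter-recovery
checks therefore generate from the two-segment model directly. Garwood
intervals ignore the correlated uncertainty a probabilistic
case-ascertainment model induces across bins. Diagnostic
misclassification, secular trends, cohort effects and competing
mortality are all outside the generator; person-time is at-risk time
from birth, not from an observation window.

## 5. Pipeline and reporting

`run_analysis()` mirrors the canonical inferential sequence: linear
fit (ages 30–80) → broken stick → sex-intercept → sex-slope → beta and
susceptibility on the full range; the ladder, windows, priors, sampler
settings and seed sit in one `analysis_config()`. Outputs are CSV
parameter/BF/steps tables, JSON fit summaries, draw CSVs, and three
figures (incidence with intervals; log–log fit with segments extended
as dashed lines past the breakpoint; full-range model overlay).
Re-running a config reproduces every table byte-identically; stage
failures retain partial outputs and write a failure manifest. The
steps table is `slope + 1` from the fits' own draws — no independent
recomputation that could drift. A thin CLI
(`inst/cli/multistep.R`: `simulate`, `fit`, `compare`, `run`) wraps
these functions for shell use.

## 6. Problem sizes

The test suite fits with the default 4×(2,000+2,000) sampler and
simulates cohorts of 10⁴–10⁵ individuals; the acceptance checks use
2×10⁶ (importance-sampled slope check), 5×10⁵ (susceptibility
recovery) and 10⁵ (sex mechanism). These sizes put Monte-Carlo error
comfortably inside the tested tolerances while keeping a full run in
minutes on one core. The 95%-coverage style calibration of
`fit_linear` is exercised in scaled-down form (replicate fits at unit
scale) through the parameter-recovery tests rather than a hundred-fold
replication.

## 7. Known limitations

* The measurement model treats per-bin intervals as independent
  symmetric-on-log normals; a deposited data set whose intervals come
  from a joint posterior violates this mildly.
* The susceptibility model treats susceptibility as binary; a graded
  (frailty-spectrum) pool is out of scope by design.
* Bayes factors inherit prior sensitivity; only evidence categories
  are claimed reproducible.
* The discontinuous broken-stick variant (`continuity = FALSE`) is a
  sensitivity flag; its jump parameter is weakly identified on smooth
  data and its posterior mixes noticeably more slowly.
* Individual-level inference (how many steps a given patient has
  undergone) is meaningless in this framework and deliberately
  unsupported.
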