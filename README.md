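# multistep

Multistage (Armitage–Doll) models of age-specific disease incidence, in R.

## The scientific problem

Many chronic diseases — cancers classically, and some neurodegenerative
disorders — show incidence that rises as a power of age. If onset
requires completing `k` rare, independent steps (each with a small,
roughly constant yearly probability), then incidence follows

```
I(t) = α · t^(k−1)
```

so that on a log–log plot

```
log I(t) = (k − 1) · log t + c ,        c = log α ,
```

a straight line whose **slope is one less than the number of steps**.
Deviations from the single straight line are themselves informative:

* a **breakpoint** in the slope (broken-stick regression with an unknown
  changepoint `t_bp`) indicates a mixture of subpopulations needing
  different numbers of steps — e.g. younger-onset cases under stronger
  genetic load requiring fewer additional hits;
* a **sex difference in intercept but not slope** indicates different
  exposure levels rather than a different pathogenic mechanism (scaling
  every step rate by `m` shifts `c` by `k·log m` and leaves the slope
  untouched);
* the **drop-off of incidence at very old ages** can be modelled either
  by an extinction factor, `I(t) = α t^(k−1) (1 − βt)` (the *beta
  model*, which turns negative past `t = 1/β`), or by a **susceptible
  fraction** `C`: only a fraction of the population can ever develop the
  disease, and depletion of that pool bends incidence down,
  `I(t) = α u^(k−1) / [1 + ((1−C)/C)·exp(Λ(t))]` with `u = t/30` and
  `Λ` the cumulative per-person hazard.

The package provides this complete workflow for epidemiologists working
from age–sex incidence tables: a validated data model with credible
intervals and the measurement-error log–log transform; a stochastic
multistep cohort simulator (sequential or any-order steps, subgroup
mixtures, sex exposure multipliers, susceptible fractions, extinction,
rare-event importance sampling); Bayesian fits of the five incidence
models by an adaptive-Metropolis sampler; bridge-sampling marginal
likelihoods with Bayes-factor comparison (moderate 3–10, strong 10–100,
decisive >100) and Bayesian R²; and an end-to-end pipeline with report
tables and figures.

## Worked example

Recovering a two-segment power law — slopes 5.2 and 6.8 with a
breakpoint at `x = log(age) − log(30) = 0.41` (age 45) — from noisy
log-scale incidence, then asking whether the data justify the
changepoint at all:

```r
library(multistep)
ages <- 30:80
x <- log(ages / 30)
set.seed(42)
y <- 5.2 * pmin(x, 0.41) + 6.8 * pmax(x - 0.41, 0) + rnorm(51, 0, 0.05)
pts <- loglog_points(x, y, sigma_y = 0.05)

bs <- fit_broken_stick(pts, seed = 1)
bs
#> <ms_fit> model 'broken_stick', 16000 posterior draws
#>    parameter  median      q2.5   q97.5  rhat    ess
#> 1     slope1 5.14800  4.940000 5.32900 1.004 1124.0
#> 2     slope2 6.85300  6.736000 6.97500 1.007 1017.0
#> 3 breakpoint 0.43590  0.397200 0.46750 1.007  990.6
#> 4      level 3.44600  3.422000 3.46900 1.004 1080.0
#> 5  sigma_res 0.02207  0.001332 0.04703 1.002 1886.0
#> 6 intercept1 0.03440 -0.015840 0.08742    NA     NA

steps_from_slope(bs, "slope2")$nearest_integer   # slope + 1
#> steps after the breakpoint: 7.9 [7.7, 8.0] -> 8

bayes_factor(bs, fit_linear(pts, seed = 1))
#> BF(broken_stick / linear) = 3.565e+15 [log BF 35.810 +/- 0.004]:
#>   decisive evidence for broken_stick
```

The posterior medians land on the generating truth (5.15 / 6.85,
breakpoint 0.436 ≈ age 46), the post-breakpoint step count reads 8, and
the evidence for the changepoint is decisive. `bayesian_r_squared()`
gives 0.995 for the straight line and 0.999 for the broken stick — on
log-linear data both fit "well", which is exactly why model comparison
runs on Bayes factors rather than R².

Simulating the old-age drop-off and recovering the susceptible
fraction:

```r
spec <- cohort_spec(n_individuals = 5e5,
                    subgroups = step_process(8, 0.0455, law = "power_law"),
                    sexes = "combined",
                    sex_rate_multiplier = c(combined = 1),
                    susceptible_fraction = 0.10, max_age = 100,
                    age_bins = seq(30, 100, 1), seed = 7)
full <- incidence_from_onsets(simulate_cohort(spec))
#> simulated incidence peaks at age 82 and then falls
sus <- fit_nonlinear(drop_zero_incidence(full), "susceptibility", seed = 2)
summary(sus)
#>   parameter      median         q2.5      q97.5     rhat      ess
#> 1 log_alpha 2.096311890 2.0353349756 2.16089476 1.003496 1421.992
#> 2         k 7.980801492 7.9097302545 8.04751337 1.003664 1472.652
#> 3         C 0.100117405 0.0992447481 0.10098900 1.002988 1536.734
#> 4 sigma_res 0.006039917 0.0002854477 0.01905623 1.000856 2088.155
```

The fit recovers `k = 7.98` and `C = 0.100` against generating values of
8 and 0.10.

A full analysis — load or simulate a table, fit the model ladder
(linear → broken-stick → sex models over ages 30–80; beta and
susceptibility over the full range), compute the pairwise Bayes-factor
table and figures — runs from one config:

```r
report <- run_analysis(analysis_config(cohort_spec(seed = 1), seed = 1,
                                       out_dir = "analysis-out"))
```

or from a shell via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/multistep.R", package="multistep"))')" \
    run --config analysis.yaml --seed 1 --out analysis-out
```

For fitting a real national incidence table, `read_incidence_table()`
takes a `dialect` argument mapping your file's column names, so
deposited data sets can be read without editing them.

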