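single_process_spec <- function(process, n, max_age = Inf, C = 1,
                                seed = 7, bins = seq(30, 80, 1)) {
  cohort_spec(n_individuals = n, subgroups = process, sexes = "combined",
              sex_rate_multiplier = c(combined = 1),
              susceptible_fraction = C, max_age = max_age, age_bins = bins,
              seed = seed)
}

test_that("cohort specification enforces its invariants", {
  expect_error(single_process_spec(step_process(8, 0.004), 100, C = 0),
               "susceptible_fraction")
  expect_error(cohort_spec(subgroups = list(
    list(weight = 0.5, process = step_process(2, 0.1)))), "sum to 1")
  expect_error(step_process(0, 0.1), "k must be")
  expect_error(step_process(2, c(0.1, -0.1)), "rates")
  expect_error(cohort_spec(n_individuals = 0), "n_individuals")
})

test_that("a one-step process is exponential and k steps are Erlang", {
  lam <- 0.05
  s1 <- simulate_cohort(single_process_spec(step_process(1, lam), 2e4))
  expect_equal(mean(s1$onset), 1 / lam, tolerance = 0.03)

  # 8 sequential equal-rate steps: onset ages follow Erlang(8, rate)
  s8 <- simulate_cohort(single_process_spec(step_process(8, 0.004), 1e5))
  ks <- suppressWarnings(
    stats::ks.test(s8$onset, stats::pgamma, shape = 8, rate = 0.004))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("closed-form hazard matches limits and numerical differentiation", {
  lam <- 0.01
  expect_equal(hazard_closed_form(step_process(1, lam), c(0, 10, 200)),
               rep(lam, 3))
  # two equal-rate steps: leading order lambda^2 t as t -> 0
  t0 <- 1e-4
  expect_equal(hazard_closed_form(step_process(2, lam), t0), lam^2 * t0,
               tolerance = 1e-5)
  # hazard = -d/dt log S(t), checked by Richardson-extrapolated differences
  num_hazard <- function(process, t, h = 1e-3) {
    ls <- function(u) log(survival_closed_form(process, u))
    -(-ls(t + 2 * h) + 8 * ls(t + h) - 8 * ls(t - h) + ls(t - 2 * h)) /
      (12 * h)
  }
  for (pr in list(step_process(8, 0.004),
                  step_process(3, c(0.01, 0.02, 0.04)),
                  step_process(3, c(0.01, 0.02, 0.04),
                               ordering = "any_order"),
                  step_process(8, 0.042, law = "power_law"))) {
    expect_equal(hazard_closed_form(pr, 60), num_hazard(pr, 60),
                 tolerance = 1e-8, label = pr$law)
  }
  expect_error(hazard_closed_form(step_process(2, 0.1), -1),
               class = "multistep_domain_error")
})

test_that("binning computes incidence and Garwood intervals exactly", {
  # one onset at age 40.5 among ~100,000 person-years in bin [40, 41)
  n <- 1e5
  samples <- structure(
    data.frame(sex = "combined", subgroup = 1L,
               susceptible = c(TRUE, rep(FALSE, n - 1)),
               onset = c(40.5, rep(NA_real_, n - 1)),
               censored = c(FALSE, rep(TRUE, n - 1)),
               weight = 1),
    max_age = 50, age_bins = c(40, 41, 42),
    class = c("onset_samples", "data.frame"))
  tab <- incidence_from_onsets(samples)
  py1 <- (n - 1) + 0.5
  expect_equal(tab$incidence[1], 1 / py1 * 1e5)
  expect_equal(tab$ci_low[1], qgamma(0.025, 1) / py1 * 1e5)
  expect_equal(tab$ci_high[1], qgamma(0.975, 2) / py1 * 1e5)
  # zero-event bin: Garwood upper bound 3.689 / PY
  py2 <- n - 1                       # the case left the risk set at onset
  expect_equal(tab$incidence[2], 0)
  expect_equal(tab$ci_high[2], qgamma(0.975, 1) / py2 * 1e5)
  expect_equal(tab$ci_high[2], 3.6889 / py2 * 1e5, tolerance = 1e-4)
})

test_that("importance-sampled rare-step cohort recovers slope k - 1", {
  spec <- single_process_spec(step_process(8, 0.004), 3e5, max_age = 100,
                              bins = seq(30, 80, 1), seed = 12)
  s <- simulate_cohort(spec, rate_boost = 10)
  tab <- suppressWarnings(incidence_from_onsets(s))
  pts <- to_loglog(suppressWarnings(drop_zero_incidence(tab)))
  slope <- unname(coef(lm(y ~ x, data = pts, weights = 1 / pts$sigma_y^2))[2])
  expect_gt(slope, 6.4)
  expect_lt(slope, 7.4)
  expect_equal(expected_loglog_slope(step_process(8, 0.004)), 7)
  expect_equal(expected_loglog_slope(step_process(1, 1)), 0)
})

test_that("identical seeds reproduce bit-identical cohorts and n extends", {
  spec <- single_process_spec(step_process(4, 0.02), 5000, max_age = 100)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$onset, b$onset)
  spec_big <- single_process_spec(step_process(4, 0.02), 8000,
                                  max_age = 100)
  big <- simulate_cohort(spec_big)
  expect_identical(big$onset[seq_len(5000)], a$onset)
})

test_that("rate multipliers shift the intercept but not the slope", {
  base <- step_process(8, 0.03, law = "power_law")
  mult <- 1.2
  spec <- cohort_spec(n_individuals = 2e5, subgroups = base,
                      sexes = c("female", "male"),
                      sex_rate_multiplier = c(female = 1, male = mult),
                      susceptible_fraction = 1, max_age = 80,
                      age_bins = seq(30, 80, 1), seed = 21)
  tab <- suppressWarnings(incidence_from_onsets(simulate_cohort(spec)))
  pts <- to_loglog(suppressWarnings(drop_zero_incidence(tab)))
  fits <- lapply(split(pts, pts$sex), function(d)
    coef(lm(y ~ x, data = d, weights = 1 / d$sigma_y^2)))
  slope_diff <- fits$male[["x"]] - fits$female[["x"]]
  int_diff <- fits$male[["(Intercept)"]] - fits$female[["(Intercept)"]]
  expect_lt(abs(slope_diff), 0.25)
  expect_equal(int_diff, 8 * log(mult), tolerance = 0.1)
})

test_that("a susceptible fraction below 1 produces the old-age drop-off", {
  spec <- cohort_spec(n_individuals = 1e5, seed = 31)  # reference cohort
  tab <- suppressWarnings(incidence_from_onsets(simulate_cohort(spec)))
  comb <- tab[tab$sex == "male", ]
  expect_lt(comb$incidence[nrow(comb)], max(comb$incidence))
  # lifetime cumulative disease probability cannot exceed C
  s <- simulate_cohort(spec)
  p_disease <- mean(!is.na(s$onset))
  expect_lte(p_disease, 0.10)
})

test_that("extinction attenuation suppresses late onsets", {
  pr <- step_process(2, 0.05)
  sp0 <- single_process_spec(pr, 2e4, max_age = 100, seed = 5)
  spb <- cohort_spec(n_individuals = 2e4, subgroups = pr,
                     sexes = "combined",
                     sex_rate_multiplier = c(combined = 1),
                     susceptible_fraction = 1, extinction_beta = 0.012,
                     max_age = 100, age_bins = seq(30, 80, 1), seed = 5)
  on0 <- simulate_cohort(sp0)
  onb <- simulate_cohort(spb)
  # with hazard factor (1 - beta t), no step can complete after 1/beta
  expect_true(all(onb$onset[!onb$censored] <= 1 / 0.012 + 1e-9))
  expect_lt(mean(!is.na(onb$onset)), mean(!is.na(on0$onset)))
})
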