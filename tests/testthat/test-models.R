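test_that("power-law predictor is the straight line in log-log space", {
  expect_equal(predict_armitage_doll(list(slope = 3, intercept = 2), 0), 2)
  expect_equal(predict_armitage_doll(list(slope = 0, intercept = 1.5),
                                     c(-1, 0, 2)), rep(1.5, 3))
  expect_equal(predict_armitage_doll(list(slope = 6.5, intercept = 0),
                                     log(2)), 4.5056, tolerance = 1e-4)
})

test_that("beta predictor reduces to the power law and crosses zero", {
  tgrid <- seq(31, 100, by = 0.5)
  p0 <- list(alpha = 5, k = 8, beta = 0)
  expect_equal(predict_beta(p0, tgrid), 5 * (tgrid / 30)^7)
  pb <- list(alpha = 5, k = 8, beta = 0.011)
  expect_equal(predict_beta(pb, 1 / 0.011), 0)
  expect_lt(predict_beta(pb, 1.05 / 0.011), 0)   # negative past the root
})

test_that("susceptibility predictor satisfies its three limit properties", {
  tgrid <- seq(31, 120, by = 0.5)
  # C = 1: exact reduction to the power law
  expect_equal(predict_susceptibility(list(alpha = 5, k = 8, C = 1), tgrid),
               5 * (tgrid / 30)^7, tolerance = 1e-14)
  # t -> 0+: leading order C * alpha * (t/30)^(k-1)
  ps <- list(alpha = 5, k = 8, C = 0.1)
  t0 <- 1e-3
  expect_equal(predict_susceptibility(ps, t0),
               0.1 * 5 * (t0 / 30)^7, tolerance = 1e-6)
  # large t: nonnegative everywhere and decaying to zero
  vals <- predict_susceptibility(list(alpha = 50, k = 8, C = 0.1),
                                 seq(31, 500, 1))
  expect_true(all(vals >= 0))
  expect_lt(vals[length(vals)], 1e-6)
  # unimodal in t for C < 1: one sign change of the finite differences
  # (above the underflow floor, where differences are meaningful)
  v <- predict_susceptibility(list(alpha = 50, k = 8, C = 0.1),
                              seq(31, 300, 0.5))
  v <- v[v > max(v) * 1e-12]
  expect_equal(sum(diff(sign(diff(v))) != 0), 1)
  # no overflow for extreme cumulative hazards (computed in log space)
  expect_equal(predict_susceptibility(ps, 1e4), 0)
})

test_that("step counts are slope + 1 with integer interval coverage", {
  st <- steps_from_slope(rep(6.8, 100))
  expect_equal(st$median, 7.8)
  expect_equal(st$nearest_integer, 8)
  st2 <- steps_from_slope(seq(3.73, 6.47, length.out = 4000))
  expect_equal(st2$integers, c(5, 6, 7))
  expect_equal(steps_from_slope(rep(0, 10))$median, 1)
})

test_that("measurement-error linear fit recovers a known slope", {
  pts <- make_linear_points(slope = 6.5, intercept = 0, sigma = 0.01,
                            seed = 3)
  f <- fit_linear(pts, mcmc = quick_mcmc(), seed = 4)
  expect_true(f$converged)
  s <- summary(f)
  expect_lt(abs(s$median[s$parameter == "slope"] - 6.5), 0.05)
  expect_lt(abs(s$median[s$parameter == "intercept"]), 0.05)

  flat <- loglog_points(log((30:60) / 30), rep(2, 31), 0.05)
  ff <- fit_linear(flat, mcmc = quick_mcmc(), seed = 5)
  sf <- summary(ff)
  expect_lt(abs(sf$median[sf$parameter == "slope"]), 0.1)
})

test_that("broken-stick fit collapses gracefully on single-slope data", {
  pts <- make_linear_points(slope = 6, sigma = 0.05, seed = 8)
  f <- suppressWarnings(fit_broken_stick(pts, mcmc = quick_mcmc(),
                                         seed = 9))
  dd <- posterior_draws(f, "slope2") - posterior_draws(f, "slope1")
  ci <- quantile(dd, c(0.025, 0.975))
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
  # posterior predictive means agree with the plain linear fit
  fl <- fit_linear(pts, mcmc = quick_mcmc(), seed = 10)
  mu_bs <- apply(multistep:::posterior_mu(f), 2, median)
  mu_l <- apply(multistep:::posterior_mu(fl), 2, median)
  expect_lt(max(abs(mu_bs - mu_l)), 0.05)
})

test_that("broken-stick fit recovers two distinct slopes and the breakpoint", {
  pts <- make_bs_points(slope1 = 4, slope2 = 8, bp = 0.5, sigma = 0.05,
                        seed = 11)
  f <- fit_broken_stick(pts, mcmc = quick_mcmc(), seed = 12)
  s <- summary(f)
  med <- setNames(s$median, s$parameter)
  expect_lt(abs(med[["slope1"]] - 4), 0.4)
  expect_lt(abs(med[["slope2"]] - 8), 0.4)
  expect_lt(abs(med[["breakpoint"]] - 0.5), 0.1)
})

test_that("sex model finds no differences when the sexes are identical", {
  pts <- rbind(make_bs_points(sigma = 0.05, seed = 13, sex = "female"),
               make_bs_points(sigma = 0.05, seed = 14, sex = "male"))
  class(pts) <- c("loglog_points", "data.frame")
  f <- suppressWarnings(fit_sex_model(pts, "vary_intercept",
                                      mcmc = quick_mcmc(), seed = 15))
  dd <- posterior_draws(f, "level_female") - posterior_draws(f, "level_male")
  ci <- quantile(dd, c(0.025, 0.975))
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("fits are deterministic under the seed", {
  pts <- make_linear_points(sigma = 0.05, seed = 16)
  f1 <- fit_linear(pts, mcmc = quick_mcmc(), seed = 17)
  f2 <- fit_linear(pts, mcmc = quick_mcmc(), seed = 17)
  expect_identical(f1$draws, f2$draws)
  expect_identical(summary(f1), summary(f2))
})

test_that("beta fit concentrates near zero when there is no drop-off", {
  ages <- seq(30.5, 99.5, 1)
  inc <- 4 * (ages / 30)^7
  tab <- incidence_table(age = ages, sex = "combined", incidence = inc,
                         ci_low = inc * exp(-0.1), ci_high = inc * exp(0.1))
  f <- suppressWarnings(fit_nonlinear(tab, "beta", mcmc = quick_mcmc(),
                                      seed = 18))
  s <- summary(f)
  expect_lt(s$q97.5[s$parameter == "beta"], 0.004)
  expect_lt(abs(s$median[s$parameter == "k"] - 8), 0.4)
})

test_that("posterior sampler cross-checks against JAGS on the linear model", {
  pts <- make_linear_points(slope = 6.5, sigma = 0.08, seed = 19)
  f <- fit_linear(pts, mcmc = quick_mcmc(), seed = 20)
  jags_code <- "model {
    for (i in 1:N) {
      y[i] ~ dnorm(slope * x[i] + intercept, 1 / (sy[i]^2 + sres^2))
    }
    slope ~ dnorm(6, 1/9)
    intercept ~ dnorm(0, 1/9)
    sres ~ dnorm(0, 1) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(jags_code),
                          data = list(y = pts$y, x = pts$x,
                                      sy = pts$sigma_y, N = nrow(pts)),
                          n.chains = 2, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  sam <- rjags::coda.samples(jm, c("slope", "intercept"), 4000,
                             progress.bar = "none")
  jag <- as.matrix(sam)
  s <- summary(f)
  expect_lt(abs(s$median[s$parameter == "slope"] -
                  median(jag[, "slope"])), 0.02)
  expect_lt(abs(s$median[s$parameter == "intercept"] -
                  median(jag[, "intercept"])), 0.02)
  expect_equal(sd(posterior_draws(f, "slope")), sd(jag[, "slope"]),
               tolerance = 0.15)
})
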