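# Shared fixtures: everything is generated in code at test time.

# fast sampler settings for unit tests; acceptance tests use the defaults
quick_mcmc <- function(...) mcmc_control(warmup = 800, iter = 800, ...)

# log-log points from a known two-segment truth (continuous at bp)
make_bs_points <- function(slope1 = 5.2, slope2 = 6.8, bp = 0.41,
                           intercept = 0, sigma = 0.05, ages = 30:80,
                           seed = 1, sex = "combined") {
  x <- log(ages / 30)
  mu <- intercept + slope1 * pmin(x, bp) + slope2 * pmax(x - bp, 0)
  y <- mu + withr::with_seed(seed, stats::rnorm(length(x), 0, sigma))
  loglog_points(x, y, sigma, sex = sex)
}

make_linear_points <- function(slope = 6.5, intercept = 0, sigma = 0.05,
                               ages = 30:80, seed = 1) {
  make_bs_points(slope, slope, 0.5, intercept, sigma, ages, seed)
}

# native-dialect CSV on disk; returns the path
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

small_table <- function() {
  incidence_table(age = c(60, 70, 60, 70), sex = c("male", "male",
                                                   "female", "female"),
                  incidence = c(120, 260, 80, 170),
                  ci_low = c(100, 230, 65, 150),
                  ci_high = c(140, 290, 95, 190))
}
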