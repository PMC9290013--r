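test_that("reader accepts a minimal valid table and rejects broken rows", {
  p <- write_fixture_csv(data.frame(age = 60, sex = "male", incidence = 120,
                                    ci_low = 100, ci_high = 140))
  tab <- read_incidence_table(p)
  expect_s3_class(tab, "incidence_table")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$incidence, 120)

  bad <- write_fixture_csv(data.frame(age = c(60, 65), sex = "male",
                                      incidence = c(120, 130),
                                      ci_low = c(100, 150),  # inverted CI
                                      ci_high = c(140, 140)))
  expect_error(read_incidence_table(bad), "2")
  expect_warning(tab2 <- read_incidence_table(bad, on_invalid = "drop"),
                 "dropping")
  expect_equal(nrow(tab2), 1L)

  nocol <- write_fixture_csv(data.frame(age = 60, sex = "male"))
  expect_error(read_incidence_table(nocol), "incidence",
               class = "multistep_config_error")
})

test_that("dialect mapping reads foreign column layouts unchanged", {
  p <- write_fixture_csv(data.frame(age_midpoint = c(50, 60), gender = "F",
                                    rate = c(30, 80), lo = c(25, 70),
                                    hi = c(36, 90)))
  tab <- read_incidence_table(p, dialect = c(age = "age_midpoint",
                                             sex = "gender",
                                             incidence = "rate",
                                             ci_low = "lo", ci_high = "hi"))
  expect_equal(tab$age, c(50, 60))
  expect_equal(unique(tab$sex), "female")
})

test_that("write/read round-trips a table bit-identically", {
  tab <- incidence_table(age = c(60.5, 70.5), sex = "male",
                         incidence = c(120.25, 1 / 3),
                         ci_low = c(100.125, 0.2),
                         ci_high = c(140 + 1e-9, 0.5),
                         person_years = c(12345.678, 23456.789),
                         cases = c(14.82, 0.5))
  p <- tempfile(fileext = ".csv")
  write_incidence_table(tab, p)
  back <- read_incidence_table(p)
  for (col in c("age", "incidence", "ci_low", "ci_high", "person_years",
                "cases"))
    expect_identical(back[[col]], tab[[col]], label = col)
})

test_that("constructor enforces the rate and interval invariants", {
  expect_error(incidence_table(60, "male", -1, -1, 2),
               class = "multistep_validation_error")
  expect_error(incidence_table(60, "male", 120, 130, 140),
               class = "multistep_validation_error")
  expect_error(incidence_table(c(60, 60), "male", c(1, 2), c(1, 2), c(1, 2)),
               "duplicate", class = "multistep_validation_error")
  expect_error(incidence_table(60, "unknown", 1, 1, 1),
               class = "multistep_validation_error")
})

test_that("log-log transform matches its closed form and inverts exactly", {
  tab <- incidence_table(age = c(30, 60), sex = "combined",
                         incidence = c(1, 120), ci_low = c(0.5, 100),
                         ci_high = c(2, 140))
  pts <- to_loglog(tab)
  expect_equal(pts$x[1], 0)                       # age 30 -> x = 0
  expect_equal(pts$y[1], 0)                       # rate 1 -> y = 0
  # invertibility to machine precision
  expect_equal(exp(pts$y), tab$incidence, tolerance = 1e-15)
  expect_equal(exp(pts$x + log(30)), tab$age, tolerance = 1e-15)

  tab2 <- incidence_table(age = 60, sex = "combined", incidence = 4,
                          ci_low = 2, ci_high = 8)
  pts2 <- to_loglog(tab2)
  expect_equal(pts2$sigma_y, log(4) / (2 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(pts2$sigma_y, 0.35368, tolerance = 1e-4)

  # sigma_y is scale-free: same table in different rate units
  tab3 <- incidence_table(age = 60, sex = "combined", incidence = 400,
                          ci_low = 200, ci_high = 800)
  expect_equal(to_loglog(tab3)$sigma_y, pts2$sigma_y)
})

test_that("zero rates and too-young ages are handled explicitly", {
  tab <- incidence_table(age = c(25, 40, 50), sex = "combined",
                         incidence = c(5, 0, 50), ci_low = c(4, 0, 45),
                         ci_high = c(6, 1, 55))
  expect_error(to_loglog(tab), "drop_zero_incidence",
               class = "multistep_validation_error")
  expect_warning(tab_nz <- drop_zero_incidence(tab), "zero-incidence")
  expect_warning(pts <- to_loglog(tab_nz), "younger")
  expect_equal(pts$age, 50)
})

test_that("age filtering keeps the window and refuses empty results", {
  ages <- 30:100
  tab <- incidence_table(age = rep(ages, 2),
                         sex = rep(c("female", "male"), each = length(ages)),
                         incidence = rep(10, 2 * length(ages)),
                         ci_low = rep(9, 2 * length(ages)),
                         ci_high = rep(11, 2 * length(ages)))
  expect_message(out <- filter_age_range(tab, 30, 80), "dropped 40")
  expect_equal(nrow(out), 2 * 51)                 # 51 one-year rows per sex
  expect_true(all(out$age >= 30 & out$age <= 80))
  tab2 <- incidence_table(age = c(85, 90), sex = "combined",
                          incidence = c(1, 1), ci_low = c(1, 1),
                          ci_high = c(1, 1))
  expect_error(filter_age_range(tab2, 30, 80), "no records")
  expect_error(filter_age_range(tab2, 90, 80), "min_age",
               class = "multistep_config_error")
})

test_that("standardized mean onset age matches hand-computed values", {
  pm <- incidence_table(age = c(60, 70, 80), sex = "combined",
                        incidence = c(0, 15, 0), ci_low = c(0, 12, 0),
                        ci_high = c(0, 18, 0))
  expect_equal(mean_onset_age(pm)$mean_age, 70)   # point mass

  sym <- incidence_table(age = c(60, 80), sex = "combined",
                         incidence = c(10, 10), ci_low = c(8, 8),
                         ci_high = c(12, 12))
  expect_equal(mean_onset_age(sym)$mean_age, 70)  # symmetric

  tab <- incidence_table(age = c(60, 70, 80), sex = "combined",
                         incidence = c(10, 20, 30), ci_low = c(9, 18, 27),
                         ci_high = c(11, 22, 33))
  w <- c(`60` = 0.5, `70` = 0.3, `80` = 0.2)
  res <- mean_onset_age(tab, weights = w)
  expect_equal(res$mean_age, 1200 / 17, tolerance = 1e-12)
  expect_true(res$ci_low < res$mean_age && res$mean_age < res$ci_high)
  expect_error(mean_onset_age(tab, weights = c(`60` = 1)),
               class = "multistep_config_error")
})

test_that("JSON export carries data and metadata", {
  js <- jsonlite::fromJSON(as_incidence_json(small_table()))
  expect_equal(nrow(js$data), 4)
  expect_equal(js$units_label, "per 100,000 person-years")
})
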