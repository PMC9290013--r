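#' Construct an age-sex incidence table
#'
#' An incidence table is the universal input of the package: one row per
#' (age bin, sex) holding the incidence rate (per 100,000 person-years by
#' convention) together with a 95% uncertainty interval, and optionally the
#' person-years denominator and (possibly fractional) case count.
#'
#' @param age numeric vector of bin-midpoint ages in years, `>= 0`.
#' @param sex character vector; each element one of `"female"`, `"male"`,
#'   `"combined"`.
#' @param incidence incidence rate per `units_label`, `>= 0`.
#' @param ci_low,ci_high bounds of the 95% interval, same units;
#'   `ci_low <= incidence <= ci_high`.
#' @param person_years optional exposure denominator (person-years).
#' @param cases optional expected case count; may be non-integer when the
#'   upstream case-ascertainment model sums per-individual probabilities.
#' @param units_label unit of the rates; the default and internal
#'   convention is `"per 100,000 person-years"`.
#' @param source free-text provenance label.
#' @return An object of class `incidence_table`: a `data.frame` with
#'   columns `age`, `sex`, `incidence`, `ci_low`, `ci_high`
#'   (`person_years`, `cases` when supplied) and attributes `units_label`
#'   and `source`.  Rows are sorted by sex then age; `(age, sex)` pairs are
#'   unique.
#' @examples
#' tab <- incidence_table(age = c(60, 70), sex = "male",
#'                        incidence = c(120, 260),
#'                        ci_low = c(100, 230), ci_high = c(140, 290))
#' tab
#' @export
incidence_table <- function(age, sex, incidence, ci_low, ci_high,
                            person_years = NULL, cases = NULL,
                            units_label = "per 100,000 person-years",
                            source = "unspecified") {
  n <- max(length(age), length(sex), length(incidence))
  df <- data.frame(age = as.numeric(age),
                   sex = normalize_sex(rep_len(as.character(sex), n)),
                   incidence = as.numeric(incidence),
                   ci_low = as.numeric(ci_low),
                   ci_high = as.numeric(ci_high),
                   stringsAsFactors = FALSE)
  if (!is.null(person_years)) df$person_years <- as.numeric(person_years)
  if (!is.null(cases)) df$cases <- as.numeric(cases)
  df <- df[order(df$sex, df$age), , drop = FALSE]
  rownames(df) <- NULL
  out <- structure(df, units_label = units_label, source = source,
                   class = c("incidence_table", "data.frame"))
  validate_incidence_table(out)
  out
}

normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c(female = "female", f = "female", male = "male", m = "male",
           combined = "combined", all = "combined", both = "combined",
           total = "combined")
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop_ms("unrecognized sex label(s): %s (expected female/male/combined)",
            paste(bad, collapse = ", "), class = "multistep_validation_error")
  }
  out
}

validate_incidence_table <- function(x) {
  problems <- character(0)
  row_issue <- function(i, what) sprintf("row %d: %s", i, what)
  for (i in seq_len(nrow(x))) {
    if (is.na(x$age[i]) || x$age[i] < 0)
      problems <- c(problems, row_issue(i, "age must be >= 0"))
    if (is.na(x$incidence[i]) || x$incidence[i] < 0)
      problems <- c(problems, row_issue(i, "incidence must be >= 0"))
    if (is.na(x$ci_low[i]) || is.na(x$ci_high[i]) ||
        x$ci_low[i] < 0 || x$ci_high[i] < 0)
      problems <- c(problems, row_issue(i, "interval bounds must be >= 0"))
    else if (x$ci_low[i] > x$incidence[i] || x$incidence[i] > x$ci_high[i])
      problems <- c(problems,
                    row_issue(i, "requires ci_low <= incidence <= ci_high"))
  }
  key <- paste(x$age, x$sex)
  if (anyDuplicated(key))
    problems <- c(problems, sprintf("duplicate (age, sex) pair(s): %s",
                                    paste(unique(key[duplicated(key)]),
                                          collapse = "; ")))
  if (length(problems))
    stop_ms("invalid incidence table:\n  %s",
            paste(problems, collapse = "\n  "),
            class = "multistep_validation_error")
  invisible(x)
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("<incidence_table> %d records, %s sex group(s), ages %g-%g\n",
              nrow(x), length(unique(x$sex)), min(x$age), max(x$age)))
  cat(sprintf("  units: %s | source: %s\n",
              attr(x, "units_label"), attr(x, "source")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Read an incidence table from CSV
#'
#' Reads a CSV of age-sex-specific incidence rates.  The native column
#' layout is `age,sex,incidence,ci_low,ci_high[,person_years,cases]`; other
#' layouts (for example a deposited data set with its own headers) are
#' handled through `dialect`, a named character vector mapping the native
#' names to the file's column names, so foreign files never need editing.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param dialect named character vector, e.g.
#'   `c(age = "age_group_midpoint", incidence = "rate")`; unmapped names
#'   are looked up verbatim.
#' @param units_label,source stored on the returned table.
#' @param rate_scale multiply rates (and bounds) by this factor on input,
#'   for files not already per 100,000 person-years.
#' @param on_invalid `"error"` (default) aborts naming every offending row;
#'   `"drop"` removes offending rows with a per-row warning report.
#' @return A validated [incidence_table()].
#' @export
read_incidence_table <- function(path, dialect = NULL,
                                 units_label = "per 100,000 person-years",
                                 source = basename(path), rate_scale = 1,
                                 on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path))
    stop_ms("file not found: %s", path, class = "multistep_config_error")
  # everything read as character: type-sniffing would turn sex labels
  # like "F" into logicals; numeric columns are converted explicitly
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character")
  need <- c("age", "sex", "incidence", "ci_low", "ci_high")
  opt <- c("person_years", "cases")
  colmap <- stats::setNames(c(need, opt), c(need, opt))
  if (!is.null(dialect)) colmap[names(dialect)] <- dialect
  for (nm in c("age", "sex", "incidence")) {
    if (!colmap[[nm]] %in% names(raw))
      stop_ms("required column '%s' (mapped to '%s') not found in %s",
              nm, colmap[[nm]], path, class = "multistep_config_error")
  }
  get_col <- function(nm) if (colmap[[nm]] %in% names(raw)) raw[[colmap[[nm]]]] else NULL
  inc <- as.numeric(get_col("incidence")) * rate_scale
  lo <- get_col("ci_low"); hi <- get_col("ci_high")
  lo <- if (is.null(lo)) inc else as.numeric(lo) * rate_scale
  hi <- if (is.null(hi)) inc else as.numeric(hi) * rate_scale
  df <- data.frame(age = as.numeric(get_col("age")),
                   sex = normalize_sex(get_col("sex")),
                   incidence = inc, ci_low = lo, ci_high = hi,
                   stringsAsFactors = FALSE)
  if (!is.null(get_col("person_years")))
    df$person_years <- as.numeric(get_col("person_years"))
  if (!is.null(get_col("cases"))) df$cases <- as.numeric(get_col("cases"))

  bad <- which(is.na(df$age) | df$age < 0 | is.na(df$incidence) |
                 df$incidence < 0 | df$ci_low > df$incidence |
                 df$incidence > df$ci_high | df$ci_low < 0)
  if (length(bad) && on_invalid == "error")
    stop_ms("invalid rows in %s: %s", path,
            paste(bad, collapse = ", "),
            class = "multistep_validation_error")
  if (length(bad)) {
    warn_ms("dropping %d invalid row(s) from %s: %s", length(bad), path,
            paste(bad, collapse = ", "))
    df <- df[-bad, , drop = FALSE]
  }
  do.call(incidence_table,
          c(as.list(df), list(units_label = units_label, source = source)))
}

#' Write an incidence table to CSV (native dialect)
#'
#' Numbers are written with 17 significant digits so that
#' `read_incidence_table(write_incidence_table(x))` round-trips
#' bit-identically.
#'
#' @param table an [incidence_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incidence_table <- function(table, path) {
  validate_incidence_table(table)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict an incidence table to an age window
#'
#' The power-law (Armitage-Doll) family is fitted on a restricted window
#' (classically 30-80 years) because the log-log linearity breaks down at
#' very old ages; the nonlinear extensions use the full range.
#'
#' @param table an [incidence_table()].
#' @param min_age,max_age inclusive bounds in years, `min_age < max_age`.
#' @return The filtered [incidence_table()]; a message reports how many
#'   records were dropped.
#' @export
filter_age_range <- function(table, min_age, max_age) {
  validate_incidence_table(table)
  if (!(min_age < max_age))
    stop_ms("min_age (%g) must be < max_age (%g)", min_age, max_age,
            class = "multistep_config_error")
  keep <- table$age >= min_age & table$age <= max_age
  if (!any(keep))
    stop_ms("age window [%g, %g] leaves no records (ages span %g-%g)",
            min_age, max_age, min(table$age), max(table$age))
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("filter_age_range: dropped %d of %d records outside [%g, %g]",
                    dropped, nrow(table), min_age, max_age))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("units_label", "source")] <-
    attributes(table)[c("units_label", "source")]
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Log-log transform of an incidence table
#'
#' Maps each record to the coordinates the regression models work in:
#' `x = log(age) - log(offset_age)` and `y = log(incidence)` (natural
#' logs), with the standard deviation of `y` derived from the 95% interval
#' under a symmetric-on-log-scale normal approximation,
#' `sigma_y = (log(ci_high) - log(ci_low)) / (2 * 1.96)`.
#'
#' Zero-incidence records are not silently patched with pseudo-counts:
#' they raise an error pointing at [drop_zero_incidence()].  Records
#' younger than `offset_age` (where `x` would be negative) are excluded
#' with a warning.
#'
#' @param table an [incidence_table()].
#' @param offset_age reference age subtracted on the log scale (years);
#'   default 30, so `x = 0` at age 30.
#' @return A `data.frame` of class `loglog_points` with columns `x`, `y`,
#'   `sigma_y`, `sex`, `age`, `incidence`, in the input row order.
#' @export
to_loglog <- function(table, offset_age = 30) {
  validate_incidence_table(table)
  if (any(table$incidence == 0))
    stop_ms(paste0("incidence is 0 in row(s) %s; zero-rate bins cannot be ",
                   "log-transformed - remove them first with ",
                   "drop_zero_incidence()"),
            paste(which(table$incidence == 0), collapse = ", "),
            class = "multistep_validation_error")
  young <- table$age < offset_age
  if (any(young)) {
    warn_ms("excluding %d record(s) younger than offset_age = %g",
            sum(young), offset_age)
    table <- table[!young, , drop = FALSE]
  }
  sigma_y <- (log(table$ci_high) - log(table$ci_low)) / (2 * stats::qnorm(0.975))
  if (any(sigma_y <= 0))
    stop_ms("degenerate interval (sigma_y <= 0) in row(s) %s",
            paste(which(sigma_y <= 0), collapse = ", "),
            class = "multistep_validation_error")
  out <- data.frame(x = log(table$age) - log(offset_age),
                    y = log(table$incidence),
                    sigma_y = sigma_y,
                    sex = table$sex,
                    age = table$age,
                    incidence = table$incidence,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, offset_age = offset_age,
            class = c("loglog_points", "data.frame"))
}

#' Construct log-log points directly
#'
#' Mostly useful for simulation studies where the generative truth lives on
#' the log-log scale already.
#'
#' @param x,y,sigma_y coordinates and per-point measurement SD.
#' @param sex sex labels (recycled).
#' @param offset_age reference age (years) used for the `x` origin.
#' @return A `loglog_points` data frame as from [to_loglog()].
#' @export
loglog_points <- function(x, y, sigma_y, sex = "combined", offset_age = 30) {
  stopifnot(all(sigma_y > 0))
  n <- length(x)
  out <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    sigma_y = rep_len(as.numeric(sigma_y), n),
                    sex = normalize_sex(rep_len(sex, n)),
                    age = exp(as.numeric(x)) * offset_age,
                    incidence = exp(as.numeric(y)),
                    stringsAsFactors = FALSE)
  structure(out, offset_age = offset_age,
            class = c("loglog_points", "data.frame"))
}

#' Drop zero-incidence records before log transformation
#'
#' @param table an [incidence_table()].
#' @return The table without zero-rate records; a warning reports how many
#'   were removed.
#' @export
drop_zero_incidence <- function(table) {
  z <- table$incidence == 0
  if (any(z)) warn_ms("dropping %d zero-incidence record(s)", sum(z))
  out <- table[!z, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("units_label", "source")] <-
    attributes(table)[c("units_label", "source")]
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Population-standardized mean age of onset
#'
#' Computes, per sex, the incidence-weighted mean onset age standardized to
#' a population age distribution: `sum(a * I(a) * w(a)) / sum(I(a) * w(a))`.
#' The uncertainty interval is propagated by applying the same functional
#' to lognormal draws per bin consistent with each record's 95% interval
#' (median at the point estimate, log-scale SD of interval width / 3.92).
#'
#' @param table an [incidence_table()].
#' @param weights population age weights: either a named numeric vector
#'   (names = ages) or a function of age.  Uniform by default.
#' @param n_draws Monte-Carlo draws for the interval (default 2000).
#' @param seed RNG seed for the propagation draws.
#' @return A `data.frame` with one row per sex: `sex`, `mean_age`,
#'   `ci_low`, `ci_high`.
#' @export
mean_onset_age <- function(table, weights = NULL, n_draws = 2000, seed = 1L) {
  validate_incidence_table(table)
  wt_of <- function(ages) {
    if (is.null(weights)) return(rep(1, length(ages)))
    if (is.function(weights)) return(weights(ages))
    w <- weights[as.character(ages)]
    if (anyNA(w))
      stop_ms("no population weight for age(s): %s",
              paste(ages[is.na(w)], collapse = ", "),
              class = "multistep_config_error")
    as.numeric(w)
  }
  res <- lapply(split(seq_len(nrow(table)), table$sex), function(idx) {
    a <- table$age[idx]; inc <- table$incidence[idx]
    w <- wt_of(a)
    if (any(w < 0)) stop_ms("population weights must be nonnegative")
    denom <- sum(inc * w)
    if (denom == 0) stop_ms("all-zero incidence x weight: mean onset undefined")
    est <- sum(a * inc * w) / denom
    sdlog <- ifelse(table$ci_high[idx] > table$ci_low[idx],
                    (log(table$ci_high[idx]) - log(table$ci_low[idx])) /
                      (2 * stats::qnorm(0.975)), 0)
    draws <- with_seed(derive_seed(seed, "mean_onset"), {
      vapply(seq_len(n_draws), function(j) {
        inc_j <- inc * exp(stats::rnorm(length(inc), 0, sdlog))
        sum(a * inc_j * w) / sum(inc_j * w)
      }, numeric(1))
    })
    data.frame(sex = table$sex[idx][1], mean_age = est,
               ci_low = unname(stats::quantile(draws, 0.025)),
               ci_high = unname(stats::quantile(draws, 0.975)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a table or point set as JSON
#'
#' @param x an [incidence_table()] or `loglog_points` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
as_incidence_json <- function(x, path = NULL) {
  payload <- list(data = as.data.frame(x),
                  units_label = attr(x, "units_label"),
                  source = attr(x, "source"),
                  offset_age = attr(x, "offset_age"))
  payload <- payload[!vapply(payload, is.null, logical(1))]
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
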