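#' Build an analysis configuration
#'
#' Describes an end-to-end run: the data source (an incidence CSV or a
#' [cohort_spec()] to simulate), the age windows, the model ladder, the
#' prior and sampler blocks, and the seed.  Mirrors the canonical
#' inferential sequence for multistep incidence analysis: linear fit on
#' the restricted window, then broken-stick, then the sex models (same
#' window), then the full-range nonlinear extensions.
#'
#' @param data path to an incidence CSV (native dialect) or a
#'   [cohort_spec()].
#' @param linear_window `c(min_age, max_age)` for the linear family.
#' @param full_window `c(min_age, max_age)` for the nonlinear family
#'   (`Inf` = no upper limit).
#' @param models character vector drawn from `"linear"`,
#'   `"broken_stick"`, `"sex_intercept"`, `"sex_full"`,
#'   `"armitage_doll_full"`, `"beta"`, `"susceptibility"`.
#' @param priors,mcmc prior and sampler blocks.
#' @param seed integer seed (mandatory).
#' @param out_dir output directory.
#' @param dialect optional column mapping for [read_incidence_table()].
#' @return A list of class `ms_config`.
#' @export
analysis_config <- function(data,
                            linear_window = c(30, 80),
                            full_window = c(30, Inf),
                            models = c("linear", "broken_stick",
                                       "sex_intercept", "sex_full",
                                       "beta", "susceptibility"),
                            priors = default_priors(),
                            mcmc = mcmc_control(),
                            seed = 1L,
                            out_dir = "multistep-analysis",
                            dialect = NULL) {
  known <- c("linear", "broken_stick", "sex_intercept", "sex_full",
             "armitage_doll_full", "beta", "susceptibility")
  bad <- setdiff(models, known)
  if (length(bad))
    stop_ms("unknown model(s): %s", paste(bad, collapse = ", "),
            class = "multistep_config_error")
  if (is.null(seed)) stop_ms("seed is mandatory",
                             class = "multistep_config_error")
  structure(list(data = data, linear_window = linear_window,
                 full_window = full_window, models = models,
                 priors = priors, mcmc = mcmc, seed = as.integer(seed),
                 out_dir = out_dir, dialect = dialect),
            class = "ms_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML mirrors [analysis_config()]; a `cohort` block (fields of
#' [cohort_spec()], with subgroups given as `weight`, `k`, `rate`,
#' `ordering`, `law`) may replace the `data` path.
#'
#' @param path YAML file.
#' @return A `ms_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  data <- if (!is.null(y$cohort)) {
    cs <- y$cohort
    subgroups <- lapply(cs$subgroups, function(g)
      list(weight = g$weight,
           process = step_process(g$k, g$rate,
                                  ordering = g$ordering %||% "sequential",
                                  law = g$law %||% "exponential")))
    cohort_spec(n_individuals = cs$n_individuals %||% 2e5,
                subgroups = subgroups,
                sexes = cs$sexes %||% c("female", "male"),
                sex_rate_multiplier =
                  unlist(cs$sex_rate_multiplier %||%
                           list(female = 0.94, male = 1, combined = 1)),
                susceptible_fraction = cs$susceptible_fraction %||% 0.1,
                extinction_beta = cs$extinction_beta %||% 0,
                max_age = cs$max_age %||% 100,
                age_bins = cs$age_bins %||% seq(30, 100, 1),
                seed = cs$seed %||% y$seed %||% 1L)
  } else y$data
  pr <- do.call(default_priors, y$priors %||% list())
  mc <- do.call(mcmc_control, y$mcmc %||% list())
  analysis_config(data = data,
                  linear_window = unlist(y$linear_window %||% c(30, 80)),
                  full_window = unlist(y$full_window %||% c(30, Inf)),
                  models = unlist(y$models %||%
                                    c("linear", "broken_stick",
                                      "sex_intercept", "sex_full",
                                      "beta", "susceptibility")),
                  priors = pr, mcmc = mc, seed = y$seed %||% 1L,
                  out_dir = y$out_dir %||% "multistep-analysis",
                  dialect = unlist(y$dialect))
}

load_config_table <- function(config) {
  if (inherits(config$data, "cohort_spec")) {
    samples <- simulate_cohort(config$data)
    incidence_from_onsets(samples)
  } else if (inherits(config$data, "incidence_table")) {
    config$data
  } else {
    read_incidence_table(config$data, dialect = config$dialect)
  }
}

#' Run the full analysis pipeline
#'
#' Loads or simulates the incidence table, fits the configured model
#' ladder, computes the pairwise Bayes-factor table, the step-count
#' interpretation, and Bayesian R-squared, and writes parameter tables
#' (CSV), fits (JSON summaries + draws CSV), and figures into
#' `config$out_dir`.  Deterministic under the config seed: re-running
#' reproduces every table byte-identically.
#'
#' @param config an [analysis_config()].
#' @param figures also write figures (default TRUE).
#' @return A list of class `ms_report`: `table` (the data), `fits`,
#'   `parameters`, `bayes_factors`, `steps`, `r_squared`, `provenance`.
#' @export
run_analysis <- function(config, figures = TRUE) {
  stopifnot(inherits(config, "ms_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- load_config_table(config)
  tab_lin <- filter_age_range(drop_zero_incidence(table),
                              config$linear_window[1],
                              config$linear_window[2])
  points <- to_loglog(tab_lin)
  tab_full <- filter_age_range(drop_zero_incidence(table),
                               config$full_window[1],
                               min(config$full_window[2], max(table$age)))
  fits <- list()
  failures <- list()
  for (m in config$models) {
    seed_m <- derive_seed(config$seed, paste0("fit_", m))
    f <- tryCatch(switch(m,
      linear = fit_linear(points, config$priors, config$mcmc, seed_m),
      broken_stick = fit_broken_stick(points, config$priors, config$mcmc,
                                      seed_m),
      sex_intercept = fit_sex_model(points, "vary_intercept",
                                    config$priors, config$mcmc, seed_m),
      sex_full = fit_sex_model(points, "vary_intercept_and_slope",
                               config$priors, config$mcmc, seed_m),
      armitage_doll_full = fit_nonlinear(tab_full, "armitage_doll",
                                         config$priors, config$mcmc, seed_m),
      beta = fit_nonlinear(tab_full, "beta", config$priors, config$mcmc,
                           seed_m),
      susceptibility = fit_nonlinear(tab_full, "susceptibility",
                                     config$priors, config$mcmc, seed_m)),
      error = function(e) e)
    if (inherits(f, "error")) failures[[m]] <- conditionMessage(f)
    else fits[[m]] <- f
  }
  if (length(failures)) {
    writeLines(jsonlite::toJSON(failures, auto_unbox = TRUE, pretty = TRUE),
               file.path(config$out_dir, "failure-manifest.json"))
    warn_ms("stage failure(s): %s; partial outputs retained",
            paste(names(failures), collapse = ", "))
  }

  parameters <- do.call(rbind, lapply(names(fits), function(m) {
    s <- fits[[m]]$summaries
    cbind(model = m, s)
  }))

  # pairwise Bayes factors within each likelihood family (identical data)
  bf_rows <- list()
  nm <- names(fits)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    a <- fits[[nm[i]]]; b <- fits[[nm[j]]]
    if (!identical(a$fingerprint, b$fingerprint)) next
    if (!a$converged || !b$converged) next
    cmp <- bayes_factor(a, b)
    bf_rows[[length(bf_rows) + 1]] <-
      data.frame(model_a = cmp$model_a, model_b = cmp$model_b,
                 log_bf = cmp$log_bf, bf = cmp$bf,
                 mc_error = cmp$mc_error, category = cmp$category,
                 stringsAsFactors = FALSE)
  }
  bayes_factors <- if (length(bf_rows)) do.call(rbind, bf_rows) else NULL

  steps <- do.call(rbind, lapply(names(fits), function(m) {
    sl <- grep("^slope", colnames(fits[[m]]$draws), value = TRUE)
    if (!length(sl)) return(NULL)
    do.call(rbind, lapply(sl, function(p) {
      st <- steps_from_slope(fits[[m]], p)
      data.frame(model = m, slope = p, steps_median = st$median,
                 steps_q2.5 = st$ci[1], steps_q97.5 = st$ci[2],
                 integers = paste(st$integers, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))

  r2 <- vapply(fits, function(f) bayesian_r_squared(f), numeric(1))

  report <- structure(list(table = table, fits = fits,
                           parameters = parameters,
                           bayes_factors = bayes_factors, steps = steps,
                           r_squared = r2,
                           provenance = list(
                             seed = config$seed,
                             package_version =
                               as.character(utils::packageVersion("multistep")),
                             data_fingerprint = data_fingerprint(table),
                             failures = failures)),
                      class = "ms_report")
  write_report(report, config$out_dir)
  if (figures) try(make_figures(report, config$out_dir), silent = TRUE)
  report
}

write_report <- function(report, out_dir) {
  wr <- function(df, name) {
    if (is.null(df)) return(invisible())
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wr(report$parameters, "parameters.csv")
  wr(report$bayes_factors, "bayes_factors.csv")
  wr(report$steps, "steps.csv")
  wr(data.frame(model = names(report$r_squared),
                r_squared = unname(report$r_squared)), "r_squared.csv")
  write_incidence_table(report$table, file.path(out_dir, "incidence.csv"))
  for (m in names(report$fits)) {
    f <- report$fits[[m]]
    js <- list(model = f$model, summaries = f$summaries,
               converged = f$converged,
               diagnostics = f$diagnostics[c("rhat", "ess", "retried")],
               priors = unclass(f$priors), seed = f$seed,
               fingerprint = f$fingerprint)
    writeLines(jsonlite::toJSON(js, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
               file.path(out_dir, paste0("fit-", m, ".json")))
    dr <- as.data.frame(f$draws)
    dr[] <- lapply(dr, fmt_num)
    utils::write.csv(dr, file.path(out_dir, paste0("draws-", m, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

#' Diagnostic figures for an analysis report
#'
#' Writes three figures: (1) incidence against age with 95% intervals;
#' (2) the log-log data with the fitted line / broken-stick segments, the
#' segments extended as dashed lines beyond the breakpoint; (3) the
#' full-age-range overlay of the power-law and its nonlinear extensions,
#' where the susceptibility curve should track the old-age drop-off.
#'
#' @param report an `ms_report` from [run_analysis()].
#' @param out_dir output directory.
#' @param format `"png"` or `"svg"` (via [grDevices::svg()]).
#' @return Paths of the written figures, invisibly; missing fits skip
#'   their figure with a warning.
#' @export
make_figures <- function(report, out_dir, format = "png") {
  paths <- character(0)
  save_fig <- function(p, name) {
    path <- file.path(out_dir, paste0(name, ".", format))
    ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
    paths <<- c(paths, path)
  }
  tab <- as.data.frame(report$table)
  p1 <- ggplot2::ggplot(tab, ggplot2::aes(x = age, y = incidence,
                                          colour = sex, fill = sex)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)",
                  y = attr(report$table, "units_label") %||% "incidence",
                  title = "Age-specific incidence") +
    ggplot2::theme_minimal()
  save_fig(p1, "incidence-age")

  bs <- report$fits$broken_stick
  lin <- report$fits$linear
  if (!is.null(bs) || !is.null(lin)) {
    f <- bs %||% lin
    pts <- f$model_def$data
    med <- f$summaries$median
    names(med) <- f$summaries$parameter
    grid <- data.frame(x = seq(min(pts$x), max(pts$x), length.out = 200))
    p2 <- ggplot2::ggplot(pts, ggplot2::aes(x = x, y = y)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = y - 1.96 * sigma_y,
                                            ymax = y + 1.96 * sigma_y),
                               size = 0.2) +
      ggplot2::labs(x = "log(age) - log(30)", y = "log incidence",
                    title = "Log-log incidence with fitted model") +
      ggplot2::theme_minimal()
    if (!is.null(bs)) {
      bp <- med[["breakpoint"]]
      seg1 <- transform(grid, y = med[["intercept1"]] +
                          med[["slope1"]] * pmin(x, bp) +
                          med[["slope2"]] * pmax(x - bp, 0))
      # dashed extensions beyond the breakpoint illustrate the slope change
      ext1 <- transform(grid, y = med[["intercept1"]] + med[["slope1"]] * x)
      ext2 <- transform(grid,
                        y = med[["intercept1"]] + med[["slope1"]] * bp +
                          med[["slope2"]] * (x - bp))
      p2 <- p2 +
        ggplot2::geom_line(data = ext1[ext1$x > bp, ],
                           ggplot2::aes(x = x, y = y), linetype = "dashed") +
        ggplot2::geom_line(data = ext2[ext2$x < bp, ],
                           ggplot2::aes(x = x, y = y), linetype = "dashed") +
        ggplot2::geom_line(data = seg1, ggplot2::aes(x = x, y = y),
                           colour = "steelblue")
    } else {
      segl <- transform(grid, y = med[["intercept"]] + med[["slope"]] * x)
      p2 <- p2 + ggplot2::geom_line(data = segl, ggplot2::aes(x = x, y = y),
                                    colour = "steelblue")
    }
    save_fig(p2, "loglog-fit")
  } else warn_ms("no linear-family fit available; skipping log-log figure")

  nl <- intersect(c("armitage_doll_full", "beta", "susceptibility"),
                  names(report$fits))
  if (length(nl)) {
    ages <- seq(min(tab$age), max(tab$age), length.out = 300)
    curves <- do.call(rbind, lapply(nl, function(m) {
      f <- report$fits[[m]]
      med <- f$summaries$median
      names(med) <- f$summaries$parameter
      do.call(rbind, lapply(f$model_def$sexes, function(sx) {
        tag <- if (length(f$model_def$sexes) == 1) "" else paste0("_", sx)
        la <- med[[paste0("log_alpha", tag)]]
        kk <- med[[paste0("k", tag)]]
        inc <- switch(f$model,
          armitage_doll = exp(la) * (ages / REF_AGE)^(kk - 1),
          beta = predict_beta(list(alpha = exp(la), k = kk,
                                   beta = med[[paste0("beta", tag)]]), ages),
          susceptibility = predict_susceptibility(
            list(alpha = exp(la), k = kk, C = med[[paste0("C", tag)]]),
            ages))
        data.frame(model = m, sex = sx, age = ages, incidence = inc)
      }))
    }))
    p3 <- ggplot2::ggplot(tab, ggplot2::aes(x = age, y = incidence)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.6) +
      ggplot2::geom_line(data = curves,
                         ggplot2::aes(colour = model, group =
                                        interaction(model, sex))) +
      ggplot2::coord_cartesian(ylim = c(0, max(tab$ci_high) * 1.1)) +
      ggplot2::facet_wrap(~sex) +
      ggplot2::labs(x = "Age (years)", y = "incidence per 100,000 py",
                    title = "Full-age-range models") +
      ggplot2::theme_minimal()
    save_fig(p3, "fullrange-models")
  }
  invisible(paths)
}
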