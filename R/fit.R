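# Fitting surface: every model goes through fit_ms_model(), which runs the
# adaptive-Metropolis sampler on the model's unconstrained log posterior,
# applies the retry-on-nonconvergence policy, and packages draws +
# summaries + provenance into an `ms_fit`.

fit_ms_model <- function(model, priors, mcmc, seed) {
  stopifnot(inherits(mcmc, "ms_mcmc_control"))
  d <- length(model$init_u)
  # convergence is judged on the constrained (reported) scale: transforms
  # like log(sigma) have flat unbounded tails whose excursions are
  # invisible - and irrelevant - on the scale the summaries live on
  diag_run <- function(run) {
    arr <- run$draws
    for (i in seq_len(d))
      arr[, , i] <- par_to_constrained(model$pars[[i]], run$draws[, , i])
    rhat <- split_rhat(arr, rank_normalize = TRUE)
    ess <- tryCatch({
      ml <- coda::mcmc.list(lapply(seq_len(dim(arr)[2]), function(c)
        coda::mcmc(matrix(arr[, c, ], ncol = d))))
      as.numeric(coda::effectiveSize(ml))
    }, error = function(e) rep(NA_real_, d))
    list(arr = arr, rhat = rhat, ess = ess,
         converged = all(is.finite(rhat)) && all(rhat < 1.01))
  }
  run <- run_mcmc(model$log_post_u, model$init_u,
                  n_chains = mcmc$n_chains, warmup = mcmc$warmup,
                  iter = mcmc$iter, seed = seed,
                  target_accept = mcmc$target_accept)
  dg <- diag_run(run)
  retried <- 0L
  while (!dg$converged && isTRUE(mcmc$retry) &&
         retried < (mcmc$max_retries %||% 2)) {
    retried <- retried + 1L
    fac <- 2^retried
    run <- run_mcmc(model$log_post_u, model$init_u,
                    n_chains = mcmc$n_chains, warmup = fac * mcmc$warmup,
                    iter = fac * mcmc$iter,
                    seed = derive_seed(seed, paste0("retry", retried)),
                    target_accept = mcmc$target_accept)
    dg <- diag_run(run)
  }
  if (!dg$converged)
    warn_ms("%s fit did not converge (max split-Rhat %.3f); inspect before use",
            model$name, max(dg$rhat))
  draws_u <- matrix(apply(run$draws, 3, c), ncol = d)  # (iter*chains) x d
  draws <- matrix(apply(dg$arr, 3, c), ncol = d)
  colnames(draws) <- model$par_names
  colnames(draws_u) <- model$par_names
  rhat <- dg$rhat; ess <- dg$ess
  if (!is.null(model$derive)) {
    # derived columns are appended AFTER the sampled parameters so the
    # positional indexing inside mu_fn stays valid
    dv <- model$derive(draws)
    draws <- cbind(draws, dv)
    rhat <- c(rhat, rep(NA_real_, ncol(dv)))
    ess <- c(ess, rep(NA_real_, ncol(dv)))
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  summaries <- data.frame(parameter = colnames(draws),
                          median = qs[1, ], q2.5 = qs[2, ], q97.5 = qs[3, ],
                          rhat = rhat, ess = ess,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = model$name, model_def = model,
                 draws = draws, draws_u = draws_u, lp = as.numeric(run$lp),
                 summaries = summaries,
                 diagnostics = list(rhat = dg$rhat, ess = dg$ess,
                                    accept_rate = run$accept_rate,
                                    retried = retried),
                 converged = dg$converged,
                 priors = priors, mcmc = mcmc, seed = seed,
                 fingerprint = data_fingerprint(model$data),
                 units_label = "per 100,000 person-years"),
            class = "ms_fit")
}

#' @export
print.ms_fit <- function(x, ...) {
  cat(sprintf("<ms_fit> model '%s'%s, %d posterior draws\n", x$model,
              if (x$converged) "" else " [NOT CONVERGED]", nrow(x$draws)))
  s <- x$summaries
  s[-1] <- lapply(s[-1], function(v) signif(v, 4))
  print.data.frame(s)
  invisible(x)
}

#' @export
summary.ms_fit <- function(object, ...) object$summaries

#' Posterior draws of an ms_fit
#' @param fit an `ms_fit`.
#' @param parameter optional parameter name; when given, a numeric vector.
#' @return Matrix of draws, or vector for one parameter.
#' @export
posterior_draws <- function(fit, parameter = NULL) {
  if (is.null(parameter)) return(fit$draws)
  if (!parameter %in% colnames(fit$draws))
    stop_ms("no parameter '%s' in fit (has: %s)", parameter,
            paste(colnames(fit$draws), collapse = ", "))
  fit$draws[, parameter]
}

check_points <- function(points, min_n) {
  if (!all(c("x", "y", "sigma_y") %in% names(points)))
    stop_ms("expected loglog points with columns x, y, sigma_y")
  if (nrow(points) < min_n)
    stop_ms("need at least %d points, got %d", min_n, nrow(points))
  if (any(points$sigma_y <= 0)) stop_ms("all sigma_y must be > 0")
  invisible(points)
}

#' Fit the linear Armitage-Doll model
#'
#' Bayesian linear regression of log incidence on log age with the
#' per-point measurement SD (from the credible intervals) and a residual
#' scale added in quadrature:
#' `y_i ~ Normal(slope * x_i + intercept, sqrt(sigma_y_i^2 + sigma_res^2))`.
#'
#' @param points a `loglog_points` frame from [to_loglog()] (>= 3 points).
#' @param priors an [default_priors()] block.
#' @param mcmc an [mcmc_control()] block.
#' @param seed integer seed.
#' @return An `ms_fit` with parameters `slope`, `intercept`, `sigma_res`.
#' @export
fit_linear <- function(points, priors = default_priors(),
                       mcmc = mcmc_control(), seed = 1L) {
  check_points(points, 3)
  fit_ms_model(build_model_linear(points, priors), priors, mcmc, seed)
}

#' Fit the broken-stick (changepoint) model
#'
#' Continuous piecewise-linear regression with an unknown breakpoint: a
#' different slope before and after `breakpoint` (on the `x` scale), the
#' two segments joined at the breakpoint, breakpoint prior Uniform over
#' the central 80% of the observed `x` range.  A discontinuous variant
#' (separate second intercept) is available for sensitivity analysis via
#' `continuity = FALSE`.
#'
#' @inheritParams fit_linear
#' @param continuity enforce continuity at the breakpoint (default TRUE).
#' @return An `ms_fit` with parameters `slope1`, `slope2`, `breakpoint`,
#'   `intercept1` (+ `intercept2` when discontinuous), `sigma_res`.
#' @export
fit_broken_stick <- function(points, priors = default_priors(),
                             mcmc = mcmc_control(), seed = 1L,
                             continuity = TRUE) {
  check_points(points, 5)
  fit_ms_model(build_model_broken_stick(points, priors, continuity),
               priors, mcmc, seed)
}

#' Fit the sex-stratified broken-stick model
#'
#' Broken-stick backbone with a breakpoint shared between the sexes;
#' intercepts always vary by sex, slopes optionally
#' (`variant = "vary_intercept_and_slope"`).  Comparing the two variants
#' against the no-sex model separates an exposure-level difference (which
#' shifts only the intercept) from a mechanistic difference (which would
#' change the slope, i.e. the number of steps).
#'
#' @inheritParams fit_linear
#' @param variant `"vary_intercept"` or `"vary_intercept_and_slope"`.
#' @return An `ms_fit`.
#' @export
fit_sex_model <- function(points,
                          variant = c("vary_intercept",
                                      "vary_intercept_and_slope"),
                          priors = default_priors(),
                          mcmc = mcmc_control(), seed = 1L) {
  variant <- match.arg(variant)
  check_points(points, 5)
  fit_ms_model(build_model_sex(points, priors,
                               vary_slope = variant == "vary_intercept_and_slope"),
               priors, mcmc, seed)
}

#' Fit a nonlinear full-age-range incidence model
#'
#' Fits the beta (extinction), susceptibility, or plain Armitage-Doll
#' model to an incidence table spanning the full age range, on the log
#' scale with the same measurement-error treatment as the linear family.
#' When the table has several sex groups each gets its own parameters
#' (jointly fitted, shared residual scale).
#'
#' @param table an [incidence_table()] covering old ages where the
#'   drop-off is informative.
#' @param model `"susceptibility"`, `"beta"` or `"armitage_doll"`.
#' @inheritParams fit_linear
#' @return An `ms_fit`; parameters are suffixed by sex when the table has
#'   more than one sex group.
#' @export
fit_nonlinear <- function(table,
                          model = c("susceptibility", "beta",
                                    "armitage_doll"),
                          priors = default_priors(),
                          mcmc = mcmc_control(), seed = 1L) {
  model <- match.arg(model)
  fit_ms_model(build_model_nonlinear(table, priors, model),
               priors, mcmc, seed)
}

#' Convert a slope posterior to a step-count posterior
#'
#' The multistep interpretation of a log-log slope: steps = slope + 1,
#' applied draw by draw.  Reports the posterior median, the 95% interval,
#' the set of integer step counts covered by that interval, and the
#' nearest integer to the median.
#'
#' @param slope posterior slope draws (numeric vector), or an `ms_fit`
#'   together with `parameter`.
#' @param parameter slope parameter name when `slope` is an `ms_fit`.
#' @return List with `draws`, `median`, `ci` (2.5/97.5%), `integers`
#'   (integer step counts covered by the interval) and `nearest_integer`.
#' @export
steps_from_slope <- function(slope, parameter = "slope") {
  if (inherits(slope, "ms_fit")) slope <- posterior_draws(slope, parameter)
  steps <- slope + 1
  ci <- unname(stats::quantile(steps, c(0.025, 0.975)))
  list(draws = steps, median = stats::median(steps), ci = ci,
       integers = seq(ceiling(ci[1]), floor(ci[2])),
       nearest_integer = round(stats::median(steps)))
}

# Posterior predictive mean matrix (draws x points); thin for speed.
posterior_mu <- function(fit, max_draws = 1000) {
  dr <- fit$draws
  idx <- if (nrow(dr) > max_draws)
    round(seq(1, nrow(dr), length.out = max_draws)) else seq_len(nrow(dr))
  t(apply(dr[idx, , drop = FALSE], 1, function(th) fit$model_def$mu_fn(th)))
}

#' Bayesian R-squared of a fitted model
#'
#' Predictive variance decomposition based on the posterior-median
#' predictions: `R2 = Var(pred) / (Var(pred) + Var(resid))` where `pred`
#' are the per-point posterior median predictions and `resid` their
#' residuals against the observed values.  Bounded in `[0, 1)`.
#'
#' @param fit an `ms_fit`.
#' @param points optional points to evaluate on; defaults to the fitted
#'   data.
#' @return Numeric scalar in `[0, 1)`.
#' @export
bayesian_r_squared <- function(fit, points = NULL) {
  data <- points %||% fit$model_def$data
  if (nrow(data) < 2) stop_ms("need at least 2 points for R-squared")
  mu <- posterior_mu(fit)
  pred <- apply(mu, 2, stats::median)
  resid <- data$y - pred
  vp <- stats::var(pred)
  vp / (vp + stats::var(resid))
}
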