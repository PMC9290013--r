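#' Predict log incidence under the power-law (Armitage-Doll) line
#'
#' `log I = slope * x + intercept` with `x = log(age) - log(30)`; the
#' slope is one less than the number of steps.
#'
#' @param params list with `slope` and `intercept`.
#' @param x log-age offsets.
#' @return Predicted log incidence.
#' @export
predict_armitage_doll <- function(params, x) {
  params$slope * x + params$intercept
}

# shared age scaling: alpha is the rate scale at the 30-year reference age
REF_AGE <- 30
RATE_UNIT <- 1e5

#' Predict incidence under the beta (extinction) model
#'
#' `I(t) = alpha * (t/30)^(k-1) * (1 - beta * t)`: the Armitage-Doll power
#' law attenuated by a linear extinction factor.  The prediction is
#' deliberately not clipped at zero - beyond `t = 1/beta` the model
#' produces negative incidence, which is its documented structural flaw.
#'
#' @param params list with `alpha` (incidence per 100,000 person-years at
#'   the 30-year reference age), `k` (steps) and `beta` (per year).
#' @param t ages in years, `> 0`.
#' @return Predicted incidence per 100,000 person-years.
#' @export
predict_beta <- function(params, t) {
  params$alpha * (t / REF_AGE)^(params$k - 1) * (1 - params$beta * t)
}

#' Predict incidence under the susceptibility model
#'
#' Only a fraction `C` of the population can ever develop the disease; as
#' the susceptible pool depletes, observed incidence falls.  With
#' `u = t/30` and cumulative per-person hazard
#' `Lambda(t) = (30 * alpha / 1e5) * u^k / k`,
#' `I(t) = alpha * u^(k-1) / (1 + ((1-C)/C) * exp(Lambda(t)))`.
#' The prediction is nonnegative everywhere, reduces exactly to the
#' Armitage-Doll law at `C = 1`, behaves as `C * alpha * u^(k-1)` for
#' small `t`, and decays to zero as `t` grows.  The exponential is
#' handled in log space so large `Lambda` cannot overflow.
#'
#' @param params list with `alpha` (incidence per 100,000 person-years at
#'   the 30-year reference age), `k` (steps) and `C` in `(0, 1]`.
#' @param t ages in years, `> 0`.
#' @return Predicted incidence per 100,000 person-years.
#' @export
predict_susceptibility <- function(params, t) {
  exp(log_susceptibility(log(params$alpha), params$k, params$C, t))
}

# log of the susceptibility-model incidence, stable for large Lambda
log_susceptibility <- function(log_alpha, k, C, t) {
  u <- t / REF_AGE
  Lam <- (REF_AGE * exp(log_alpha) / RATE_UNIT) * u^k / k
  if (C >= 1) return(log_alpha + (k - 1) * log(u))
  z <- log((1 - C) / C) + Lam
  # log(1 + exp(z)) without overflow
  log1pexp <- ifelse(z > 30, z, log1p(exp(z)))
  log_alpha + (k - 1) * log(u) - log1pexp
}

# log of the beta-model incidence; -Inf where the prediction is <= 0
log_beta_model <- function(log_alpha, k, beta, t) {
  u <- t / REF_AGE
  fac <- 1 - beta * t
  out <- rep(-Inf, length(t))
  pos <- fac > 0
  out[pos] <- log_alpha + (k - 1) * log(u[pos]) + log(fac[pos])
  out
}

# Linear-family model builders -------------------------------------------

# Two-segment slope path relative to the breakpoint; the mean function
# anchors its level at a fixed interior point x0 (the median of the data)
# so the level parameter stays identified - and uncorrelated with the
# breakpoint - even when the data carry a single slope and the breakpoint
# is only weakly determined.  Anchoring at x = 0 (or at the breakpoint
# itself) couples the level to slope1/breakpoint along an
# identifiability ridge; the conventional intercept at x = 0 is instead
# reported as a derived quantity.
bs_path <- function(x, slope1, slope2, bp) {
  slope1 * (pmin(x, bp) - bp) + slope2 * pmax(x - bp, 0)
}
mu_broken_stick <- function(x, slope1, slope2, bp, level, x0) {
  level + bs_path(x, slope1, slope2, bp) - bs_path(x0, slope1, slope2, bp)
}

breakpoint_range <- function(x, q) {
  r <- range(x)
  c(r[1] + q * diff(r), r[2] - q * diff(r))
}

build_model_linear <- function(points, priors) {
  x <- points$x; y <- points$y; sy <- points$sigma_y
  pars <- list(
    ms_par("slope", "identity",
           log_prior = prior_normal(priors$slope_mean, priors$slope_sd),
           init = priors$slope_mean),
    ms_par("intercept", "identity",
           log_prior = prior_normal(priors$intercept_mean,
                                    priors$intercept_sd),
           init = stats::median(y - priors$slope_mean * x)),
    ms_par("sigma_res", "abs",
           log_prior = prior_half_normal(priors$sigma_res_sd), init = 0.2))
  mu_fn <- function(th, newx = x) th[1] * newx + th[2]
  log_lik <- function(th)
    sum(stats::dnorm(y, th[1] * x + th[2], sqrt(sy^2 + th[3]^2), log = TRUE))
  ms_model("linear", pars, log_lik, mu_fn, points)
}

build_model_broken_stick <- function(points, priors, continuity = TRUE) {
  x <- points$x; y <- points$y; sy <- points$sigma_y
  x0 <- stats::median(x)
  bpr <- breakpoint_range(x, priors$breakpoint_quantile)
  pars <- list(
    ms_par("slope1", "identity",
           log_prior = prior_normal(priors$slope_mean, priors$slope_sd),
           init = priors$slope_mean - 1),
    ms_par("slope2", "identity",
           log_prior = prior_normal(priors$slope_mean, priors$slope_sd),
           init = priors$slope_mean + 1),
    ms_par("breakpoint", "logit", lo = bpr[1], hi = bpr[2],
           log_prior = prior_uniform(bpr[1], bpr[2]), init = mean(bpr)),
    ms_par("level", "identity",
           log_prior = prior_normal(priors$intercept_mean,
                                    priors$intercept_sd),
           init = stats::median(y)),
    ms_par("sigma_res", "abs",
           log_prior = prior_half_normal(priors$sigma_res_sd), init = 0.2))
  if (!continuity)
    pars <- append(pars, list(
      ms_par("jump", "identity",
             log_prior = prior_normal(0, priors$intercept_sd),
             init = 0)), after = 4)
  mu_fn <- if (continuity) {
    function(th, newx = x)
      mu_broken_stick(newx, th[1], th[2], th[3], th[4], x0)
  } else {
    function(th, newx = x)
      mu_broken_stick(newx, th[1], th[2], th[3], th[4], x0) +
      ifelse(newx > th[3], th[5], 0)
  }
  log_lik <- function(th) {
    sig <- th[length(th)]
    sum(stats::dnorm(y, mu_fn(th), sqrt(sy^2 + sig^2), log = TRUE))
  }
  derive <- function(draws)
    cbind(intercept1 = draws[, "level"] +
            bs_path(0, draws[, "slope1"], draws[, "slope2"],
                    draws[, "breakpoint"]) -
            bs_path(x0, draws[, "slope1"], draws[, "slope2"],
                    draws[, "breakpoint"]))
  ms_model("broken_stick", pars, log_lik, mu_fn, points,
           extra = list(breakpoint_range = bpr, continuity = continuity,
                        derive = derive, x0 = x0))
}

build_model_sex <- function(points, priors, vary_slope = FALSE) {
  sexes <- c("female", "male")
  if (!all(sexes %in% points$sex))
    stop_ms("sex model needs both female and male records")
  if (!all(points$sex %in% sexes))   # keep the object identical otherwise,
    points <- points[points$sex %in% sexes, , drop = FALSE]  # for fingerprints
  x <- points$x; y <- points$y; sy <- points$sigma_y
  is_f <- points$sex == "female"
  bpr <- breakpoint_range(x, priors$breakpoint_quantile)
  p_slope <- prior_normal(priors$slope_mean, priors$slope_sd)
  p_int <- prior_normal(priors$intercept_mean, priors$intercept_sd)
  int0 <- stats::median(y)
  x0 <- stats::median(x)
  if (!vary_slope) {
    pars <- list(
      ms_par("slope1", "identity", log_prior = p_slope,
             init = priors$slope_mean - 1),
      ms_par("slope2", "identity", log_prior = p_slope,
             init = priors$slope_mean + 1),
      ms_par("breakpoint", "logit", lo = bpr[1], hi = bpr[2],
             log_prior = prior_uniform(bpr[1], bpr[2]), init = mean(bpr)),
      ms_par("level_female", "identity", log_prior = p_int, init = int0),
      ms_par("level_male", "identity", log_prior = p_int, init = int0),
      ms_par("sigma_res", "abs",
             log_prior = prior_half_normal(priors$sigma_res_sd), init = 0.2))
    mu_fn <- function(th, newx = x, newsex_f = is_f)
      ifelse(newsex_f, th[4], th[5]) +
      bs_path(newx, th[1], th[2], th[3]) - bs_path(x0, th[1], th[2], th[3])
    derive <- function(draws) {
      shift <- bs_path(0, draws[, "slope1"], draws[, "slope2"],
                       draws[, "breakpoint"]) -
        bs_path(x0, draws[, "slope1"], draws[, "slope2"],
                draws[, "breakpoint"])
      cbind(intercept_female = draws[, "level_female"] + shift,
            intercept_male = draws[, "level_male"] + shift)
    }
  } else {
    pars <- list(
      ms_par("slope1_female", "identity", log_prior = p_slope,
             init = priors$slope_mean - 1),
      ms_par("slope1_male", "identity", log_prior = p_slope,
             init = priors$slope_mean - 1),
      ms_par("slope2_female", "identity", log_prior = p_slope,
             init = priors$slope_mean + 1),
      ms_par("slope2_male", "identity", log_prior = p_slope,
             init = priors$slope_mean + 1),
      ms_par("breakpoint", "logit", lo = bpr[1], hi = bpr[2],
             log_prior = prior_uniform(bpr[1], bpr[2]), init = mean(bpr)),
      ms_par("level_female", "identity", log_prior = p_int, init = int0),
      ms_par("level_male", "identity", log_prior = p_int, init = int0),
      ms_par("sigma_res", "abs",
             log_prior = prior_half_normal(priors$sigma_res_sd), init = 0.2))
    mu_fn <- function(th, newx = x, newsex_f = is_f) {
      s1 <- ifelse(newsex_f, th[1], th[2])
      s2 <- ifelse(newsex_f, th[3], th[4])
      lev <- ifelse(newsex_f, th[6], th[7])
      lev + bs_path(newx, s1, s2, th[5]) - bs_path(x0, s1, s2, th[5])
    }
    derive <- function(draws) {
      bp <- draws[, "breakpoint"]
      sh_f <- bs_path(0, draws[, "slope1_female"], draws[, "slope2_female"],
                      bp) -
        bs_path(x0, draws[, "slope1_female"], draws[, "slope2_female"], bp)
      sh_m <- bs_path(0, draws[, "slope1_male"], draws[, "slope2_male"],
                      bp) -
        bs_path(x0, draws[, "slope1_male"], draws[, "slope2_male"], bp)
      cbind(intercept_female = draws[, "level_female"] + sh_f,
            intercept_male = draws[, "level_male"] + sh_m)
    }
  }
  log_lik <- function(th) {
    sig <- th[length(th)]
    sum(stats::dnorm(y, mu_fn(th), sqrt(sy^2 + sig^2), log = TRUE))
  }
  nm <- if (vary_slope) "sex_full" else "sex_intercept"
  ms_model(nm, pars, log_lik, mu_fn, points,
           extra = list(breakpoint_range = bpr, vary_slope = vary_slope,
                        derive = derive, x0 = x0))
}

build_model_nonlinear <- function(table, priors,
                                  model = c("susceptibility", "beta",
                                            "armitage_doll")) {
  model <- match.arg(model)
  tab <- drop_zero_incidence(table)
  pts <- to_loglog(tab)
  t_age <- pts$age; y <- pts$y; sy <- pts$sigma_y
  sexes <- sort(unique(pts$sex))
  sex_idx <- match(pts$sex, sexes)
  p_la <- prior_normal(priors$log_alpha_mean, priors$log_alpha_sd)
  p_k <- prior_trunc_normal(priors$k_mean, priors$k_sd, 1)
  pars <- list()
  for (s in sexes) {
    tag <- if (length(sexes) == 1) "" else paste0("_", s)
    pars <- append(pars, list(
      ms_par(paste0("log_alpha", tag), "identity", log_prior = p_la,
             init = min(y)),
      ms_par(paste0("k", tag), "shifted_log", shift = 1, log_prior = p_k,
             init = priors$k_mean)))
    if (model == "beta")
      pars <- append(pars, list(
        ms_par(paste0("beta", tag), "abs",
               log_prior = prior_half_normal(priors$beta_sd),
               init = 0.005)))
    if (model == "susceptibility")
      pars <- append(pars, list(
        ms_par(paste0("C", tag), "logit", lo = 0, hi = 1,
               log_prior = prior_beta(priors$C_shape1, priors$C_shape2),
               init = priors$C_shape1 / (priors$C_shape1 + priors$C_shape2))))
  }
  npps <- length(pars) / length(sexes)  # params per sex
  pars <- append(pars, list(
    ms_par("sigma_res", "abs",
           log_prior = prior_half_normal(priors$sigma_res_sd), init = 0.2)))
  mu_fn <- function(th, newt = t_age, newsex_idx = sex_idx) {
    out <- numeric(length(newt))
    for (s in seq_along(sexes)) {
      off <- (s - 1) * npps
      sel <- newsex_idx == s
      if (!any(sel)) next
      out[sel] <- switch(model,
        armitage_doll = th[off + 1] + (th[off + 2] - 1) *
          log(newt[sel] / REF_AGE),
        beta = log_beta_model(th[off + 1], th[off + 2], th[off + 3],
                              newt[sel]),
        susceptibility = log_susceptibility(th[off + 1], th[off + 2],
                                            th[off + 3], newt[sel]))
    }
    out
  }
  log_lik <- function(th) {
    mu <- mu_fn(th)
    if (any(!is.finite(mu))) return(-Inf)
    sig <- th[length(th)]
    sum(stats::dnorm(y, mu, sqrt(sy^2 + sig^2), log = TRUE))
  }
  ms_model(model, pars, log_lik, mu_fn, pts,
           extra = list(sexes = sexes, pars_per_sex = npps,
                        nonlinear = TRUE))
}
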