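#' Define a multistep onset process
#'
#' A disease that only arises once `k` rare, independent steps have all
#' occurred produces age-specific incidence rising as `t^(k-1)` while the
#' per-step cumulative risks stay small; the log-log slope of incidence
#' against age is then `k - 1`.
#'
#' Two generative laws are available.  `"exponential"` draws literal
#' exponential step durations at the given per-step hazards (the slope is
#' `k - 1` only in the rare-step regime `rate * t << 1`).  `"power_law"`
#' uses the rare-step limiting form itself as the exact onset hazard,
#' `h(t) = prod(rates) * t^(k-1) / (k-1)!`: this is the regime the
#' phenomenological incidence models describe, and the only way a `k`-step
#' power law can coexist with a non-negligible lifetime risk (as needed for
#' susceptible-pool depletion at old ages).
#'
#' @param k positive integer, number of steps.
#' @param rates per-step hazards per year (scalar recycled to `k`); each
#'   should be well below 1.
#' @param ordering `"sequential"` (steps happen one after another; onset is
#'   the sum of step durations) or `"any_order"` (steps run in parallel
#'   from birth; onset is when the last completes).  Both give log-log
#'   slope `k - 1` in the rare-step regime.
#' @param law `"exponential"` or `"power_law"`, see Details.
#' @return An object of class `step_process`.
#' @export
step_process <- function(k, rates, ordering = c("sequential", "any_order"),
                         law = c("exponential", "power_law")) {
  ordering <- match.arg(ordering)
  law <- match.arg(law)
  k <- as.integer(k)
  if (k < 1) stop_ms("k must be >= 1")
  rates <- rep_len(as.numeric(rates), k)
  if (any(rates <= 0)) stop_ms("all step rates must be > 0")
  structure(list(k = k, rates = rates, ordering = ordering, law = law),
            class = "step_process")
}

#' Expected log-log incidence slope of a step process
#'
#' In the rare-step regime the slope of log incidence against log age is
#' one less than the number of steps, regardless of step ordering.
#'
#' @param process a [step_process()].
#' @return `k - 1`.
#' @export
expected_loglog_slope <- function(process) process$k - 1

#' Closed-form onset hazard of a step process
#'
#' Analytic oracle for the simulator.  Sequential equal rates give the
#' Erlang hazard; sequential distinct rates the hypoexponential hazard;
#' any-order the hazard of the maximum of independent exponentials.  The
#' `"power_law"` law returns `prod(rates) * t^(k-1) / (k-1)!` exactly.
#'
#' @param process a [step_process()].
#' @param t vector of ages in years, `>= 0`.
#' @return Onset hazard (per year) at each `t`.
#' @export
hazard_closed_form <- function(process, t) {
  if (any(t < 0)) stop_ms("t must be >= 0", class = "multistep_domain_error")
  k <- process$k; rates <- process$rates
  if (process$law == "power_law")
    return(prod(rates) * t^(k - 1) / factorial(k - 1))
  if (k == 1) return(rep(rates[1], length(t)))
  if (process$ordering == "sequential") {
    if (length(unique(rates)) == 1) {
      lam <- rates[1]
      f <- stats::dgamma(t, shape = k, rate = lam)
      s <- stats::pgamma(t, shape = k, rate = lam, lower.tail = FALSE)
      return(f / s)
    }
    if (anyDuplicated(rates))
      stop_ms("sequential hazard needs all-equal or all-distinct rates")
    # hypoexponential: f(t) = sum_j w_j * lam_j * exp(-lam_j t)
    w <- vapply(seq_len(k), function(j)
      prod(rates[-j] / (rates[-j] - rates[j])), numeric(1))
    f <- colSums(w * rates * exp(-outer(rates, t)))
    s <- colSums(w * exp(-outer(rates, t)))
    return(f / s)
  }
  # any_order: F(t) = prod(1 - exp(-lam_i t))
  em <- exp(-outer(rates, t))                  # k x length(t)
  Fi <- 1 - em                                 # per-step cdf
  Ft <- apply(Fi, 2, prod)
  f <- Ft * colSums(rates * em / pmax(Fi, .Machine$double.xmin))
  ifelse(t == 0, 0, f / pmax(1 - Ft, .Machine$double.xmin))
}

#' Closed-form survival (disease-free) function of a step process
#'
#' @param process a [step_process()].
#' @param t vector of ages in years.
#' @return `P(onset > t)` at each `t`.
#' @export
survival_closed_form <- function(process, t) {
  if (any(t < 0)) stop_ms("t must be >= 0", class = "multistep_domain_error")
  k <- process$k; rates <- process$rates
  if (process$law == "power_law")
    return(exp(-prod(rates) * t^k / factorial(k)))
  if (process$ordering == "sequential") {
    if (length(unique(rates)) == 1)
      return(stats::pgamma(t, shape = k, rate = rates[1], lower.tail = FALSE))
    if (anyDuplicated(rates))
      stop_ms("sequential survival needs all-equal or all-distinct rates")
    w <- vapply(seq_len(k), function(j)
      prod(rates[-j] / (rates[-j] - rates[j])), numeric(1))
    return(colSums(w * exp(-outer(rates, t))))
  }
  1 - apply(1 - exp(-outer(rates, t)), 2, prod)
}

#' Specify a synthetic multistep cohort
#'
#' Full generative description of a cohort in which onset requires
#' completing the steps of a [step_process()].  Supports subpopulation
#' mixtures with different step counts (the mechanism behind an incidence
#' breakpoint), a per-sex exposure multiplier applied to every step rate
#' (shifting the log-log intercept but not the slope), a susceptible
#' fraction `C` (only a fraction of the population can ever convert, which
#' produces the old-age incidence drop-off), and an optional extinction
#' attenuation `(1 - beta * t)` (floored at 0) on every hazard.
#'
#' The defaults describe the reference synthetic population used
#' throughout the package's examples: a 10%/90% mixture of 6- and 8-step
#' subgroups under the power-law limiting hazard, female step rates 0.94
#' times the male rates, a 10% susceptible fraction, and ages observed in
#' 1-year bins from 30 to 100.
#'
#' @param n_individuals individuals per sex.
#' @param subgroups list of `list(weight =, process =)` mixture components;
#'   weights must sum to 1.
#' @param sexes character vector of sex labels to simulate.
#' @param sex_rate_multiplier named numeric; every step rate is multiplied
#'   by this factor for the corresponding sex.
#' @param susceptible_fraction `C` in `(0, 1]`; non-susceptibles never
#'   convert but contribute person-time.
#' @param extinction_beta `beta >= 0` per year; hazards are attenuated by
#'   `max(0, 1 - beta * t)` at age `t`.
#' @param max_age censoring age in years (may be `Inf` when only onset
#'   times, not incidence tables, are needed).
#' @param age_bins bin edges (years) for [incidence_from_onsets()].
#' @param seed root RNG seed.  Draws are laid out per individual so that
#'   enlarging `n_individuals` extends, rather than reshuffles, an
#'   existing cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 2e5,
                        subgroups = list(
                          list(weight = 0.1,
                               process = step_process(6, 0.0402, law = "power_law")),
                          list(weight = 0.9,
                               process = step_process(8, 0.042, law = "power_law"))),
                        sexes = c("female", "male"),
                        sex_rate_multiplier = c(female = 0.94, male = 1,
                                                combined = 1),
                        susceptible_fraction = 0.10,
                        extinction_beta = 0,
                        max_age = 100,
                        age_bins = seq(30, 100, by = 1),
                        seed = 1L) {
  if (inherits(subgroups, "step_process"))
    subgroups <- list(list(weight = 1, process = subgroups))
  w <- vapply(subgroups, function(g) g$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8)
    stop_ms("subgroup weights must sum to 1 (got %g)", sum(w))
  if (!(susceptible_fraction > 0 && susceptible_fraction <= 1))
    stop_ms("susceptible_fraction C must be in (0, 1]")
  if (extinction_beta < 0) stop_ms("extinction_beta must be >= 0")
  if (n_individuals < 1) stop_ms("n_individuals must be >= 1")
  sexes <- normalize_sex(sexes)
  miss <- setdiff(sexes, names(sex_rate_multiplier))
  if (length(miss))
    stop_ms("sex_rate_multiplier missing entries for: %s",
            paste(miss, collapse = ", "))
  structure(list(n_individuals = as.integer(n_individuals),
                 subgroups = subgroups, sexes = sexes,
                 sex_rate_multiplier = sex_rate_multiplier,
                 susceptible_fraction = susceptible_fraction,
                 extinction_beta = extinction_beta,
                 max_age = max_age, age_bins = age_bins,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Invert the cumulative hazard of one exponential step under the
# (1 - beta*t) attenuation, for a step starting at age s with unit-rate
# exponential draw E.  Returns Inf when the step can never complete.
invert_step_attenuated <- function(E, lam, beta, s) {
  if (beta == 0) return(E / lam)
  disc <- (1 - beta * s)^2 - 2 * beta * E / lam
  d <- ifelse(disc >= 0, ((1 - beta * s) - sqrt(pmax(disc, 0))) / beta, Inf)
  ifelse(s >= 1 / beta, Inf, d)
}

# Sample onset ages for n individuals of one subgroup/sex.
# E is a k x n matrix of unit exponential draws.
sample_onsets_process <- function(process, E, rate_mult, beta, boost) {
  k <- process$k
  rates <- process$rates * rate_mult * boost
  n <- ncol(E)
  if (process$law == "power_law") {
    if (boost != 1)
      stop_ms("rate_boost is only supported for law = 'exponential'")
    P <- prod(rates)
    if (beta == 0) return((E[1, ] * factorial(k) / P)^(1 / k))
    # cumulative hazard P/(k-1)! * (t^k/k - beta t^(k+1)/(k+1)) up to 1/beta
    tmax <- 1 / beta
    Lmax <- P / factorial(k - 1) * (tmax^k / k - beta * tmax^(k + 1) / (k + 1))
    grid <- seq(0, tmax, length.out = 4096)
    Lg <- P / factorial(k - 1) * (grid^k / k - beta * grid^(k + 1) / (k + 1))
    out <- rep(Inf, n)
    ok <- E[1, ] < Lmax
    out[ok] <- stats::approx(Lg, grid, xout = E[1, ok], ties = "ordered")$y
    return(out)
  }
  if (process$ordering == "any_order") {
    tmax_step <- rep(0, n)
    for (j in seq_len(k))
      tmax_step <- pmax(tmax_step,
                        invert_step_attenuated(E[j, ], rates[j], beta, 0))
    return(tmax_step)
  }
  # sequential
  s <- numeric(n)
  for (j in seq_len(k)) {
    d <- invert_step_attenuated(E[j, ], rates[j], beta, s)
    s <- s + d
  }
  s
}

#' Simulate a multistep cohort
#'
#' Draws individual onset ages under a [cohort_spec()].  Each individual
#' is assigned a subgroup by mixture weight and is susceptible with
#' probability `C`; susceptible individuals draw their step durations at
#' the sex-multiplied (and extinction-attenuated) rates and convert at the
#' resulting onset age, censored at `max_age`.
#'
#' `rate_boost` enables rare-event importance sampling for the literal
#' exponential-step law: step durations are drawn at `boost` times the
#' true rates and every sample carries the exact likelihood ratio as a
#' weight (uncensored: the density ratio of the step durations; censored:
#' the ratio of disease-free survival at `max_age`).  Weighted event and
#' person-time sums are then unbiased for the cohort at the *true* rates,
#' which makes slope estimation feasible in the deep rare-step regime
#' where unweighted events are essentially never observed.
#'
#' @param spec a [cohort_spec()].
#' @param rate_boost proposal-rate multiplier for importance sampling
#'   (default 1 = plain simulation).  Requires sequential exponential
#'   steps and `extinction_beta = 0`.
#' @return A `data.frame` of class `onset_samples` with columns `sex`,
#'   `subgroup`, `susceptible`, `onset` (`NA` when censored), `censored`,
#'   `weight`; attributes `max_age`, `age_bins`, `spec`.
#' @export
simulate_cohort <- function(spec, rate_boost = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (rate_boost != 1) {
    laws <- vapply(spec$subgroups, function(g) g$process$law, character(1))
    ords <- vapply(spec$subgroups, function(g) g$process$ordering, character(1))
    if (any(laws != "exponential") || any(ords != "sequential") ||
        spec$extinction_beta > 0)
      stop_ms(paste0("rate_boost requires sequential exponential steps ",
                     "with extinction_beta = 0"))
  }
  n <- spec$n_individuals
  kmax <- max(vapply(spec$subgroups, function(g) g$process$k, integer(1)))
  nsub <- length(spec$subgroups)
  wts <- vapply(spec$subgroups, function(g) g$weight, numeric(1))
  cum_w <- cumsum(wts)

  out <- vector("list", length(spec$sexes))
  for (si in seq_along(spec$sexes)) {
    sx <- spec$sexes[si]
    mult <- spec$sex_rate_multiplier[[sx]]
    u_sub <- with_seed(derive_seed(spec$seed, paste0("subgroup_", sx)),
                       stats::runif(n))
    u_sus <- with_seed(derive_seed(spec$seed, paste0("susceptible_", sx)),
                       stats::runif(n))
    E <- with_seed(derive_seed(spec$seed, paste0("steps_", sx)),
                   matrix(stats::rexp(n * kmax), nrow = kmax))
    subgroup <- findInterval(u_sub, cum_w, left.open = TRUE) + 1L
    susceptible <- u_sus < spec$susceptible_fraction

    onset <- rep(NA_real_, n)
    weight <- rep(1, n)
    for (g in seq_len(nsub)) {
      idx <- which(subgroup == g & susceptible)
      if (!length(idx)) next
      pr <- spec$subgroups[[g]]$process
      Tg <- sample_onsets_process(pr, E[seq_len(pr$k), idx, drop = FALSE],
                                  mult, spec$extinction_beta, rate_boost)
      onset[idx] <- Tg
      if (rate_boost != 1) {
        # likelihood ratio: boost^-k * exp((boost-1)/boost * sum(E)) for
        # uncensored draws; survival ratio at max_age for censored ones
        Esum <- colSums(E[seq_len(pr$k), idx, drop = FALSE])
        w_unc <- rate_boost^(-pr$k) *
          exp((rate_boost - 1) / rate_boost * Esum)
        pr_true <- step_process(pr$k, pr$rates * mult,
                                ordering = pr$ordering, law = pr$law)
        pr_prop <- step_process(pr$k, pr$rates * mult * rate_boost,
                                ordering = pr$ordering, law = pr$law)
        w_cen <- survival_closed_form(pr_true, spec$max_age) /
          survival_closed_form(pr_prop, spec$max_age)
        weight[idx] <- ifelse(Tg > spec$max_age, w_cen, w_unc)
      }
    }
    censored <- is.na(onset) | onset > spec$max_age
    onset[censored] <- NA_real_
    out[[si]] <- data.frame(sex = sx, subgroup = subgroup,
                            susceptible = susceptible, onset = onset,
                            censored = censored, weight = weight,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, max_age = spec$max_age, age_bins = spec$age_bins,
            spec = spec, class = c("onset_samples", "data.frame"))
}

#' Bin onset samples into an incidence table
#'
#' Converts simulated onset ages to an [incidence_table()]:
#' per bin, incidence = events / person-years-at-risk x 1e5, with exact
#' event-time integration of person-time (individuals leave the risk set
#' at onset; censored and never-susceptible individuals contribute time
#' until `max_age`).  95% intervals are Poisson (Garwood) intervals on the
#' bin's event count; for weighted (importance-sampled) cohorts the
#' Garwood interval is taken on the effective event count
#' `(sum w)^2 / sum(w^2)`.
#'
#' @param samples an `onset_samples` frame from [simulate_cohort()].
#' @param age_bins bin edges in years (defaults to the bins recorded in
#'   the cohort specification).
#' @return An [incidence_table()] with `person_years` and `cases` columns.
#' @export
incidence_from_onsets <- function(samples, age_bins = NULL) {
  age_bins <- age_bins %||% attr(samples, "age_bins")
  max_age <- attr(samples, "max_age") %||% Inf
  if (is.null(age_bins) || length(age_bins) < 2)
    stop_ms("age_bins must give at least one bin")
  if (!any(!samples$censored & samples$susceptible))
    stop_ms("no uncensored onsets: nothing to bin")
  lo <- age_bins[-length(age_bins)]
  hi <- age_bins[-1]
  res <- lapply(split(samples, samples$sex), function(d) {
    end <- ifelse(is.na(d$onset), min(max_age, max(hi)), d$onset)
    rows <- lapply(seq_along(lo), function(b) {
      at_risk <- pmax(0, pmin(end, hi[b]) - lo[b])
      py <- sum(d$weight * at_risk)
      ev <- !is.na(d$onset) & d$onset >= lo[b] & d$onset < hi[b]
      evw <- sum(d$weight[ev])
      sumw2 <- sum(d$weight[ev]^2)
      if (py <= 0) return(NULL)
      rate <- evw / py * 1e5
      n_eff <- if (evw > 0) evw^2 / sumw2 else 0
      scale <- if (evw > 0) n_eff / evw else 1
      ci_lo <- if (n_eff > 0) stats::qgamma(0.025, n_eff) / (py * scale) * 1e5 else 0
      ci_hi <- stats::qgamma(0.975, n_eff + 1) / (py * scale) * 1e5
      data.frame(age = (lo[b] + hi[b]) / 2, sex = d$sex[1], incidence = rate,
                 ci_low = ci_lo, ci_high = ci_hi, person_years = py,
                 cases = evw, stringsAsFactors = FALSE)
    })
    empty <- vapply(rows, is.null, logical(1))
    if (any(empty))
      warn_ms("omitting %d bin(s) with zero person-years", sum(empty))
    do.call(rbind, rows[!empty])
  })
  df <- do.call(rbind, res)
  do.call(incidence_table,
          c(as.list(df),
            list(units_label = "per 100,000 person-years",
                 source = "multistep simulation")))
}
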