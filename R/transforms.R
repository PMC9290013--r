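# Parameter transforms between the constrained (scientific) scale and the
# unconstrained scale the sampler and bridge estimator work on.  Each
# parameter definition carries its transform, its log prior on the
# constrained scale, and an initial value; the model's log posterior on
# the unconstrained scale adds the transform's log Jacobian.

ms_par <- function(name, transform = c("identity", "log", "logit",
                                       "shifted_log", "abs"),
                   lo = NA_real_, hi = NA_real_, shift = 1,
                   log_prior, init) {
  transform <- match.arg(transform)
  list(name = name, transform = transform, lo = lo, hi = hi, shift = shift,
       log_prior = log_prior, init = init)
}

par_to_constrained <- function(p, u) {
  switch(p$transform,
         identity = u,
         log = exp(u),
         shifted_log = p$shift + exp(u),
         logit = p$lo + (p$hi - p$lo) * stats::plogis(u),
         abs = abs(u))
}

par_to_unconstrained <- function(p, th) {
  switch(p$transform,
         identity = th,
         log = log(th),
         shifted_log = log(th - p$shift),
         logit = stats::qlogis((th - p$lo) / (p$hi - p$lo)),
         abs = th)
}

par_log_jacobian <- function(p, u) {
  switch(p$transform,
         identity = 0,
         log = u,
         shifted_log = u,
         logit = log(p$hi - p$lo) + stats::plogis(u, log.p = TRUE) +
           stats::plogis(-u, log.p = TRUE),
         # folded parameterization for scale parameters: theta = |u| has
         # two preimages, so the density on u carries a factor 1/2; this
         # keeps the evidence integral on the u scale exactly equal to
         # the evidence on the constrained scale
         abs = log(0.5))
}

# Assemble the pieces of a model: pars is a list of ms_par.
ms_model <- function(name, pars, log_lik, mu_fn, data, extra = list()) {
  to_constrained <- function(u)
    vapply(seq_along(pars), function(i) par_to_constrained(pars[[i]], u[i]),
           numeric(1))
  to_unconstrained <- function(th)
    vapply(seq_along(pars), function(i) par_to_unconstrained(pars[[i]], th[i]),
           numeric(1))
  log_prior <- function(th)
    sum(vapply(seq_along(pars), function(i) pars[[i]]$log_prior(th[i]),
               numeric(1)))
  log_jac <- function(u)
    sum(vapply(seq_along(pars), function(i) par_log_jacobian(pars[[i]], u[i]),
               numeric(1)))
  log_post_u <- function(u) {
    th <- to_constrained(u)
    lpr <- log_prior(th)
    if (!is.finite(lpr)) return(-Inf)
    ll <- log_lik(th)
    if (!is.finite(ll)) return(-Inf)
    ll + lpr + log_jac(u)
  }
  init_u <- to_unconstrained(vapply(pars, `[[`, numeric(1), "init"))
  c(list(name = name, pars = pars, par_names = vapply(pars, `[[`,
                                                      character(1), "name"),
         log_lik = log_lik, log_prior = log_prior,
         to_constrained = to_constrained,
         to_unconstrained = to_unconstrained,
         log_post_u = log_post_u, init_u = init_u, mu_fn = mu_fn,
         data = data), extra)
}

# Prior builders shared across models ------------------------------------

prior_normal <- function(mean, sd) function(th) stats::dnorm(th, mean, sd, log = TRUE)

prior_half_normal <- function(sd) function(th) {
  if (th < 0) return(-Inf)
  stats::dnorm(th, 0, sd, log = TRUE) + log(2)
}

prior_uniform <- function(lo, hi) function(th) {
  if (th < lo || th > hi) return(-Inf)
  -log(hi - lo)
}

prior_trunc_normal <- function(mean, sd, lower) {
  lognorm <- stats::pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE)
  function(th) {
    if (th < lower) return(-Inf)
    stats::dnorm(th, mean, sd, log = TRUE) - lognorm
  }
}

prior_beta <- function(a, b) function(th) stats::dbeta(th, a, b, log = TRUE)
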