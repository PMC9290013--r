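# Marginal likelihood, Bayes factors and evidence categories.
#
# The marginal likelihood is estimated by bridge sampling on the model's
# unconstrained scale: the bridge is built between the posterior draws and
# a moment-matched multivariate normal proposal, iterating the optimal
# bridge function to convergence.  Because the evidence integral is taken
# on the unconstrained scale with the transform Jacobian included in the
# density, it equals the evidence on the original parameter scale.

mvn_fit <- function(draws) {
  m <- colMeans(draws)
  S <- stats::cov(draws)
  S <- S + diag(1e-10, ncol(draws))
  list(mean = m, chol = chol(S),
       logdet = 2 * sum(log(diag(chol(S)))))
}

mvn_logpdf <- function(q, x) {
  z <- backsolve(q$chol, t(x) - q$mean, transpose = TRUE)
  -0.5 * (colSums(z^2) + q$logdet + ncol(x) * log(2 * pi))
}

mvn_sample <- function(q, n) {
  d <- length(q$mean)
  z <- matrix(stats::rnorm(n * d), d, n)
  t(crossprod(q$chol, z) + q$mean)
}

# Iterative optimal-bridge estimate given l1 = lp - lq on posterior draws
# and l2 = lp - lq on proposal draws.  Returns log marginal likelihood.
bridge_iterate <- function(l1, l2, tol = 1e-10, max_iter = 1000) {
  n1 <- length(l1); n2 <- length(l2)
  ls1 <- log(n1 / (n1 + n2)); ls2 <- log(n2 / (n1 + n2))
  shift <- stats::median(l1)                  # numerical centring
  l1 <- l1 - shift; l2 <- l2 - shift
  pair_lse <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))
  logr <- 0
  for (it in seq_len(max_iter)) {
    # numerator: mean over proposal draws of exp(l2)/(s1 exp(l2) + s2 r)
    num_terms <- l2 - pair_lse(ls1 + l2, ls2 + logr)
    den_terms <- -pair_lse(ls1 + l1, ls2 + logr)
    new_logr <- (logsumexp(num_terms) - log(n2)) -
      (logsumexp(den_terms) - log(n1))
    if (!is.finite(new_logr)) break
    if (abs(new_logr - logr) < tol) { logr <- new_logr; break }
    logr <- new_logr
  }
  list(logml = logr + shift, n_iter = it)
}

#' Bridge-sampling estimate of a log marginal likelihood
#'
#' Low-level entry point taking an un-normalised log posterior density on
#' an unconstrained scale and draws from it; [log_marginal_likelihood()]
#' wraps it for `ms_fit` objects.  Half the posterior draws fit the
#' moment-matched normal proposal, the other half enter the bridge; the
#' Monte-Carlo error is estimated by bootstrap over both draw sets.
#'
#' @param log_post vectorisable-via-apply function of one unconstrained
#'   parameter vector.
#' @param draws_u matrix of posterior draws (rows = draws).
#' @param n_proposal_draws number of proposal draws (default: as many as
#'   bridge-side posterior draws).
#' @param seed integer seed (proposal draws + bootstrap).
#' @param n_boot bootstrap replicates for the MC error.
#' @return List of class `ms_evidence`: `logml`, `mc_error`, `n_iter`,
#'   `n_posterior`, `n_proposal`.
#' @export
bridge_sampler <- function(log_post, draws_u, n_proposal_draws = NULL,
                           seed = 1L, n_boot = 12) {
  draws_u <- as.matrix(draws_u)
  n <- nrow(draws_u)
  if (n < 40) stop_ms("too few posterior draws for bridge sampling")
  fit_idx <- seq_len(floor(n / 2))
  q <- mvn_fit(draws_u[fit_idx, , drop = FALSE])
  u1 <- draws_u[-fit_idx, , drop = FALSE]
  n2 <- n_proposal_draws %||% nrow(u1)
  u2 <- with_seed(derive_seed(seed, "bridge_proposal"), mvn_sample(q, n2))
  lp1 <- apply(u1, 1, log_post)
  lp2 <- apply(u2, 1, log_post)
  l1 <- lp1 - mvn_logpdf(q, u1)
  l2 <- lp2 - mvn_logpdf(q, u2)
  if (any(!is.finite(l1)))
    stop_ms("posterior draws with non-finite density: invalid draws_u")
  # proposal draws outside the posterior support keep l2 = -Inf: they
  # contribute zero to the bridge numerator but must stay in the count,
  # otherwise the estimate is biased upward by the excluded mass
  est <- bridge_iterate(l1, l2)
  boot <- with_seed(derive_seed(seed, "bridge_boot"), {
    vapply(seq_len(n_boot), function(b) {
      i1 <- sample(length(l1), replace = TRUE)
      i2 <- sample(length(l2), replace = TRUE)
      bridge_iterate(l1[i1], l2[i2])$logml
    }, numeric(1))
  })
  structure(list(logml = est$logml, mc_error = stats::sd(boot),
                 n_iter = est$n_iter, n_posterior = length(l1),
                 n_proposal = length(l2)),
            class = "ms_evidence")
}

#' Log marginal likelihood of a fitted model
#'
#' @param fit a converged `ms_fit` (all priors in the package are proper,
#'   which the evidence requires).
#' @param n_bridge_draws proposal draws for the bridge (default: half the
#'   posterior draws).
#' @param seed integer seed; the default derives from the fit's own seed
#'   so repeated calls - and the two orders of a Bayes factor - reuse the
#'   identical estimate.
#' @return An `ms_evidence` list (`logml`, `mc_error`, ...).
#' @export
log_marginal_likelihood <- function(fit, n_bridge_draws = NULL,
                                    seed = NULL) {
  stopifnot(inherits(fit, "ms_fit"))
  if (!fit$converged)
    stop_ms("refusing to compute evidence for a non-converged fit")
  seed <- seed %||% derive_seed(fit$seed, paste0("evidence_", fit$model))
  # Folded (theta = |u|) scale parameters have a symmetric, potentially
  # bimodal posterior on the u scale, which defeats a moment-matched
  # normal bridge proposal.  Folding the draws onto the positive
  # half-space and adding log(2) per folded coordinate leaves the
  # evidence integral unchanged while restoring unimodality.
  model <- fit$model_def
  idx <- which(vapply(model$pars, `[[`, character(1), "transform") == "abs")
  draws_u <- fit$draws_u[, seq_along(model$pars), drop = FALSE]
  log_post <- model$log_post_u
  if (length(idx)) {
    draws_u[, idx] <- abs(draws_u[, idx])
    log_post <- function(u) {
      if (any(u[idx] < 0)) return(-Inf)
      model$log_post_u(u) + length(idx) * log(2)
    }
  }
  bridge_sampler(log_post, draws_u, n_proposal_draws = n_bridge_draws,
                 seed = seed)
}

#' Brute-force quadrature check of a log marginal likelihood
#'
#' Tensor-product trapezoidal integration of `exp(log_post)` over a box on
#' the unconstrained scale, centred on the posterior.  Only feasible for
#' models with at most 3 parameters; used as an independent cross-check of
#' the bridge estimator.
#'
#' @param log_post as in [bridge_sampler()].
#' @param draws_u posterior draws locating the integration box.
#' @param half_width box half-width in posterior SDs (default 8).
#' @param n_grid grid points per dimension.
#' @return Log marginal likelihood (numeric scalar).
#' @export
evidence_quadrature <- function(log_post, draws_u, half_width = 8,
                                n_grid = NULL) {
  draws_u <- as.matrix(draws_u)
  d <- ncol(draws_u)
  if (d > 3) stop_ms("quadrature cross-check supports at most 3 parameters")
  n_grid <- n_grid %||% c(4001, 301, 101)[d]
  m <- colMeans(draws_u); s <- apply(draws_u, 2, stats::sd)
  grids <- lapply(seq_len(d), function(i)
    seq(m[i] - half_width * s[i], m[i] + half_width * s[i],
        length.out = n_grid))
  steps <- vapply(grids, function(g) g[2] - g[1], numeric(1))
  pts <- as.matrix(expand.grid(grids))
  lp <- apply(pts, 1, log_post)
  logsumexp(lp) + sum(log(steps))
}

#' Evidence category of a Bayes factor
#'
#' Conventional thresholds: moderate `[3, 10)`, strong `[10, 100)`,
#' decisive `>= 100`; below 1 the data support the other model.
#'
#' @param bf Bayes factor (model A over model B).
#' @return One of `"supports_b"`, `"anecdotal"`, `"moderate"`, `"strong"`,
#'   `"decisive"`.
#' @export
evidence_category <- function(bf) {
  stopifnot(bf >= 0)
  if (bf < 1) "supports_b"
  else if (bf < 3) "anecdotal"
  else if (bf < 10) "moderate"
  else if (bf < 100) "strong"
  else "decisive"
}

#' Bayes factor between two fitted models
#'
#' Ratio of marginal likelihoods of two models fitted to the identical
#' data under the identical likelihood convention (enforced via the data
#' fingerprint recorded in each fit).  Each fit's evidence is estimated
#' deterministically from its own seed, so `bayes_factor(a, b)` and
#' `bayes_factor(b, a)` are exact reciprocals.
#'
#' @param fit_a,fit_b converged `ms_fit` objects on the same data.
#' @param n_bridge_draws passed to [log_marginal_likelihood()].
#' @return List of class `ms_comparison`: `model_a`, `model_b`, `log_bf`,
#'   `bf`, `mc_error` (of `log_bf`), `category`, and the two evidence
#'   objects.
#' @export
bayes_factor <- function(fit_a, fit_b, n_bridge_draws = NULL) {
  if (!identical(fit_a$fingerprint, fit_b$fingerprint))
    stop_ms(paste0("fits were made on different data ",
                   "(fingerprints %s vs %s); a Bayes factor would be ",
                   "meaningless"), fit_a$fingerprint, fit_b$fingerprint)
  ev_a <- log_marginal_likelihood(fit_a, n_bridge_draws)
  ev_b <- log_marginal_likelihood(fit_b, n_bridge_draws)
  log_bf <- ev_a$logml - ev_b$logml
  structure(list(model_a = fit_a$model, model_b = fit_b$model,
                 log_bf = log_bf, bf = exp(log_bf),
                 mc_error = sqrt(ev_a$mc_error^2 + ev_b$mc_error^2),
                 category = evidence_category(exp(log_bf)),
                 evidence_a = ev_a, evidence_b = ev_b),
            class = "ms_comparison")
}

#' @export
print.ms_comparison <- function(x, ...) {
  cat(sprintf("BF(%s / %s) = %.4g [log BF %.3f +/- %.3f]: %s\n",
              x$model_a, x$model_b, x$bf, x$log_bf, x$mc_error,
              if (x$category == "supports_b")
                sprintf("supports %s", x$model_b) else
                  sprintf("%s evidence for %s", x$category, x$model_a)))
  invisible(x)
}
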