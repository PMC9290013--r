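#' Default prior configuration
#'
#' One explicit block holding every prior hyperparameter used by the
#' fitting functions; the block is stored verbatim inside each fit so a
#' reported Bayes factor is always traceable to the priors it assumed.
#' The defaults are informative but moderately tight, centred on values
#' typical of multistage-incidence applications: log-log slopes around 6,
#' step counts around 7, and small susceptible fractions.
#'
#' @param slope_mean,slope_sd Normal prior on log-log slopes.
#' @param intercept_mean,intercept_sd Normal prior on log-scale intercepts
#'   (log incidence per 100,000 person-years at the reference age).
#' @param breakpoint_quantile the breakpoint prior is Uniform over the
#'   central `1 - 2 * breakpoint_quantile` fraction of the observed
#'   `x` range (default: central 80%).
#' @param sigma_res_sd half-Normal prior SD on the residual scale.
#' @param k_mean,k_sd Normal prior on the step count `k`, truncated at 1.
#' @param log_alpha_mean,log_alpha_sd Normal prior on `log(alpha)`, the
#'   log rate scale at the 30-year reference age.
#' @param C_shape1,C_shape2 Beta prior on the susceptible fraction `C`.
#' @param beta_sd half-Normal prior SD on the extinction rate `beta`
#'   (per year).
#' @return A named list of class `ms_priors`.
#' @export
default_priors <- function(slope_mean = 6, slope_sd = 3,
                           intercept_mean = 0, intercept_sd = 3,
                           breakpoint_quantile = 0.1,
                           sigma_res_sd = 1,
                           k_mean = 7, k_sd = 3,
                           log_alpha_mean = 0, log_alpha_sd = 5,
                           C_shape1 = 2, C_shape2 = 20,
                           beta_sd = 0.02) {
  structure(list(slope_mean = slope_mean, slope_sd = slope_sd,
                 intercept_mean = intercept_mean,
                 intercept_sd = intercept_sd,
                 breakpoint_quantile = breakpoint_quantile,
                 sigma_res_sd = sigma_res_sd,
                 k_mean = k_mean, k_sd = k_sd,
                 log_alpha_mean = log_alpha_mean,
                 log_alpha_sd = log_alpha_sd,
                 C_shape1 = C_shape1, C_shape2 = C_shape2,
                 beta_sd = beta_sd),
            class = "ms_priors")
}

#' Sampler control settings
#'
#' @param n_chains number of chains.
#' @param warmup adaptation iterations per chain (discarded).
#' @param iter retained iterations per chain.
#' @param target_accept acceptance target of the adaptive random-walk
#'   kernel.
#' @param retry when split-R-hat exceeds 1.01, retry with doubled draws,
#'   escalating up to `max_retries` times (changepoint posteriors
#'   occasionally need the second doubling).
#' @param max_retries maximum number of draw-doubling retries.
#' @return A named list of class `ms_mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 4, warmup = 2000, iter = 2000,
                         target_accept = 0.30, retry = TRUE,
                         max_retries = 2) {
  structure(list(n_chains = n_chains, warmup = warmup, iter = iter,
                 target_accept = target_accept, retry = retry,
                 max_retries = max_retries),
            class = "ms_mcmc_control")
}
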