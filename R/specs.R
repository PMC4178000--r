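# Model structure, priors and sampler settings.

#' Model structure specification
#'
#' Selects one of the six candidate model structures: the model family
#' (basic occupancy vs Royle-Nichols abundance), whether the camera sample
#' is pooled into one binary replicate or disaggregated into 41 snapshots,
#' and whether a site random effect is added (on the camera detection logit
#' for the basic family; on log mean abundance for the Royle-Nichols
#' family). Random effects are only identifiable with the disaggregated
#' camera data, and requesting them with pooled data is an error.
#'
#' @param family `"basic"` or `"royle_nichols"`.
#' @param camera_mode `"pooled"` or `"disaggregated"`.
#' @param random_effect Logical; site random effect.
#' @return An `occugear_model_spec`.
#' @export
model_spec <- function(family = c("basic", "royle_nichols"),
                       camera_mode = c("pooled", "disaggregated"),
                       random_effect = FALSE) {
  family <- match.arg(family)
  camera_mode <- match.arg(camera_mode)
  if (random_effect && camera_mode != "disaggregated") {
    abort(paste0("random_effect = TRUE requires camera_mode = 'disaggregated'; ",
                 "the pooled data cannot identify a site random effect"))
  }
  structure(list(family = family, camera_mode = camera_mode,
                 random_effect = isTRUE(random_effect)),
            class = "occugear_model_spec")
}

#' @export
format.occugear_model_spec <- function(x, ...) {
  paste0(if (x$family == "basic") "Bin(psi)" else "Pois(lambda)",
         if (x$random_effect && x$family == "royle_nichols") "-logNorm" else "",
         " Bin(p_chevron) ",
         if (x$random_effect && x$family == "basic") "Bin-logNorm(p_camera)"
         else "Bin(p_camera)",
         " [camera ", x$camera_mode, "]")
}

#' @export
print.occugear_model_spec <- function(x, ...) {
  cat("<occugear_model_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Prior specification
#'
#' Defaults follow the weakly informative choices standard for occupancy
#' models: every link-scale regression coefficient gets a Student-t prior
#' with scale 1.566 and 7.763 degrees of freedom (so a back-transformed
#' intercept is approximately uniform on (0, 1)); random-effect standard
#' deviations get Uniform(0, 100); inclusion indicators get independent
#' Bernoulli(0.5) priors (equal prior odds of inclusion and exclusion).
#'
#' @param logit_t_sigma Scale of the t prior on link-scale coefficients.
#' @param logit_t_nu Degrees of freedom of the t prior.
#' @param sd_uniform_upper Upper bound of the uniform prior on SDs.
#' @param inclusion_prior Prior inclusion probability of each covariate.
#' @return An `occugear_prior_spec`.
#' @export
prior_spec <- function(logit_t_sigma = 1.566, logit_t_nu = 7.763,
                       sd_uniform_upper = 100, inclusion_prior = 0.5) {
  stopifnot(logit_t_sigma > 0, logit_t_nu > 0, sd_uniform_upper > 0,
            inclusion_prior > 0, inclusion_prior < 1)
  structure(list(logit_t_sigma = logit_t_sigma, logit_t_nu = logit_t_nu,
                 sd_uniform_upper = sd_uniform_upper,
                 inclusion_prior = inclusion_prior),
            class = "occugear_prior_spec")
}

#' MCMC settings
#'
#' The full-scale defaults retain 30,000 posterior samples: 3 chains of
#' 100,000 iterations, a 10,000-iteration burn-in, thinned to every 10th
#' draw. [mcmc_settings_reduced()] gives desk-scale settings (3 chains of
#' 6,000 with 1,000 burn-in, no thinning) suitable for tests and examples.
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain (including burn-in).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; each chain derives its own stream from it.
#' @param N_max Truncation bound for the latent Royle-Nichols abundance.
#' @return An `occugear_mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 100000, burn_in = 10000,
                          thin = 10, seed = 1, N_max = 100) {
  stopifnot(n_chains >= 1, n_iter > burn_in, thin >= 1, N_max >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), N_max = as.integer(N_max)),
            class = "occugear_mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
mcmc_settings_reduced <- function(seed = 1, n_chains = 3, n_iter = 6000,
                                  burn_in = 1000, thin = 1, N_max = 100) {
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                thin = thin, seed = seed, N_max = N_max)
}

#' @export
print.occugear_mcmc_settings <- function(x, ...) {
  cat("<occugear_mcmc_settings> ", x$n_chains, " chains x ", x$n_iter,
      " iterations (burn-in ", x$burn_in, ", thin ", x$thin, "), seed ",
      x$seed, "\n", sep = "")
  cat("  retained draws: ",
      x$n_chains * ((x$n_iter - x$burn_in) %/% x$thin), "\n", sep = "")
  invisible(x)
}
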