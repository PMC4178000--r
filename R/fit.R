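# Posterior sampling and fitted-model methods.

draw_col_names <- function(design) {
  cn <- function(X) colnames(X) %||% character(0)
  c(paste0("occ_", c("intercept", cn(design$X_occ))),
    paste0("chev_", c("intercept", cn(design$X_chev))),
    paste0("cam_", c("intercept", cn(design$X_cam))),
    paste0("w_occ_", cn(design$X_occ), recycle0 = TRUE),
    paste0("w_chev_", cn(design$X_chev), recycle0 = TRUE),
    paste0("w_cam_", cn(design$X_cam), recycle0 = TRUE),
    "sigma_eps", "latent_mean")
}

#' Draw from the posterior of a two-gear occupancy model
#'
#' Runs the package's MCMC sampler: single-site Gibbs updates for the
#' latent occupancy states (or a discrete Metropolis walk on `0..N_max` for
#' latent abundances), adaptive random-walk Metropolis for link-scale
#' coefficients under the Student-t prior, Gibbs updates of the Kuo-Mallick
#' inclusion indicators (an excluded coefficient is refreshed from its
#' prior, so the linear predictor uses `w * beta`), and Metropolis updates
#' of random-effect terms and their SD under a Uniform(0, upper) prior.
#' Proposal adaptation is frozen at the end of burn-in. Given the same seed
#' and inputs the draws are identical.
#'
#' @param detection An `occugear_detection` (see [build_detection_data()]).
#' @param design An `occugear_design` (see [build_design_matrices()]).
#' @param spec An `occugear_model_spec`.
#' @param priors An `occugear_prior_spec`.
#' @param settings An `occugear_mcmc_settings`.
#' @return A tibble of retained draws with `chain` and `iter` columns, raw
#'   coefficients (`occ_*`, `chev_*`, `cam_*`), inclusion indicators
#'   (`w_*`), `sigma_eps`, and `latent_mean` (per-draw mean of `z`, or of
#'   `N` for the Royle-Nichols family).
#' @export
sample_posterior <- function(detection, design, spec, priors = prior_spec(),
                             settings = mcmc_settings()) {
  stopifnot(inherits(detection, "occugear_detection"),
            inherits(design, "occugear_design"),
            inherits(spec, "occugear_model_spec"),
            inherits(priors, "occugear_prior_spec"),
            inherits(settings, "occugear_mcmc_settings"))
  if (detection$camera_mode != spec$camera_mode) {
    abort("detection data and model spec disagree on camera_mode")
  }
  if (spec$random_effect && spec$camera_mode != "disaggregated") {
    abort("random effects require disaggregated camera data")
  }
  family_code <- if (spec$family == "basic") 0L else 1L
  chains <- purrr::map(seq_len(settings$n_chains), function(ch) {
    set.seed(settings$seed + ch - 1L)
    out <- run_chain_cpp(
      family_code,
      as.integer(detection$y[, "chevron"]), as.integer(detection$y[, "camera"]),
      as.integer(detection$k[["camera"]]),
      design$X_occ, design$X_chev, design$X_cam,
      spec$random_effect,
      settings$n_iter, settings$burn_in, settings$thin,
      priors$logit_t_sigma, priors$logit_t_nu,
      priors$sd_uniform_upper, priors$inclusion_prior,
      settings$N_max)
    m <- out$draws
    colnames(m) <- draw_col_names(design)
    tibble::as_tibble(m) |>
      dplyr::mutate(chain = ch, iter = dplyr::row_number(), .before = 1)
  })
  dplyr::bind_rows(chains)
}

#' Fit a two-gear occupancy or Royle-Nichols model to a site table
#'
#' High-level entry point: validates the site table, builds the detection
#' histories and standardized design matrices, and samples the posterior.
#'
#' @param tbl A site table (see [read_site_table()]).
#' @param spec An `occugear_model_spec`.
#' @param priors An `occugear_prior_spec`.
#' @param settings An `occugear_mcmc_settings`.
#' @param square_terms Squared-term convention, see [build_design_matrices()].
#' @return An `occugear_fit`: the draws tibble plus the model spec, priors,
#'   settings, detection data and design used. Summarize with [tidy()],
#'   [glance()], [inclusion_probabilities()] and [gelman_rubin()].
#' @export
fit_occupancy <- function(tbl, spec = model_spec(), priors = prior_spec(),
                          settings = mcmc_settings(),
                          square_terms = c("scaled", "raw")) {
  tbl <- validate_site_table(tbl)
  detection <- build_detection_data(tbl, camera_mode = spec$camera_mode)
  design <- build_design_matrices(tbl, square_terms = square_terms)
  draws <- sample_posterior(detection, design, spec, priors, settings)
  structure(list(draws = draws, spec = spec, priors = priors,
                 settings = settings, detection = detection, design = design),
            class = "occugear_fit")
}

#' @export
print.occugear_fit <- function(x, ...) {
  cat("<occugear_fit> ", format(x$spec), "\n", sep = "")
  cat("  sites: ", x$design$n_sites, "; retained draws: ", nrow(x$draws),
      " (", x$settings$n_chains, " chains)\n", sep = "")
  g <- glance(x)
  lab <- if (x$spec$family == "basic") "mean occupancy" else "mean abundance"
  cat(sprintf("  %s: %.3f [%.3f, %.3f]\n", lab, g$estimate,
              g$conf.low, g$conf.high))
  cat(sprintf("  max split R-hat: %.3f\n", g$max_rhat))
  invisible(x)
}

# effective (model-averaged) coefficient draws: w * beta, intercepts raw
effective_draws <- function(fit) {
  d <- fit$draws
  for (block in c("occ", "chev", "cam")) {
    terms <- colnames(fit$design[[switch(block, occ = "X_occ",
                                         chev = "X_chev", cam = "X_cam")]])
    for (tm in terms) {
      d[[paste0(block, "_", tm)]] <-
        d[[paste0(block, "_", tm)]] * d[[paste0("w_", block, "_", tm)]]
    }
  }
  d
}

# draws x sites matrix of psi (basic) or lambda (RN) at the observed
# covariates, from model-averaged coefficients
site_rate_draws <- function(fit) {
  d <- effective_draws(fit)
  terms <- colnames(fit$design$X_occ)
  B <- as.matrix(d[, paste0("occ_", terms), drop = FALSE])
  lp <- d$occ_intercept + B %*% t(fit$design$X_occ)
  if (fit$spec$family == "basic") inv_logit(lp) else exp(lp)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor computed across chains for every
#' sampled quantity; values below 1.1 are the conventional convergence
#' criterion. Quantities with no variance at all (e.g. an indicator pinned
#' at 1) get R-hat 1 by convention.
#'
#' @param fit An `occugear_fit`, or a draws tibble with a `chain` column.
#' @param parameter Optional parameter name; default all.
#' @return A tibble with `term` and `rhat`.
#' @export
gelman_rubin <- function(fit, parameter = NULL) {
  draws <- if (inherits(fit, "occugear_fit")) fit$draws else fit
  if (length(unique(draws$chain)) < 2) abort("need at least 2 chains")
  params <- setdiff(names(draws), c("chain", "iter"))
  if (!is.null(parameter)) {
    stopifnot(all(parameter %in% params))
    params <- parameter
  }
  split_chains <- draws |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(half = ifelse(dplyr::row_number() <=
                                  dplyr::n() / 2, 1L, 2L)) |>
    dplyr::ungroup() |>
    dplyr::mutate(chain2 = .data$chain * 2L - 2L + .data$half)
  rhat1 <- function(x, g) {
    n <- min(table(g))
    if (n < 2) return(NA_real_)
    means <- tapply(x, g, mean)
    vars <- tapply(x, g, var)
    W <- mean(vars)
    B <- n * var(as.numeric(means))
    if (!is.finite(W) || W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  tibble::tibble(
    term = params,
    rhat = vapply(params, function(p)
      rhat1(split_chains[[p]], split_chains$chain2), numeric(1)))
}

#' Posterior inclusion probabilities
#'
#' Mean of each covariate's inclusion-indicator draws; a covariate with
#' posterior inclusion probability above 0.5 is conventionally considered
#' supported by the data.
#'
#' @param fit An `occugear_fit`.
#' @param threshold Support threshold (default 0.5).
#' @return A tibble with `submodel`, `term`, `inclusion_prob`, `supported`.
#' @export
inclusion_probabilities <- function(fit, threshold = 0.5) {
  d <- fit$draws
  blocks <- list(distribution = "w_occ_", chevron = "w_chev_", camera = "w_cam_")
  purrr::imap_dfr(blocks, function(prefix, submodel) {
    cols <- names(d)[startsWith(names(d), prefix)]
    tibble::tibble(
      submodel = submodel,
      term = substring(cols, nchar(prefix) + 1),
      inclusion_prob = vapply(cols, function(cc) mean(d[[cc]]), numeric(1)))
  }) |>
    dplyr::mutate(supported = .data$inclusion_prob > threshold)
}

#' @rdname tidy_occugear
#' @name tidy_occugear
#' @title Broom-style summaries of a fitted model
#'
#' @description
#' `tidy()` returns model-averaged posterior summaries per coefficient,
#' laid out like the published parameter tables: posterior mean, SD, 2.5%
#' and 97.5% quantiles of the effective coefficient (`w * beta`; draws with
#' the covariate excluded contribute zeros, i.e. the true model-averaged
#' estimate), plus the inclusion probability. `glance()` returns one row
#' with the derived mean occupancy (or mean site abundance), its credible
#' interval, the worst R-hat and bookkeeping sizes.
#'
#' @param x An `occugear_fit`.
#' @param average Either `"all"` (default; average over all draws) or
#'   `"conditional"` (average only over draws in which the covariate is
#'   included).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.occugear_fit <- function(x, average = c("all", "conditional"), ...) {
  average <- match.arg(average)
  d <- effective_draws(x)
  blocks <- list(distribution = "occ", chevron = "chev", camera = "cam")
  purrr::imap_dfr(blocks, function(block, submodel) {
    terms <- c("intercept", colnames(x$design[[switch(block,
      occ = "X_occ", chev = "X_chev", cam = "X_cam")]]))
    purrr::map_dfr(terms, function(tm) {
      v <- d[[paste0(block, "_", tm)]]
      w <- if (tm == "intercept") NULL else d[[paste0("w_", block, "_", tm)]]
      if (average == "conditional" && !is.null(w) && any(w > 0)) v <- v[w > 0]
      qs <- quantile(v, c(0.025, 0.975), names = FALSE)
      tibble::tibble(
        submodel = submodel, term = tm,
        estimate = mean(v), std.error = sd(v),
        conf.low = qs[1], conf.high = qs[2],
        inclusion_prob = if (is.null(w)) NA_real_ else mean(w))
    })
  })
}

#' @rdname tidy_occugear
#' @export
augment.occugear_fit <- function(x, ...) {
  rates <- site_rate_draws(x)
  tibble::tibble(
    site_id = x$detection$site_id %||% as.character(seq_len(ncol(rates))),
    .fitted = colMeans(rates),
    .lower = apply(rates, 2, quantile, 0.025, names = FALSE),
    .upper = apply(rates, 2, quantile, 0.975, names = FALSE))
}

#' @rdname tidy_occugear
#' @export
glance.occugear_fit <- function(x, ...) {
  rates <- site_rate_draws(x)
  mean_rate <- rowMeans(rates)
  qs <- quantile(mean_rate, c(0.025, 0.975), names = FALSE)
  rh <- tryCatch(gelman_rubin(x),
                 error = function(e) tibble::tibble(rhat = NA_real_))
  site_means <- colMeans(rates)
  tibble::tibble(
    family = x$spec$family,
    camera_mode = x$spec$camera_mode,
    random_effect = x$spec$random_effect,
    n_sites = x$design$n_sites,
    n_draws = nrow(x$draws),
    estimate = mean(mean_rate),
    conf.low = qs[1],
    conf.high = qs[2],
    site_rate_min = min(site_means),
    site_rate_max = max(site_means),
    max_rhat = if (all(is.na(rh$rhat))) NA_real_
               else max(rh$rhat, na.rm = TRUE))
}

#' Write a fitted model's summary table to CSV
#'
#' The layout mirrors the published parameter tables: one row per
#' coefficient with posterior mean, SD, 2.5%/97.5% bounds and inclusion
#' probability.
#'
#' @param fit An `occugear_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  readr::write_csv(tidy(fit), path, progress = FALSE)
  invisible(path)
}
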