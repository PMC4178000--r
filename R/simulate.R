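# Synthetic two-gear survey data. The generator emulates the study design
# the models assume -- simultaneous chevron-trap and 41-snapshot camera
# sampling over reef sites -- and exposes two controlled violations:
# serially correlated snapshots (within-site clustering in time) and
# clustered individuals (schooling), the mechanisms that break the binomial
# sampling assumption.

default_true_params <- function(family) {
  # calibration conveniences near published regime, not ground truth:
  # mean occupancy ~0.45, chevron p ~0.39, camera pooled p ~0.75 (basic);
  # lambda <= ~2, chevron r ~0.30, camera pooled r ~0.61 (RN)
  beta <- setNames(numeric(16), c("intercept", occ_columns))
  alpha <- setNames(numeric(7), c("intercept", chev_columns))
  phi <- setNames(numeric(5), c("intercept", cam_columns))
  if (family == "basic") {
    beta["intercept"] <- logit(0.45)
    beta["depth"] <- -0.35
    beta["lat"] <- -0.40
    beta["lat2"] <- -0.42
    alpha["intercept"] <- logit(0.39)
    phi["intercept"] <- logit(0.75)
  } else {
    beta["intercept"] <- log(0.65)
    beta["depth"] <- -0.28
    beta["lat"] <- -0.41
    beta["lat2"] <- -0.38
    alpha["intercept"] <- logit(0.30)
    phi["intercept"] <- logit(0.61)
  }
  list(beta = beta, alpha = alpha, phi = phi)
}

default_covariate_gens <- function() {
  list(
    depth_range = c(16, 83),        # m
    lat_range = c(27, 32),          # degrees N
    temp_mean = 22.5, temp_sd = 2.5, # bottom temperature, deg C
    soak_mean = 90, soak_sd = 10,   # minutes
    year_freq = c("2010" = 0.5, "2011" = 0.5),
    livebot_freq = c(l = 0.4, m = 0.4, h = 0.2),
    hardsub_freq = c(l = 0.4, m = 0.4, h = 0.2),
    relief_freq = c(l = 0.5, m = 0.3, h = 0.2),
    cdir_freq = c(toward = 1 / 3, perpendicular = 1 / 3, away = 1 / 3),
    cspeed_freq = c(low = 0.5, high = 0.5),
    turb_freq = c(low = 0.7, high = 0.3)
  )
}

#' Define a simulation scenario
#'
#' Bundles everything the generator needs: the number of sites, the model
#' family generating the data, true coefficient vectors on the standardized
#' scale (detection intercepts/effects are on the pooled-replicate scale;
#' the generator derives per-snapshot rates internally, see the vignette),
#' covariate generators, and the two assumption-violation dials:
#' `snapshot_rho` (lag-1 serial correlation among the 41 snapshots, via a
#' two-state Markov chain, or a beta-binomial if
#' `snapshot_mechanism = "betabinom"`) and `group_dispersion` (Royle-Nichols
#' only: individuals arrive in groups of mean size `1 + group_dispersion`
#' that are detected jointly, so groups are perceived as individuals).
#'
#' @param S Number of sites.
#' @param family `"basic"` or `"royle_nichols"`.
#' @param beta,alpha,phi True coefficient vectors (intercept first) for the
#'   distribution, chevron-detection and camera-detection sub-models;
#'   defaults are calibrated near published estimates for the study system.
#'   Partial named vectors are merged over the defaults.
#' @param sigma_eps SD of the site random effect (camera-detection logit for
#'   the basic family, log-abundance for Royle-Nichols). 0 disables it.
#' @param snapshot_rho Within-site snapshot clustering in `[0, 1)`.
#' @param snapshot_mechanism `"markov"` (serial autocorrelation) or
#'   `"betabinom"` (exchangeable extra-binomial variation).
#' @param group_dispersion Clustered-individual violation strength (>= 0).
#' @param covariates Covariate generator settings; see
#'   `occugear:::default_covariate_gens()` for the full list.
#' @param seed Integer seed; every simulation from the scenario is
#'   reproducible from it.
#' @return An `occugear_scenario`.
#' @export
sim_scenario <- function(S = 200, family = c("basic", "royle_nichols"),
                         beta = NULL, alpha = NULL, phi = NULL,
                         sigma_eps = 0, snapshot_rho = 0,
                         snapshot_mechanism = c("markov", "betabinom"),
                         group_dispersion = 0, covariates = list(),
                         seed = 1) {
  family <- match.arg(family)
  snapshot_mechanism <- match.arg(snapshot_mechanism)
  stopifnot(S >= 0, sigma_eps >= 0, snapshot_rho >= 0, snapshot_rho < 1,
            group_dispersion >= 0)
  defaults <- default_true_params(family)
  merge_par <- function(def, user, label) {
    if (is.null(user)) return(def)
    if (is.null(names(user))) {
      if (length(user) != length(def)) {
        abort(paste0(label, " must have length ", length(def),
                     " or be a named vector"))
      }
      return(setNames(as.numeric(user), names(def)))
    }
    bad <- setdiff(names(user), names(def))
    if (length(bad) > 0) abort(paste0("unknown ", label, " term(s): ",
                                      paste(bad, collapse = ", ")))
    def[names(user)] <- user
    def
  }
  gens <- utils::modifyList(default_covariate_gens(), covariates)
  structure(list(
    S = as.integer(S), family = family,
    beta = merge_par(defaults$beta, beta, "beta"),
    alpha = merge_par(defaults$alpha, alpha, "alpha"),
    phi = merge_par(defaults$phi, phi, "phi"),
    sigma_eps = sigma_eps, snapshot_rho = snapshot_rho,
    snapshot_mechanism = snapshot_mechanism,
    group_dispersion = group_dispersion,
    covariates = gens, seed = as.integer(seed)),
    class = "occugear_scenario")
}

empty_site_table <- function() {
  tibble::tibble(site_id = character(0), year = integer(0),
                 chevron_count = integer(0), camera_snapshot_hits = integer(0),
                 depth_m = numeric(0), lat_deg = numeric(0),
                 temp_c = numeric(0),
                 livebot = factor(character(0), c("l", "m", "h")),
                 hardsub = factor(character(0), c("l", "m", "h")),
                 relief = factor(character(0), c("l", "m", "h")),
                 soak_min = numeric(0),
                 cdir = factor(character(0), c("toward", "perpendicular", "away")),
                 cspeed = factor(character(0), c("low", "high")),
                 turb = factor(character(0), c("low", "high")))
}

#' Generate site covariates for a scenario
#'
#' Draws the covariate part of a site table (detection columns are zero
#' placeholders): depths uniform over the scenario's range, latitudes
#' uniform, normal bottom temperatures and soak times (soak truncated
#' positive), and categorical levels at the scenario's frequencies.
#'
#' @param scenario An `occugear_scenario`.
#' @return A validated site table with all-zero detection columns.
#' @export
generate_covariates <- function(scenario) {
  stopifnot(inherits(scenario, "occugear_scenario"))
  S <- scenario$S
  if (S == 0) return(empty_site_table())
  g <- scenario$covariates
  set.seed(scenario$seed)
  draw_cat <- function(freq) {
    factor(sample(names(freq), S, replace = TRUE, prob = freq),
           levels = names(freq))
  }
  tbl <- tibble::tibble(
    site_id = sprintf("site_%04d", seq_len(S)),
    year = as.integer(sample(c(2010L, 2011L), S, TRUE, prob = g$year_freq)),
    chevron_count = 0L,
    camera_snapshot_hits = 0L,
    depth_m = runif(S, g$depth_range[1], g$depth_range[2]),
    lat_deg = runif(S, g$lat_range[1], g$lat_range[2]),
    temp_c = rnorm(S, g$temp_mean, g$temp_sd),
    livebot = draw_cat(g$livebot_freq),
    hardsub = draw_cat(g$hardsub_freq),
    relief = draw_cat(g$relief_freq),
    soak_min = pmax(rnorm(S, g$soak_mean, g$soak_sd), 1),
    cdir = draw_cat(g$cdir_freq),
    cspeed = draw_cat(g$cspeed_freq),
    turb = draw_cat(g$turb_freq))
  validate_site_table(tbl)
}

# stationary per-snapshot rate q such that a 41-snapshot series with lag-1
# correlation rho (or beta-binomial ICC rho) has P(>= 1 positive) = p_pool
snapshot_rate_for_pooled <- function(p_pool, rho, mechanism = "markov") {
  n <- N_SNAPSHOTS
  miss_prob <- function(q) {
    if (mechanism == "markov") {
      (1 - q) * (1 - q * (1 - rho))^(n - 1)
    } else if (rho == 0) {
      (1 - q)^n
    } else {
      a <- q * (1 - rho) / rho
      b <- (1 - q) * (1 - rho) / rho
      exp(lbeta(a, b + n) - lbeta(a, b))
    }
  }
  one <- function(p) {
    if (p <= 0) return(0)
    if (p >= 1) return(1)
    stats::uniroot(function(q) (1 - miss_prob(q)) - p,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  vapply(p_pool, one, numeric(1))
}

# one 41-snapshot 0/1 series with stationary rate q and the scenario's
# clustering mechanism
sim_snapshots <- function(q, rho, mechanism) {
  n <- N_SNAPSHOTS
  if (rho == 0) return(rbinom(n, 1, q))
  if (mechanism == "betabinom") {
    a <- q * (1 - rho) / rho
    b <- (1 - q) * (1 - rho) / rho
    return(rbinom(n, 1, stats::rbeta(1, a, b)))
  }
  x <- integer(n)
  x[1] <- rbinom(1, 1, q)
  p01 <- q * (1 - rho)          # P(1 | previous 0)
  p11 <- q + (1 - q) * rho      # P(1 | previous 1)
  for (t in 2:n) x[t] <- rbinom(1, 1, if (x[t - 1] == 1) p11 else p01)
  x
}

#' Simulate a complete two-gear site table
#'
#' `simulate_basic()` draws latent occupancy `z ~ Bernoulli(psi_i)`, a
#' chevron detection `Bernoulli(z * p1_i)` and 41 camera snapshots whose
#' pooled detection probability is `p2_i` (under snapshot clustering the
#' per-snapshot rate is adjusted so the pooled rate is preserved).
#' `simulate_rn()` draws latent abundance `N ~ Poisson(lambda_i)` (with
#' log-normal mixing when `sigma_eps > 0`), detects each individual
#' independently with the gear's individual detection probability, and --
#' when `group_dispersion > 0` -- replaces independent individuals with
#' jointly detected groups, the clustering violation that biases abundance
#' estimates downward. `simulate_sites()` dispatches on the scenario
#' family. The true parameters and latent states are attached as the
#' `"truth"` attribute (see [truth_bundle()]).
#'
#' @param scenario An `occugear_scenario`.
#' @return A validated site table with a `"truth"` attribute.
#' @export
simulate_sites <- function(scenario) {
  stopifnot(inherits(scenario, "occugear_scenario"))
  if (scenario$family == "basic") simulate_basic(scenario)
  else simulate_rn(scenario)
}

scenario_site_probs <- function(scenario, tbl) {
  design <- build_design_matrices(tbl)
  list(
    design = design,
    occ_lp = drop(scenario$beta[1] + design$X_occ %*% scenario$beta[-1]),
    p1 = drop(inv_logit(scenario$alpha[1] + design$X_chev %*% scenario$alpha[-1])),
    cam_lp = drop(scenario$phi[1] + design$X_cam %*% scenario$phi[-1]))
}

#' @rdname simulate_sites
#' @export
simulate_basic <- function(scenario) {
  stopifnot(scenario$family == "basic")
  tbl <- generate_covariates(scenario)
  if (nrow(tbl) == 0) return(structure(tbl, truth = list(scenario = scenario)))
  pr <- scenario_site_probs(scenario, tbl)
  S <- scenario$S
  eps <- if (scenario$sigma_eps > 0) rnorm(S, 0, scenario$sigma_eps) else numeric(S)
  psi <- inv_logit(pr$occ_lp)
  p2 <- inv_logit(pr$cam_lp + eps)   # pooled-scale camera detection
  z <- rbinom(S, 1, psi)
  y1 <- rbinom(S, 1, z * pr$p1)
  q_snap <- snapshot_rate_for_pooled(p2, scenario$snapshot_rho,
                                     scenario$snapshot_mechanism)
  hits <- integer(S)
  for (i in seq_len(S)) {
    if (z[i] == 1) {
      hits[i] <- sum(sim_snapshots(q_snap[i], scenario$snapshot_rho,
                                   scenario$snapshot_mechanism))
    }
  }
  tbl$chevron_count <- as.integer(y1)
  tbl$camera_snapshot_hits <- hits
  truth <- list(scenario = scenario, z = z, psi = psi, p_chevron = pr$p1,
                p_camera_pooled = p2, p_camera_snapshot = q_snap, eps = eps)
  structure(validate_site_table(tbl), truth = truth)
}

#' @rdname simulate_sites
#' @export
simulate_rn <- function(scenario) {
  stopifnot(scenario$family == "royle_nichols")
  tbl <- generate_covariates(scenario)
  if (nrow(tbl) == 0) return(structure(tbl, truth = list(scenario = scenario)))
  pr <- scenario_site_probs(scenario, tbl)
  S <- scenario$S
  eps <- if (scenario$sigma_eps > 0) rnorm(S, 0, scenario$sigma_eps) else numeric(S)
  lambda <- exp(pr$occ_lp + eps)
  r1 <- pr$p1                          # individual detection, chevron
  r2 <- inv_logit(pr$cam_lp)           # individual detection, camera (pooled)
  disp <- scenario$group_dispersion
  mu_group <- 1 + disp
  # detection units: independent individuals, or jointly detected groups
  units <- rpois(S, lambda / mu_group)
  N <- if (disp == 0) units else {
    vapply(units, function(g) {
      if (g == 0) 0L else sum(1L + rpois(g, disp))
    }, integer(1))
  }
  y1 <- rbinom(S, 1, species_detection_from_individual(r1, units))
  r2_snap <- snapshot_rate_for_pooled(r2, scenario$snapshot_rho,
                                      scenario$snapshot_mechanism)
  hits <- integer(S)
  for (i in seq_len(S)) {
    if (units[i] > 0) {
      # each detection unit is an independent snapshot series; a snapshot
      # is positive if any unit shows
      series <- replicate(units[i],
        sim_snapshots(r2_snap[i], scenario$snapshot_rho,
                      scenario$snapshot_mechanism))
      hits[i] <- sum(apply(series, 1, max))
    }
  }
  tbl$chevron_count <- as.integer(y1)
  tbl$camera_snapshot_hits <- hits
  truth <- list(scenario = scenario, N = N, units = units, lambda = lambda,
                r_chevron = r1, r_camera_pooled = r2,
                r_camera_snapshot = r2_snap, eps = eps)
  structure(validate_site_table(tbl), truth = truth)
}

#' Extract or serialize the truth bundle of a simulated table
#'
#' Simulated site tables carry their generating parameters and latent
#' states in the `"truth"` attribute; `truth_bundle()` extracts it and
#' `write_truth_bundle()` serializes it to JSON (factors and parameter
#' vectors included) so parameter-recovery scoring can run out of process.
#'
#' @param tbl A table returned by [simulate_sites()].
#' @param path Output JSON path.
#' @return `truth_bundle()`: the truth list. `write_truth_bundle()`:
#'   `path`, invisibly.
#' @export
truth_bundle <- function(tbl) {
  tr <- attr(tbl, "truth")
  if (is.null(tr)) abort("table carries no truth bundle; was it simulated?")
  tr
}

#' @rdname truth_bundle
#' @export
write_truth_bundle <- function(tbl, path) {
  tr <- truth_bundle(tbl)
  tr$scenario <- unclass(tr$scenario)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score an estimate against a truth bundle
#'
#' Root-mean-square error of per-site estimates against the generating
#' latent rates (`psi` for the basic family, `lambda` for Royle-Nichols).
#'
#' @param tbl A simulated site table.
#' @param estimate Per-site estimates.
#' @return RMSE as a single number.
#' @export
score_against_truth <- function(tbl, estimate) {
  tr <- truth_bundle(tbl)
  target <- tr$psi %||% tr$lambda
  if (length(estimate) != length(target)) abort("estimate length mismatch")
  sqrt(mean((estimate - target)^2))
}
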