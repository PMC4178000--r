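# shared fixtures: everything is built in code at test time

# a tiny hand-specified site table (3 rows, both years, all level types)
tiny_table <- function() {
  tibble::tibble(
    site_id = c("a", "b", "c"),
    year = c(2010L, 2011L, 2010L),
    chevron_count = c(3L, 0L, 0L),
    camera_snapshot_hits = c(0L, 14L, 0L),
    depth_m = c(20, 40, 60),
    lat_deg = c(27.5, 29.5, 31.5),
    temp_c = c(24, 22, 20),
    livebot = c("l", "m", "h"),
    hardsub = c("h", "m", "l"),
    relief = c("l", "m", "h"),
    soak_min = c(80, 90, 100),
    cdir = c("toward", "perpendicular", "away"),
    cspeed = c("low", "high", "low"),
    turb = c("low", "high", "low"))
}

# detection data built directly from vectors (bypasses the site table)
make_detection <- function(y1, y2, k2 = 1L,
                           camera_mode = if (k2 == 1L) "pooled" else "disaggregated") {
  structure(list(y = cbind(chevron = as.integer(y1), camera = as.integer(y2)),
                 k = c(chevron = 1L, camera = as.integer(k2)),
                 camera_mode = camera_mode),
            class = "occugear_detection")
}

# parameter list in the likelihood functions' shape, defaults intercept-only
make_params <- function(design, beta0 = 0, alpha0 = 0, phi0 = 0,
                        beta = NULL, alpha = NULL, phi = NULL, eps = 0) {
  np <- function(X) ncol(X)
  list(beta = c(beta0, beta %||% numeric(np(design$X_occ))),
       alpha = c(alpha0, alpha %||% numeric(np(design$X_chev))),
       phi = c(phi0, phi %||% numeric(np(design$X_cam))),
       w_occ = rep(1, np(design$X_occ)),
       w_chev = rep(1, np(design$X_chev)),
       w_cam = rep(1, np(design$X_cam)),
       eps = eps)
}

quick_settings <- function(seed = 1, n_iter = 3000, burn_in = 600, n_chains = 2) {
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                thin = 1, seed = seed)
}

intercept_design <- function(S) occugear:::intercept_only_design(S)
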