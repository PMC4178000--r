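# A synthetic stand-in for the red snapper study's site table. The real
# per-site records are not redistributed with this package, so analyses
# that need study-like data use this emulation instead. It is moment-
# matched to the study's published observable summaries rather than being
# a draw from a fitted model:
#
#   * naive detection rates pinned exactly at 0.14 (chevron) and 0.31
#     (camera) by quota assignment of detections among occupied sites;
#   * a both-gear overlap rate (0.106) equal to the product implied by a
#     camera detection probability of ~0.757, the published estimate --
#     which, through the two-gear occupancy identity, implies occupancy
#     ~0.41 and chevron detection ~0.34;
#   * occupancy structured by depth and latitude (linear + quadratic) at
#     the published conditional effect sizes, detections unstructured.

#' Synthetic emulation of the study's site table
#'
#' Builds a deterministic, synthetic 500-site two-gear table that mimics
#' the reef-fish trap/camera survey: covariates drawn from the survey's
#' ranges, occupancy driven by depth and a quadratic latitude effect, and
#' detection histories whose naive rates and two-gear overlap match the
#' published observed rates exactly (0.14 chevron, 0.31 camera). This is
#' **synthetic** data: a stand-in with the study's summary statistics, not
#' the study's records.
#'
#' @param S Number of sites.
#' @param seed Integer seed; the default gives the canonical table.
#' @return A validated site table with a `"truth"` attribute holding the
#'   calibration targets.
#' @export
synthetic_study_table <- function(S = 500, seed = 101) {
  naive_chev <- 0.14
  naive_cam <- 0.31
  p_cam <- 0.757                    # published camera detection estimate
  overlap <- naive_chev * p_cam     # P(both gears detect)
  mean_psi <- naive_chev * naive_cam / overlap   # two-gear identity: ~0.409

  scenario <- sim_scenario(S = S, family = "basic", seed = seed)
  tbl <- generate_covariates(scenario)
  design <- build_design_matrices(tbl)
  # conditional (given-inclusion) published effect sizes
  slopes <- c(depth = -0.38, lat = -0.42, lat2 = -0.425)
  lp0 <- drop(design$X_occ[, names(slopes)] %*% slopes)
  intercept <- stats::uniroot(
    function(c0) mean(inv_logit(c0 + lp0)) - mean_psi, c(-4, 4),
    tol = 1e-10)$root
  psi <- inv_logit(intercept + lp0)

  z <- as.integer(runif(S) < psi)
  n_both <- round(S * overlap)
  n_chev_only <- round(S * naive_chev) - n_both
  n_cam_only <- round(S * naive_cam) - n_both
  need <- n_both + n_chev_only + n_cam_only
  occ <- which(z == 1)
  if (length(occ) < need) {
    # top up occupancy from the highest-psi unoccupied sites
    extra <- order(psi * (z == 0), decreasing = TRUE)[seq_len(need - length(occ))]
    z[extra] <- 1L
    occ <- which(z == 1)
  }
  picked <- sample(occ, need)
  both <- picked[seq_len(n_both)]
  chev_only <- picked[n_both + seq_len(n_chev_only)]
  cam_only <- picked[n_both + n_chev_only + seq_len(n_cam_only)]

  chev_det <- sort(c(both, chev_only))
  cam_det <- sort(c(both, cam_only))
  chevron_count <- integer(S)
  chevron_count[chev_det] <- pmin(1L + rpois(length(chev_det), 0.8), 13L)
  hits <- integer(S)
  hits[cam_det] <- pmin(1L + rpois(length(cam_det), 4), 14L)

  tbl$chevron_count <- chevron_count
  tbl$camera_snapshot_hits <- hits
  tbl <- validate_site_table(tbl)
  attr(tbl, "truth") <- list(
    synthetic = TRUE, mean_psi = mean_psi,
    p_chevron = naive_chev / mean_psi, p_camera = p_cam,
    slopes = slopes, intercept = intercept, z = z)
  tbl
}
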