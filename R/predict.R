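# Posterior predictions over covariate grids, and gear-level detection
# summaries. All predictions are made per retained draw with the
# model-averaged (w * beta) coefficients, then summarized pointwise, so
# credible bands reflect both coefficient and model-selection uncertainty.

default_grid <- function(fit, covariate, n = 50) {
  sc <- fit$design$scaling[[covariate]]
  lo <- sc$center - 2.5 * sc$scale
  hi <- sc$center + 2.5 * sc$scale
  seq(lo, hi, length.out = n)
}

# standardized occupancy design row(s) for grid predictions: everything at
# reference (0 for standardized continuous covariates, reference category
# for dummies, year 2010), focal covariate(s) moving with their quadratic
# partners
reference_X_occ <- function(fit, n) {
  X <- matrix(0, n, length(occ_columns))
  colnames(X) <- occ_columns
  # squared columns at reference: the square of the standardized base (0 or
  # the raw-square), re-standardized -- not zero
  for (nm in c("depth", "lat", "temp")) {
    sq <- fit$design$scaling[[paste0(nm, "2")]]
    base_ref <- if (fit$design$square_terms == "scaled") 0
                else fit$design$scaling[[nm]]$center^2
    X[, paste0(nm, "2")] <- (base_ref - sq$center) / sq$scale
  }
  X
}

set_focal <- function(fit, X, covariate, values) {
  pair <- standardize_pair(fit$design, covariate, values)
  X[, covariate] <- pair$base
  if (!is.null(pair$square)) X[, paste0(covariate, "2")] <- pair$square
  X
}

grid_guard <- function(fit, covariate, values, extrapolate) {
  sc <- fit$design$scaling[[covariate]]
  z <- abs(values - sc$center) / sc$scale
  if (!extrapolate && any(z > 4)) {
    abort(paste0("grid for '", covariate, "' extends more than 4 SD beyond ",
                 "the training data; pass extrapolate = TRUE to override"))
  }
}

summarize_grid_draws <- function(lp_draws, family) {
  vals <- if (family == "basic") inv_logit(lp_draws) else exp(lp_draws)
  tibble::tibble(
    mean = colMeans(vals),
    lower = apply(vals, 2, quantile, 0.025, names = FALSE),
    upper = apply(vals, 2, quantile, 0.975, names = FALSE))
}

occ_lp_draws <- function(fit, X) {
  d <- effective_draws(fit)
  B <- as.matrix(d[, paste0("occ_", occ_columns), drop = FALSE])
  d$occ_intercept + B %*% t(X)
}

#' Posterior prediction curve along one covariate
#'
#' Evaluates occupancy probability (basic family) or mean site abundance
#' (Royle-Nichols) over a grid of one continuous covariate, holding all
#' other covariates at reference: continuous at their training mean,
#' categorical at reference levels, year 2010. The quadratic partner of the
#' focal covariate (e.g. `lat2` with `lat`) moves coherently with it, using
#' the training standardization of the squared column.
#'
#' @param fit An `occugear_fit`.
#' @param covariate `"depth"`, `"lat"`, `"temp"` or `"soak"` (distribution
#'   sub-model covariates: the first three).
#' @param grid Raw-scale grid values; default spans the training range.
#' @param extrapolate Allow the grid beyond 4 SD from the training mean.
#' @return An `occugear_prediction` tibble: the grid column plus `mean`,
#'   `lower`, `upper` (posterior mean and 95% credible bounds).
#' @export
predict_curve <- function(fit, covariate = c("depth", "lat", "temp"),
                          grid = NULL, extrapolate = FALSE) {
  covariate <- match.arg(covariate)
  grid <- grid %||% default_grid(fit, covariate)
  grid_guard(fit, covariate, grid, extrapolate)
  X <- set_focal(fit, reference_X_occ(fit, length(grid)), covariate, grid)
  out <- summarize_grid_draws(occ_lp_draws(fit, X), fit$spec$family)
  out <- dplyr::bind_cols(tibble::tibble(!!covariate := grid), out)
  attr(out, "family") <- fit$spec$family
  attr(out, "covariate") <- covariate
  class(out) <- c("occugear_prediction", class(out))
  out
}

#' Posterior prediction surface over depth and latitude
#'
#' Outer-product version of [predict_curve()]: occupancy or abundance over
#' a depth-by-latitude grid, other covariates at reference.
#'
#' @param fit An `occugear_fit`.
#' @param depth_grid,lat_grid Raw-scale grid axes.
#' @param extrapolate Allow grids beyond 4 SD from the training mean.
#' @return An `occugear_prediction` tibble with `depth`, `lat`, `mean`,
#'   `lower`, `upper`.
#' @export
predict_surface <- function(fit, depth_grid = NULL, lat_grid = NULL,
                            extrapolate = FALSE) {
  depth_grid <- depth_grid %||% default_grid(fit, "depth", n = 25)
  lat_grid <- lat_grid %||% default_grid(fit, "lat", n = 25)
  grid_guard(fit, "depth", depth_grid, extrapolate)
  grid_guard(fit, "lat", lat_grid, extrapolate)
  cells <- tidyr::expand_grid(depth = depth_grid, lat = lat_grid)
  X <- reference_X_occ(fit, nrow(cells))
  X <- set_focal(fit, X, "depth", cells$depth)
  X <- set_focal(fit, X, "lat", cells$lat)
  out <- dplyr::bind_cols(cells,
                          summarize_grid_draws(occ_lp_draws(fit, X),
                                               fit$spec$family))
  attr(out, "family") <- fit$spec$family
  attr(out, "covariate") <- c("depth", "lat")
  class(out) <- c("occugear_prediction", class(out))
  out
}

#' Gear-level detection summaries at reference covariates
#'
#' Posterior of each gear's detection probability at the reference
#' covariate values (the inverse-logit of the intercept draws; species
#' detection `p` for the basic family, individual detection `r` for
#' Royle-Nichols), plus camera contrasts: the per-draw difference in
#' detection between high turbidity and reference, and between
#' current-away and reference.
#'
#' @param fit An `occugear_fit`.
#' @return A tibble with `quantity`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
detection_summary <- function(fit) {
  d <- effective_draws(fit)
  p_chev <- inv_logit(d$chev_intercept)
  p_cam <- inv_logit(d$cam_intercept)
  contrast <- function(term) {
    inv_logit(d$cam_intercept + d[[paste0("cam_", term)]]) - p_cam
  }
  draws <- list(p_chevron = p_chev, p_camera = p_cam,
                camera_contrast_turb.h = contrast("turb.h"),
                camera_contrast_cdir.a = contrast("cdir.a"))
  purrr::imap_dfr(draws, function(v, nm) {
    qs <- quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(quantity = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = qs[1], conf.high = qs[2])
  })
}

#' Export a prediction grid to CSV
#'
#' @param pred An `occugear_prediction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(pred, path) {
  readr::write_csv(tibble::as_tibble(pred), path, progress = FALSE)
  invisible(path)
}

#' Plot a prediction curve or surface
#'
#' Curves get a posterior-mean line with a 95% credible ribbon; surfaces a
#' filled raster of the posterior mean.
#'
#' @param object An `occugear_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occugear_prediction <- function(object, ...) {
  fam <- attr(object, "family")
  ylab <- if (identical(fam, "basic")) "Occupancy probability"
          else "Mean site abundance"
  covs <- attr(object, "covariate")
  if (length(covs) == 1) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[covs]])) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), alpha = 0.25) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
      ggplot2::labs(x = covs, y = ylab) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$lat, y = .data$depth,
                                         fill = .data$mean)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(x = "Latitude (deg N)", y = "Depth (m)", fill = ylab) +
      ggplot2::theme_minimal()
  }
}

#' Plot gear-level detection summaries
#'
#' @param fit An `occugear_fit`.
#' @return A ggplot object with posterior means and 95% intervals per gear.
#' @export
plot_detection <- function(fit) {
  ds <- detection_summary(fit)
  ds <- ds[ds$quantity %in% c("p_chevron", "p_camera"), ]
  ggplot2::ggplot(ds, ggplot2::aes(x = .data$quantity, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_x_discrete(labels = c(p_camera = "camera",
                                         p_chevron = "chevron")) +
    ggplot2::labs(x = "Gear", y = "Detection probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
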