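# build a small fitted object whose draws are set by hand, so prediction
# behavior can be checked against closed forms
handmade_fit <- function(tbl, draws_mod = identity, family = "basic") {
  spec <- model_spec(family, "pooled")
  fit <- fit_occupancy(tbl, spec,
                       settings = quick_settings(seed = 51, n_iter = 400,
                                                 burn_in = 100))
  fit$draws <- draws_mod(fit$draws)
  fit
}

constant_draws <- function(draws, values = list()) {
  for (nm in setdiff(names(draws), c("chain", "iter"))) {
    draws[[nm]] <- values[[nm]] %||% 0
  }
  # all indicators on so effective coefficients equal the raw columns
  for (nm in names(draws)[startsWith(names(draws), "w_")]) draws[[nm]] <- 1
  draws
}

test_that("constant draws give flat zero-width bands at the intercept value", {
  tbl <- simulate_sites(sim_scenario(S = 60, seed = 50))
  fit <- handmade_fit(tbl, function(d)
    constant_draws(d, list(occ_intercept = logit(0.37))))
  pred <- predict_curve(fit, "depth")
  expect_true(all(abs(pred$mean - 0.37) < 1e-10))
  expect_true(all(pred$upper - pred$lower < 1e-10))
})

test_that("a negative depth coefficient yields a strictly decreasing curve", {
  tbl <- simulate_sites(sim_scenario(S = 60, seed = 50))
  fit <- handmade_fit(tbl, function(d)
    constant_draws(d, list(occ_intercept = 0.2, occ_depth = -0.8)))
  pred <- predict_curve(fit, "depth")
  expect_true(all(diff(pred$mean) < 0))
  expect_true(all(pred$mean >= 0 & pred$mean <= 1))
})

test_that("negative-curvature latitude draws produce an interior maximum", {
  tbl <- simulate_sites(sim_scenario(S = 120, seed = 52))
  fit <- handmade_fit(tbl, function(d)
    constant_draws(d, list(occ_intercept = -0.2, occ_lat = 0.3,
                           occ_lat2 = -0.9)))
  grid <- seq(min(tbl$lat_deg), max(tbl$lat_deg), length.out = 61)
  pred <- predict_curve(fit, "lat", grid = grid)
  peak <- which.max(pred$mean)
  expect_gt(peak, 1)
  expect_lt(peak, length(grid))
  # the peak location matches the vertex computed from the coefficients
  # and the stored standardization of lat and lat2
  sc <- fit$design$scaling
  zgrid <- (grid - sc$lat$center) / sc$lat$scale
  q <- (zgrid^2 - sc$lat2$center) / sc$lat2$scale
  lp <- -0.2 + 0.3 * zgrid - 0.9 * q
  expect_equal(peak, which.max(lp))
})

test_that("surfaces agree with pointwise curve evaluation", {
  tbl <- simulate_sites(sim_scenario(S = 80, seed = 53))
  fit <- handmade_fit(tbl, function(d)
    constant_draws(d, list(occ_intercept = 0.1, occ_depth = -0.6,
                           occ_lat = 0.2, occ_lat2 = -0.5)))
  surf <- predict_surface(fit, depth_grid = c(20, 40, 60),
                          lat_grid = c(28, 29.5, 31))
  expect_equal(nrow(surf), 9)
  expect_true(all(surf$lower <= surf$mean & surf$mean <= surf$upper))
  # oracle re-evaluation at three grid points
  sc <- fit$design$scaling
  for (row in c(1, 5, 9)) {
    zd <- (surf$depth[row] - sc$depth$center) / sc$depth$scale
    zl <- (surf$lat[row] - sc$lat$center) / sc$lat$scale
    qd <- (zd^2 - sc$depth2$center) / sc$depth2$scale
    ql <- (zl^2 - sc$lat2$center) / sc$lat2$scale
    want <- inv_logit(0.1 - 0.6 * zd + 0 * qd + 0.2 * zl - 0.5 * ql)
    expect_equal(surf$mean[row], unname(want), tolerance = 1e-10)
  }
})

test_that("predictions are invariant to the raw units of the covariate", {
  set.seed(54)
  tbl <- simulate_sites(sim_scenario(S = 100, seed = 54))
  tbl_ft <- tbl
  tbl_ft$depth_m <- tbl$depth_m * 3.28084   # refit scaling in feet
  st <- quick_settings(seed = 55, n_iter = 1200, burn_in = 300)
  fit_m <- fit_occupancy(tbl, model_spec("basic", "pooled"), settings = st)
  fit_ft <- fit_occupancy(tbl_ft, model_spec("basic", "pooled"),
                          settings = st)
  # identical standardized designs -> identical draws
  expect_equal(fit_m$draws, fit_ft$draws, tolerance = 1e-12)
  grid_m <- seq(20, 70, length.out = 11)
  pm <- predict_curve(fit_m, "depth", grid = grid_m)
  pf <- predict_curve(fit_ft, "depth", grid = grid_m * 3.28084)
  expect_equal(pm$mean, pf$mean, tolerance = 1e-10)
  expect_equal(pm$lower, pf$lower, tolerance = 1e-10)
})

test_that("extrapolation is guarded and detection summaries match closed forms", {
  tbl <- simulate_sites(sim_scenario(S = 60, seed = 56))
  fit <- handmade_fit(tbl, function(d)
    constant_draws(d, list(chev_intercept = logit(0.39),
                           cam_intercept = logit(0.75))))
  expect_error(predict_curve(fit, "depth", grid = c(10, 500)), "extrapolate")
  expect_silent(predict_curve(fit, "depth", grid = c(10, 500),
                              extrapolate = TRUE))

  ds <- detection_summary(fit)
  expect_equal(ds$estimate[ds$quantity == "p_chevron"], 0.39,
               tolerance = 1e-10)
  expect_equal(ds$estimate[ds$quantity == "p_camera"], 0.75,
               tolerance = 1e-10)
  # zero coefficient draws give zero contrasts
  expect_equal(ds$estimate[grepl("contrast", ds$quantity)], c(0, 0),
               tolerance = 1e-12)

  p <- autoplot(predict_curve(fit, "depth"))
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(predict_surface(fit)), "ggplot")
  expect_s3_class(plot_detection(fit), "ggplot")
})
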