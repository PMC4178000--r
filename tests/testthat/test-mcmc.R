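test_that("sampling is deterministic given a seed and validates its inputs", {
  tbl <- simulate_sites(sim_scenario(S = 40, seed = 15))
  st <- quick_settings(seed = 2, n_iter = 800, burn_in = 200)
  f1 <- fit_occupancy(tbl, model_spec("basic", "pooled"), settings = st)
  f2 <- fit_occupancy(tbl, model_spec("basic", "pooled"), settings = st)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_occupancy(tbl, model_spec("basic", "pooled"),
                      settings = quick_settings(seed = 3, n_iter = 800,
                                                burn_in = 200))
  expect_false(identical(f1$draws$occ_intercept, f3$draws$occ_intercept))

  expect_error(model_spec("basic", "pooled", random_effect = TRUE),
               "disaggregated")
  det <- build_detection_data(tbl, "pooled")
  des <- build_design_matrices(tbl)
  expect_error(sample_posterior(det, des,
                                model_spec("basic", "disaggregated"),
                                settings = st), "camera_mode")
})

test_that("posterior on a no-covariate toy matches dense grid enumeration", {
  # 30 sites with fixed two-gear pattern counts (11, 10, 01, 00)
  y1 <- rep(c(1, 1, 0, 0), c(4, 2, 7, 17))
  y2 <- rep(c(1, 0, 1, 0), c(4, 2, 7, 17))
  det <- make_detection(y1, y2)
  des <- intercept_design(30)
  draws <- sample_posterior(det, des, model_spec("basic", "pooled"),
                            settings = mcmc_settings(n_chains = 3,
                                                     n_iter = 12000,
                                                     burn_in = 2000,
                                                     thin = 1, seed = 3))
  got <- c(psi = mean(inv_logit(draws$occ_intercept)),
           p1 = mean(inv_logit(draws$chev_intercept)),
           p2 = mean(inv_logit(draws$cam_intercept)))

  g <- seq(-7, 7, length.out = 113)
  lt <- function(x) stats::dt(x / 1.566, df = 7.763, log = TRUE)
  G <- expand.grid(a = g, b = g, c = g)
  psi <- inv_logit(G$a); p1 <- inv_logit(G$b); p2 <- inv_logit(G$c)
  ll <- 4 * log(psi * p1 * p2) + 2 * log(psi * p1 * (1 - p2)) +
    7 * log(psi * (1 - p1) * p2) +
    17 * log(psi * (1 - p1) * (1 - p2) + 1 - psi) +
    lt(G$a) + lt(G$b) + lt(G$c)
  w <- exp(ll - max(ll)); w <- w / sum(w)
  want <- c(psi = sum(w * psi), p1 = sum(w * p1), p2 = sum(w * p2))
  expect_equal(got, want, tolerance = 0.02)
})

test_that("a prior-only run recovers the prior", {
  # no sites: the posterior is the prior
  des <- intercept_design(0)
  det <- make_detection(integer(0), integer(0))
  draws <- sample_posterior(det, des, model_spec("basic", "pooled"),
                            settings = mcmc_settings(n_chains = 2,
                                                     n_iter = 60000,
                                                     burn_in = 5000,
                                                     thin = 10, seed = 4))
  # back-transformed intercept approximately uniform on (0, 1)
  u <- inv_logit(draws$occ_intercept)
  d_stat <- suppressWarnings(stats::ks.test(u, "punif")$statistic)
  expect_lt(unname(d_stat), 0.05)
  expect_equal(mean(u), 0.5, tolerance = 0.03)

  # with covariates present, indicator means sit at the 0.5 prior
  des2 <- intercept_design(0)
  des2$X_occ <- matrix(numeric(0), 0, 2,
                       dimnames = list(NULL, c("x1", "x2")))
  draws2 <- sample_posterior(det, des2, model_spec("basic", "pooled"),
                             settings = mcmc_settings(n_chains = 2,
                                                      n_iter = 20000,
                                                      burn_in = 2000,
                                                      thin = 4, seed = 5))
  expect_equal(mean(draws2$w_occ_x1), 0.5, tolerance = 0.03)
  expect_equal(mean(draws2$w_occ_x2), 0.5, tolerance = 0.03)
})

test_that("gelman_rubin flags non-convergence and passes clean chains", {
  fake <- function(ch1, ch2) {
    tibble::tibble(chain = rep(1:2, each = length(ch1)),
                   iter = rep(seq_along(ch1), 2),
                   theta = c(ch1, ch2))
  }
  set.seed(6)
  clean <- fake(rnorm(400), rnorm(400))
  expect_lt(gelman_rubin(clean)$rhat[gelman_rubin(clean)$term == "theta"], 1.1)
  apart <- fake(rnorm(400, -5), rnorm(400, 5))
  expect_gt(gelman_rubin(apart)$rhat[1], 2)
  x <- rnorm(400)
  dup <- fake(x, x)
  expect_lte(gelman_rubin(dup)$rhat[1], 1.01)
  expect_error(gelman_rubin(dplyr::filter(clean, chain == 1)), "2 chains")
})

test_that("credible intervals tighten as the number of sites grows", {
  width <- function(S) {
    tbl <- simulate_sites(sim_scenario(S = S, seed = 16))
    fit <- fit_occupancy(tbl, model_spec("basic", "pooled"),
                         settings = quick_settings(seed = 17, n_iter = 2500,
                                                   burn_in = 500))
    g <- glance(fit)
    g$conf.high - g$conf.low
  }
  expect_lt(width(800), width(100))
})

test_that("fit summaries expose the Tables-style layout", {
  tbl <- simulate_sites(sim_scenario(S = 80, seed = 18))
  fit <- fit_occupancy(tbl, model_spec("basic", "pooled"),
                       settings = quick_settings(seed = 19, n_iter = 1500,
                                                 burn_in = 300))
  td <- tidy(fit)
  expect_equal(nrow(td), (1 + 15) + (1 + 6) + (1 + 4))
  expect_true(all(c("estimate", "std.error", "conf.low", "conf.high",
                    "inclusion_prob") %in% names(td)))
  expect_true(all(td$conf.low <= td$conf.high))
  expect_true(all(is.na(td$inclusion_prob[td$term == "intercept"])))
  ip <- td$inclusion_prob[!is.na(td$inclusion_prob)]
  expect_true(all(ip >= 0 & ip <= 1))

  # conditional averaging only differs where exclusion happens
  tdc <- tidy(fit, average = "conditional")
  expect_true(all(abs(tdc$estimate) >= abs(td$estimate) - 1e-9))

  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_summary(fit, path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), nrow(td))

  au <- augment(fit)
  expect_equal(nrow(au), 80)
  expect_true(all(au$.lower <= au$.fitted & au$.fitted <= au$.upper))
  expect_true(all(au$.fitted >= 0 & au$.fitted <= 1))

  g <- glance(fit)
  expect_true(g$conf.low <= g$estimate && g$estimate <= g$conf.high)
  expect_true(all(dplyr::between(
    inclusion_probabilities(fit)$inclusion_prob, 0, 1)))
})
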