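test_that("history cell probabilities sum to one and match enumeration", {
  des <- intercept_design(3)
  spec <- model_spec("basic", "pooled")
  # psi = 1, p = (0.5, 0.5): uniform over the four histories
  par <- make_params(des, beta0 = 60, alpha0 = 0, phi0 = 0)
  cells <- history_cell_probs(par, spec, des)
  expect_equal(unname(cells[1, ]), rep(0.25, 4), tolerance = 1e-10)
  # psi = 0: all mass on the all-zero history
  par0 <- make_params(des, beta0 = -60, alpha0 = 0, phi0 = 0)
  cells0 <- history_cell_probs(par0, spec, des)
  expect_equal(unname(cells0[2, "0:0"]), 1, tolerance = 1e-10)

  # random basic / RN cases match brute-force enumeration and sum to 1
  set.seed(41)
  for (family in c("basic", "royle_nichols")) {
    sp <- model_spec(family, "disaggregated")
    par_r <- make_params(des, beta0 = rnorm(1, 0, 0.5),
                         alpha0 = rnorm(1), phi0 = rnorm(1))
    cells_r <- history_cell_probs(par_r, sp, des, N_max = 300)
    expect_equal(unname(rowSums(cells_r)), rep(1, 3), tolerance = 1e-8)
    y2 <- 3
    if (family == "basic") {
      psi <- inv_logit(par_r$beta[1])
      p1 <- inv_logit(par_r$alpha[1]); p2 <- inv_logit(par_r$phi[1])
      want <- psi * stats::dbinom(1, 1, p1) * stats::dbinom(y2, 41, p2)
    } else {
      lam <- exp(par_r$beta[1])
      r1 <- inv_logit(par_r$alpha[1]); r2 <- inv_logit(par_r$phi[1])
      Ns <- 0:300
      want <- sum(stats::dpois(Ns, lam) *
        stats::dbinom(1, 1, 1 - (1 - r1)^Ns) *
        stats::dbinom(y2, 41, 1 - (1 - r2)^Ns))
    }
    expect_equal(unname(cells_r[1, paste0("1:", y2)]), want,
                 tolerance = 1e-8)
  }
})

test_that("the chi-square statistic matches hand arithmetic and is permutation invariant", {
  spec <- model_spec("basic", "pooled")
  des <- intercept_design(2)
  par <- make_params(des, beta0 = logit(0.5), alpha0 = logit(0.4),
                     phi0 = logit(0.6))
  E <- history_cell_probs(par, spec, des)
  det <- make_detection(c(1, 0), c(1, 0))
  # hand computation: each site contributes sum over 4 cells
  O1 <- c("0:0" = 0, "1:0" = 0, "0:1" = 0, "1:1" = 1)
  O2 <- c("0:0" = 1, "1:0" = 0, "0:1" = 0, "1:1" = 0)
  hand <- sum((O1 - E[1, names(O1)])^2 / E[1, names(O1)]) +
    sum((O2 - E[2, names(O2)])^2 / E[2, names(O2)])
  expect_equal(chisq_stat(det, E, spec), hand, tolerance = 1e-12)

  # data exactly at expectation in a two-site toy gives zero
  spec_d <- model_spec("basic", "pooled")
  # with indicator observations the statistic vanishes exactly when each
  # site's observed cell carries probability one
  E_point <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0), 2, 4, byrow = TRUE,
                    dimnames = list(NULL, c("0:0", "1:0", "0:1", "1:1")))
  det00 <- make_detection(c(0, 0), c(0, 0))
  expect_equal(chisq_stat(det00, E_point, spec_d), 0)

  # site order does not change the statistic
  sim <- simulate_sites(sim_scenario(S = 25, seed = 42))
  det_a <- build_detection_data(sim, "pooled")
  perm <- sample(25)
  det_b <- det_a; det_b$y <- det_a$y[perm, ]
  E_a <- history_cell_probs(
    make_params(intercept_design(25), beta0 = 0.2, alpha0 = -0.4,
                phi0 = 0.9), spec, intercept_design(25))
  expect_equal(chisq_stat(det_a, E_a, spec), chisq_stat(det_b, E_a, spec))
})

test_that("disaggregated camera cells are pooled to the expected floor", {
  counts <- c(50, 10, 3, 1, 0.5, 0.3, 0.1, 0.1)
  bins <- occugear:::camera_count_bins(counts, min_expected = 2)
  expect_equal(length(bins), length(counts))
  # merged-from-the-tail: aggregate expected per bin reaches the floor
  agg <- tapply(counts, bins, sum)
  expect_true(all(agg >= 2))
  # low counts keep their own bins
  expect_equal(bins[1], 1)
  expect_equal(bins[2], 2)
})

test_that("the bootstrap p-value matches its definition and contracts hold", {
  tbl <- simulate_sites(sim_scenario(S = 80, seed = 43))
  fit <- fit_occupancy(tbl, model_spec("basic", "pooled"),
                       settings = quick_settings(seed = 44, n_iter = 1500,
                                                 burn_in = 300))
  g <- gof_test(fit, n_boot = 60, seed = 45)
  expect_equal(g$gof_p, mean(g$boot_stats >= g$observed_stat))
  expect_equal(g$gof_p,
               1 - stats::ecdf(g$boot_stats)(g$observed_stat),
               tolerance = 1 / 60 + 1e-9)
  expect_true(g$gof_p >= 0 && g$gof_p <= 1)
  expect_length(g$boot_stats, 60)
  expect_error(gof_test(fit, n_boot = 0), "at least 1")

  # identical seed reproduces the bootstrap
  g2 <- gof_test(fit, n_boot = 60, seed = 45)
  expect_identical(g$boot_stats, g2$boot_stats)

  path <- withr::local_tempfile(fileext = ".json")
  write_gof(g, path)
  expect_equal(jsonlite::read_json(path)$gof_p, g$gof_p)
})
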