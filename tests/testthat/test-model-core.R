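test_that("link functions and masked linear predictors behave", {
  expect_equal(inv_logit(0), 0.5)
  expect_equal(inv_logit(logit(0.3)), 0.3)
  xs <- seq(-30, 30, by = 2.5)
  expect_equal(inv_logit(xs), 1 - inv_logit(-xs), tolerance = 1e-12)
  expect_true(all(inv_logit(c(-750, 750)) >= 0 & inv_logit(c(-750, 750)) <= 1))

  # masked predictor matches a brute-force loop oracle on random inputs
  set.seed(11)
  for (rep in 1:5) {
    S <- 7; P <- 4
    X <- matrix(rnorm(S * P), S, P)
    beta <- rnorm(P + 1)
    w <- rbinom(P, 1, 0.5)
    loop <- vapply(seq_len(S), function(i)
      1 / (1 + exp(-(beta[1] + sum(w * beta[-1] * X[i, ])))), numeric(1))
    expect_equal(occupancy_prob(beta, w, X), loop, tolerance = 1e-12)
    expect_equal(detection_prob_chevron(beta[1:(P + 1)], w, X), loop,
                 tolerance = 1e-12)
  }
  # intercept never masked; all-zero mask gives a constant
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(occupancy_prob(c(0.4, 1, 2, 3), c(0, 0, 0), X),
               rep(inv_logit(0.4), 4))
  expect_error(occupancy_prob(c(0, 1), c(1, 1), X), "length")
})

test_that("abundance-detection identity and its inverse match the closed forms", {
  expect_equal(species_detection_from_individual(0.5, 2), 0.75)
  expect_equal(species_detection_from_individual(0.3, 0), 0)
  expect_true(species_detection_from_individual(0.61, 4) > 0.95)
  expect_error(species_detection_from_individual(1.2, 1), "\\[0, 1\\]")

  # published camera / chevron thresholds
  expect_equal(min_abundance_for_detection(0.61, 0.95), 4L)
  expect_equal(min_abundance_for_detection(0.30, 0.95), 9L)
  expect_equal(min_abundance_for_detection(0.999, 0.95), 1L)
  expect_error(min_abundance_for_detection(0, 0.95), "never")

  # monotonicity: nondecreasing in r and N; threshold nonincreasing in r
  rs <- seq(0.05, 0.95, by = 0.1)
  for (N in c(1, 3, 8)) {
    expect_true(all(diff(species_detection_from_individual(rs, N)) >= 0))
  }
  expect_true(all(diff(species_detection_from_individual(0.35, 0:12)) >= 0))
  expect_true(all(diff(min_abundance_for_detection(rs, 0.95)) <= 0))
  # the returned N is minimal: N-1 misses the threshold
  for (r in rs) {
    n <- min_abundance_for_detection(r, 0.9)
    expect_gte(species_detection_from_individual(r, n), 0.9)
    if (n > 1) expect_lt(species_detection_from_individual(r, n - 1), 0.9)
  }
})

test_that("basic site likelihoods match direct binomial computation", {
  des <- intercept_design(2)
  det <- make_detection(y1 = c(0, 1), y2 = c(0, 1))
  par <- make_params(des, beta0 = logit(0.5), alpha0 = logit(0.3),
                     phi0 = logit(0.7))
  # z = 0: all-zero history certain, any detection impossible
  expect_equal(site_loglik_basic(par, det, des, 1, z = 0), 0)
  expect_identical(site_loglik_basic(par, det, des, 2, z = 0), -Inf)
  # z = 1 matches hand-rolled pmf products
  expect_equal(site_loglik_basic(par, det, des, 2, z = 1),
               log(0.3) + log(0.7))
  expect_equal(site_loglik_basic(par, det, des, 1, z = 1),
               log(0.7) + log(0.3))

  # marginal equals logsumexp over the two z branches (random cases, k2=41)
  set.seed(21)
  for (rep in 1:10) {
    y2 <- sample(0:41, 1)
    det1 <- make_detection(y1 = sample(0:1, 1), y2 = y2, k2 = 41L)
    par1 <- make_params(intercept_design(1), beta0 = rnorm(1),
                        alpha0 = rnorm(1), phi0 = rnorm(1))
    psi <- inv_logit(par1$beta[1])
    p1 <- inv_logit(par1$alpha[1]); p2 <- inv_logit(par1$phi[1])
    l1 <- stats::dbinom(unname(det1$y[1, 1]), 1, p1, log = TRUE) +
      stats::dbinom(unname(det1$y[1, 2]), 41, p2, log = TRUE)
    direct <- log(psi * exp(l1) +
                  (1 - psi) * all(det1$y[1, ] == 0))
    expect_equal(site_marginal_loglik_basic(par1, det1, intercept_design(1), 1),
                 direct, tolerance = 1e-10)
  }
  # psi = 1 degenerates to the conditional likelihood at z = 1
  par$beta[1] <- 50
  expect_equal(site_marginal_loglik_basic(par, det, des, 2),
               site_loglik_basic(par, det, des, 2, z = 1), tolerance = 1e-8)
})

test_that("RN marginal likelihood matches exhaustive latent enumeration", {
  des <- intercept_design(1)
  set.seed(31)
  for (rep in 1:10) {
    lam <- runif(1, 0.1, 3)
    r1 <- runif(1, 0.05, 0.9); r2 <- runif(1, 0.05, 0.9)
    y1 <- sample(0:1, 1); y2 <- sample(0:5, 1)
    det <- make_detection(y1, y2, k2 = 41L)
    par <- make_params(des, beta0 = log(lam), alpha0 = logit(r1),
                       phi0 = logit(r2))
    # independent exhaustive oracle with stats::dbinom / dpois
    Ns <- 0:400
    oracle <- log(sum(stats::dpois(Ns, lam) *
      stats::dbinom(y1, 1, 1 - (1 - r1)^Ns) *
      stats::dbinom(y2, 41, 1 - (1 - r2)^Ns)))
    expect_equal(site_marginal_loglik_rn(par, det, des, 1, N_max = 400),
                 oracle, tolerance = 1e-10)
    # truncation convergence: generous bounds agree
    expect_equal(site_marginal_loglik_rn(par, det, des, 1, N_max = 200),
                 site_marginal_loglik_rn(par, det, des, 1, N_max = 2000),
                 tolerance = 1e-10)
  }
  # empty site with tiny lambda: probability ~ 1
  det0 <- make_detection(0, 0, k2 = 41L)
  par0 <- make_params(des, beta0 = log(1e-8), alpha0 = 0, phi0 = 0)
  expect_equal(site_marginal_loglik_rn(par0, det0, des, 1), 0,
               tolerance = 1e-6)
  # r = 1: detection iff N >= 1, so y = (1,1) has probability P(N >= 1)
  det1 <- make_detection(1, 1, k2 = 1L)
  par1 <- make_params(des, beta0 = log(0.8), alpha0 = 40, phi0 = 40)
  expect_equal(site_marginal_loglik_rn(par1, det1, des, 1),
               stats::ppois(0, 0.8, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-6)
  # too-small N_max warns about unaccounted tail mass
  parbig <- make_params(des, beta0 = log(50), alpha0 = 0, phi0 = 0)
  expect_warning(site_marginal_loglik_rn(parbig, det0, des, 1, N_max = 60),
                 "tail mass")
})

test_that("RN marginal approaches Poisson-thinning basic likelihood for small r", {
  des <- intercept_design(1)
  # hold lambda * r fixed while r -> 0: the between-gear correlation induced
  # by shared N vanishes at rate lambda * r1 * r2
  for (lam in c(50, 200)) {
    r1 <- 0.05 / lam; r2 <- 0.10 / lam
    for (y in list(c(0, 0), c(1, 0), c(1, 1))) {
      det <- make_detection(y[1], y[2], k2 = 1L)
      par <- make_params(des, beta0 = log(lam), alpha0 = logit(r1),
                         phi0 = logit(r2))
      rn <- site_marginal_loglik_rn(par, det, des, 1, N_max = 800)
      p1 <- 1 - exp(-lam * r1); p2 <- 1 - exp(-lam * r2)
      thin <- stats::dbinom(y[1], 1, p1, log = TRUE) +
        stats::dbinom(y[2], 1, p2, log = TRUE)
      expect_equal(rn, thin, tolerance = max(0.03, 10 / lam))
    }
  }
})
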