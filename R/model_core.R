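# Pure model arithmetic shared by the sampler, the goodness-of-fit machinery
# and the prediction utilities. Everything here is vectorized, side-effect
# free, and computed in log space where underflow is a risk (41-replicate
# binomials).

#' Logit and inverse-logit links
#'
#' @param p A probability in `(0, 1)`.
#' @param x A real number.
#' @return `logit()` returns `log(p / (1 - p))`; `inv_logit()` returns
#'   `1 / (1 + exp(-x))`, computed stably for large `|x|`.
#' @export
logit <- function(p) log(p) - log1p(-p)

#' @rdname logit
#' @export
inv_logit <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# linear predictor with Kuo-Mallick inclusion mask: intercept + X %*% (w * b)
masked_lp <- function(intercept, beta, w, X) {
  if (length(beta) != ncol(X) || length(w) != ncol(X)) {
    abort("coefficient / inclusion-mask length must match the design matrix")
  }
  drop(intercept + X %*% (w * beta))
}

#' Occupancy (or mean-abundance) linear predictor on the probability scale
#'
#' Evaluates per-site occupancy probability `psi_i = inv_logit(b1 + sum_m
#' w_m b_m x_im)` under an inclusion mask `w`. The intercept is never
#' masked. For the Royle-Nichols family the same linear predictor feeds a
#' log link; use [abundance_rate()].
#'
#' @param beta Coefficient vector: intercept first, then one entry per
#'   design-matrix column.
#' @param w 0/1 inclusion mask, one entry per design-matrix column.
#' @param X_occ Site-by-covariate design matrix (no intercept column).
#' @return Vector of per-site probabilities.
#' @export
occupancy_prob <- function(beta, w, X_occ) {
  inv_logit(masked_lp(beta[1], beta[-1], w, X_occ))
}

#' @rdname occupancy_prob
#' @export
abundance_rate <- function(beta, w, X_occ) {
  exp(masked_lp(beta[1], beta[-1], w, X_occ))
}

#' Gear-specific detection probabilities
#'
#' Per-site detection probability (species-level `p` in the basic family,
#' individual-level `r` in the Royle-Nichols family) under an inclusion
#' mask. The camera variant accepts an optional site random effect `eps`
#' added inside the logit.
#'
#' @inheritParams occupancy_prob
#' @param alpha,phi Coefficient vectors (intercept first).
#' @param X_chev,X_cam Detection design matrices.
#' @param eps Per-site random effects (scalar 0 for none).
#' @return Vector of per-site probabilities.
#' @export
detection_prob_chevron <- function(alpha, w, X_chev) {
  inv_logit(masked_lp(alpha[1], alpha[-1], w, X_chev))
}

#' @rdname detection_prob_chevron
#' @export
detection_prob_camera <- function(phi, w, X_cam, eps = 0) {
  inv_logit(masked_lp(phi[1], phi[-1], w, X_cam) + eps)
}

#' Species detection probability from individual detection and abundance
#'
#' Under the Royle-Nichols assumption of independent individuals, a site
#' holding `N` individuals each detected with probability `r` yields a
#' species-level detection probability `p = 1 - (1 - r)^N`.
#'
#' @param r Individual detection probability in `[0, 1]`.
#' @param N Non-negative integer abundance.
#' @return `p = 1 - (1 - r)^N` (0 when `N = 0`).
#' @export
species_detection_from_individual <- function(r, N) {
  if (any(r < 0 | r > 1)) abort("r must lie in [0, 1]")
  if (any(N < 0 | N != round(N))) abort("N must be a non-negative integer")
  n <- max(length(r), length(N))
  r <- rep_len(r, n)
  N <- rep_len(N, n)
  out <- -expm1(N * log1p(-r))
  out[N == 0] <- 0                  # also covers the 0 * log(0) = NaN case
  out[r == 1 & N > 0] <- 1
  out
}

#' Minimum abundance for a target species detection probability
#'
#' Smallest integer `N` such that `1 - (1 - r)^N >= threshold`; the closed
#' form is `ceiling(log(1 - threshold) / log(1 - r))`. Used to answer
#' questions like "how many fish must be present for a 95% chance the gear
#' records the species at all?".
#'
#' @param r Individual detection probability, strictly inside `(0, 1)`.
#' @param threshold Target species detection probability in `(0, 1)`.
#' @return Integer abundance.
#' @export
min_abundance_for_detection <- function(r, threshold = 0.95) {
  if (any(threshold <= 0 | threshold >= 1)) abort("threshold must lie in (0, 1)")
  if (any(r <= 0)) abort("r = 0 can never attain the threshold")
  if (any(r >= 1)) return(rep(1L, length(r)))
  n <- ceiling(log1p(-threshold) / log1p(-r))
  # guard against the ceiling landing one too high/low from rounding
  n <- pmax(n, 1)
  adjust <- species_detection_from_individual(r, pmax(n - 1, 0)) >= threshold & n > 1
  as.integer(n - adjust)
}

log_dbinom <- function(y, k, p) {
  # stable log Binomial(y | k, p) allowing p in {0, 1}
  out <- lchoose(k, y)
  out <- out + ifelse(y == 0, 0, y * log(p))
  out <- out + ifelse(k - y == 0, 0, (k - y) * log1p(-p))
  out[p == 0 & y > 0] <- -Inf
  out[p == 1 & y < k] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# per-site linear predictors / detection probabilities from a parameter list
# params: list(beta, alpha, phi, w_occ, w_chev, w_cam, eps (optional)).
# eps_on says where the site random effect enters: the camera logit (basic
# family) or the log-abundance (RN family); it is NOT applied here.
site_probs <- function(params, design, site_i = NULL) {
  idx <- site_i %||% seq_len(nrow(design$X_occ))
  list(
    occ_lp = masked_lp(params$beta[1], params$beta[-1], params$w_occ,
                       design$X_occ[idx, , drop = FALSE]),
    p1 = detection_prob_chevron(params$alpha, params$w_chev,
                                design$X_chev[idx, , drop = FALSE]),
    cam_lp = masked_lp(params$phi[1], params$phi[-1], params$w_cam,
                       design$X_cam[idx, , drop = FALSE])
  )
}

site_eps <- function(params, site_i) {
  eps <- params$eps %||% 0
  if (length(eps) > 1) eps[site_i] else eps
}

#' Site log-likelihoods for the basic occupancy family
#'
#' `site_loglik_basic()` is conditional on the latent occupancy state `z`;
#' `site_marginal_loglik_basic()` marginalizes `z` over `Bernoulli(psi)`.
#' With `z = 0`, any detection has probability zero and the conditional
#' log-likelihood is `-Inf`.
#'
#' @param params List with elements `beta`, `alpha`, `phi` (intercept-first
#'   coefficient vectors), inclusion masks `w_occ`, `w_chev`, `w_cam`, and
#'   optionally per-site `eps` (camera random effect).
#' @param detection An `occugear_detection` object.
#' @param design An `occugear_design` object.
#' @param site_i Site index (scalar).
#' @param z Latent occupancy state, 0 or 1.
#' @return Log-likelihood of site `site_i`'s two-gear detection history.
#' @export
site_loglik_basic <- function(params, detection, design, site_i, z) {
  stopifnot(z %in% c(0, 1))
  pr <- site_probs(params, design, site_i)
  p2 <- inv_logit(pr$cam_lp + site_eps(params, site_i))
  y <- detection$y[site_i, ]
  k <- detection$k
  sum(log_dbinom(y, k, z * c(pr$p1, p2)))
}

#' @rdname site_loglik_basic
#' @export
site_marginal_loglik_basic <- function(params, detection, design, site_i) {
  pr <- site_probs(params, design, site_i)
  psi <- inv_logit(pr$occ_lp)
  l1 <- log(psi) + site_loglik_basic(params, detection, design, site_i, z = 1)
  l0 <- log1p(-psi) + site_loglik_basic(params, detection, design, site_i, z = 0)
  logsumexp(c(l1, l0))
}

#' Site marginal log-likelihood for the Royle-Nichols family
#'
#' Marginalizes the latent site abundance `N ~ Poisson(lambda)` (with
#' optional log-normal mixing through `eps`) over `0..N_max`, with
#' per-replicate species detection `1 - (1 - r)^N` for each gear. If the
#' Poisson tail mass beyond `N_max` exceeds `tail_tol`, a warning is issued.
#'
#' @inheritParams site_loglik_basic
#' @param N_max Truncation bound for the latent abundance sum.
#' @param tail_tol Tolerance on the Poisson tail mass beyond `N_max`.
#' @return Marginal log-likelihood of the site's detection history.
#' @export
site_marginal_loglik_rn <- function(params, detection, design, site_i,
                                    N_max = 100, tail_tol = 1e-8) {
  pr <- site_probs(params, design, site_i)
  # in the RN family the site random effect mixes log-lambda (extra-Poisson
  # variation), not the camera logit
  lambda <- exp(pr$occ_lp + site_eps(params, site_i))
  r1 <- pr$p1
  r2 <- inv_logit(pr$cam_lp)
  y <- detection$y[site_i, ]
  k <- detection$k
  tail_mass <- stats::ppois(N_max, lambda, lower.tail = FALSE)
  if (tail_mass > tail_tol) {
    warn(paste0("Poisson tail mass beyond N_max = ", N_max, " is ",
                signif(tail_mass, 3), "; increase N_max"))
  }
  Ns <- 0:N_max
  terms <- stats::dpois(Ns, lambda, log = TRUE) +
    vapply(Ns, function(N) {
      p <- species_detection_from_individual(c(r1, r2), N)
      sum(log_dbinom(y, k, p))
    }, numeric(1))
  logsumexp(terms)
}
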