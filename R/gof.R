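# MacKenzie-Bailey style chi-square goodness of fit with parametric
# bootstrap. Expected detection-history frequencies come from point
# estimates of the (model-averaged) parameters; the observed chi-square
# statistic is referred to the distribution of statistics from datasets
# simulated under those same estimates.

#' Point estimates from a fitted model
#'
#' Model-averaged posterior means (or medians) of all coefficients, in the
#' parameter-list shape used by the likelihood functions: effective
#' coefficients (`w * beta` averaged over draws) with all-ones inclusion
#' masks.
#'
#' @param fit An `occugear_fit`.
#' @param method `"mean"` or `"median"`.
#' @return A named list with `beta`, `alpha`, `phi`, `w_occ`, `w_chev`,
#'   `w_cam`.
#' @export
point_estimates <- function(fit, method = c("mean", "median")) {
  method <- match.arg(method)
  f <- if (method == "mean") mean else stats::median
  d <- effective_draws(fit)
  grab <- function(block, X) {
    cols <- paste0(block, "_", c("intercept", colnames(X)))
    vapply(cols, function(cc) f(d[[cc]]), numeric(1))
  }
  list(beta = grab("occ", fit$design$X_occ),
       alpha = grab("chev", fit$design$X_chev),
       phi = grab("cam", fit$design$X_cam),
       w_occ = rep(1, ncol(fit$design$X_occ)),
       w_chev = rep(1, ncol(fit$design$X_chev)),
       w_cam = rep(1, ncol(fit$design$X_cam)))
}

#' Expected detection-history cell probabilities
#'
#' Per-site probability of each possible two-gear detection history under
#' point estimates. With pooled camera data there are 4 cells (chevron x
#' camera in \{0,1\}^2); with disaggregated data, 2 x 42 cells (chevron
#' 0/1 by camera snapshot count 0..41). Basic family mixes over the latent
#' occupancy state; Royle-Nichols mixes over latent abundance `0..N_max`.
#' Rows sum to one.
#'
#' @param params Parameter list as from [point_estimates()].
#' @param spec An `occugear_model_spec`.
#' @param design An `occugear_design`.
#' @param site_i Optional site subset.
#' @param N_max Latent-abundance truncation for the Royle-Nichols mixture.
#' @return A sites-by-cells matrix; columns named `"<chev>:<cam>"`.
#' @export
history_cell_probs <- function(params, spec, design, site_i = NULL,
                               N_max = 100) {
  idx <- site_i %||% seq_len(nrow(design$X_occ))
  pr <- site_probs(params, design, idx)
  k2 <- if (spec$camera_mode == "pooled") 1L else N_SNAPSHOTS
  cam_counts <- 0:k2
  p1 <- pr$p1
  p2 <- inv_logit(pr$cam_lp)
  S <- length(idx)
  n_cells <- 2L * (k2 + 1L)
  cells <- matrix(0, S, n_cells)
  colnames(cells) <- as.vector(outer(0:1, cam_counts,
                                     function(a, b) paste0(a, ":", b)))
  cell_idx <- function(y1, y2) 1L + y1 + 2L * y2

  if (spec$family == "basic") {
    psi <- inv_logit(pr$occ_lp)
    for (y1 in 0:1) {
      for (y2 in cam_counts) {
        occ_part <- (p1^y1 * (1 - p1)^(1 - y1)) *
          stats::dbinom(y2, k2, p2)
        unocc_part <- as.numeric(y1 == 0 & y2 == 0)
        cells[, cell_idx(y1, y2)] <- psi * occ_part + (1 - psi) * unocc_part
      }
    }
  } else {
    lambda <- exp(pr$occ_lp)
    for (N in 0:N_max) {
      wN <- stats::dpois(N, lambda)
      s1 <- species_detection_from_individual(p1, N)
      s2 <- species_detection_from_individual(p2, N)
      for (y1 in 0:1) {
        for (y2 in cam_counts) {
          cells[, cell_idx(y1, y2)] <- cells[, cell_idx(y1, y2)] +
            wN * (s1^y1 * (1 - s1)^(1 - y1)) * stats::dbinom(y2, k2, s2)
        }
      }
    }
    # assign residual tail mass to the all-zero cell is wrong; renormalize
    cells <- cells / rowSums(cells)
  }
  cells
}

# merge camera-count columns from the tail so every aggregate expected
# count is >= min_expected; returns an integer bin id per camera count
camera_count_bins <- function(expected_by_count, min_expected) {
  n <- length(expected_by_count)
  bin <- integer(n)
  current <- 0L
  acc <- 0
  # walk from the highest count downward, closing a bin once it holds
  # enough expected mass
  for (j in n:1) {
    if (acc == 0) current <- current + 1L
    bin[j] <- current
    acc <- acc + expected_by_count[j]
    if (acc >= min_expected) acc <- 0
  }
  if (acc > 0 && current > 1L) bin[bin == current] <- current - 1L
  # renumber in increasing camera-count order
  match(bin, unique(bin))
}

bin_cells <- function(cells, spec, min_expected) {
  if (spec$camera_mode == "pooled") return(cells)
  k2 <- N_SNAPSHOTS
  # expected counts per camera count, aggregated over sites and chevron
  counts <- as.integer(sub(".*:", "", colnames(cells)))
  exp_by_count <- vapply(0:k2, function(cc)
    sum(cells[, counts == cc, drop = FALSE]), numeric(1))
  bins <- camera_count_bins(exp_by_count, min_expected)
  new_cols <- paste0(rep(0:1, times = max(bins)), ":b",
                     rep(seq_len(max(bins)), each = 2))
  out <- matrix(0, nrow(cells), 2 * max(bins))
  colnames(out) <- new_cols
  for (j in seq_len(ncol(cells))) {
    y1 <- as.integer(sub(":.*", "", colnames(cells)[j]))
    b <- bins[counts[j] + 1L]
    tgt <- paste0(y1, ":b", b)
    out[, tgt] <- out[, tgt] + cells[, j]
  }
  out
}

observed_cells <- function(detection, template) {
  S <- nrow(detection$y)
  O <- matrix(0, S, ncol(template))
  colnames(O) <- colnames(template)
  if (grepl(":b", colnames(template)[1], fixed = TRUE)) {
    abort("observed_cells needs unbinned template columns")
  }
  key <- paste0(detection$y[, "chevron"], ":", detection$y[, "camera"])
  O[cbind(seq_len(S), match(key, colnames(template)))] <- 1
  O
}

#' Chi-square detection-history statistic
#'
#' `sum_i sum_c (O_ic - E_ic)^2 / E_ic`, where `O_ic` indicates site `i`'s
#' observed history cell and `E_ic` is its expected probability. For
#' disaggregated camera data, sparse camera-count cells are merged from the
#' tail until each aggregate expected count reaches `min_expected`.
#'
#' @param detection An `occugear_detection`.
#' @param cell_probs Per-site expected cell probabilities, as from
#'   [history_cell_probs()] (unbinned).
#' @param spec The model spec the probabilities came from.
#' @param min_expected Pooling floor for aggregate expected counts.
#' @return The statistic (a single non-negative number).
#' @export
chisq_stat <- function(detection, cell_probs, spec, min_expected = 2) {
  O <- observed_cells(detection, cell_probs)
  Eb <- bin_cells(cell_probs, spec, min_expected)
  if (ncol(Eb) != ncol(cell_probs)) {
    # apply the identical binning to the observed indicators
    Ob <- matrix(0, nrow(O), ncol(Eb))
    colnames(Ob) <- colnames(Eb)
    counts <- as.integer(sub(".*:", "", colnames(cell_probs)))
    exp_by_count <- vapply(0:N_SNAPSHOTS, function(cc)
      sum(cell_probs[, counts == cc, drop = FALSE]), numeric(1))
    bins <- camera_count_bins(exp_by_count, min_expected)
    for (j in seq_len(ncol(cell_probs))) {
      y1 <- as.integer(sub(":.*", "", colnames(cell_probs)[j]))
      tgt <- paste0(y1, ":b", bins[counts[j] + 1L])
      Ob[, tgt] <- Ob[, tgt] + O[, j]
    }
    O <- Ob
  }
  ok <- Eb > 0
  sum(((O - Eb)^2 / Eb)[ok])
}

simulate_detection_from <- function(params, spec, design, N_max = 100) {
  pr <- site_probs(params, design)
  S <- nrow(design$X_occ)
  k2 <- if (spec$camera_mode == "pooled") 1L else N_SNAPSHOTS
  p1 <- pr$p1
  p2 <- inv_logit(pr$cam_lp)
  if (spec$family == "basic") {
    z <- rbinom(S, 1, inv_logit(pr$occ_lp))
    y1 <- rbinom(S, 1, z * p1)
    y2 <- rbinom(S, k2, z * p2)
  } else {
    N <- pmin(rpois(S, exp(pr$occ_lp)), N_max)
    y1 <- rbinom(S, 1, species_detection_from_individual(p1, N))
    y2 <- rbinom(S, k2, species_detection_from_individual(p2, N))
  }
  out <- list(y = cbind(chevron = y1, camera = y2),
              k = setNames(c(1L, k2), c("chevron", "camera")),
              camera_mode = spec$camera_mode)
  class(out) <- "occugear_detection"
  out
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' Simulates `n_boot` datasets at the observed covariates from the fitted
#' model's point estimates, computes the chi-square history statistic on
#' each, and reports `gof_p`, the proportion of bootstrap statistics at
#' least as large as the observed one. Values near zero signal lack of
#' fit; values near one signal no evidence of misfit. With
#' `refit = TRUE` each bootstrap dataset is refit before its statistic is
#' computed (the stricter original procedure; much slower), and failed
#' refits are counted in `n_failed`.
#'
#' @param fit An `occugear_fit`.
#' @param n_boot Number of bootstrap datasets (>= 1).
#' @param refit Refit the model to each bootstrap dataset?
#' @param seed Integer seed for the bootstrap simulations.
#' @param min_expected Cell-pooling floor, see [chisq_stat()].
#' @param point `"mean"` or `"median"` point estimates.
#' @param refit_settings MCMC settings used when `refit = TRUE`.
#' @return An `occugear_gof`: `observed_stat`, `boot_stats`, `gof_p`,
#'   `n_boot`, `seed`, `n_failed`.
#' @export
gof_test <- function(fit, n_boot = 100, refit = FALSE, seed = 1,
                     min_expected = 2, point = c("mean", "median"),
                     refit_settings = NULL) {
  point <- match.arg(point)
  if (n_boot < 1) abort("n_boot must be at least 1")
  est <- point_estimates(fit, method = point)
  E <- history_cell_probs(est, fit$spec, fit$design, N_max = fit$settings$N_max)
  obs <- chisq_stat(fit$detection, E, fit$spec, min_expected)
  # simulate every bootstrap dataset up front: refitting below reseeds the
  # RNG, which must not feed back into the bootstrap data stream
  set.seed(seed)
  sims <- lapply(seq_len(n_boot), function(b)
    simulate_detection_from(est, fit$spec, fit$design,
                            N_max = fit$settings$N_max))
  n_failed <- 0L
  boot <- vapply(sims, function(sim) {
    Eb <- E
    if (refit) {
      st <- refit_settings %||% fit$settings
      fb <- tryCatch(
        sample_posterior(sim, fit$design, fit$spec, fit$priors, st),
        error = function(e) NULL)
      if (is.null(fb)) {
        n_failed <<- n_failed + 1L
        return(NA_real_)
      }
      fit_b <- fit
      fit_b$draws <- fb
      fit_b$detection <- sim
      est_b <- point_estimates(fit_b, method = point)
      Eb <- history_cell_probs(est_b, fit$spec, fit$design,
                               N_max = fit$settings$N_max)
    }
    chisq_stat(sim, Eb, fit$spec, min_expected)
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  structure(list(observed_stat = obs, boot_stats = boot,
                 gof_p = mean(boot >= obs), n_boot = n_boot,
                 n_failed = n_failed, refit = refit, seed = seed),
            class = "occugear_gof")
}

#' @export
print.occugear_gof <- function(x, ...) {
  cat("<occugear_gof> observed chi-square ", signif(x$observed_stat, 4),
      ", gof_p = ", signif(x$gof_p, 3), " (", length(x$boot_stats),
      " bootstrap datasets)\n", sep = "")
  invisible(x)
}

#' @export
glance.occugear_gof <- function(x, ...) {
  tibble::tibble(observed_stat = x$observed_stat, gof_p = x$gof_p,
                 n_boot = x$n_boot, n_failed = x$n_failed, refit = x$refit)
}

#' Serialize a GOF result to JSON
#'
#' @param gof An `occugear_gof`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gof <- function(gof, path) {
  jsonlite::write_json(unclass(gof), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
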