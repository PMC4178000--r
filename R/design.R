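# Standardized design matrices for the three sub-models (occupancy /
# abundance, chevron detection, camera detection). Continuous covariates are
# centered and scaled so coefficients are directly comparable; squared terms
# get the same treatment so their coefficients live on the same scale.

occ_columns <- c("yr2011", "depth", "depth2", "lat", "lat2", "temp", "temp2",
                 "livebot.l", "livebot.m", "livebot.h",
                 "hardsub.l", "hardsub.m", "hardsub.h",
                 "relief.m", "relief.h")
chev_columns <- c("temp", "temp2", "soak", "cdir.p", "cdir.a", "cspeed")
cam_columns <- c("turb.h", "cdir.p", "cdir.a", "cspeed")

std_col <- function(x, center, scale) (x - center) / scale

#' Build standardized design matrices
#'
#' Constructs the three covariate matrices used by the models, without
#' intercept columns (intercepts are separate parameters):
#'
#' * occupancy / abundance: `yr2011, depth, depth2, lat, lat2, temp, temp2,
#'   livebot.l/m/h, hardsub.l/m/h, relief.m, relief.h` (15 columns);
#' * chevron detection: `temp, temp2, soak, cdir.p, cdir.a, cspeed`;
#' * camera detection: `turb.h, cdir.p, cdir.a, cspeed`.
#'
#' Continuous covariates (`depth`, `lat`, `temp`, `soak`) are centered on
#' their sample mean and scaled by one sample standard deviation. Squared
#' terms are, by default, the square of the standardized covariate, itself
#' re-standardized (`square_terms = "scaled"`), so every column enters on a
#' unit scale; `square_terms = "raw"` instead squares the raw covariate
#' before standardizing. Reference levels: `relief = l`, `cdir = toward`,
#' `year = 2010`, `cspeed = low`, `turb = low`. All three `livebot` and
#' `hardsub` indicator columns are carried; the indicator-selection prior
#' regularizes the resulting redundancy with the intercept.
#'
#' @param tbl A site table.
#' @param square_terms `"scaled"` (default) or `"raw"`; see above.
#' @return An `occugear_design` object: matrices `X_occ`, `X_chev`, `X_cam`,
#'   the per-column `scaling` (center/scale, and the base covariate for
#'   squared terms), and `square_terms`.
#' @export
build_design_matrices <- function(tbl, square_terms = c("scaled", "raw")) {
  square_terms <- match.arg(square_terms)
  tbl <- validate_site_table(tbl)
  cont <- c(depth = "depth_m", lat = "lat_deg", temp = "temp_c", soak = "soak_min")
  scaling <- list()
  cols <- list()
  for (nm in names(cont)) {
    x <- tbl[[cont[[nm]]]]
    if (length(unique(x)) < 2) {
      abort(paste0("continuous covariate '", nm, "' has zero variance; ",
                   "it cannot be standardized"))
    }
    mu <- mean(x); sdev <- sd(x)
    scaling[[nm]] <- list(center = mu, scale = sdev, source = cont[[nm]])
    cols[[nm]] <- std_col(x, mu, sdev)
  }
  for (nm in c("depth", "lat", "temp")) {
    sq_name <- paste0(nm, "2")
    base <- if (square_terms == "scaled") cols[[nm]] else tbl[[cont[[nm]]]]
    q <- base^2
    mu <- mean(q); sdev <- sd(q)
    if (sdev == 0) abort(paste0("squared term '", sq_name, "' has zero variance"))
    scaling[[sq_name]] <- list(center = mu, scale = sdev, base = nm)
    cols[[sq_name]] <- std_col(q, mu, sdev)
  }

  dummy <- function(x, level) as.numeric(x == level)
  cols$yr2011 <- as.numeric(tbl$year == 2011L)
  for (lv in c("l", "m", "h")) {
    cols[[paste0("livebot.", lv)]] <- dummy(tbl$livebot, lv)
    cols[[paste0("hardsub.", lv)]] <- dummy(tbl$hardsub, lv)
  }
  cols$relief.m <- dummy(tbl$relief, "m")
  cols$relief.h <- dummy(tbl$relief, "h")
  cols$cdir.p <- dummy(tbl$cdir, "perpendicular")
  cols$cdir.a <- dummy(tbl$cdir, "away")
  cols$cspeed <- dummy(tbl$cspeed, "high")
  cols$turb.h <- dummy(tbl$turb, "high")

  pick <- function(nms) {
    m <- do.call(cbind, cols[nms])
    colnames(m) <- nms
    m
  }
  out <- list(
    X_occ = pick(occ_columns),
    X_chev = pick(chev_columns),
    X_cam = pick(cam_columns),
    scaling = scaling,
    square_terms = square_terms,
    n_sites = nrow(tbl)
  )
  class(out) <- "occugear_design"
  out
}

# Standardize raw values of one continuous covariate with a design's stored
# scaling; returns the standardized base column and its squared companion,
# processed exactly as during training.
standardize_pair <- function(design, covariate, values) {
  sc <- design$scaling[[covariate]]
  if (is.null(sc)) abort(paste0("'", covariate, "' is not a continuous covariate"))
  z <- std_col(values, sc$center, sc$scale)
  sq_name <- paste0(covariate, "2")
  out <- list(base = z)
  sq <- design$scaling[[sq_name]]
  if (!is.null(sq)) {
    q <- if (design$square_terms == "scaled") z^2 else values^2
    out$square <- std_col(q, sq$center, sq$scale)
  }
  out
}

# Recover raw covariate values from a standardized column (tests use this to
# check that standardization is invertible).
destandardize <- function(design, covariate, z) {
  sc <- design$scaling[[covariate]]
  if (is.null(sc)) abort(paste0("no scaling stored for '", covariate, "'"))
  z * sc$scale + sc$center
}

# intercept-only design (no covariates in any sub-model); used for toy
# posteriors that can be checked against dense grid enumeration
intercept_only_design <- function(S) {
  zero <- matrix(numeric(0), nrow = S, ncol = 0)
  structure(list(X_occ = zero, X_chev = zero, X_cam = zero,
                 scaling = list(), square_terms = "scaled", n_sites = S),
            class = "occugear_design")
}

#' Serialize design scaling metadata to JSON
#'
#' Writes the centering/scaling constants (and the squared-term convention)
#' needed to reproduce predictions from a fitted model without the original
#' data.
#'
#' @param design An `occugear_design`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_design_scaling <- function(design, path) {
  stopifnot(inherits(design, "occugear_design"))
  jsonlite::write_json(
    list(scaling = design$scaling, square_terms = design$square_terms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.occugear_design <- function(x, ...) {
  cat("<occugear_design> ", x$n_sites, " sites\n", sep = "")
  cat("  X_occ: ", ncol(x$X_occ), " columns; X_chev: ", ncol(x$X_chev),
      "; X_cam: ", ncol(x$X_cam), "\n", sep = "")
  cat("  squared terms: ", x$square_terms, "\n", sep = "")
  invisible(x)
}
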