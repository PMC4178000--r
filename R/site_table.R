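# Site-level table: one row per trap deployment, two gears observed
# simultaneously (chevron trap catch + camera snapshot hits out of 41).

#' Number of camera snapshots per deployment
#'
#' The camera protocol examines one 1-second frame every 30 seconds for 20
#' minutes starting 10 minutes after deployment, giving 41 snapshots. This
#' constant bounds `camera_snapshot_hits` and sets the replicate count of the
#' disaggregated camera sample.
#' @export
N_SNAPSHOTS <- 41L

# canonical schema: column -> type / allowed levels
site_table_schema <- function() {
  list(
    site_id  = list(type = "character"),
    year     = list(type = "integer", levels = c(2010L, 2011L)),
    chevron_count = list(type = "integer", min = 0L),
    camera_snapshot_hits = list(type = "integer", min = 0L, max = N_SNAPSHOTS),
    depth_m  = list(type = "double", positive = TRUE),
    lat_deg  = list(type = "double"),
    temp_c   = list(type = "double"),
    livebot  = list(type = "factor", levels = c("l", "m", "h")),
    hardsub  = list(type = "factor", levels = c("l", "m", "h")),
    relief   = list(type = "factor", levels = c("l", "m", "h")),
    soak_min = list(type = "double", positive = TRUE),
    cdir     = list(type = "factor", levels = c("toward", "perpendicular", "away")),
    cspeed   = list(type = "factor", levels = c("low", "high")),
    turb     = list(type = "factor", levels = c("low", "high"))
  )
}

#' Validate a site-level table
#'
#' Checks that a data frame conforms to the two-gear site-table schema:
#' required columns present, snapshot hits within `[0, 41]`, positive depths
#' and soak times, and categorical fields restricted to their allowed levels.
#' Violations are reported with the offending row numbers.
#'
#' @param tbl A data frame with one row per sampling event.
#' @return The validated table as a tibble, with integer and factor columns
#'   coerced to their canonical types.
#' @export
validate_site_table <- function(tbl) {
  schema <- site_table_schema()
  missing <- setdiff(names(schema), names(tbl))
  if (length(missing) > 0) {
    abort(paste0("site table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(tbl)
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(
        what, " (row", if (length(rows) > 1) "s" else "", " ",
        paste(head(rows, 5), collapse = ", "),
        if (length(rows) > 5) ", ..." else "", ")"))
    }
  }

  for (col in names(schema)) {
    spec <- schema[[col]]
    x <- tbl[[col]]
    if (spec$type == "integer") {
      xn <- suppressWarnings(as.numeric(x))
      note(which(is.na(xn) | xn != round(xn)), paste0(col, " must be an integer"))
      xi <- as.integer(round(xn))
      if (!is.null(spec$min)) note(which(!is.na(xi) & xi < spec$min),
                                   paste0(col, " below ", spec$min))
      if (!is.null(spec$max)) note(which(!is.na(xi) & xi > spec$max),
                                   paste0(col, " above ", spec$max))
      if (!is.null(spec$levels)) note(which(!is.na(xi) & !(xi %in% spec$levels)),
                                      paste0(col, " must be one of ",
                                             paste(spec$levels, collapse = ", ")))
      tbl[[col]] <- xi
    } else if (spec$type == "double") {
      xn <- suppressWarnings(as.numeric(x))
      note(which(is.na(xn)), paste0(col, " must be numeric"))
      if (isTRUE(spec$positive)) note(which(!is.na(xn) & xn <= 0),
                                      paste0(col, " must be positive"))
      tbl[[col]] <- xn
    } else if (spec$type == "factor") {
      xc <- as.character(x)
      note(which(!(xc %in% spec$levels)),
           paste0(col, " has unknown level; allowed: ",
                  paste(spec$levels, collapse = ", ")))
      tbl[[col]] <- factor(xc, levels = spec$levels)
    } else {
      tbl[[col]] <- as.character(x)
    }
  }
  if (length(problems) > 0) {
    abort(paste0("invalid site table:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  dplyr::select(tbl, dplyr::all_of(names(schema)))
}

#' Read a site-level table from delimited text
#'
#' Reads a comma-separated file (header required, UTF-8) holding one row per
#' two-gear deployment and validates it against the site-table schema. The
#' chevron column may hold either fish counts or 0/1 detection flags; a
#' binary flag is simply a count that never exceeds one.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the headers used in the file, e.g.
#'   `c(chevron_count = "chev.det", camera_snapshot_hits = "cam.det")`.
#' @return A validated tibble of site records.
#' @export
read_site_table <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    bad <- setdiff(unname(col_map), names(raw))
    if (length(bad) > 0) {
      abort(paste0("col_map refers to absent column(s): ",
                   paste(bad, collapse = ", ")))
    }
    for (canonical in names(col_map)) {
      names(raw)[names(raw) == col_map[[canonical]]] <- canonical
    }
  }
  validate_site_table(raw)
}

#' Write a site-level table to CSV
#'
#' Inverse of [read_site_table()]: a table written by this function reads
#' back to identical records.
#'
#' @param tbl A site table (validated on the way out).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(tbl, path) {
  tbl <- validate_site_table(tbl)
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Build per-gear detection histories
#'
#' Converts a site table into the detection data the models consume. The
#' chevron trap is always a single replicate (`k = 1`, detection = any fish
#' caught). The camera is either pooled into one binary replicate (`k = 1`,
#' detection = any snapshot with the species) or disaggregated into the 41
#' snapshot replicates (`k = 41`, response = number of positive snapshots).
#'
#' @param tbl A site table.
#' @param camera_mode `"pooled"` or `"disaggregated"`.
#' @return An object of class `occugear_detection`: a list with integer
#'   matrix `y` (sites x 2 gears, columns `chevron`, `camera`), replicate
#'   counts `k` (length 2), and `camera_mode`.
#' @export
build_detection_data <- function(tbl, camera_mode = c("pooled", "disaggregated")) {
  camera_mode <- match.arg(camera_mode)
  tbl <- validate_site_table(tbl)
  y_chev <- as.integer(tbl$chevron_count > 0)
  y_cam <- if (camera_mode == "pooled") {
    as.integer(tbl$camera_snapshot_hits > 0)
  } else {
    tbl$camera_snapshot_hits
  }
  k <- c(1L, if (camera_mode == "pooled") 1L else N_SNAPSHOTS)
  out <- list(
    y = cbind(chevron = y_chev, camera = y_cam),
    k = setNames(k, c("chevron", "camera")),
    camera_mode = camera_mode,
    site_id = tbl$site_id
  )
  class(out) <- "occugear_detection"
  out
}

#' Naive (observed) occupancy rate
#'
#' Fraction of sites at which a gear detected the species at least once,
#' uncorrected for imperfect detection. Always a lower bound on true
#' occupancy when detection is imperfect.
#'
#' @param tbl A site table.
#' @param gear `"chevron"`, `"camera"`, or `"either"` (detected by at least
#'   one gear).
#' @return A single proportion in `[0, 1]`.
#' @export
naive_occupancy <- function(tbl, gear = c("chevron", "camera", "either")) {
  gear <- match.arg(gear)
  tbl <- validate_site_table(tbl)
  if (nrow(tbl) == 0) abort("naive_occupancy needs at least one site")
  det <- switch(gear,
    chevron = tbl$chevron_count > 0,
    camera = tbl$camera_snapshot_hits > 0,
    either = tbl$chevron_count > 0 | tbl$camera_snapshot_hits > 0
  )
  mean(det)
}
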