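#' Detection history for one species
#'
#' A detection history holds binary detections and survey effort for
#' `n_sites` sites over `n_years` primary periods (years, within which
#' occupancy is assumed closed) each split into `n_secondary` secondary
#' periods (repeat camera sessions).  A site-year-period cell where no
#' camera was deployed is `NA` in both `y` and `effort` and contributes
#' nothing to any likelihood; a deployed camera with zero active days is a
#' legal observation with `effort = 0`.
#'
#' @param y binary array `n_sites x n_years x n_secondary` (`NA` = no
#'   deployment).
#' @param effort nonnegative array of camera-active days, same shape as
#'   `y`, `NA` exactly where `y` is `NA`.
#' @param species species label.
#' @param sites optional site identifiers (default `1:n_sites`).
#' @param years optional primary-period labels (default `1:n_years`).
#' @return an object of class `detection_history`.
#' @export
detection_history <- function(y, effort, species = "species",
                              sites = NULL, years = NULL) {
  y <- as.array(y); effort <- as.array(effort)
  if (length(dim(y)) != 3L) stop("`y` must be a 3-d array (site x year x period)")
  if (!identical(dim(y), dim(effort))) stop("`y` and `effort` dimensions differ")
  bad <- !is.na(y) & !(y %in% c(0, 1))
  if (any(bad)) stop("non-binary detection value at cell(s): ",
                     paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", "))
  if (any(!is.na(effort) & effort < 0)) stop("negative effort")
  if (!identical(is.na(y), is.na(effort)))
    stop("`y` and `effort` must be missing in exactly the same cells")
  storage.mode(y) <- "double"; storage.mode(effort) <- "double"
  d <- dim(y)
  out <- list(species = species,
              y = y, effort = effort,
              n_sites = d[1L], n_years = d[2L], n_secondary = d[3L],
              sites = sites %||% seq_len(d[1L]),
              years = years %||% seq_len(d[2L]))
  class(out) <- "detection_history"
  out
}

#' @export
print.detection_history <- function(x, ...) {
  obs <- sum(!is.na(x$y))
  cat(sprintf("Detection history: %s\n", x$species))
  cat(sprintf("  %d sites x %d years x %d secondary periods (%d observed occasions)\n",
              x$n_sites, x$n_years, x$n_secondary, obs))
  cat(sprintf("  detections: %d; naive occupancy: %d/%d sites\n",
              sum(x$y, na.rm = TRUE),
              sum(apply(x$y == 1, 1, any, na.rm = TRUE)), x$n_sites))
  invisible(x)
}

#' Read a detection-history CSV
#'
#' Long format, one row per site-year-period cell, columns
#' `site,year,period,y,effort`; cells with no deployment carry empty `y`
#' and empty `effort`.
#'
#' @param path CSV file path.
#' @param species species label attached to the result.
#' @return a [detection_history()].
#' @export
read_detection_history <- function(path, species = "species") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "period", "y", "effort")
  if (!all(need %in% names(df)))
    stop("malformed header: need columns ", paste(need, collapse = ","))
  sites <- sort(unique(df$site)); years <- sort(unique(df$year))
  periods <- sort(unique(df$period))
  n <- length(sites); T <- length(years); J <- length(periods)
  y <- array(NA_real_, c(n, T, J)); eff <- array(NA_real_, c(n, T, J))
  i <- match(df$site, sites); t <- match(df$year, years); j <- match(df$period, periods)
  yv <- suppressWarnings(as.numeric(df$y))
  ev <- suppressWarnings(as.numeric(df$effort))
  bad <- !is.na(yv) & !(yv %in% c(0, 1))
  if (any(bad)) stop("non-binary detection value at row(s): ",
                     paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", "))
  if (any(!is.na(ev) & ev < 0)) stop("negative effort at row(s): ",
                                     paste(which(!is.na(ev) & ev < 0), collapse = ", "))
  y[cbind(i, t, j)] <- yv
  eff[cbind(i, t, j)] <- ev
  # a recorded y with no effort (or vice versa) is inconsistent
  if (!identical(is.na(y), is.na(eff))) {
    off <- which(is.na(y) != is.na(eff))
    stop("y/effort missingness mismatch at cell(s): ",
         paste(off[seq_len(min(5, length(off)))], collapse = ", "))
  }
  detection_history(y, eff, species = species, sites = sites, years = years)
}

#' Write a detection history to CSV
#'
#' Inverse of [read_detection_history()]; missing cells are written with
#' empty `y`/`effort` fields so round trips are lossless.
#'
#' @param det a [detection_history()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detection_history <- function(det, path) {
  g <- expand.grid(i = seq_len(det$n_sites), t = seq_len(det$n_years),
                   j = seq_len(det$n_secondary))
  df <- data.frame(site = det$sites[g$i], year = det$years[g$t], period = g$j,
                   y = det$y[cbind(g$i, g$t, g$j)],
                   effort = det$effort[cbind(g$i, g$t, g$j)])
  df <- df[order(df$site, df$year, df$period), ]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Extract a single primary period as a one-year history
#'
#' @param det a [detection_history()].
#' @param year year index (1-based) or label present in `det$years`.
#' @return a [detection_history()] with `n_years = 1`.
#' @export
slice_year <- function(det, year) {
  t <- if (year %in% det$years) match(year, det$years) else as.integer(year)
  if (is.na(t) || t < 1 || t > det$n_years) stop("unknown year: ", year)
  detection_history(det$y[, t, , drop = FALSE], det$effort[, t, , drop = FALSE],
                    species = det$species, sites = det$sites,
                    years = det$years[t])
}

#' Co-detection summary for two species
#'
#' Counts, over non-missing site-year-period occasions, how often the two
#' species were photographed together, alone, or not at all, plus per-year
#' detection/nondetection tallies and the number of sites with at least
#' one detection per species (naive occupancy numerators).
#'
#' @param a,b [detection_history()] objects on the same design (matching
#'   dimensions and missingness).
#' @return a list with elements `both`, `only_a`, `only_b`, `neither`,
#'   `total`, `by_year` (data frame of detections/nondetections per species
#'   per year) and `sites_detected` (named vector).
#' @export
summarize_codetection <- function(a, b) {
  if (!identical(dim(a$y), dim(b$y))) stop("dimension mismatch between species")
  if (!identical(is.na(a$y), is.na(b$y))) stop("missingness mismatch between species")
  ok <- !is.na(a$y)
  ya <- a$y[ok]; yb <- b$y[ok]
  by_year <- do.call(rbind, lapply(seq_len(a$n_years), function(t) {
    sa <- a$y[, t, ]; sb <- b$y[, t, ]
    data.frame(year = a$years[t],
               det_a = sum(sa == 1, na.rm = TRUE),
               nondet_a = sum(sa == 0, na.rm = TRUE),
               det_b = sum(sb == 1, na.rm = TRUE),
               nondet_b = sum(sb == 0, na.rm = TRUE))
  }))
  names(by_year)[2:5] <- c(paste0(c("det_", "nondet_"), a$species),
                           paste0(c("det_", "nondet_"), b$species))
  sites_det <- c(sum(apply(a$y == 1, 1, any, na.rm = TRUE)),
                 sum(apply(b$y == 1, 1, any, na.rm = TRUE)))
  names(sites_det) <- c(a$species, b$species)
  list(both = sum(ya == 1 & yb == 1),
       only_a = sum(ya == 1 & yb == 0),
       only_b = sum(ya == 0 & yb == 1),
       neither = sum(ya == 0 & yb == 0),
       total = sum(ok),
       by_year = by_year,
       sites_detected = sites_det)
}
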