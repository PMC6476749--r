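#' Circular sample of detection times
#'
#' Clock times of camera detections mapped to the circle, 24 h = `2*pi`.
#' Clock time (not sun-anchored time) is used throughout.
#'
#' @param times numeric radians in `[0, 2*pi)`.
#' @param species species label.
#' @param years optional per-observation year labels.
#' @return an object of class `activity_sample` (numeric vector with
#'   attributes).
#' @export
activity_sample <- function(times, species = "species", years = NULL) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0) || any(times >= 2 * pi))
    stop("times must be finite radians in [0, 2*pi)")
  if (!is.null(years) && length(years) != length(times))
    stop("`years` must match `times` in length")
  structure(times, species = species, years = years, class = "activity_sample")
}

#' @export
print.activity_sample <- function(x, ...) {
  cat(sprintf("Activity sample: %s, n = %d detections\n",
              attr(x, "species"), length(x)))
  invisible(x)
}

#' Convert clock times to radians on the diel circle
#'
#' `HH:MM` or `HH:MM:SS` strings become `seconds-since-midnight / 86400 *
#' 2*pi`, in `[0, 2*pi)`.
#'
#' @param times character clock times.
#' @param species,years passed to [activity_sample()].
#' @return an [activity_sample()].
#' @export
times_to_radians <- function(times, species = "species", years = NULL) {
  parts <- strsplit(as.character(times), ":", fixed = TRUE)
  secs <- vapply(seq_along(parts), function(k) {
    p <- suppressWarnings(as.numeric(parts[[k]]))
    if (!(length(p) %in% 2:3) || any(is.na(p)))
      stop("unparseable time string: ", times[k])
    if (p[1] > 23 || p[2] > 59 || (length(p) == 3 && p[3] >= 60))
      stop("time out of range: ", times[k])
    p[1] * 3600 + p[2] * 60 + if (length(p) == 3) p[3] else 0
  }, numeric(1))
  activity_sample(secs / 86400 * 2 * pi, species = species, years = years)
}

#' Read a detection timestamp CSV
#'
#' Columns `species,date,time` (ISO 8601 date, `HH:MM:SS`).  Returns one
#' [activity_sample()] per species, with the detection year carried as a
#' label for per-year overlap analyses.
#'
#' @param path CSV path.
#' @return named list of [activity_sample()] objects.
#' @export
read_activity_times <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "date", "time")
  if (!all(need %in% names(df)))
    stop("malformed header: need columns ", paste(need, collapse = ","))
  yr <- as.integer(substr(df$date, 1, 4))
  out <- lapply(split(seq_len(nrow(df)), df$species), function(idx)
    times_to_radians(df$time[idx], species = df$species[idx[1]], years = yr[idx]))
  out
}
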