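#' Site covariate handling
#'
#' Site covariates live in a plain data frame with a `site` column plus one
#' numeric column per covariate.  The canonical covariate set for a
#' camera-grid study is six vegetation-cover proportions (`DEA` = deciduous
#' excluding aspen, `Evergreen`, `Mixed_grassland`, `Wetland`, `Aspen`,
#' `Unsuitable`), `road` and `hydrology` network densities, and `distance`
#' to the nearest water source; any numeric columns are accepted.
#'
#' @param path covariate CSV path (`site` column plus covariates).
#' @param check_veg validate that vegetation proportions, when present, lie
#'   in `[0, 1]` and sum to at most 1 (plus tolerance) per site.
#' @return a data frame of class `site_covariates`.
#' @export
read_site_covariates <- function(path, check_veg = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_site_covariates(df, check_veg = check_veg)
}

veg_covariate_names <- c("DEA", "Evergreen", "Mixed_grassland", "Wetland",
                         "Aspen", "Unsuitable")

#' @rdname read_site_covariates
#' @param df a data frame with a `site` column.
#' @export
as_site_covariates <- function(df, check_veg = TRUE) {
  if (!"site" %in% names(df)) stop("covariate table needs a `site` column")
  num <- setdiff(names(df), "site")
  if (!all(vapply(df[num], is.numeric, TRUE))) stop("non-numeric covariate column")
  veg <- intersect(veg_covariate_names, names(df))
  if (check_veg && length(veg)) {
    v <- as.matrix(df[veg])
    if (any(v < -1e-9 | v > 1 + 1e-9)) stop("vegetation proportions outside [0, 1]")
    if (any(rowSums(v) > 1 + 1e-6)) stop("vegetation proportions sum to > 1")
  }
  class(df) <- c("site_covariates", "data.frame")
  df
}

#' Centre and scale selected covariates
#'
#' Replaces each named covariate by `(x - mean) / sd` (sample sd, `n - 1`
#' denominator) and records the centring constants in the `"scaling"`
#' attribute so the transform can be inverted or applied to new sites.
#'
#' @param cov a `site_covariates` data frame.
#' @param names covariates to scale (default: `road`, `hydrology`,
#'   `distance` where present).
#' @return `cov` with the named columns standardised and a `"scaling"`
#'   attribute (data frame `name`, `center`, `scale`).
#' @export
scale_covariates <- function(cov, names = intersect(c("road", "hydrology", "distance"),
                                                    colnames(cov))) {
  miss <- setdiff(names, colnames(cov))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  old <- attr(cov, "scaling")
  rec <- data.frame(name = names, center = NA_real_, scale = NA_real_)
  for (k in seq_along(names)) {
    x <- cov[[names[k]]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("zero variance in covariate `", names[k], "`")
    rec$center[k] <- mean(x); rec$scale[k] <- s
    cov[[names[k]]] <- (x - rec$center[k]) / s
  }
  attr(cov, "scaling") <- rbind(old[!(old$name %in% names), , drop = FALSE], rec)
  cov
}

#' Invert [scale_covariates()]
#'
#' @param cov a scaled `site_covariates` data frame carrying a `"scaling"`
#'   attribute.
#' @return `cov` on the original scale, with the attribute removed.
#' @export
unscale_covariates <- function(cov) {
  rec <- attr(cov, "scaling")
  if (is.null(rec)) return(cov)
  for (k in seq_len(nrow(rec)))
    cov[[rec$name[k]]] <- cov[[rec$name[k]]] * rec$scale[k] + rec$center[k]
  attr(cov, "scaling") <- NULL
  cov
}

#' Apply a stored scaling record to new sites
#'
#' Standardises covariates of a new table with the training means and sds,
#' as required when predicting occupancy for sites not used in fitting.
#'
#' @param cov a `site_covariates` data frame on the original scale.
#' @param scaling a scaling record as stored by [scale_covariates()].
#' @return the standardised table.
#' @export
apply_scaling <- function(cov, scaling) {
  for (k in seq_len(nrow(scaling)))
    cov[[scaling$name[k]]] <- (cov[[scaling$name[k]]] - scaling$center[k]) /
      scaling$scale[k]
  attr(cov, "scaling") <- scaling
  cov
}
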