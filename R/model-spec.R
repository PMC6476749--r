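#' Occupancy model specification
#'
#' Names the covariates entering each parameter block.  A single-season
#' model has an occupancy block (`psi`) and a detection block (`p`); a
#' dynamic (multi-season) model adds colonization (`gamma`) and persistence
#' (`phi`) blocks.  Every block carries an implicit intercept; an empty
#' block is intercept-only (printed `~1`).
#'
#' Reserved covariate names: `"effort"` (detection block; per-occasion
#' camera-active days from the detection history), `"year"` (dynamics
#' blocks; additive logit offsets for origin years 2..T-1, origin year 1 as
#' reference), and `"other_psi"` (dynamics blocks; the other species'
#' predicted yearly occupancy probability, supplied at fit time, entering
#' the logit linearly and unscaled since it already lives in `[0, 1]`).
#' All other names must be columns of the site-covariate table.
#'
#' @param psi covariate names for initial (or single-season) occupancy.
#' @param gamma,phi covariate names for colonization and persistence;
#'   leave both `NULL` for a single-season model.
#' @param p covariate names for detection (default `"effort"`).
#' @return an object of class `occu_spec`.
#' @export
occu_spec <- function(psi = character(0), gamma = NULL, phi = NULL,
                      p = "effort") {
  dynamic <- !(is.null(gamma) && is.null(phi))
  if (dynamic && (is.null(gamma) || is.null(phi)))
    stop("supply both `gamma` and `phi` (possibly character(0)) for a dynamic model")
  bad <- intersect(c("year", "other_psi", "effort"), psi)
  if (length(bad)) stop("not allowed in psi block: ", paste(bad, collapse = ", "))
  if ("effort" %in% c(gamma, phi)) stop("`effort` is a detection covariate only")
  if (any(c("year", "other_psi") %in% p))
    stop("`year`/`other_psi` are dynamics-block covariates only")
  out <- list(psi = as.character(psi),
              gamma = if (dynamic) as.character(gamma),
              phi = if (dynamic) as.character(phi),
              p = as.character(p), dynamic = dynamic)
  class(out) <- "occu_spec"
  out
}

block_formula <- function(v) if (length(v) == 0) "1" else paste(v, collapse = " + ")

#' @export
format.occu_spec <- function(x, ...) {
  if (x$dynamic)
    paste0("~", block_formula(x$psi), " ~", block_formula(x$gamma),
           " ~", block_formula(x$phi), " ~", block_formula(x$p))
  else
    paste0("~", block_formula(x$psi), " ~", block_formula(x$p))
}

#' @export
print.occu_spec <- function(x, ...) {
  cat(if (x$dynamic) "Dynamic occupancy model spec:\n" else
    "Single-season occupancy model spec:\n")
  cat(" ", format(x), "\n")
  invisible(x)
}

# drop one covariate from one block; errors if absent
spec_drop <- function(spec, block, name) {
  v <- spec[[block]]
  if (!(name %in% v)) stop("`", name, "` not in block `", block, "`")
  spec[[block]] <- setdiff(v, name)
  spec
}

# ---- internal design machinery ------------------------------------------

# per-block coefficient names given the data dimensions; canonical order is
# intercept, plain covariates (as given), year offsets, other_psi slope
block_parnames <- function(names, block, n_years) {
  plain <- setdiff(names, c("year", "other_psi"))
  out <- c("(Intercept)", plain)
  if ("year" %in% names && n_years >= 3)
    out <- c(out, paste0("year", 2:(n_years - 1)))
  if ("other_psi" %in% names) out <- c(out, "other_psi")
  paste0(block, ".", out)
}

spec_parnames <- function(spec, n_years) {
  if (spec$dynamic)
    c(block_parnames(spec$psi, "psi", n_years),
      block_parnames(spec$gamma, "gamma", n_years),
      block_parnames(spec$phi, "phi", n_years),
      block_parnames(spec$p, "p", n_years))
  else
    c(block_parnames(spec$psi, "psi", n_years),
      block_parnames(spec$p, "p", n_years))
}

site_design <- function(cov, names) {
  plain <- setdiff(names, c("year", "other_psi"))
  miss <- setdiff(plain, colnames(cov))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = rep(1, nrow(cov)))
  if (length(plain)) X <- cbind(X, as.matrix(cov[plain]))
  if (any(!is.finite(X))) stop("non-finite covariate values")
  X
}

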