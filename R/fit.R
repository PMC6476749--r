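#' Fit an occupancy model by maximum likelihood
#'
#' Maximises the marginal occupancy likelihood ([occu_loglik()]) by
#' quasi-Newton (BFGS) iteration, for either a single-season model (T = 1,
#' spec without dynamics blocks) or a dynamic model (T >= 2, spec with
#' colonization and persistence blocks).  Standard errors come from the
#' inverse of the numerical Hessian at the optimum.
#'
#' Starting values default to 0 for every coefficient (all probabilities
#' 0.5); on non-convergence a small restart grid (+-1 on the block
#' intercepts) is tried and the best converged solution kept.
#' Non-convergence is flagged on the returned object, never thrown.
#' Estimates pushed to the boundary (fitted probabilities within 1e-6 of
#' 0 or 1) are flagged, and a singular Hessian marks the standard errors
#' unavailable rather than failing.
#'
#' @param det a [detection_history()].
#' @param cov a `site_covariates` data frame, one row per site in `det`
#'   order (scale covariates beforehand with [scale_covariates()]).
#' @param spec an [occu_spec()].
#' @param other_psi optional `n_sites x n_years` matrix of the other
#'   species' predicted occupancy (needed when the spec names `other_psi`).
#' @param start optional starting coefficient vector.
#' @param control optimizer settings passed to [stats::optim()]; defaults
#'   `maxit = 1000`, `reltol = 1e-10`.
#' @param hessian compute the numerical Hessian for standard errors.
#' @return an object of class `occu_fit` with components `coef`, `se`,
#'   `vcov`, `logLik`, `AIC`, `K`, `converged`, `boundary`, `se_ok`, the
#'   spec, and the data used (for prediction, simulation and GOF).
#' @seealso [predict.occu_fit()], [simulate.occu_fit()], [occu_gof()],
#'   [backward_stepwise()]
#' @export
occu_fit <- function(det, cov, spec, other_psi = NULL, start = NULL,
                     control = list(), hessian = TRUE) {
  if (spec$dynamic && det$n_years < 2)
    stop("dynamic model needs >= 2 years; use a single-season spec (see slice_year)")
  parnames <- spec_parnames(spec, det$n_years)
  K <- length(parnames)
  if (K >= det$n_sites)
    warning("as many parameters as sites; the design is likely unidentifiable")
  ctrl <- utils::modifyList(list(maxit = 1000, reltol = 1e-10), control)
  fr <- build_frame(det, cov, spec, other_psi)
  negll <- function(par) -frame_loglik(par, fr)
  neggr <- function(par) -frame_grad(par, fr)
  run <- function(p0) {
    tryCatch(stats::optim(p0, negll, neggr, method = "BFGS", control = ctrl),
             error = function(e) NULL)
  }
  p0 <- start %||% rep(0, K)
  if (length(p0) != K) stop("`start` must have length ", K)
  opt <- run(p0)
  if (is.null(opt) || opt$convergence != 0) {
    ints <- grep("\\(Intercept\\)$", parnames)
    for (s in c(-1, 1)) {
      alt <- p0; alt[ints] <- alt[ints] + s
      cand <- run(alt)
      if (!is.null(cand) && cand$convergence == 0 &&
          (is.null(opt) || cand$value < opt$value)) opt <- cand
    }
  }
  if (is.null(opt)) stop("optimizer failed from all starting values")
  est <- stats::setNames(opt$par, parnames)
  ll <- -opt$value
  vc <- matrix(NA_real_, K, K, dimnames = list(parnames, parnames))
  se <- stats::setNames(rep(NA_real_, K), parnames)
  se_ok <- FALSE
  if (hessian) {
    H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vci <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vci) && all(is.finite(diag(vci))) && all(diag(vci) > 0)) {
        vc[] <- vci
        se[] <- sqrt(diag(vci))
        se_ok <- TRUE
      }
    }
  }
  pr <- spec_probs(est, det, cov, spec, other_psi)
  eps <- 1e-6
  boundary <- any(vapply(pr, function(m) any(m < eps | m > 1 - eps), TRUE))
  out <- list(coef = est, se = se, vcov = vc, se_ok = se_ok,
              logLik = ll, K = K, AIC = -2 * ll + 2 * K,
              converged = opt$convergence == 0, boundary = boundary,
              optim = opt[c("convergence", "counts", "message")],
              spec = spec, det = det, cov = cov, other_psi = other_psi,
              call = match.call())
  class(out) <- "occu_fit"
  out
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(if (x$spec$dynamic) "Dynamic occupancy model fit\n"
      else "Single-season occupancy model fit\n")
  cat(" ", format(x$spec), "\n")
  cat(sprintf("  logLik = %.3f, K = %d, AIC = %.2f\n", x$logLik, x$K, x$AIC))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (x$boundary) cat("  note: estimate on the probability boundary\n")
  if (!x$se_ok) cat("  note: Hessian singular; standard errors unavailable\n")
  invisible(x)
}

#' @export
summary.occu_fit <- function(object, ...) {
  z <- object$coef / object$se
  tab <- data.frame(Estimate = object$coef, `Std. Error` = object$se,
                    `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)),
                    check.names = FALSE)
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.occu_fit"
  out
}

#' @export
print.summary.occu_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (logit scale):\n")
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE, na.print = "NA")
  invisible(x)
}

#' @export
coef.occu_fit <- function(object, ...) object$coef

#' @export
vcov.occu_fit <- function(object, ...) object$vcov

#' @export
logLik.occu_fit <- function(object, ...) {
  structure(object$logLik, df = object$K, nobs = object$det$n_sites,
            class = "logLik")
}

#' Predicted occupancy and detection probabilities
#'
#' `type = "psi"` returns initial (or single-season) occupancy for each
#' site; `type = "projected"` returns the unconditional yearly occupancy
#' matrix `psi[i, t]` obtained from the recursion
#' `psi_t = phi_t * psi_{t-1} + gamma_t * (1 - psi_{t-1})`;
#' `type = "p"` returns the per-occasion detection probability array.
#'
#' @param object an [occu_fit()].
#' @param newdata optional `site_covariates` table for new sites (must be
#'   standardised with the training scaling record, see [apply_scaling()]);
#'   only `type = "psi"` supports new sites.
#' @param type one of `"psi"`, `"projected"`, `"p"`.
#' @param ... unused.
#' @return numeric vector (`psi`), matrix (`projected`) or array (`p`).
#' @export
predict.occu_fit <- function(object, newdata = NULL,
                             type = c("psi", "projected", "p"), ...) {
  type <- match.arg(type)
  if (type == "psi") {
    cov <- newdata %||% object$cov
    X <- site_design(cov, object$spec$psi)
    bl <- sub("\\..*$", "", names(object$coef))
    return(as.vector(stats::plogis(X %*% object$coef[bl == "psi"])))
  }
  if (!is.null(newdata)) stop("`newdata` only supported for type = \"psi\"")
  pr <- spec_probs(object$coef, object$det, object$cov, object$spec,
                   object$other_psi)
  if (type == "p") return(pr$p)
  if (!object$spec$dynamic)
    stop("projection requires a dynamic model")
  T <- object$det$n_years
  psi <- matrix(NA_real_, object$det$n_sites, T)
  psi[, 1] <- pr$psi1
  for (t in 2:T)
    psi[, t] <- pr$phi[, t - 1] * psi[, t - 1] +
      pr$gamma[, t - 1] * (1 - psi[, t - 1])
  psi
}

#' @rdname predict.occu_fit
#' @param fit an [occu_fit()] for a dynamic model.
#' @export
project_psi <- function(fit) predict(fit, type = "projected")

#' Simulate detection histories from a fitted model
#'
#' Parametric simulation under the fitted coefficients, reusing the
#' original design: same sites, effort and missingness pattern (and, for a
#' conditional two-species model, the same `other_psi` surface).  This is
#' the generator behind the parametric-bootstrap goodness-of-fit test.
#'
#' @param object an [occu_fit()].
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `nsim` [detection_history()] objects.
#' @export
simulate.occu_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  det <- object$det
  pr <- spec_probs(object$coef, det, object$cov, object$spec, object$other_psi)
  n <- det$n_sites; T <- det$n_years; J <- det$n_secondary
  lapply(seq_len(nsim), function(s) {
    Z <- matrix(0L, n, T)
    Z[, 1] <- stats::rbinom(n, 1, pr$psi1)
    if (T >= 2) for (t in 2:T) {
      pt <- ifelse(Z[, t - 1] == 1, pr$phi[, t - 1], pr$gamma[, t - 1])
      Z[, t] <- stats::rbinom(n, 1, pt)
    }
    y <- array(stats::rbinom(n * T * J, 1,
                             as.vector(pr$p) * as.vector(array(Z, c(n, T, J)))),
               c(n, T, J))
    y[is.na(det$y)] <- NA
    detection_history(y, det$effort, species = det$species,
                      sites = det$sites, years = det$years)
  })
}

#' @export
fitted.occu_fit <- function(object, ...) {
  if (object$spec$dynamic) predict(object, type = "projected")
  else predict(object, type = "psi")
}

#' Pearson residuals on the occasion scale
#'
#' Residuals `(y - m) / sqrt(m (1 - m))` where `m = psi_hat[i, t] *
#' p_hat[i, t, j]` is the marginal probability of a detection at the
#' occasion; `NA` at unobserved occasions.
#'
#' @param object an [occu_fit()].
#' @param ... unused.
#' @return array shaped like `object$det$y`.
#' @export
residuals.occu_fit <- function(object, ...) {
  det <- object$det
  psi <- if (object$spec$dynamic) predict(object, type = "projected")
         else matrix(predict(object, type = "psi"), det$n_sites, 1)
  p <- predict(object, type = "p")
  m <- array(psi, dim(det$y)) * p
  (det$y - m) / sqrt(m * (1 - m))
}

#' @export
plot.occu_fit <- function(x, ...) {
  psi <- fitted(x)
  if (is.matrix(psi)) {
    graphics::boxplot(psi, names = x$det$years, xlab = "year",
                      ylab = expression(hat(psi)), ylim = c(0, 1),
                      main = "Fitted yearly occupancy", ...)
  } else {
    graphics::hist(psi, xlab = expression(hat(psi)), xlim = c(0, 1),
                   main = "Fitted occupancy", ...)
  }
  invisible(x)
}
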