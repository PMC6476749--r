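# Marginal likelihoods for single-season and dynamic occupancy models.
#
# Latent occupancy Z is never observed; the likelihood marginalises over it.
# Single season: L_i = psi_i * prod_j p^y (1-p)^(1-y) + (1-psi_i) * I(all y = 0).
# Dynamic: forward recursion over the two latent states with transition
# matrix [[phi, 1-phi], [gamma, 1-gamma]] between primary periods.  All
# log-likelihood products are accumulated on the log scale (log-sum-exp) so
# extreme detection probabilities cannot underflow.  The analytic gradient
# uses the scaled forward-backward (Baum-Welch) posteriors: state posterior
# gamma_t(s) and transition posterior xi_t(a, b) give the score of each
# logit-linear block directly.

# precomputed design structures shared by every likelihood/gradient call
build_frame <- function(det, cov, spec, other_psi = NULL) {
  n <- det$n_sites; T <- det$n_years; J <- det$n_secondary
  if (!is.null(other_psi)) {
    other_psi <- as.matrix(other_psi)
    if (nrow(other_psi) != n || ncol(other_psi) < T - 1)
      stop("`other_psi` must be n_sites x n_years (origin years 1..T-1 are used)")
  } else if (spec$dynamic &&
             "other_psi" %in% c(spec$gamma, spec$phi)) {
    stop("`other_psi` required by the dynamics blocks")
  }
  obs <- !is.na(det$y)
  y0 <- det$y; y0[!obs] <- 0
  obsn <- array(as.numeric(obs), dim(obs))
  parnames <- spec_parnames(spec, T)
  blocks <- sub("\\..*$", "", parnames)
  # detection design: one n x T x J array per coefficient
  pX <- list(array(1, c(n, T, J)))
  for (nm in spec$p) {
    pX[[length(pX) + 1L]] <- if (nm == "effort") {
      e <- det$effort; e[!obs] <- 0; e
    } else {
      if (is.null(cov[[nm]])) stop("unknown covariate: ", nm)
      array(cov[[nm]], c(n, T, J))
    }
  }
  fr <- list(n = n, T = T, J = J, y0 = y0, obsn = obsn,
             any_det = rowSums(obsn * y0, dims = 2) > 0,
             Xpsi = site_design(cov, spec$psi), pX = pX,
             parnames = parnames, blocks = blocks, spec = spec,
             other_psi = other_psi)
  if (spec$dynamic) {
    fr$Xg <- site_design(cov, setdiff(spec$gamma, c("year", "other_psi")))
    fr$Xf <- site_design(cov, setdiff(spec$phi, c("year", "other_psi")))
    fr$g_year <- "year" %in% spec$gamma && T >= 3
    fr$f_year <- "year" %in% spec$phi && T >= 3
    fr$g_opsi <- "other_psi" %in% spec$gamma
    fr$f_opsi <- "other_psi" %in% spec$phi
  }
  fr
}

# linear predictors (logit scale) from a frame
frame_etas <- function(par, fr) {
  if (length(par) != length(fr$parnames))
    stop("parameter vector length ", length(par), " != expected ",
         length(fr$parnames))
  b <- split(par, factor(fr$blocks, levels = unique(fr$blocks)))
  eta_p <- 0
  for (k in seq_along(fr$pX)) eta_p <- eta_p + b$p[k] * fr$pX[[k]]
  out <- list(psi = as.vector(fr$Xpsi %*% b$psi), p = eta_p)
  trans <- function(beta, X, yearly, opsi) {
    eta <- matrix(as.vector(X %*% beta[seq_len(ncol(X))]), fr$n, fr$T - 1)
    pos <- ncol(X)
    if (yearly) {
      eta <- sweep(eta, 2, c(0, beta[pos + seq_len(fr$T - 2)]), "+")
      pos <- pos + fr$T - 2
    }
    if (opsi)
      eta <- eta + beta[pos + 1] *
        fr$other_psi[, seq_len(fr$T - 1), drop = FALSE]
    eta
  }
  if (fr$spec$dynamic) {
    out$gamma <- trans(b$gamma, fr$Xg, fr$g_year, fr$g_opsi)
    out$phi <- trans(b$phi, fr$Xf, fr$f_year, fr$f_opsi)
  }
  out
}

# log emissions per site-year: under occupancy (le1) and absence (le0);
# an all-missing site-year is uninformative (le1 = le0 = 0)
frame_emissions <- function(eta_p, fr) {
  lp <- stats::plogis(eta_p, log.p = TRUE)
  l1p <- stats::plogis(-eta_p, log.p = TRUE)
  le1 <- rowSums(fr$obsn * (fr$y0 * lp + (1 - fr$y0) * l1p), dims = 2)
  le0 <- ifelse(fr$any_det, -Inf, 0)
  list(le1 = le1, le0 = le0)
}

frame_loglik <- function(par, fr, by_site = FALSE) {
  eta <- frame_etas(par, fr)
  em <- frame_emissions(eta$p, fr)
  lpsi <- stats::plogis(eta$psi, log.p = TRUE)
  l1mpsi <- stats::plogis(-eta$psi, log.p = TRUE)
  if (!fr$spec$dynamic) {
    ll <- logsumexp2(lpsi + em$le1[, 1], l1mpsi + em$le0[, 1])
  } else {
    la1 <- lpsi + em$le1[, 1]
    la0 <- l1mpsi + em$le0[, 1]
    for (t in 2:fr$T) {
      lph <- stats::plogis(eta$phi[, t - 1], log.p = TRUE)
      l1ph <- stats::plogis(-eta$phi[, t - 1], log.p = TRUE)
      lga <- stats::plogis(eta$gamma[, t - 1], log.p = TRUE)
      l1ga <- stats::plogis(-eta$gamma[, t - 1], log.p = TRUE)
      b1 <- logsumexp2(la1 + lph, la0 + lga) + em$le1[, t]
      b0 <- logsumexp2(la1 + l1ph, la0 + l1ga) + em$le0[, t]
      la1 <- b1; la0 <- b0
    }
    ll <- logsumexp2(la1, la0)
  }
  if (any(is.nan(ll)))
    stop("non-finite likelihood at site(s) ",
         paste(utils::head(which(is.nan(ll)), 5), collapse = ", "))
  if (by_site) ll else sum(ll)
}

# analytic score vector; same parameter order as frame_loglik
frame_grad <- function(par, fr) {
  n <- fr$n; T <- fr$T
  eta <- frame_etas(par, fr)
  psi <- stats::plogis(eta$psi)
  p <- stats::plogis(eta$p)
  em <- frame_emissions(eta$p, fr)
  e1 <- exp(em$le1); e0 <- exp(em$le0)        # n x T, in (0, 1]
  tiny <- 1e-300
  if (!fr$spec$dynamic) {
    tot <- pmax(psi * e1[, 1] + (1 - psi) * e0[, 1], tiny)
    post1 <- psi * e1[, 1] / tot              # P(occupied | y)
    g_psi <- as.vector(crossprod(fr$Xpsi, post1 - psi))
    w <- post1 * fr$obsn[, 1, ] * (fr$y0[, 1, ] - p[, 1, ])
    g_p <- vapply(fr$pX, function(X) sum(w * X[, 1, ]), numeric(1))
    return(stats::setNames(c(g_psi, g_p), fr$parnames))
  }
  phi <- stats::plogis(eta$phi); gam <- stats::plogis(eta$gamma)
  # scaled forward: ahat[, s, t] = P(Z_t = s | y_1..t)
  ahat1 <- matrix(0, n, T); ahat0 <- matrix(0, n, T)
  a1 <- psi * e1[, 1]; a0 <- (1 - psi) * e0[, 1]
  s <- pmax(a1 + a0, tiny)
  ahat1[, 1] <- a1 / s; ahat0[, 1] <- a0 / s
  for (t in 2:T) {
    a1 <- (ahat1[, t - 1] * phi[, t - 1] + ahat0[, t - 1] * gam[, t - 1]) * e1[, t]
    a0 <- (ahat1[, t - 1] * (1 - phi[, t - 1]) +
             ahat0[, t - 1] * (1 - gam[, t - 1])) * e0[, t]
    s <- pmax(a1 + a0, tiny)
    ahat1[, t] <- a1 / s; ahat0[, t] <- a0 / s
  }
  # scaled backward: bt[, s, t] proportional to P(y_{t+1..T} | Z_t = s)
  bt1 <- matrix(0, n, T); bt0 <- matrix(0, n, T)
  bt1[, T] <- 1; bt0[, T] <- 1
  for (t in (T - 1):1) {
    b1 <- phi[, t] * e1[, t + 1] * bt1[, t + 1] +
      (1 - phi[, t]) * e0[, t + 1] * bt0[, t + 1]
    b0 <- gam[, t] * e1[, t + 1] * bt1[, t + 1] +
      (1 - gam[, t]) * e0[, t + 1] * bt0[, t + 1]
    s <- pmax(b1 + b0, tiny)
    bt1[, t] <- b1 / s; bt0[, t] <- b0 / s
  }
  # state posteriors P(Z_t = s | all y)
  post1 <- ahat1 * bt1
  post0 <- ahat0 * bt0
  s <- pmax(post1 + post0, tiny)
  post1 <- post1 / s; post0 <- post0 / s
  # transition posteriors xi_t(a, b), normalised per site and transition
  g_phi_eta <- matrix(0, n, T - 1); g_gam_eta <- matrix(0, n, T - 1)
  for (t in 2:T) {
    x11 <- ahat1[, t - 1] * phi[, t - 1] * e1[, t] * bt1[, t]
    x10 <- ahat1[, t - 1] * (1 - phi[, t - 1]) * e0[, t] * bt0[, t]
    x01 <- ahat0[, t - 1] * gam[, t - 1] * e1[, t] * bt1[, t]
    x00 <- ahat0[, t - 1] * (1 - gam[, t - 1]) * e0[, t] * bt0[, t]
    s <- pmax(x11 + x10 + x01 + x00, tiny)
    g_phi_eta[, t - 1] <- (x11 * (1 - phi[, t - 1]) - x10 * phi[, t - 1]) / s
    g_gam_eta[, t - 1] <- (x01 * (1 - gam[, t - 1]) - x00 * gam[, t - 1]) / s
  }
  g_psi <- as.vector(crossprod(fr$Xpsi, post1[, 1] - psi))
  trans_grad <- function(g_eta, X, yearly, opsi) {
    g <- as.vector(crossprod(X, rowSums(g_eta)))
    if (yearly) g <- c(g, colSums(g_eta)[-1])
    if (opsi)
      g <- c(g, sum(g_eta * fr$other_psi[, seq_len(T - 1), drop = FALSE]))
    g
  }
  g_gam <- trans_grad(g_gam_eta, fr$Xg, fr$g_year, fr$g_opsi)
  g_phi <- trans_grad(g_phi_eta, fr$Xf, fr$f_year, fr$f_opsi)
  w <- array(post1, c(n, T, fr$J)) * fr$obsn * (fr$y0 - p)
  g_p <- vapply(fr$pX, function(X) sum(w * X), numeric(1))
  stats::setNames(c(g_psi, g_gam, g_phi, g_p), fr$parnames)
}

#' Occupancy model log-likelihood
#'
#' Evaluates the marginal log-likelihood of a coefficient vector for a
#' single-season or dynamic occupancy model.  Exposed mainly for testing
#' and profiling; [occu_fit()] maximises it.
#'
#' @param par coefficient vector in the block order given by the spec
#'   (initial occupancy, colonization, persistence, detection; intercept
#'   first within each block).
#' @param det a [detection_history()].
#' @param cov a `site_covariates` data frame aligned with `det` rows.
#' @param spec an [occu_spec()].
#' @param other_psi optional `n_sites x n_years` matrix of the other
#'   species' occupancy probabilities (origin-year columns 1..T-1 enter the
#'   dynamics blocks when the spec names `other_psi`).
#' @param by_site return the per-site log-likelihood vector instead of the
#'   sum.
#' @return the log-likelihood (scalar, or per-site vector).
#' @export
occu_loglik <- function(par, det, cov, spec, other_psi = NULL,
                        by_site = FALSE) {
  if (spec$dynamic && det$n_years < 2)
    stop("dynamic model needs >= 2 primary periods; use a single-season spec")
  if (!spec$dynamic && det$n_years != 1)
    stop("single-season likelihood takes a one-year history; see slice_year()")
  if (det$n_sites == 0) stop("empty site set")
  frame_loglik(par, build_frame(det, cov, spec, other_psi), by_site = by_site)
}

# probability-scale parameter arrays for a coefficient vector
spec_probs <- function(par, det, cov, spec, other_psi = NULL) {
  eta <- frame_etas(par, build_frame(det, cov, spec, other_psi))
  out <- list(psi1 = stats::plogis(eta$psi), p = stats::plogis(eta$p))
  if (spec$dynamic) {
    out$phi <- stats::plogis(eta$phi)
    out$gamma <- stats::plogis(eta$gamma)
  }
  out
}
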