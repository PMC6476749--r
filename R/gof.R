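# MacKenzie-Bailey chi-square goodness of fit.
#
# Sites are grouped into cohorts sharing a missingness pattern.  Within a
# cohort the test compares, for each detection history actually observed,
# its observed frequency O_h with its expected frequency E_h under the
# fitted model (computed exactly by the same forward marginalisation the
# likelihood uses), via chi-square = sum_h (O_h - E_h)^2 / E_h.  All
# never-observed histories form one remainder cell with O = 0 and
# E = cohort size - sum(E_h) (their probabilities sum to the complement),
# contributing E_remainder to the statistic; expected counts therefore
# always sum to the cohort size.  The dynamic extension evaluates full
# multi-year history probabilities through the transition recursion.

chisq_stat <- function(O, E) {
  keep <- E > 0
  sum((O[keep] - E[keep])^2 / E[keep])
}

# P(history) for each site, for one fixed history ymat (T x J, NA = not
# observed); vectorised over sites via the forward recursion
history_prob <- function(pr, sites, ymat, dynamic) {
  T <- nrow(ymat); J <- ncol(ymat)
  ns <- length(sites)
  e1 <- matrix(1, ns, T); e0 <- matrix(1, ns, T)
  for (t in seq_len(T)) {
    jj <- which(!is.na(ymat[t, ]))
    if (!length(jj)) next
    yv <- ymat[t, jj]
    pm <- matrix(pr$p[sites, t, jj], ns, length(jj))
    e1[, t] <- apply(pm^rep(yv, each = ns) *
                       (1 - pm)^rep(1 - yv, each = ns), 1, prod)
    e0[, t] <- as.numeric(sum(yv) == 0)
  }
  a1 <- pr$psi1[sites] * e1[, 1]
  a0 <- (1 - pr$psi1[sites]) * e0[, 1]
  if (dynamic && T >= 2) for (t in 2:T) {
    phi <- pr$phi[sites, t - 1]; gam <- pr$gamma[sites, t - 1]
    b1 <- (a1 * phi + a0 * gam) * e1[, t]
    b0 <- (a1 * (1 - phi) + a0 * (1 - gam)) * e0[, t]
    a1 <- b1; a0 <- b0
  }
  a1 + a0
}

#' MacKenzie-Bailey chi-square statistic
#'
#' Computes the observed chi-square discrepancy between the detection
#' histories and their expected frequencies under a fitted single-season
#' or dynamic occupancy model (see the file-level notes on cohorting and
#' the remainder cell for never-observed histories).
#'
#' @param fit an [occu_fit()].
#' @param det detection history to evaluate (default: the fitted data;
#'   pass a simulated replicate for bootstrapping).
#' @param pool additionally pool observed-history cells with expected
#'   count below this value into the remainder cell (default 0: no extra
#'   pooling, every observed history is its own cell).
#' @param details also return the per-cohort observed/expected tables.
#' @return the chi-square value, or (with `details = TRUE`) a list with
#'   `chisq` and `cohorts`.
#' @export
mb_chisq <- function(fit, det = fit$det, pool = 0, details = FALSE) {
  pr <- spec_probs(fit$coef, det, fit$cov, fit$spec, fit$other_psi)
  obs <- !is.na(det$y)
  flat <- matrix(det$y, det$n_sites)                 # sites x (T*J)
  pat_key <- apply(matrix(obs, det$n_sites), 1, paste, collapse = "")
  hist_key <- apply(flat, 1, paste, collapse = ",")
  chisq <- 0
  cohorts <- list()
  for (key in unique(pat_key)) {
    sites <- which(pat_key == key)
    if (!any(obs[sites[1], , ])) next                # no deployment at all
    uh <- unique(hist_key[sites])
    O <- as.numeric(table(factor(hist_key[sites], levels = uh)))
    E <- vapply(uh, function(h) {
      i <- sites[match(h, hist_key[sites])]
      ymat <- matrix(det$y[i, , ], det$n_years, det$n_secondary)
      sum(history_prob(pr, sites, ymat, fit$spec$dynamic))
    }, numeric(1))
    n_coh <- length(sites)
    keep <- E >= pool
    O_rem <- sum(O[!keep])
    E_rem <- (n_coh - sum(E[keep]))                  # all unobserved + pooled
    stat <- chisq_stat(O[keep], E[keep]) +
      if (E_rem > 0) (O_rem - E_rem)^2 / E_rem else 0
    chisq <- chisq + stat
    if (details)
      cohorts[[length(cohorts) + 1L]] <-
        list(n_sites = n_coh, histories = uh[keep], O = O[keep], E = E[keep],
             O_remainder = O_rem, E_remainder = E_rem, chisq = stat)
  }
  if (details) list(chisq = chisq, cohorts = cohorts) else chisq
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' Simulates `n_boot` datasets from the fitted model on the original design
#' ([simulate.occu_fit()]), refits the model to each (warm-started at the
#' original MLE), and compares the observed [mb_chisq()] statistic with the
#' bootstrap distribution.  The p-value is the proportion of bootstrap
#' statistics at least as large as the observed one, and the variance
#' inflation factor is `c_hat = observed / mean(bootstrap)`.  Replicates
#' whose refit fails are dropped and counted; the result is flagged when
#' more than 10 percent fail.  `c_hat < 1` (underdispersion) is reported
#' as-is with a note, never truncated.
#'
#' @param fit an [occu_fit()].
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed integer seed governing all simulation.
#' @param pool pooling threshold forwarded to [mb_chisq()].
#' @return an object of class `occu_gof`: observed statistic, bootstrap
#'   sample, `p_value`, `c_hat`, failure count and seed.
#' @export
occu_gof <- function(fit, n_boot = 200, seed = NULL, pool = 0) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  observed <- mb_chisq(fit, pool = pool)
  sims <- simulate(fit, nsim = n_boot)
  boot <- rep(NA_real_, n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    rf <- tryCatch({
      f <- occu_fit(sims[[b]], fit$cov, fit$spec, other_psi = fit$other_psi,
                    start = fit$coef, hessian = FALSE)
      if (!f$converged) NULL else f
    }, error = function(e) NULL)
    if (is.null(rf)) { failed <- failed + 1L; next }
    boot[b] <- mb_chisq(rf, det = sims[[b]], pool = pool)
  }
  boot <- boot[!is.na(boot)]
  out <- list(observed = observed, boot = boot,
              p_value = mean(boot >= observed),
              c_hat = observed / mean(boot),
              n_boot = n_boot, n_failed = failed,
              flagged = failed > 0.1 * n_boot, seed = seed)
  class(out) <- "occu_gof"
  out
}

#' @export
print.occu_gof <- function(x, ...) {
  cat("Parametric-bootstrap goodness of fit (MacKenzie-Bailey chi-square)\n")
  cat(sprintf("  observed chi-square = %.2f, bootstrap n = %d, p = %.3f\n",
              x$observed, length(x$boot), x$p_value))
  cat(sprintf("  c-hat = %.2f%s\n", x$c_hat,
              if (x$c_hat < 1) " (underdispersion; possible lack of fit)"
              else if (x$c_hat > 1) " (overdispersion)" else ""))
  if (x$n_failed > 0)
    cat(sprintf("  %d refit(s) failed%s\n", x$n_failed,
                if (x$flagged) " [>10% failure: result flagged]" else ""))
  invisible(x)
}
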