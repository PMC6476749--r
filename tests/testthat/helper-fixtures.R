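# small in-code fixtures shared across test files

# detection history with given per-site-year secondary vectors
toy_history <- function(ylist, effort = 14, species = "sp") {
  # ylist: list over sites of matrix T x J (or vector J for T = 1)
  arrs <- lapply(ylist, function(m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m
  })
  T <- nrow(arrs[[1]]); J <- ncol(arrs[[1]])
  y <- array(NA_real_, c(length(arrs), T, J))
  for (i in seq_along(arrs)) y[i, , ] <- arrs[[i]]
  eff <- array(effort, dim(y))
  eff[is.na(y)] <- NA
  detection_history(y, eff, species = species)
}

# intercept-only covariates for n sites
null_cov <- function(n) as_site_covariates(data.frame(site = seq_len(n)))

# log of a Bernoulli(plogis(eta)) mass, full precision at extreme eta
lbern <- function(y, eta) ifelse(y == 1, plogis(eta, log.p = TRUE),
                                 plogis(-eta, log.p = TRUE))

# brute-force single-season site log-likelihood: marginalise Z by hand;
# logit-scale inputs keep the oracle exact when probabilities approach 0/1
enum_single_site_loglik <- function(eta_psi, eta_p, y) {
  obs <- !is.na(y)
  l1 <- plogis(eta_psi, log.p = TRUE) + sum(lbern(y[obs], eta_p[obs]))
  l0 <- plogis(-eta_psi, log.p = TRUE) +
    if (all(y[obs] == 0)) 0 else -Inf
  m <- max(l1, l0)
  m + log(exp(l1 - m) + exp(l0 - m))
}

# brute-force dynamic site log-likelihood: enumerate all 2^T latent paths
# (eta_phi, eta_gam: length T - 1; eta_p, y: T x J)
enum_dynamic_site_loglik <- function(eta_psi, eta_phi, eta_gam, eta_p, y) {
  T <- nrow(y)
  paths <- as.matrix(expand.grid(rep(list(0:1), T)))
  lps <- apply(paths, 1, function(z) {
    lp <- lbern(z[1], eta_psi)
    if (T >= 2) for (t in 2:T) {
      lp <- lp + if (z[t - 1] == 1) lbern(z[t], eta_phi[t - 1])
                 else lbern(z[t], eta_gam[t - 1])
    }
    for (t in seq_len(T)) {
      obs <- !is.na(y[t, ])
      if (!any(obs)) next
      lp <- lp + if (z[t] == 1) sum(lbern(y[t, obs], eta_p[t, obs]))
                 else if (all(y[t, obs] == 0)) 0 else -Inf
    }
    lp
  })
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

# probability-scale convenience wrapper for moderate parameter values
enum_dynamic_site_lik <- function(psi1, phi, gam, p, y) {
  exp(enum_dynamic_site_loglik(qlogis(psi1), qlogis(phi), qlogis(gam),
                               qlogis(p), y))
}

# all binary histories of length m as rows
all_histories <- function(m) as.matrix(expand.grid(rep(list(0:1), m)))
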