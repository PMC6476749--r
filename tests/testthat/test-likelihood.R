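# psi = p = 0.5 closed forms: logit 0 everywhere
par0 <- c(0, 0)   # psi intercept, p intercept

test_that("single-season likelihood matches closed forms", {
  spec <- occu_spec(psi = character(0), p = character(0))
  d <- toy_history(list(c(1, 0)))
  ll <- occu_loglik(par0, d, null_cov(1), spec)
  expect_equal(ll, log(0.5 * 0.5 * 0.5), tolerance = 1e-12)  # 0.125

  d2 <- toy_history(list(c(0, 0)))
  ll2 <- occu_loglik(par0, d2, null_cov(1), spec)
  expect_equal(ll2, log(0.5 * 0.25 + 0.5), tolerance = 1e-12)  # 0.625
})

test_that("single-season site likelihoods sum to 1 over all histories", {
  spec <- occu_spec(psi = character(0), p = character(0))
  for (par in list(c(0, 0), c(0.7, -1.2), c(-2, 2))) {
    for (J in c(2, 4)) {
      H <- all_histories(J)
      tot <- sum(vapply(seq_len(nrow(H)), function(r) {
        d <- toy_history(list(H[r, ]))
        exp(occu_loglik(par, d, null_cov(1), spec))
      }, numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("single-season likelihood agrees with explicit latent-state enumeration", {
  set.seed(101)
  spec <- occu_spec(psi = "x", p = "effort")
  for (rep in 1:5) {
    n <- 20; J <- 4
    cov <- as_site_covariates(data.frame(site = 1:n, x = rnorm(n)))
    eff <- array(sample(5:14, n * J, TRUE), c(n, 1, J))
    y <- array(rbinom(n * J, 1, 0.4), c(n, 1, J))
    y[2, 1, 2] <- NA; eff[2, 1, 2] <- NA   # exercise missingness
    d <- detection_history(y, eff)
    par <- rnorm(4, 0, 0.7)
    ll <- occu_loglik(par, d, cov, spec, by_site = TRUE)
    for (i in seq_len(n)) {
      eta_psi <- par[1] + par[2] * cov$x[i]
      eta_p <- par[3] + par[4] * eff[i, 1, ]
      # absolute scale: relative comparison is ill-posed for logs near 0
      expect_lt(abs(ll[i] - enum_single_site_loglik(eta_psi, eta_p,
                                                    y[i, 1, ])), 1e-12)
    }
  }
})

test_that("dynamic forward recursion equals brute-force path enumeration", {
  set.seed(202)
  spec <- occu_spec(psi = "x", gamma = c("x", "year"), phi = "year",
                    p = "effort")
  n <- 50; T <- 3; J <- 3
  cov <- as_site_covariates(data.frame(site = 1:n, x = rnorm(n)))
  eff <- array(sample(5:14, n * T * J, TRUE), c(n, T, J))
  y <- array(rbinom(n * T * J, 1, 0.4), c(n, T, J))
  y[1, 2, ] <- NA; eff[1, 2, ] <- NA      # a whole missing site-year
  y[3, 1, 2] <- NA; eff[3, 1, 2] <- NA
  d <- detection_history(y, eff)
  for (rep in 1:4) {
    par <- rnorm(9, 0, 0.8)
    ll <- occu_loglik(par, d, cov, spec, by_site = TRUE)
    for (i in c(1, 2, 3, 17, 50)) {
      eta_psi <- par[1] + par[2] * cov$x[i]
      eta_gam <- par[3] + par[4] * cov$x[i] + c(0, par[5])
      eta_phi <- par[6] + c(0, par[7])
      eta_p <- matrix(par[8] + par[9] * eff[i, , ], T, J)
      expect_lt(abs(ll[i] -
                      enum_dynamic_site_loglik(eta_psi, eta_phi, eta_gam,
                                               eta_p,
                                               matrix(y[i, , ], T, J))),
                1e-12)
    }
  }
})

test_that("dynamic history probabilities sum to 1 over all observable histories", {
  spec <- occu_spec(psi = character(0), gamma = character(0),
                    phi = character(0), p = character(0))
  T <- 2; J <- 2
  par <- c(0.3, -0.5, 0.8, -0.2)
  H <- all_histories(T * J)
  tot <- sum(vapply(seq_len(nrow(H)), function(r) {
    d <- toy_history(list(matrix(H[r, ], T, J, byrow = TRUE)))
    exp(occu_loglik(par, d, null_cov(1), spec))
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("deterministic dynamics concentrate on persistence paths", {
  # psi1 = 0.5, phi ~ 1, gamma ~ 0, p ~ 1: histories (1,1) and (0,0) each 0.5
  spec <- occu_spec(psi = character(0), gamma = character(0),
                    phi = character(0), p = character(0))
  par <- c(0, -30, 30, 30)
  d11 <- toy_history(list(matrix(c(1, 1), 2, 1)))
  d00 <- toy_history(list(matrix(c(0, 0), 2, 1)))
  expect_equal(exp(occu_loglik(par, d11, null_cov(1), spec)), 0.5,
               tolerance = 1e-9)
  expect_equal(exp(occu_loglik(par, d00, null_cov(1), spec)), 0.5,
               tolerance = 1e-9)
})

test_that("with phi = gamma the years decouple into single-season products", {
  set.seed(303)
  spec_d <- occu_spec(psi = character(0), gamma = character(0),
                      phi = character(0), p = character(0))
  spec_s <- occu_spec(psi = character(0), p = character(0))
  n <- 15; T <- 3; J <- 3
  y <- array(rbinom(n * T * J, 1, 0.4), c(n, T, J))
  d <- detection_history(y, array(14, c(n, T, J)))
  c_logit <- 0.4; p_logit <- -0.3
  # psi1 set equal to the common phi = gamma value makes every year iid
  ll_dyn <- occu_loglik(c(c_logit, c_logit, c_logit, p_logit), d, null_cov(n),
                        spec_d)
  ll_ind <- sum(vapply(1:T, function(t)
    occu_loglik(c(c_logit, p_logit), slice_year(d, t), null_cov(n), spec_s),
    numeric(1)))
  expect_equal(ll_dyn, ll_ind, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(404)
  study <- simulate_camera_study(sim_config(n_sites = 25), seed = 13)
  covs <- scale_covariates(study$cov)
  spec <- occu_spec(psi = c("DEA", "road"), gamma = c("other_psi", "year"),
                    phi = "year", p = "effort")
  fr <- occudiel:::build_frame(study$det_b, covs, spec, study$psi_a)
  for (rep in 1:3) {
    par <- rnorm(length(occudiel:::spec_parnames(spec, 3)), 0, 0.5)
    g <- occudiel:::frame_grad(par, fr)
    gn <- vapply(seq_along(par), function(k) {
      h <- 1e-6; e <- rep(0, length(par)); e[k] <- h
      (occudiel:::frame_loglik(par + e, fr) -
         occudiel:::frame_loglik(par - e, fr)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(g), gn, tolerance = 1e-5)
  }
})

test_that("likelihood rejects inconsistent inputs", {
  spec <- occu_spec(psi = character(0), p = character(0))
  d <- toy_history(list(matrix(c(1, 0), 2, 1)))   # T = 2
  expect_error(occu_loglik(c(0, 0), d, null_cov(1), spec), "one-year")
  spec_d <- occu_spec(psi = character(0), gamma = character(0),
                      phi = character(0), p = character(0))
  d1 <- toy_history(list(c(1, 0)))
  expect_error(occu_loglik(c(0, 0, 0, 0), d1, null_cov(1), spec_d),
               ">= 2 primary periods")
  expect_error(occu_loglik(c(0), d1, null_cov(1), spec), "length")
})
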