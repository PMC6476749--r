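test_that("intercept-only MLE matches a 2-d grid-search oracle", {
  set.seed(11)
  n <- 150; J <- 4
  z <- rbinom(n, 1, 0.6)
  y <- array(rbinom(n * J, 1, 0.5 * rep(z, J)), c(n, 1, J))
  d <- detection_history(y, array(14, c(n, 1, J)))
  cov <- null_cov(n)
  spec <- occu_spec(psi = character(0), p = character(0))
  fit <- occu_fit(d, cov, spec)
  # coarse-to-fine grid over (psi, p) on the probability scale
  grid_ll <- function(psi, p) {
    det1 <- rowSums(y[, 1, ]); J0 <- J
    sum(log(psi * p^det1 * (1 - p)^(J0 - det1) +
              (1 - psi) * (det1 == 0)))
  }
  ps <- seq(0.01, 0.99, by = 0.0025)
  best <- c(NA, NA); bv <- -Inf
  for (a in ps) {
    v <- vapply(ps, function(b) grid_ll(a, b), numeric(1))
    k <- which.max(v)
    if (v[k] > bv) { bv <- v[k]; best <- c(a, ps[k]) }
  }
  expect_equal(unname(plogis(coef(fit)[1])), best[1], tolerance = 1e-2)
  expect_equal(unname(plogis(coef(fit)[2])), best[2], tolerance = 1e-2)
  expect_gte(fit$logLik, bv - 1e-6)      # MLE at least as good as the grid
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$K)
})

test_that("single-season fit recovers generating parameters", {
  set.seed(21)
  n <- 2000; J <- 4
  z <- rbinom(n, 1, 0.6)
  y <- array(rbinom(n * J, 1, 0.5 * rep(z, J)), c(n, 1, J))
  d <- detection_history(y, array(14, c(n, 1, J)))
  fit <- occu_fit(d, null_cov(n), occu_spec(psi = character(0),
                                            p = character(0)))
  expect_true(fit$converged)
  # 3-se band: a single replicate, so use the 99.7% interval
  expect_lt(abs(coef(fit)[1] - qlogis(0.6)) / fit$se[1], 3)
  expect_lt(abs(coef(fit)[2] - qlogis(0.5)) / fit$se[2], 3)
})

test_that("degenerate all-detected data is flagged as a boundary fit", {
  n <- 30; J <- 3
  d <- detection_history(array(1, c(n, 1, J)), array(14, c(n, 1, J)))
  fit <- occu_fit(d, null_cov(n), occu_spec(psi = character(0),
                                            p = character(0)))
  expect_true(fit$boundary)
  expect_gt(predict(fit, type = "psi")[1], 0.99)
})

test_that("prediction follows the logit-linear structure", {
  set.seed(31)
  study <- simulate_camera_study(sim_config(), seed = 41)
  covs <- scale_covariates(study$cov)
  fit <- occu_fit(slice_year(study$det_a, 1), covs, occu_spec(psi = "DEA"))
  # all-zero covariates give inverse-logit of the intercept
  new0 <- as_site_covariates(data.frame(site = 1, DEA = 0))
  expect_equal(predict(fit, newdata = new0, type = "psi"),
               plogis(unname(coef(fit)[1])))
  # monotone in a covariate with positive estimated coefficient
  grid <- as_site_covariates(data.frame(site = 1:21, DEA = seq(0, 1, 0.05)))
  pr <- predict(fit, newdata = grid, type = "psi")
  if (coef(fit)["psi.DEA"] > 0) expect_true(all(diff(pr) > 0))
  expect_true(all(pr > 0 & pr < 1))
  expect_error(predict(fit, newdata = data.frame(site = 1, wrong = 1)),
               "unknown covariate")
})

test_that("projection has the fixed-point and absorbing properties", {
  study <- simulate_camera_study(sim_config(), seed = 51)
  covs <- scale_covariates(study$cov)
  spec <- occu_spec(psi = "DEA", gamma = character(0), phi = character(0),
                    p = "effort")
  fit <- occu_fit(study$det_b, covs, spec)
  # phi = gamma = c  =>  psi_t = c from year 2 on
  f2 <- fit
  f2$coef[c("gamma.(Intercept)", "phi.(Intercept)")] <- qlogis(0.3)
  pp <- predict(f2, type = "projected")
  expect_equal(unname(pp[, 2]), rep(0.3, nrow(pp)), tolerance = 1e-12)
  expect_equal(unname(pp[, 3]), rep(0.3, nrow(pp)), tolerance = 1e-12)
  # phi = 1, gamma = 0  =>  psi_t = psi_1
  f3 <- fit
  f3$coef["phi.(Intercept)"] <- 40; f3$coef["gamma.(Intercept)"] <- -40
  pp3 <- predict(f3, type = "projected")
  expect_equal(pp3[, 3], pp3[, 1], tolerance = 1e-9)
})

test_that("projection agrees with the simulator's latent occupancy frequency", {
  cfg <- sim_config(n_sites = 10000)
  covs <- scale_covariates(simulate_covariates(cfg, seed = 61))
  Z <- simulate_occupancy_dynamics(cfg, covs, seed = 62)
  # expected occupancy under the generating parameters, per year
  psi <- plogis(cfg$beta_psi1[["(Intercept)"]] + cfg$beta_psi1[["DEA"]] * covs$DEA)
  phi <- plogis(cfg$beta_phi[["(Intercept)"]])
  gam <- plogis(cfg$beta_gamma[["(Intercept)"]])
  for (t in 1:3) {
    if (t > 1) psi <- phi * psi + gam * (1 - psi)
    expect_lt(abs(mean(Z[, t]) - mean(psi)), 0.02)
  }
})

test_that("T = 1 data with a dynamic spec is rejected with direction", {
  d <- toy_history(list(c(1, 0)))
  spec <- occu_spec(psi = character(0), gamma = character(0),
                    phi = character(0), p = character(0))
  expect_error(occu_fit(d, null_cov(1), spec), "single-season")
})

test_that("simulate() respects the fitted design and conditional structure", {
  study <- simulate_camera_study(sim_config(), seed = 71)
  covs <- scale_covariates(study$cov)
  det <- study$det_b
  det$y[5, 2, ] <- NA; det$effort[5, 2, ] <- NA
  spec <- occu_spec(psi = "DEA", gamma = "other_psi", phi = character(0),
                    p = "effort")
  fit <- occu_fit(det, covs, spec, other_psi = study$psi_a)
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_length(sims, 3)
  for (s in sims) {
    expect_identical(is.na(s$y), is.na(det$y))
    expect_identical(s$effort, det$effort)
  }
  # deterministic under seed
  sims2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(sims[[1]]$y, sims2[[1]]$y)
})

test_that("residuals are Pearson residuals at observed occasions", {
  study <- simulate_camera_study(sim_config(), seed = 81)
  covs <- scale_covariates(study$cov)
  fit <- occu_fit(slice_year(study$det_a, 1), covs,
                  occu_spec(psi = "DEA"))
  r <- residuals(fit)
  m <- array(predict(fit, type = "psi"), dim(fit$det$y)) *
    predict(fit, type = "p")
  i <- which(!is.na(fit$det$y))[1]
  expect_equal(r[i], (fit$det$y[i] - m[i]) / sqrt(m[i] * (1 - m[i])))
})
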