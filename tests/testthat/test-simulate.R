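test_that("covariate simulation is seeded and lives on the simplex", {
  cfg <- sim_config()
  a <- simulate_covariates(cfg, seed = 5)
  b <- simulate_covariates(cfg, seed = 5)
  expect_identical(a, b)
  veg <- as.matrix(a[c("DEA", "Evergreen", "Mixed_grassland", "Wetland",
                       "Aspen", "Unsuitable")])
  expect_equal(rowSums(veg), rep(1, nrow(veg)), tolerance = 1e-12)
  expect_true(all(a$road > 0 & a$hydrology > 0 & a$distance > 0))
})

test_that("Dirichlet shares match their closed-form mean", {
  cfg <- sim_config(n_sites = 10000)
  cov <- simulate_covariates(cfg, seed = 6)
  expected <- cfg$veg_alpha[["DEA"]] / sum(cfg$veg_alpha)
  se <- sqrt(expected * (1 - expected) / (sum(cfg$veg_alpha) + 1) / 10000)
  expect_lt(abs(mean(cov$DEA) - expected), 4 * se)
})

test_that("occupancy dynamics honour their limiting regimes", {
  # absorbing dynamics: phi ~ 1, gamma ~ 0 freeze the initial state
  cfg <- sim_config(n_sites = 500,
                    beta_phi = c("(Intercept)" = 20),
                    beta_gamma = c("(Intercept)" = -20))
  cov <- scale_covariates(simulate_covariates(cfg, seed = 7))
  Z <- simulate_occupancy_dynamics(cfg, cov, seed = 8)
  expect_true(all(Z[, 2] == Z[, 1] & Z[, 3] == Z[, 1]))

  # intercept 0, no covariates: half the sites start occupied
  cfg2 <- sim_config(n_sites = 10000, beta_psi1 = c("(Intercept)" = 0))
  Z2 <- simulate_occupancy_dynamics(cfg2, cov[rep(1, 10000), ], seed = 9)
  expect_lt(abs(mean(Z2[, 1]) - 0.5), 0.015)

  # strong negative other-species effect suppresses colonization entirely
  cfg3 <- sim_config(n_sites = 2000,
                     beta_psi1 = c("(Intercept)" = -20),
                     beta_gamma = c("(Intercept)" = 2, other_psi = -40))
  psiA <- matrix(1, 2000, 3)
  Z3 <- simulate_occupancy_dynamics(cfg3, cov[rep(1, 2000), ],
                                    other_psi = psiA, seed = 10)
  expect_equal(sum(Z3), 0)
  expect_error(simulate_occupancy_dynamics(cfg3, cov[rep(1, 2000), ]),
               "other_psi")
})

test_that("detections are conditional on occupancy and monotone in effort", {
  cfg <- sim_config(n_sites = 200)
  Z <- cbind(rep(0:1, 100), rep(0:1, 100), rep(0:1, 100))
  det <- simulate_detections(cfg, Z, seed = 11)
  expect_true(all(det$y[Z[, 1] == 0, 1, ] == 0))

  # near-certain detection when occupied
  cfgc <- sim_config(beta_p = c("(Intercept)" = 20))
  detc <- simulate_detections(cfgc, matrix(1, 64, 3), seed = 12)
  expect_true(all(detc$y == 1))

  # detection frequency rises with effort under a positive effort slope
  cfge <- sim_config(n_sites = 10000, downtime_prob = 0.3,
                     beta_p = c("(Intercept)" = -1, effort = 0.25))
  dete <- simulate_detections(cfge, matrix(1, 10000, 3), seed = 13)
  eff <- as.vector(dete$effort); yy <- as.vector(dete$y)
  bins <- cut(eff, c(-1, 8, 10, 12, 15))
  rates <- tapply(yy, bins, mean)
  expect_true(all(diff(rates) > 0))
})

test_that("activity-time generator obeys concentration limits and the seed", {
  cfg <- sim_config(diel = list(sp = list(mean = pi / 2, kappa = 200,
                                          weight = 1)))
  s <- simulate_activity_times(cfg, "sp", 500, seed = 14)
  # nearly all mass within a tight arc of the component mean
  expect_lt(max(abs(as.numeric(s) - pi / 2)), 0.4)

  cfg2 <- sim_config(diel = list(sp = list(mean = c(pi / 2, 3 * pi / 2),
                                           kappa = c(3, 3),
                                           weight = c(0.5, 0.5))))
  s2 <- simulate_activity_times(cfg2, "sp", 10000, seed = 15)
  x <- as.numeric(s2)
  rbar <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
  expect_lt(rbar, 0.03)                 # antipodal components cancel

  s3 <- simulate_activity_times(cfg2, "sp", 100, seed = 16)
  s4 <- simulate_activity_times(cfg2, "sp", 100, seed = 16)
  expect_identical(as.numeric(s3), as.numeric(s4))
  expect_error(simulate_activity_times(cfg2, "ghost", 10), "no diel mixture")
})

test_that("camera-delay thinning removes only near-coincident events", {
  cfg <- sim_config(thin_delay = TRUE, n_sites = 2,
                    diel = list(sp = list(mean = pi, kappa = 50, weight = 1)))
  s <- simulate_activity_times(cfg, "sp", 2000, seed = 17)
  expect_lt(length(s), 2000)
  expect_gt(length(s), 500)
})

test_that("the full study bundle is reproducible and internally consistent", {
  st1 <- simulate_camera_study(sim_config(), seed = 18)
  st2 <- simulate_camera_study(sim_config(), seed = 18)
  expect_identical(st1$det_b$y, st2$det_b$y)
  expect_identical(as.numeric(st1$times$marten), as.numeric(st2$times$marten))
  expect_identical(dim(st1$psi_a), c(64L, 3L))
  expect_true(all(st1$psi_a > 0 & st1$psi_a < 1))
  # bundle round-trips through the CSV formats
  dir <- tempfile(); write_camera_study(st1, dir)
  back <- read_detection_history(file.path(dir, "det_fisher.csv"), "fisher")
  expect_identical(back$y, st1$det_b$y)
  cov <- read_site_covariates(file.path(dir, "covariates.csv"))
  expect_equal(cov$DEA, st1$cov$DEA, tolerance = 1e-12)
  ts <- read_activity_times(file.path(dir, "timestamps.csv"))
  expect_equal(sort(names(ts)), c("fisher", "marten"))
  # second resolution is the write format's precision
  expect_equal(as.numeric(ts$marten), as.numeric(st1$times$marten),
               tolerance = 2 * pi / 86400 + 1e-9)
})
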