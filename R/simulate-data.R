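#' Configuration for the synthetic camera-trap study generator
#'
#' The generator emulates a winter camera-trap grid study of two
#' interacting forest mustelids: 64 sites on a 2.5 x 2.5 km grid, 3 annual
#' primary periods, 4 two-week secondary periods per year (effort in
#' camera-active days, up to 14), per-period detection probability around
#' 0.5 at typical effort, crepuscular diel activity peaking near 06:00 and
#' 18:00, and an effect of one species' yearly occupancy probability on
#' the other species' colonization.
#'
#' Coefficient vectors are named: `"(Intercept)"` plus covariate-column
#' names for `beta_psi1`; dynamics blocks may also use `"year2"`, ... and
#' `"other_psi"`; `beta_p` uses `"(Intercept)"` and `"effort"`.
#' Vegetation shares are drawn from a Dirichlet whose concentration
#' reflects the study landscape (deciduous-dominated with extensive
#' wetland); road/hydrology densities and distance-to-water are
#' log-normal.
#'
#' @param n_sites,n_years,n_secondary,days_per_period study design.
#' @param beta_psi1,beta_gamma,beta_phi,beta_p generating coefficient
#'   vectors (logit scale).
#' @param veg_alpha Dirichlet concentration over the six vegetation
#'   categories.
#' @param road_lnorm,hydro_lnorm,dist_lnorm `c(meanlog, sdlog)` for the
#'   log-normal density/distance covariates.
#' @param downtime_prob per-day probability a camera is down, thinning
#'   effort below `days_per_period`.
#' @param diel von Mises mixture per species: list of lists with `mean`
#'   (radians), `kappa`, `weight` vectors.
#' @param camera_delay_min minimum minutes between recorded images at a
#'   site (thinning is off by default: `thin_delay = FALSE`).
#' @param thin_delay apply the camera-delay thinning to activity times.
#' @param seed default seed recorded in outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 64, n_years = 3, n_secondary = 4,
                       days_per_period = 14,
                       beta_psi1 = c("(Intercept)" = -1.4, DEA = 3.0),
                       beta_gamma = c("(Intercept)" = -2.0),
                       beta_phi = c("(Intercept)" = 1.0),
                       beta_p = c("(Intercept)" = -1.15, effort = 0.1),
                       veg_alpha = c(DEA = 1.9, Evergreen = 0.4,
                                     Mixed_grassland = 1.0, Wetland = 1.8,
                                     Aspen = 0.5, Unsuitable = 0.6),
                       road_lnorm = c(log(1.2), 0.5),
                       hydro_lnorm = c(log(0.8), 0.5),
                       dist_lnorm = c(log(300), 0.7),
                       downtime_prob = 0.1,
                       diel = list(
                         marten = list(mean = c(pi / 2, 3 * pi / 2),
                                       kappa = c(1.5, 1.5),
                                       weight = c(0.5, 0.5)),
                         fisher = list(mean = c(pi / 2, 3 * pi / 2),
                                       kappa = c(2.5, 2.5),
                                       weight = c(0.35, 0.65))),
                       camera_delay_min = 5, thin_delay = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (sp in names(diel)) {
    w <- diel[[sp]]$weight
    if (abs(sum(w) - 1) > 1e-8) stop("diel weights must sum to 1 (", sp, ")")
    if (any(diel[[sp]]$kappa < 0)) stop("diel kappa must be >= 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate site covariates
#'
#' Vegetation shares per site from a Dirichlet over the six cover
#' categories (rows sum to 1); road/hydrology densities and distance to
#' water from log-normals.  Deterministic under `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (default `cfg$seed`).
#' @return an unscaled `site_covariates` data frame.
#' @export
simulate_covariates <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_sites
  veg <- rdirichlet(n, cfg$veg_alpha)
  colnames(veg) <- names(cfg$veg_alpha)
  df <- data.frame(site = seq_len(n), veg,
                   road = stats::rlnorm(n, cfg$road_lnorm[1], cfg$road_lnorm[2]),
                   hydrology = stats::rlnorm(n, cfg$hydro_lnorm[1], cfg$hydro_lnorm[2]),
                   distance = stats::rlnorm(n, cfg$dist_lnorm[1], cfg$dist_lnorm[2]))
  as_site_covariates(df)
}

# linear predictor from a named generating coefficient vector
gen_eta <- function(beta, cov, n_years = NULL, other_psi = NULL, t = NULL) {
  eta <- rep(beta[["(Intercept)"]], nrow(cov))
  for (nm in setdiff(names(beta), "(Intercept)")) {
    if (nm == "other_psi") {
      eta <- eta + beta[[nm]] * other_psi[, t]
    } else if (grepl("^year[0-9]+$", nm)) {
      if (!is.null(t) && t == as.integer(sub("year", "", nm)))
        eta <- eta + beta[[nm]]
    } else eta <- eta + beta[[nm]] * cov[[nm]]
  }
  eta
}

#' Simulate latent occupancy dynamics
#'
#' `Z[i, 1] ~ Bernoulli(psi1_i)` with logit-linear initial occupancy; for
#' `t >= 2`, occupied sites persist with probability `phi` and empty sites
#' are colonized with probability `gamma`, both logit-linear in year
#' offsets, site covariates and (optionally) the other species' occupancy
#' probability at the origin year.
#'
#' @param cfg a [sim_config()].
#' @param cov site covariates (on the scale the generating coefficients
#'   expect).
#' @param other_psi optional `n_sites x n_years` matrix; required when a
#'   dynamics coefficient vector names `other_psi`.
#' @param seed integer seed.
#' @return integer matrix `Z` (`n_sites x n_years`).
#' @export
simulate_occupancy_dynamics <- function(cfg, cov, other_psi = NULL,
                                        seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  needs <- "other_psi" %in% c(names(cfg$beta_gamma), names(cfg$beta_phi))
  if (needs && is.null(other_psi))
    stop("`other_psi` required: dynamics coefficients include an other_psi effect")
  n <- cfg$n_sites; T <- cfg$n_years
  Z <- matrix(0L, n, T)
  Z[, 1] <- stats::rbinom(n, 1, invlogit(gen_eta(cfg$beta_psi1, cov)))
  if (T >= 2) for (t in 2:T) {
    # year offsets and other_psi indexed by origin year t - 1
    phi <- invlogit(gen_eta(cfg$beta_phi, cov, other_psi = other_psi, t = t - 1))
    gam <- invlogit(gen_eta(cfg$beta_gamma, cov, other_psi = other_psi, t = t - 1))
    Z[, t] <- stats::rbinom(n, 1, ifelse(Z[, t - 1] == 1, phi, gam))
  }
  Z
}

#' Simulate a detection history given latent occupancy
#'
#' Effort per site-year-period is `days_per_period` minus binomial camera
#' downtime; detections are `Y ~ Bernoulli(p * Z)` with
#' `logit(p) = intercept + slope * effort`.
#'
#' @param cfg a [sim_config()].
#' @param Z latent occupancy matrix from [simulate_occupancy_dynamics()].
#' @param species species label for the result.
#' @param seed integer seed.
#' @return a [detection_history()].
#' @export
simulate_detections <- function(cfg, Z, species = "species", seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Z); T <- ncol(Z); J <- cfg$n_secondary
  effort <- array(cfg$days_per_period -
                    stats::rbinom(n * T * J, cfg$days_per_period,
                                  cfg$downtime_prob), c(n, T, J))
  b_eff <- if ("effort" %in% names(cfg$beta_p)) cfg$beta_p[["effort"]] else 0
  eta <- cfg$beta_p[["(Intercept)"]] + b_eff * effort
  p <- invlogit(eta)
  zarr <- array(Z, c(n, T, J))
  y <- array(stats::rbinom(n * T * J, 1, as.vector(p * zarr)), c(n, T, J))
  detection_history(y, effort, species = species)
}

#' Simulate diel activity times
#'
#' Draws detection clock times from a species' von Mises mixture on the
#' 24-hour circle (components default to crepuscular peaks at 06:00 and
#' 18:00).  With `cfg$thin_delay`, events closer together than the camera
#' delay within a site-day are thinned, emulating the camera's minimum
#' inter-image interval.
#'
#' @param cfg a [sim_config()].
#' @param species name of a mixture in `cfg$diel`.
#' @param n number of detection times.
#' @param seed integer seed.
#' @return an [activity_sample()]; years are assigned uniformly over the
#'   study years so per-year analyses can run on the output.
#' @export
simulate_activity_times <- function(cfg, species, n, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  mix <- cfg$diel[[species]]
  if (is.null(mix)) stop("no diel mixture configured for species: ", species)
  comp <- sample.int(length(mix$weight), n, replace = TRUE, prob = mix$weight)
  th <- numeric(n)
  for (k in seq_along(mix$weight)) {
    idx <- comp == k
    if (any(idx)) th[idx] <- rvonmises(sum(idx), mix$mean[k], mix$kappa[k])
  }
  yrs <- sample(seq_len(cfg$n_years), n, replace = TRUE)
  if (isTRUE(cfg$thin_delay)) {
    # events at the same notional site-day closer than the camera delay
    site_day <- sample.int(cfg$n_sites * cfg$n_years * cfg$n_secondary *
                             cfg$days_per_period, n, replace = TRUE)
    keep <- rep(TRUE, n)
    delay <- cfg$camera_delay_min / 60 / 24 * 2 * pi
    for (g in split(seq_len(n), site_day)) {
      if (length(g) < 2) next
      o <- g[order(th[g])]
      drop <- diff(th[o]) < delay
      keep[o[-1][drop]] <- FALSE
    }
    th <- th[keep]; yrs <- yrs[keep]
  }
  activity_sample(th, species = species, years = yrs)
}

#' Simulate a full two-species camera-trap study
#'
#' Generates everything the analysis pipeline consumes: site covariates,
#' latent occupancy and detection histories for a marten-like species A
#' and a fisher-like species B (B's colonization responding to A's true
#' yearly occupancy probability with coefficient `b_gamma_other_psi`), and
#' diel detection timestamps for both species.
#'
#' @param cfg a [sim_config()] describing species A; species B reuses the
#'   same blocks except for the `other_psi` colonization effect.
#' @param b_gamma_other_psi effect (logit scale) of species A's yearly
#'   occupancy probability on species B's colonization.
#' @param times_per_detection expected number of camera images (activity
#'   timestamps) per detected site-period.
#' @param seed root seed; sub-streams are derived per component.
#' @return a list with `cov` (unscaled covariates), `det_a`, `det_b`,
#'   `psi_a` (species A's true yearly occupancy probabilities), `Z_a`,
#'   `Z_b`, `times` (list of two [activity_sample()]s), and `cfg`.
#' @export
simulate_camera_study <- function(cfg = sim_config(), b_gamma_other_psi = -1,
                                  times_per_detection = 3, seed = cfg$seed) {
  cov <- simulate_covariates(cfg, seed = seed)
  covs <- scale_covariates(cov)
  # species A's true unconditional yearly occupancy, by the projection
  # recursion, feeds species B's dynamics
  n <- cfg$n_sites; T <- cfg$n_years
  psi_a <- matrix(NA_real_, n, T)
  psi_a[, 1] <- invlogit(gen_eta(cfg$beta_psi1, covs))
  if (T >= 2) for (t in 2:T) {
    phi <- invlogit(gen_eta(cfg$beta_phi, covs, t = t - 1))
    gam <- invlogit(gen_eta(cfg$beta_gamma, covs, t = t - 1))
    psi_a[, t] <- phi * psi_a[, t - 1] + gam * (1 - psi_a[, t - 1])
  }
  Z_a <- simulate_occupancy_dynamics(cfg, covs, seed = seed + 1L)
  det_a <- simulate_detections(cfg, Z_a, species = "marten", seed = seed + 2L)
  cfg_b <- cfg
  cfg_b$beta_gamma <- c(cfg$beta_gamma, other_psi = b_gamma_other_psi)
  Z_b <- simulate_occupancy_dynamics(cfg_b, covs, other_psi = psi_a,
                                     seed = seed + 3L)
  det_b <- simulate_detections(cfg_b, Z_b, species = "fisher", seed = seed + 4L)
  n_a <- max(2, stats::rpois(1, times_per_detection * sum(det_a$y, na.rm = TRUE)))
  n_b <- max(2, stats::rpois(1, times_per_detection * sum(det_b$y, na.rm = TRUE)))
  times <- list(marten = simulate_activity_times(cfg, "marten", n_a, seed = seed + 5L),
                fisher = simulate_activity_times(cfg, "fisher", n_b, seed = seed + 6L))
  list(cov = cov, det_a = det_a, det_b = det_b, psi_a = psi_a,
       Z_a = Z_a, Z_b = Z_b, times = times, cfg = cfg, seed = seed)
}

#' Write a simulated study to the three CSV formats
#'
#' @param study output of [simulate_camera_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_camera_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_detection_history(study$det_a, file.path(dir, "det_marten.csv"))
  write_detection_history(study$det_b, file.path(dir, "det_fisher.csv"))
  utils::write.csv(study$cov, file.path(dir, "covariates.csv"), row.names = FALSE)
  tt <- do.call(rbind, lapply(study$times, function(s) {
    frac <- as.numeric(s) / (2 * pi) * 86400
    data.frame(species = attr(s, "species"),
               date = sprintf("%04d-01-15", 2012 + attr(s, "years")),
               time = sprintf("%02d:%02d:%02d", floor(frac / 3600) %% 24,
                              floor(frac / 60) %% 60, floor(frac) %% 60))
  }))
  utils::write.csv(tt, file.path(dir, "timestamps.csv"), row.names = FALSE)
  invisible(dir)
}
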