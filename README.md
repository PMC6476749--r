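# occudiel

Occupancy dynamics and diel activity overlap for two-species camera-trap
studies.

Ecologically similar carnivores (the motivating case: American marten and
fisher on a winter camera grid) can coexist by partitioning space or time.
`occudiel` implements both sides of that question for the standard robust
design — sites surveyed in annual primary periods, each split into repeated
two-week sessions — for ecologists analysing paired detection histories:

* **Occupancy models with imperfect detection.** Single-season:
  `logit(ψ_i) = α + Σ β_k x_ik`, detection
  `logit(p_ij) = α_p + β_p · effort_ij`, latent occupancy marginalised out.
  Dynamic (multi-season): initial occupancy ψ₁, then persistence φ and
  colonization γ between years, both logit-linear in year effects, site
  covariates, and optionally the *other* species' predicted occupancy ψ̂ —
  fitted by maximum likelihood with an analytic forward–backward gradient
  (`occu_fit()`).
* **Backward stepwise AIC selection** with Akaike weights
  (`backward_stepwise()`).
* **MacKenzie–Bailey χ² goodness of fit** by parametric bootstrap, with the
  variance-inflation factor ĉ = χ²_obs / mean(χ²_boot) (`occu_gof()`).
* **Two-stage conditional pipeline** (`run_pipeline()`): yearly
  single-season models for species A feed predicted ψ̂ into species B's
  dynamic model as a colonization/persistence covariate.
* **Diel overlap**: von Mises circular kernel densities and the Δ̂₄
  coefficient, Δ̂₄ = ½[mean min{1, f̂_b/f̂_a at a's times} +
  mean min{1, f̂_a/f̂_b at b's times}] ∈ [0, 1], with smoothed-bootstrap
  confidence intervals (`delta4()`, `overlap_ci()`, `yearly_overlap()`).
* **Synthetic study generator** (`simulate_camera_study()`): 64 sites × 3
  years × 4 two-week sessions with known parameters, for recovery and
  calibration studies.

## Worked example

```r
library(occudiel)

study <- simulate_camera_study(sim_config(), seed = 7)   # synthetic bundle
covs  <- scale_covariates(study$cov)

fit <- occu_fit(study$det_b, covs,
                occu_spec(psi = "DEA", gamma = "other_psi",
                          phi = character(0), p = "effort"),
                other_psi = study$psi_a)
fit
#> Dynamic occupancy model fit
#>   ~DEA ~other_psi ~1 ~effort
#>   logLik = -267.140, K = 7, AIC = 548.28

occu_gof(fit, n_boot = 100, seed = 11)
#> Parametric-bootstrap goodness of fit (MacKenzie-Bailey chi-square)
#>   observed chi-square = 4158.77, bootstrap n = 100, p = 0.440
#>   c-hat = 1.00 (overdispersion)

overlap_ci(study$times$marten, study$times$fisher, n_boot = 200, seed = 13)
#> Diel activity overlap (Delta-4): marten vs fisher
#>   Delta4 = 0.86, 95% CI (basic) = 0.81-0.91  [n = 454, 414; n_boot = 200]
```

The model line reads `~initial occupancy ~colonization ~persistence
~detection`. Here species B's colonization is modelled on species A's
yearly occupancy probability; the GOF p-value (0.44) and ĉ near 1 say the
fitted model reproduces its own detection-history frequencies, and Δ̂₄ =
0.86 means the two species' diel activity densities share 86% of their
area. `run_pipeline()` chains all stages (selection in both stages, GOF,
co-detection counts, overlap) into one seeded, reproducible report.

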