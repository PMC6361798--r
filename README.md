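# gradedRT

Joint modeling of graded item responses and item-level response times for
interviewer-administered health-outcome item banks.

## The problem

Patient-reported outcome instruments such as multi-domain functional
measures are calibrated from field interviews in which an interviewer reads
each Likert-type item to a patient and software records both the ordinal
response and the response time (RT). RTs carry collateral information about
the latent traits being measured — but they are also contaminated by
outliers (interrupted interviews, recording glitches) and by the
interviewer's own pace. `gradedRT` implements the full calibration and
scoring pipeline for this setting:

* **Measurement model.** Responses follow a multidimensional graded response
  model (MGRM) with simple structure: item *j* measuring dimension *d* has
  boundary curves
  `P_jk(θ) = 1 / (1 + exp(−a_j (θ_d − b_jk)))`
  with one discrimination `a_j` and ordered thresholds `b_j1 < … < b_j,K−1`.
  Log RTs follow a lognormal factor model with a cross-relation:
  `ln t_ij = λ_j + φ_j τ_i − φ_j ρ_d θ_id + ω_ij`,
  where `λ_j` is the time intensity, `φ_j` the time discrimination loading
  on the latent speed `τ_i ~ N(0,1)` (independent of θ), `ρ_d` the
  cross-relation through which ability shifts log RT, and
  `ω_ij ~ N(0, σ_ωj²)`. Interviewer effects enter as nothing (`model0`),
  per-item effects `γ_jp` (`model1`), a proportional effect `φ_j γ_p`
  (`model2` — equivalently a hierarchical model in which the interviewer
  shifts latent speed), or a common main effect `γ_p` (`model3`); `mgrm`
  ignores RTs entirely.
* **Estimation.** Marginal maximum likelihood via EM. Conditional on θ the
  log RTs are a one-factor linear Gaussian model, so τ is integrated in
  closed form and only the θ dimensions are integrated numerically
  (Gauss–Hermite tensor grid reweighted to the correlated prior). A
  parameter-expanded first phase keeps the structural parameters (γ, ρ,
  trait correlations) from crawling. Model comparison by AIC, BIC, −2LL and
  likelihood-ratio (deviance) tests; free-parameter counts follow the
  per-item and design rules.
* **Preprocessing.** Respondent exclusion by missing-item count, RT trimming
  (< 3 s and above the batch's 97.5th percentile), one-sample K–S and
  Shapiro–Wilk log-normality diagnostics, and collapsing of response
  categories observed at most once (with the matching threshold remapping).
* **Calibration across batches.** Concurrent calibration of stacked batches
  sharing anchor items (missing-by-design), and fixed-parameter calibration
  that freezes anchor values from a previous stage.
* **Scoring.** Expected a posteriori estimates of the trait vector and
  latent speed with posterior-SD standard errors, with and without RTs.
* **Synthetic data.** A generator that emulates the multi-batch,
  interviewer-administered design (correlated traits, linking items,
  contaminated RTs, missing-by-design), so the whole pipeline is testable
  without any field data.

## Worked example

```r
library(gradedRT)

cfg <- simulation_config(seed = 1, n_persons = 500, n_unique_items = 24,
                         n_linking = 0, H = 3, P = 4,
                         contamination_fraction = 0, missing_rate = 0)
bank    <- generate_item_bank(cfg, J = 24)
persons <- generate_persons(cfg, N = 500, roster = paste0("I", 1:4),
                            seed = NULL)
design  <- interviewer_design(4, reference = 4,
                              gamma = c(0.9, -0.6, 0.4, 0),
                              levels = paste0("I", 1:4))
data    <- simulate_dataset(bank, persons, cfg, variant = "model2",
                            design = design, seed = NULL)

fit <- fit_mml(data, setNames(bank$domain, bank$item_id), "model2",
               reference_interviewer = "I4")
print(fit)
#> Joint graded response / response time fit (model2)
#>   items: 24  persons: 500  dimensions: 3
#>   -2LL = 86265.86  free parameters = 177  converged after 26 iterations
#>   AIC = 86619.9  BIC = 87365.8
round(fit$design$gamma, 2)
#> [1]  0.96 -0.44  0.43  0.00
round(fit$population$rho, 2)
#> [1] 0.40 0.39 0.39
```

The fitted interviewer effects sit near the generating values
(0.9, −0.6, 0.4; the reference is fixed at 0), and the cross-relations
recover the generating 0.42–0.46 up to sampling error. Scoring the same
persons with and without RTs shows the precision gain RTs buy:

```r
pop <- population_structure(3, cfg$R_theta, cfg$rho)
s_resp  <- score_dataset(data, bank, pop, variant = "mgrm")
s_joint <- score_dataset(data, bank, pop, variant = "model0")
se_summary_compare(s_resp, s_joint)[, c("dimension", "mean_se_a",
                                        "mean_se_b", "mean_diff")]
#>   dimension mean_se_a mean_se_b mean_diff
#> 1         1     0.372     0.334    -0.038
#> 2         2     0.318     0.298    -0.020
#> 3         3     0.335     0.312    -0.024
```

(negative differences: the joint model is more precise on every dimension).

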