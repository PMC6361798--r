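---
title: "Joint modeling of graded responses and response times: models, estimation and design choices"
author: "gradedRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modeling of graded responses and response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
measurement models, the estimation machinery, the preprocessing rules, the
synthetic-data generator, and the design decisions taken where the design
was genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The measurement models

### Graded responses

Each item presents 2–4 ordered response options. Under the
multidimensional graded response model with simple structure, item $j$
measures exactly one of $H$ correlated trait dimensions $d(j)$, and the
probability of responding in category $k$ *or above* is a two-parameter
logistic in that dimension,

$$P^+_{jk}(\theta) = \frac{1}{1 + \exp\{-D\,a_j(\theta_{d(j)} - b_{jk})\}},$$

with $P^+_{j1} \equiv 1$ and $P^+_{j,K+1} \equiv 0$; category
probabilities are successive differences of the boundaries. The package's
canonical scale is $D = 1$ — the slope–intercept ("a–c") convention, with
$c_{jk} = -a_j b_{jk}$ available through `threshold_to_intercept()` — and
$D = 1.7$ is supported as an option for the normal-ogive metric. Keeping
one canonical scale internally avoids double-scaling bugs; the
equivalence $D = 1.7, a$ vs. $D = 1, 1.7a$ is asserted in the tests.

### Response times

Log response times follow a lognormal factor model with a cross-relation:

$$\ln t_{ij} = \lambda_j + \varphi_j \tau_i - \varphi_j \rho_{d(j)}
\theta_{i,d(j)} + \omega_{ij}, \qquad \omega_{ij} \sim N(0,
\sigma^2_{\omega j}).$$

$\lambda_j$ (time intensity, log seconds) is how long the item takes on
average; $\varphi_j$ (time discrimination) is the item's loading on the
latent speed $\tau_i$; and the cross-relation $\rho_d$ routes ability into
log RT, so RTs carry information about $\theta$ while the response model
stays untouched. $\theta$ thus accounts for the ability variance shared by
responses and RTs, and $\tau$ for the RT-specific variance.

Identifiability: $\theta$ has mean 0, unit variances, and a freely
estimated correlation matrix $R$; $\tau \sim N(0,1)$ independent of
$\theta$ (the cross-relation term already carries their dependence). An
alternative "dispersion" parameterization of the lognormal RT model
(dispersion $\alpha_j = 1/\sigma_{\omega j}$, intensity $\beta_j =
\lambda_j$) is provided as a conversion, defined only for $\varphi_j = 1$
since that form has no time discrimination; its printed source omits the
square on the exponent, which we read as the standard squared form — the
unsquared expression is not a density.

### Interviewer effects

Because an interviewer reads each item aloud, the observed RT mixes the
patient's speed with the interviewer's pace. Four variants of the joint
model handle this, dummy-coded against a reference interviewer:

| variant  | RT regression adds | interpretation |
|----------|--------------------|----------------|
| `model0` | —                  | no interviewer term |
| `model1` | $\gamma_{jp}$      | item-by-interviewer interaction |
| `model2` | $\varphi_j \gamma_p$ | interviewer shifts latent speed (hierarchical: $\tau_i = \gamma_{p(i)} + \varepsilon_i$, $\varepsilon_i \sim N(0,1)$) |
| `model3` | $\gamma_p$         | common main effect |

`model2` and `model3` coincide when all $\varphi_j = 1$ (a tested
property). For `model2` the person-level latent variable the package
integrates over is the residual speed $\varepsilon_i$; reported speed
scores add the interviewer effect back.

## Estimation

### Likelihood

Conditional on $\theta$, the observed log RTs of a person are a one-factor
linear Gaussian model in $\tau$: $y = \varphi\tau + \omega$ with
$\Sigma = \varphi\varphi^\top + \mathrm{diag}(\sigma^2_\omega)$. The
package therefore integrates $\tau$ (or $\varepsilon$) in closed form via
the rank-one Woodbury identities and integrates only the $H$ trait
dimensions numerically. The grid is a tensor product of Gauss–Hermite
nodes per dimension (default 11), reweighted by the correlated-prior
density ratio and normalized into a proper discrete prior. Simple
structure makes both the response log-likelihood and the
$\tau$-marginalized RT quadratic form separable per dimension, so the
per-person cost is a set of `q × N` matrix operations plus one combination
over the `q^H` tensor — the whole E-step is a handful of dense matrix
sweeps. A full numeric-$\tau$ path (an extra quadrature dimension) is
retained purely as an internal oracle; the tests require agreement to
1e-6, and agreement with a $10^6$-draw Monte Carlo integration to relative
1e-3.

Missing responses and missing RTs contribute nothing to the likelihood
(missing at random, which is what person-by-item RT trimming and
missing-by-design batch structure induce); a person with no observed data
has log marginal likelihood 0.

### EM with a parameter-expanded phase

`fit_mml()` maximizes the marginal likelihood by EM. The M-step is a set
of conditional maximizers of the expected complete-data log-likelihood:
Bock–Aitkin expected-count updates per item for $(a_j, b_j)$ (small
bounded `nlminb` problems on a log-discrimination / ordered-threshold
parameterization), closed-form weighted least squares for $(\lambda_j,
\varphi_j, \sigma_{\omega j})$ using the posterior moments of the latent
predictor, closed forms for $\gamma$ and $\rho$, and an exact
3-parameter optimization for the unit-diagonal correlation matrix.
$\varphi_j$ is constrained positive (a negative time discrimination is
uninterpretable here; the sources never state a constraint, so this is a
package decision), as is $a_j$.

Plain EM has a structural weakness in this model: parameters that trade
off against a *well-measured* latent variable move at rate
$c/(1+c)$ per iteration, where $c = \sum_j \varphi_j^2/\sigma_{\omega
j}^2$ is the RT precision for speed. With realistic item numbers $c
\approx 30$, so interviewer effects and cross-relations crawl at rate
$\approx 0.97$ — slowly enough that a deviance-based stopping rule fires
long before they arrive. The package therefore runs a parameter-expanded
(PX-EM) first phase: each iteration re-estimates the latent location and
scale unconstrained (group means and variance of speed; means and
covariance of the traits) and maps the expanded model back to the
identified metric (rescaling $a, b, \lambda, \varphi, \rho, \gamma$ and
setting $R$ to the correlation of the expanded covariance). Once the
relative deviance change falls below 1e-4 the fitter hands over to the
exact constrained conditional updates, which polish to the constrained
optimum. On the package's own acceptance-scale problem (N = 500, J = 24,
H = 3) this reaches, in ~25 iterations, the same optimum plain EM needs
several hundred iterations to find. During fixed-parameter calibration the
latent scale is pinned by the anchors, so PX is disabled and the
constrained updates are used throughout.

Convergence requires both a relative deviance change below `tol` (default
1e-5) *and* a largest absolute parameter change below `par_tol` (default
1e-3); the second condition prevents declaring convergence while a
slow-moving structural parameter still drifts. Starting values: unit
discriminations with thresholds from inverse-logit cumulative proportions,
$\lambda_j$ from item mean log RT, $\varphi_j = \sigma_{\omega j} = 1$,
$\rho = 0$, and trait correlations from pairwise domain sum-score
correlations.

### Model comparison and standard errors

Free parameters per item are one discrimination plus $K-1$ thresholds,
plus (RT variants) one time intensity, one time discrimination and one
residual variance; the population contributes $H(H-1)/2$ correlations and
(RT variants) $H$ cross-relations; interviewer terms add $J(P-1)$
(`model1`) or $P-1$ (`model2`/`model3`). `AIC` $= -2LL + 2k$ and `BIC`
$= -2LL + k\ln n$ with $n$ the number of cleaned respondents — the BIC
sample-size convention is pinned by reproducing published values in the
acceptance tests. Nested variants (`model0` within the others, `model2`
and `model3` within `model1`) are compared by the deviance test.
`standard_errors()` inverts the numerical Hessian of the marginal
log-likelihood; it is intended for modest parameter counts (the Hessian
costs $O(p^2)$ likelihood evaluations) and the tests exercise it on small
problems, checking the $1/\sqrt{2}$ shrinkage under sample doubling.

## Preprocessing

The cleaning pipeline mirrors field practice for interviewer-administered
RT data, in this order:

1. **Respondent exclusion** — persons missing at least a configurable
   number of their batch's items are dropped (inclusive semantics;
   per-batch thresholds supported, since field batches typically use
   slightly different rules).
2. **RT trimming** — RTs below 3 s or above the batch's 97.5th percentile
   become missing; the response is retained. Both cut-points are computed
   from the *pre-trim pooled batch* distribution (per-batch pooling is
   assumed where the granularity is ambiguous, since batch-level
   distributions are what get reported). The percentile uses the linear
   interpolation convention (R type 7), values exactly at either cut
   survive, and the cut-points are recorded on the output and reused if
   the pipeline is re-run — recomputing a 97.5th percentile on
   already-trimmed data would shave a further 2.5% on every pass, so
   idempotence requires treating the cuts as a property of the raw data.
3. **Category collapsing** — a category observed at most once merges into
   the next higher category; a sparse *top* category merges downward (the
   merge rule only names "next higher"; merging down at the top preserves
   ordinality with minimal distortion — a package decision). Codes are
   recoded contiguously, and because the graded model is a difference
   model, the remapped item keeps its discrimination and its surviving
   thresholds unchanged — `remap_collapsed_parameters()` implements
   exactly that, and a simulation test refits a collapsed item to confirm
   the approximation.

Log-normality diagnostics per item use the plain one-sample
Kolmogorov–Smirnov test against a normal with the item's sample moments
(no small-sample correction — matching the field procedure being
emulated) plus the Shapiro–Wilk test, which is the more powerful of the
two.

## The synthetic-data generator

The field data this pipeline is designed for are not publicly deposited,
so the generator is a first-class module: every stage of the package is
tested end-to-end on data with the structure the analysis assumes. Its
defaults are fixed at the study conditions the package emulates — four
batches of 85/72/72/71 unique items plus 24 linking items balanced 8 per
domain over $H = 3$ correlated dimensions; pre-cleaning samples of
630/542/555/543; six interviewers in batch 1, three of them shared with
the common roster of five used elsewhere; trait correlations
(0.62, 0.47, 0.85); cross-relations ≈ 0.43/0.46/0.42; time intensities
$N(\log 8, 0.25)$ so median RTs sit near 8 s; time discriminations
U(0.25, 0.5) and residual SDs U(0.25, 0.45), giving log-RT dispersion of
the size seen in practice; interviewer effects of order ±1 on the speed
scale; 4% RT contamination (half implausibly fast at 0.5–3 s, half 10–50×
slow, exercising both trim rules); 2% missing responses. Interviewers are
assigned in contiguous person blocks, reflecting a design where each
interviewer works through their share of the sample — this is what makes
the time discriminations of `model0` and `model2` fits linearly related,
a mechanism the acceptance suite checks ($r > 0.99$).

Clean generated RTs are floored at 3 s (`rt_floor`): reading an item aloud
and answering takes a few seconds, so sub-3 s values should only arise
from recording glitches, i.e. contamination. The floor makes the
"contamination 0 ⇒ nothing trips the lower trim rule" property hold by
construction; its cost is a small upward truncation bias in the mean log
RT of fast items (a few hundredths for items with median RT near 5 s),
which the moment-identity test avoids by using slow items and which the
parameter-recovery tolerances absorb.

What passing tests on these data do **not** show about real data: the
generator draws exactly from the fitted model family (no misspecified RT
residuals, no speed–accuracy trade-offs within person, no
interviewer-by-item idiosyncrasies beyond the additive terms), its
missingness is MCAR rather than clinically structured, and its outliers
are a stylized two-component mixture. Recovery results here demonstrate
the estimator is correct, not that the model is right for any particular
instrument.

## Calibration across batches

`stack_batches()` combines per-batch tables into one long table whose
structural missingness encodes the design (each person saw only their
batch's items); the validator enforces that linking items appear in every
batch, non-linking items in exactly one, and persons in exactly one.
`concurrent_calibrate()` is then a single joint fit — linking items get
one parameter set, which places everything on a common scale in one
stage. A configurable warning (default 20%, the usual anchor-share rule
of thumb) flags thin linking; it is a warning rather than an error because
small simulated designs can be perfectly estimable below it.

`fixed_parameter_calibrate()` freezes anchors' $a, b, \lambda, \varphi$
at stage-1 values (residual SDs and all population parameters stay free)
and estimates the remaining items on the anchors' scale; frozen values
are returned bit-identical, and no post-hoc transformation is applied.
When an anchor shows fewer categories in the new data than its frozen
values carry (collapsing in a smaller sample), only the corresponding top
thresholds are imposed — the same difference-model logic as above.
Interviewer rosters may differ by stage, with a stage-specific reference,
so interviewer effects are not comparable across stages; the package makes
no attempt to align them. Both one-stage and two-stage paths are
supported and tested; which one a dataset needs is an empirical
convergence question, not something the package asserts.

## Scoring

`score_dataset()` produces EAP (posterior-mean) estimates of each trait
dimension and of latent speed, with the posterior SD as the standard
error, on the same quadrature grid used in estimation. EAP was chosen
over MAP for its shrinkage behaviour and because the posterior SD is then
the natural precision summary; the quantity reported as "SE" is labeled a
posterior SD deliberately, since information-based SEs differ in small
samples. A person with no observed data receives the prior (0, 1) and a
flag. Speed is reported for RT variants even though it is a nuisance for
trait precision — it is a construct of independent interest.

Two precision properties anchor the scoring tests: the posterior SD never
exceeds the prior SD, and the Fisher information RTs add about a trait is
bounded by $\rho^2/(1-\rho^2)$ — in this parameterization the exact
marginal-RT information is $\rho^2 c/(1+c) < \rho^2$, and the acceptance
suite verifies the numeric information on a 1-D toy sits below the bound
and matches the closed form. The practical consequence, reproduced in the
tests: adding RTs buys a visible SE reduction, adding interviewer terms on
top of RTs buys essentially nothing (mean SE differences below 0.005).

## Numerical choices and limitations

* Quadrature: 11 Gauss–Hermite nodes per dimension by default
  (`quadrature_spec()`); tests that need speed use 7–9, oracles use 21–61.
  Problem sizes in the test suite — recovery at N = 500, J = 24, H = 3;
  calibration checks at N = 150–250 per batch; oracles on 1–3 item toys —
  were chosen as the smallest designs at which the tested properties are
  identifiable with comfortable margins.
* Degenerate inputs: items with unobserved interior categories are
  rejected with a pointer to the collapsing step; constant log-RT vectors
  are rejected by the diagnostics; correlation updates are guarded to the
  positive-definite region; $\varphi, \sigma_\omega$ are clamped away
  from 0.
* Ties in thresholds are broken by a minimum spacing in starting values
  and generator draws.
* Not implemented (out of scope by design): cross-loading (complex)
  multidimensional structure; skewed RT residual families; Box–Cox
  transformation and automated discordancy methods as alternatives to
  trimming; separate calibration with post-hoc linking transformations;
  optimization-based selection of linking items; adaptive-test delivery.
* The PX-EM phase is heuristic in combination with conditional M-steps
  (it can overshoot in a small limit cycle, which is why the final phase
  uses exact constrained updates); the fitted optimum is verified in tests
  against long plain-EM runs via the likelihood itself.
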