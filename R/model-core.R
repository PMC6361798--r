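# Measurement-model primitives: graded-response probabilities and the
# lognormal response-time model with cross-relation and interviewer effects.

#' Boundary response probability of the graded response model
#'
#' Probability of responding in category `k` or above, a two-parameter
#' logistic in the latent trait: `1 / (1 + exp(-D * a * (theta - b)))`.
#'
#' @param a discrimination.
#' @param b boundary location.
#' @param theta latent trait value(s).
#' @param D logistic scaling constant; the package's canonical scale is
#'   `D = 1` (the a-c "intercept" parameterization); `D = 1.7` rescales to the
#'   normal-ogive metric.
#' @return probabilities in (0, 1), vectorized over `theta`.
#' @export
boundary_prob <- function(a, b, theta, D = 1) {
  if (!all(is.finite(a), is.finite(b), is.finite(theta), is.finite(D))) {
    stop("boundary_prob: all inputs must be finite")
  }
  plogis(D * a * (theta - b))
}

#' Category response probabilities of a graded item
#'
#' Successive differences of boundary probabilities, with the conventions
#' that the probability of responding in category 1 or above is 1 and above
#' the top category is 0.  Under simple structure only the trait component
#' the item loads on enters.
#'
#' @param item one-row item bank (see [item_parameters()]).
#' @param theta latent trait vector of length `H` (or a scalar for `H = 1`).
#' @param D logistic scaling constant.
#' @return numeric vector of length `n_categories`, summing to 1.
#' @export
category_probs <- function(item, theta, D = 1) {
  item <- item_bank(item)
  if (nrow(item) != 1L) stop("category_probs expects a single item")
  b <- item_thresholds(item, 1L)
  th <- theta[min(item$domain[1L], length(theta))]
  cum <- c(1, boundary_prob(item$a[1L], b, th, D), 0)
  p <- -diff(cum)
  names(p) <- seq_along(p)
  p
}

#' Convert between threshold and intercept parameterizations
#'
#' The boundary curve can be written in trait-distance form,
#' `D * a * (theta - b)`, or in slope-intercept form, `D * (a * theta + c)`,
#' with `c = -a * b`.
#'
#' @param a discrimination.
#' @param b boundary location.
#' @return intercept `c`.
#' @export
threshold_to_intercept <- function(a, b) -a * b

#' @rdname threshold_to_intercept
#' @param c intercept.
#' @export
intercept_to_threshold <- function(a, c) {
  if (any(a == 0)) stop("cannot recover a threshold when a = 0")
  -c / a
}

#' Expected log response time
#'
#' Under the joint model the log RT of person `i` on item `j` is
#' `lambda_j + phi_j * tau_i - phi_j * rho_d * theta_id` plus an interviewer
#' term that depends on the model variant: nothing (`model0`), an
#' item-by-interviewer effect (`model1`), `phi_j * gamma_p` (`model2`, the
#' hierarchical interviewer-shifts-speed form), or a main effect `gamma_p`
#' (`model3`).  For `model2`, `tau` is interpreted as the residual speed
#' after the interviewer effect.
#'
#' @param item one-row item bank with RT parameters.
#' @param theta latent trait vector.
#' @param tau latent speed (residual speed for `model2`).
#' @param structure a [population_structure()] carrying the cross-relations.
#' @param variant one of `"model0"` to `"model3"`.
#' @param interviewer interviewer index (1..P); ignored for `model0`.
#' @param design an [interviewer_design()]; required for `model1`--`model3`.
#' @return expected log RT in log seconds.
#' @export
predicted_log_rt <- function(item, theta, tau, structure,
                             variant = "model0", interviewer = NULL,
                             design = NULL) {
  variant <- model_variant(variant)
  if (variant == "mgrm") {
    stop("predicted_log_rt is undefined for the response-only model")
  }
  item <- item_bank(item)
  if (nrow(item) != 1L) stop("predicted_log_rt expects a single item")
  d <- item$domain[1L]
  th <- theta[min(d, length(theta))]
  mu <- item$lam[1L] + item$phi[1L] * tau -
    item$phi[1L] * structure$rho[d] * th
  if (variant_uses_interviewer(variant)) {
    if (is.null(design) || is.null(interviewer)) {
      stop(variant, " requires an interviewer design and index")
    }
    if (interviewer < 1L || interviewer > design$P) {
      stop("interviewer index out of range")
    }
    mu <- mu + interviewer_shift(design, variant, 1L, interviewer,
                                 phi = item$phi[1L])
  }
  mu
}

#' Lognormal response-time log density
#'
#' @param t response time in seconds (> 0).
#' @param mu expected log RT.
#' @param sigma_omega residual SD of log RT (> 0).
#' @return log density of the lognormal distribution at `t`.
#' @export
rt_log_density <- function(t, mu, sigma_omega) {
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("rt_log_density: response times must be finite and positive")
  }
  if (any(sigma_omega <= 0)) stop("sigma_omega must be positive")
  dnorm(log(t), mean = mu, sd = sigma_omega, log = TRUE) - log(t)
}

#' Convert to the dispersion parameterization of the lognormal RT model
#'
#' An alternative parameterization writes the RT density with a dispersion
#' parameter `alpha` multiplying the standardized log-time deviation
#' `alpha * (ln t - (beta - tau))` (squared in the exponent), so that
#' `alpha = 1 / sigma_omega` and `beta = lam`.  That form has no time
#' discrimination on the speed factor, so the conversion is only defined for
#' `phi = 1`.
#'
#' @param lam time intensity.
#' @param sigma_omega residual SD (> 0).
#' @param phi time discrimination; must equal 1.
#' @return list with elements `alpha` and `beta`.
#' @export
dispersion_form <- function(lam, sigma_omega, phi = 1) {
  if (any(phi != 1)) {
    stop("dispersion parameterization is only defined for phi = 1")
  }
  if (any(sigma_omega <= 0)) stop("sigma_omega must be positive")
  list(alpha = 1 / sigma_omega, beta = lam)
}

#' @rdname dispersion_form
#' @param alpha dispersion (> 0).
#' @param beta time intensity.
#' @export
from_dispersion_form <- function(alpha, beta) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  list(lam = beta, sigma_omega = 1 / alpha, phi = 1)
}
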