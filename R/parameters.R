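# Containers for item, population and interviewer parameters.
#
# An item bank is a data.frame (class "grt_items") with one row per item:
#   item_id, domain, a, n_categories, b1..b3, lam, phi, sigma_omega.
# Threshold columns beyond n_categories - 1 are NA.  RT columns may be NA
# for response-only analyses.

MAX_CATEGORIES <- 4L

MODEL_VARIANTS <- c("mgrm", "model0", "model1", "model2", "model3")

#' Match a model-variant name
#'
#' The package distinguishes five measurement models: `"mgrm"` (graded
#' responses only, RTs ignored), `"model0"` (joint response + RT model with a
#' cross-relation and no interviewer terms), `"model1"` (item-by-interviewer
#' interaction effects on log RT), `"model2"` (interviewer effect proportional
#' to the item time discrimination, equivalently a hierarchical model in which
#' interviewers shift latent speed) and `"model3"` (a common interviewer main
#' effect on log RT).
#'
#' @param variant character; partial matching against the five names above.
#' @return the matched variant name.
#' @export
model_variant <- function(variant) {
  match.arg(tolower(variant), MODEL_VARIANTS)
}

variant_uses_rt <- function(variant) variant != "mgrm"
variant_uses_interviewer <- function(variant) {
  variant %in% c("model1", "model2", "model3")
}

#' Construct an item bank
#'
#' @param items data.frame with columns `item_id`, `domain` (integer in
#'   `1..H`), `a` (discrimination, > 0), `n_categories` (2--4), threshold
#'   columns `b1`, `b2`, `b3` (strictly increasing where present; columns for
#'   unused boundaries are `NA`), and optionally the RT columns `lam` (time
#'   intensity, log seconds), `phi` (time discrimination, > 0) and
#'   `sigma_omega` (residual SD of log RT, > 0).
#' @return the validated data.frame with class `grt_items`.
#' @export
item_bank <- function(items) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  req <- c("item_id", "domain", "a", "n_categories")
  miss <- setdiff(req, names(items))
  if (length(miss)) {
    stop("item bank is missing columns: ", paste(miss, collapse = ", "))
  }
  for (b in paste0("b", seq_len(MAX_CATEGORIES - 1L))) {
    if (!b %in% names(items)) items[[b]] <- NA_real_
  }
  for (col in c("lam", "phi", "sigma_omega")) {
    if (!col %in% names(items)) items[[col]] <- NA_real_
  }
  items$item_id <- as.character(items$item_id)
  items$domain <- as.integer(items$domain)
  items$n_categories <- as.integer(items$n_categories)
  if (anyDuplicated(items$item_id)) stop("duplicated item_id in item bank")
  if (any(items$n_categories < 2L | items$n_categories > MAX_CATEGORIES)) {
    stop("n_categories must be between 2 and ", MAX_CATEGORIES)
  }
  if (any(!is.finite(items$a)) || any(items$a <= 0)) {
    stop("discriminations 'a' must be finite and positive")
  }
  for (i in seq_len(nrow(items))) {
    b <- item_thresholds(items, i)
    if (length(b) != items$n_categories[i] - 1L) {
      stop("item ", items$item_id[i], ": expected ",
           items$n_categories[i] - 1L, " thresholds, found ", length(b))
    }
    if (length(b) > 1L && any(diff(b) <= 0)) {
      stop("item ", items$item_id[i], ": thresholds must be strictly increasing")
    }
  }
  if (any(!is.na(items$phi) & items$phi <= 0)) {
    stop("time discriminations 'phi' must be positive")
  }
  if (any(!is.na(items$sigma_omega) & items$sigma_omega <= 0)) {
    stop("residual SDs 'sigma_omega' must be positive")
  }
  class(items) <- c("grt_items", "data.frame")
  items
}

#' Construct a one-item bank
#'
#' Convenience wrapper around [item_bank()] for a single item.
#'
#' @param item_id identifier.
#' @param domain dimension the item loads on (simple structure).
#' @param a discrimination (> 0).
#' @param thresholds strictly increasing boundary locations, length
#'   `n_categories - 1`.
#' @param lam,phi,sigma_omega lognormal RT parameters (time intensity in log
#'   seconds, time discrimination > 0, residual SD > 0); `NA` for
#'   response-only items.
#' @export
item_parameters <- function(item_id, domain, a, thresholds,
                            lam = NA_real_, phi = NA_real_,
                            sigma_omega = NA_real_) {
  K <- length(thresholds) + 1L
  row <- data.frame(item_id = as.character(item_id), domain = domain, a = a,
                    n_categories = K, b1 = NA_real_, b2 = NA_real_,
                    b3 = NA_real_, lam = lam, phi = phi,
                    sigma_omega = sigma_omega, stringsAsFactors = FALSE)
  row[1L, paste0("b", seq_len(K - 1L))] <- thresholds
  item_bank(row)
}

# thresholds of item in row i, as a plain vector of length K - 1
item_thresholds <- function(items, i) {
  K <- items$n_categories[i]
  b <- as.numeric(items[i, paste0("b", seq_len(MAX_CATEGORIES - 1L))])
  b <- b[seq_len(K - 1L)]
  if (anyNA(b)) {
    stop("item ", items$item_id[i], ": missing threshold among the first ",
         K - 1L)
  }
  b
}

set_item_thresholds <- function(items, i, thresholds) {
  items[i, paste0("b", seq_len(MAX_CATEGORIES - 1L))] <- NA_real_
  items[i, paste0("b", seq_along(thresholds))] <- thresholds
  items$n_categories[i] <- length(thresholds) + 1L
  items
}

#' Construct the latent population structure
#'
#' Identifiability fixes the latent trait vector theta to mean 0 and unit
#' variances, so only the `H * (H - 1) / 2` correlations are free; the latent
#' speed factor tau is standard normal and uncorrelated with theta because the
#' cross-relation term already carries the ability--speed dependence.
#'
#' @param H number of ability dimensions.
#' @param R_theta `H x H` correlation matrix of theta (unit diagonal,
#'   positive definite).
#' @param rho cross-relation coefficients, one per dimension: the coefficient
#'   with which the ability dimension an item measures enters that item's
#'   expected log RT (scaled by the item's time discrimination).
#' @return list with class `grt_population`.
#' @export
population_structure <- function(H = 3L, R_theta = diag(H), rho = rep(0, H)) {
  H <- as.integer(H)
  R_theta <- as.matrix(R_theta)
  if (!isTRUE(all.equal(dim(R_theta), c(H, H)))) {
    stop("R_theta must be ", H, " x ", H)
  }
  if (max(abs(R_theta - t(R_theta))) > 1e-8) stop("R_theta must be symmetric")
  if (max(abs(diag(R_theta) - 1)) > 1e-8) stop("R_theta must have unit diagonal")
  ev <- eigen(R_theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("R_theta must be positive definite")
  if (length(rho) != H) stop("rho must have length H")
  structure(list(H = H, R_theta = R_theta, rho = as.numeric(rho)),
            class = "grt_population")
}

#' Construct an interviewer design
#'
#' Interviewer effects are dummy-coded against a reference interviewer whose
#' effect is fixed at 0.  For `model1` the effect is a `J x P` matrix (one row
#' per item); for `model2` and `model3` it is a vector of length `P`.
#'
#' @param P number of interviewers.
#' @param reference index (1..P) of the reference interviewer.
#' @param gamma effect parameters with the reference entries equal to 0;
#'   either a vector of length `P` or a `J x P` matrix.  Defaults to all
#'   zeros (vector form).
#' @param levels optional character vector of interviewer identifiers, in
#'   column order of `gamma`.
#' @export
interviewer_design <- function(P, reference = 1L, gamma = NULL,
                               levels = NULL) {
  P <- as.integer(P)
  if (P < 1L) stop("P must be at least 1")
  reference <- as.integer(reference)
  if (reference < 1L || reference > P) stop("reference must be in 1..P")
  if (is.null(gamma)) gamma <- rep(0, P)
  if (is.matrix(gamma)) {
    if (ncol(gamma) != P) stop("gamma matrix must have P columns")
    if (any(gamma[, reference] != 0)) {
      stop("gamma must be 0 for the reference interviewer")
    }
  } else {
    if (length(gamma) != P) stop("gamma vector must have length P")
    if (gamma[reference] != 0) {
      stop("gamma must be 0 for the reference interviewer")
    }
  }
  if (!is.null(levels) && length(levels) != P) {
    stop("levels must have length P")
  }
  structure(list(P = P, reference = reference, gamma = gamma,
                 levels = levels),
            class = "grt_design")
}

# Interviewer shift added to the expected log RT of item row j for a person
# seen by interviewer p.  phi is the item's time discrimination (model2).
interviewer_shift <- function(design, variant, j, p, phi = NULL) {
  if (!variant_uses_interviewer(variant)) return(0)
  g <- design$gamma
  if (variant == "model1") {
    if (!is.matrix(g)) stop("model1 requires a J x P gamma matrix")
    g[j, p]
  } else if (is.matrix(g)) {
    stop(variant, " requires a gamma vector, not a matrix")
  } else if (variant == "model2") {
    phi * g[p]
  } else {
    g[p]
  }
}
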