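# Marginal likelihood machinery.
#
# Conditional on theta, the observed log RTs of a person follow a one-factor
# linear Gaussian model in the latent speed tau (y = phi * tau + omega), so
# tau is integrated in closed form via the rank-one Woodbury identities and
# only the H ability dimensions are integrated numerically, on a tensor-
# product Gauss-Hermite grid reweighted to the (correlated) normal prior.

#' Quadrature specification
#'
#' @param nodes_per_dim Gauss-Hermite nodes per ability dimension
#'   (default 11).
#' @param tau_integration `"analytic"` (closed-form integration of the speed
#'   factor given theta; the default) or `"numeric"` (an extra quadrature
#'   dimension for tau, retained as an internal cross-check).
#' @param tau_nodes nodes for tau when `tau_integration = "numeric"`.
#' @export
quadrature_spec <- function(nodes_per_dim = 11L,
                            tau_integration = c("analytic", "numeric"),
                            tau_nodes = nodes_per_dim) {
  nodes_per_dim <- as.integer(nodes_per_dim)
  if (nodes_per_dim < 3L) stop("nodes_per_dim must be at least 3")
  structure(list(nodes_per_dim = nodes_per_dim,
                 tau_integration = match.arg(tau_integration),
                 tau_nodes = as.integer(tau_nodes)),
            class = "grt_quad")
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

col_log_sum_exp <- function(M) {
  mx <- apply(M, 2L, max)
  mx + log(colSums(exp(sweep(M, 2L, mx, "-"))))
}

# Tensor-product quadrature grid for the theta prior N(0, R).  Nodes are the
# standard-normal Gauss-Hermite nodes per dimension; tensor weights are
# reweighted by the correlated-prior density ratio and normalized so the
# grid is a proper discrete prior.
make_grid <- function(pop, quad) {
  H <- pop$H
  gq <- statmod::gauss.quad.prob(quad$nodes_per_dim, dist = "normal")
  x <- gq$nodes
  lw <- log(gq$weights)
  q <- length(x)
  idx <- as.matrix(expand.grid(rep(list(seq_len(q)), H)))
  dimnames(idx) <- NULL
  theta <- matrix(x[idx], nrow(idx), H)
  logW <- rowSums(matrix(lw[idx], nrow(idx), H))
  if (H > 1L && max(abs(pop$R_theta - diag(H))) > 1e-12) {
    logW <- logW +
      mvtnorm::dmvnorm(theta, sigma = pop$R_theta, log = TRUE) -
      rowSums(dnorm(theta, log = TRUE))
  }
  logW <- logW - log_sum_exp(logW)
  list(x = x, q = q, H = H, idx = idx, theta = theta, logW = logW)
}

# q x K matrix of log category probabilities of one item at nodes x.
item_logprob_grid <- function(a, b, x, D = 1) {
  cum <- cbind(1, plogis(D * a * outer(x, b, "-")), 0)
  p <- cum[, -ncol(cum), drop = FALSE] - cum[, -1L, drop = FALSE]
  log(pmax(p, 1e-300))
}

# Convert a long table into wide J x N matrices aligned with the item bank.
# Returns resp, lnt (J x N), interviewer index per person (vs `levels`),
# and person/batch bookkeeping.
build_wide <- function(table, items, interviewer_levels = NULL) {
  table <- check_raw_table(table)
  unknown <- setdiff(unique(table$item_id), items$item_id)
  if (length(unknown)) {
    stop("items in data but not in the bank: ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  person_ids <- sort(unique(table$person_id))
  J <- nrow(items)
  N <- length(person_ids)
  ri <- match(table$item_id, items$item_id)
  ci <- match(table$person_id, person_ids)
  resp <- matrix(NA_integer_, J, N)
  lnt <- matrix(NA_real_, J, N)
  resp[cbind(ri, ci)] <- as.integer(table$response)
  lnt[cbind(ri, ci)] <- ifelse(is.na(table$rt), NA_real_, log(table$rt))
  bad <- which(!is.na(resp) & (resp < 1L |
                 resp > items$n_categories[row(resp)]), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("response out of category range for item ",
         items$item_id[bad[1L, 1L]])
  }
  iv <- rep(NA_character_, N)
  has_iv <- !is.na(table$interviewer_id)
  if (any(has_iv)) {
    per <- tapply(as.character(table$interviewer_id)[has_iv],
                  table$person_id[has_iv],
                  function(x) {
                    u <- unique(x)
                    if (length(u) > 1L) {
                      stop("a person must have a single interviewer")
                    }
                    u
                  })
    iv[match(names(per), person_ids)] <- as.character(per)
  }
  if (is.null(interviewer_levels)) {
    interviewer_levels <- sort(unique(iv[!is.na(iv)]))
  }
  interviewer <- match(iv, interviewer_levels)
  batch <- tapply(as.character(table$batch_id), table$person_id,
                  function(x) x[1L])[person_ids]
  list(resp = resp, lnt = lnt, interviewer = interviewer,
       interviewer_levels = interviewer_levels,
       person_ids = person_ids, batch = unname(batch))
}

# Per person x item additive shift on expected log RT implied by the
# interviewer design (J x N matrix), on the scale of Equation's mu.
shift_matrix <- function(items, wide, design, variant) {
  J <- nrow(items)
  N <- length(wide$person_ids)
  S <- matrix(0, J, N)
  if (!variant_uses_interviewer(variant)) return(S)
  p <- wide$interviewer
  if (anyNA(p)) stop(variant, " requires an interviewer for every person")
  if (variant == "model1") {
    S[] <- design$gamma[, p]
  } else if (variant == "model2") {
    S[] <- outer(items$phi, design$gamma[p])
  } else {
    S[] <- rep(design$gamma[p], each = J)
  }
  S
}

# E-step over a wide dataset.  Returns per-person marginal log-likelihoods
# and, when moments = TRUE, the posterior moments used by the M-step and by
# EAP scoring.
estep <- function(wide, items, pop, design = NULL, variant = "model0",
                  quad = quadrature_spec(), moments = FALSE) {
  variant <- model_variant(variant)
  H <- pop$H
  grid <- make_grid(pop, quad)
  q <- grid$q
  N <- length(wide$person_ids)
  G <- nrow(grid$idx)
  use_rt <- variant_uses_rt(variant)

  # per-dimension response log-likelihood matrices (q x N)
  Td <- lapply(seq_len(H), function(d) matrix(0, q, N))
  for (j in seq_len(nrow(items))) {
    obs <- which(!is.na(wide$resp[j, ]))
    if (!length(obs)) next
    d <- items$domain[j]
    lp <- item_logprob_grid(items$a[j], item_thresholds(items, j), grid$x)
    Td[[d]][, obs] <- Td[[d]][, obs] + lp[, wide$resp[j, obs], drop = FALSE]
  }

  const <- numeric(N)
  cinv <- rep(1, N)
  b0 <- numeric(N)
  Vd <- NULL
  if (use_rt) {
    if (anyNA(items$lam) || anyNA(items$phi) || anyNA(items$sigma_omega)) {
      stop("RT variants require lam, phi and sigma_omega for every item")
    }
    S <- shift_matrix(items, wide, design, variant)
    z <- wide$lnt - items$lam - S
    O <- !is.na(z)
    z0 <- ifelse(O, z, 0)
    lnt0 <- ifelse(O, wide$lnt, 0)
    s2 <- items$sigma_omega^2
    wphi2 <- items$phi^2 / s2
    cc <- colSums(O * wphi2)                  # phi' D^-1 phi per person
    const <- -0.5 * colSums(O * log(2 * pi * s2)) - colSums(O * lnt0) -
      0.5 * log1p(cc)
    b0 <- colSums(O * (items$phi / s2) * z0)
    cinv <- 1 / (1 + cc)
    Vd <- vector("list", H)
    for (d in seq_len(H)) {
      jd <- which(items$domain == d)
      Od <- O[jd, , drop = FALSE]
      a0 <- colSums(Od * (z0[jd, , drop = FALSE]^2 / s2[jd]))
      s1 <- colSums(Od * (items$phi[jd] / s2[jd]) * z0[jd, , drop = FALSE])
      cphi <- colSums(Od * wphi2[jd])
      rho <- pop$rho[d]
      # -(1/2) * sum_j (z + phi rho theta)^2 / sigma^2, quadratic in theta_d
      Td[[d]] <- Td[[d]] - 0.5 * (rep(a0, each = q) +
        2 * rho * outer(grid$x, s1) + rho^2 * outer(grid$x^2, cphi))
      Vd[[d]] <- rho * outer(grid$x, cphi)    # theta part of phi' D^-1 e
    }
  }

  # combine per-dimension pieces on the tensor grid
  M <- grid$logW
  for (d in seq_len(H)) M <- M + Td[[d]][grid$idx[, d], , drop = FALSE]
  if (use_rt) {
    B <- rep(b0, each = G)
    for (d in seq_len(H)) B <- B + Vd[[d]][grid$idx[, d], , drop = FALSE]
    M <- M + 0.5 * sweep(B^2, 2L, cinv, "*")
    M <- sweep(M, 2L, const, "+")
  }
  loglik_i <- col_log_sum_exp(M)
  no_data <- colSums(!is.na(wide$resp)) == 0L &
    (!use_rt | colSums(!is.na(wide$lnt)) == 0L)
  loglik_i[no_data] <- 0
  out <- list(loglik_i = loglik_i, loglik = sum(loglik_i), no_data = no_data)
  if (!moments) return(out)

  P <- exp(sweep(M, 2L, col_log_sum_exp(M), "-"))
  Eth <- matrix(0, N, H)
  Eth2 <- matrix(0, N, H)
  Ethth <- array(0, c(N, H, H))
  p_marg <- vector("list", H)
  for (d in seq_len(H)) {
    thd <- grid$theta[, d]
    Eth[, d] <- colSums(P * thd)
    Eth2[, d] <- colSums(P * thd^2)
    Ethth[, d, d] <- Eth2[, d]
    p_marg[[d]] <- rowsum(P, grid$idx[, d])
  }
  if (H > 1L) {
    for (d in seq_len(H - 1L)) {
      for (e in seq((d + 1L), H)) {
        Ethth[, d, e] <- Ethth[, e, d] <-
          colSums(P * grid$theta[, d] * grid$theta[, e])
      }
    }
  }
  out$Eth <- Eth
  out$Eth2 <- Eth2
  out$Ethth <- Ethth
  out$p_marg <- p_marg
  out$grid <- grid
  if (use_rt) {
    mpost <- sweep(B, 2L, cinv, "*")          # E[tau | theta, data]
    out$Etau <- colSums(P * mpost)
    out$Etau2 <- cinv + colSums(P * mpost^2)
    Etauth <- matrix(0, N, H)
    for (d in seq_len(H)) Etauth[, d] <- colSums(P * mpost * grid$theta[, d])
    out$Etauth <- Etauth
  }
  out
}

# Full numeric-quadrature log-likelihood with tau as an extra dimension;
# a slow reference path used to validate the analytic integration.
loglik_numeric_tau <- function(wide, items, pop, design = NULL,
                               variant = "model0",
                               quad = quadrature_spec()) {
  variant <- model_variant(variant)
  if (!variant_uses_rt(variant)) stop("numeric tau path needs an RT variant")
  grid <- make_grid(pop, quad)
  gq <- statmod::gauss.quad.prob(quad$tau_nodes, dist = "normal")
  N <- length(wide$person_ids)
  S <- shift_matrix(items, wide, design, variant)
  loglik_i <- numeric(N)
  for (i in seq_len(N)) {
    robs <- which(!is.na(wide$resp[, i]))
    tobs <- which(!is.na(wide$lnt[, i]))
    if (!length(robs) && !length(tobs)) next
    ll_resp <- rep(0, nrow(grid$theta))
    for (j in robs) {
      lp <- item_logprob_grid(items$a[j], item_thresholds(items, j),
                              grid$theta[, items$domain[j]])
      ll_resp <- ll_resp + lp[, wide$resp[j, i]]
    }
    per_tau <- matrix(0, nrow(grid$theta), length(gq$nodes))
    for (k in seq_along(gq$nodes)) {
      ll_rt <- rep(0, nrow(grid$theta))
      for (j in tobs) {
        d <- items$domain[j]
        mu <- items$lam[j] + items$phi[j] * gq$nodes[k] -
          items$phi[j] * pop$rho[d] * grid$theta[, d] + S[j, i]
        ll_rt <- ll_rt + dnorm(wide$lnt[j, i], mu, items$sigma_omega[j],
                               log = TRUE) - wide$lnt[j, i]
      }
      per_tau[, k] <- ll_rt + log(gq$weights[k])
    }
    ll_rt_marg <- apply(per_tau, 1L, log_sum_exp)
    loglik_i[i] <- log_sum_exp(grid$logW + ll_resp + ll_rt_marg)
  }
  loglik_i
}

#' Marginal log-likelihood of one person's records
#'
#' Integrates the joint likelihood of a person's observed responses and RTs
#' over the latent traits and the latent speed.  Missing responses and
#' missing RTs contribute nothing (missing at random); a person with no
#' observed data has log marginal likelihood 0.
#'
#' @param records long-format rows for a single person.
#' @param items item bank with the relevant parameters.
#' @param structure a [population_structure()].
#' @param design an [interviewer_design()] (for `model1`--`model3`).
#' @param variant model variant, see [model_variant()].
#' @param quad a [quadrature_spec()]; with `tau_integration = "numeric"` the
#'   speed factor is integrated on its own quadrature grid instead of in
#'   closed form.
#' @return log marginal likelihood (scalar).
#' @export
person_loglik <- function(records, items, structure, design = NULL,
                          variant = "model0", quad = quadrature_spec()) {
  variant <- model_variant(variant)
  items <- item_bank(items)
  if (nrow(records) && length(unique(records$person_id)) > 1L) {
    stop("person_loglik expects records for a single person")
  }
  if (nrow(records) == 0L) return(0)
  lv <- if (!is.null(design)) design$levels
  wide <- build_wide(records, items, interviewer_levels = lv)
  if (variant_uses_rt(variant) && quad$tau_integration == "numeric") {
    return(sum(loglik_numeric_tau(wide, items, structure, design, variant,
                                  quad)))
  }
  estep(wide, items, structure, design, variant, quad)$loglik
}

#' Marginal log-likelihood of a dataset
#'
#' Sum of [person_loglik()] over the persons of a long-format table.
#'
#' @inheritParams person_loglik
#' @param table long-format data.frame.
#' @return scalar log-likelihood with attributes `per_person` (named vector)
#'   and `minus2ll`.
#' @export
dataset_loglik <- function(table, items, structure, design = NULL,
                           variant = "model0", quad = quadrature_spec()) {
  variant <- model_variant(variant)
  items <- item_bank(items)
  lv <- if (!is.null(design)) design$levels
  wide <- build_wide(table, items, interviewer_levels = lv)
  if (variant_uses_rt(variant) && quad$tau_integration == "numeric") {
    ll_i <- loglik_numeric_tau(wide, items, structure, design, variant, quad)
  } else {
    ll_i <- estep(wide, items, structure, design, variant, quad)$loglik_i
  }
  out <- sum(ll_i)
  attr(out, "per_person") <- setNames(ll_i, wide$person_ids)
  attr(out, "minus2ll") <- -2 * sum(ll_i)
  out
}
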