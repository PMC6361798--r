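# Marginal maximum likelihood estimation by an EM algorithm.
#
# E-step: posterior moments of (theta, tau) per person on the quadrature
# grid (tau in closed form given theta).  M-step: Bock-Aitkin expected-count
# updates for the graded-response parameters (small per-item optimizations),
# closed-form conditional updates for the lognormal RT parameters, the
# interviewer effects and the cross-relations, and a low-dimensional
# optimization for the trait correlation matrix under its unit-diagonal
# identifiability constraint.

#' Summarize a calibration design
#'
#' @param items_by_categories named count vector of items by number of
#'   response categories, e.g. `c("2" = 1, "3" = 31, "4" = 77)`.
#' @param H number of latent trait dimensions.
#' @param P number of interviewers (0 if none).
#' @param n_persons number of (cleaned) respondents.
#' @return list of class `grt_design_summary`.
#' @export
design_summary <- function(items_by_categories, H, P = 0L,
                           n_persons = NA_integer_) {
  if (is.null(names(items_by_categories))) {
    stop("items_by_categories must be named by category count")
  }
  K <- as.integer(names(items_by_categories))
  if (any(is.na(K)) || any(K < 2L)) stop("invalid category-count names")
  structure(list(items_by_categories = items_by_categories,
                 J = sum(items_by_categories), H = as.integer(H),
                 P = as.integer(P), n_persons = n_persons),
            class = "grt_design_summary")
}

design_summary_of_items <- function(items, H, P, n_persons) {
  tab <- table(items$n_categories)
  design_summary(setNames(as.integer(tab), names(tab)), H = H, P = P,
                 n_persons = n_persons)
}

#' Count free parameters of a model variant
#'
#' Each item contributes one discrimination and `K - 1` thresholds; variants
#' that model RTs add per item a time intensity, a time discrimination and a
#' residual variance, plus one cross-relation per dimension.  The trait
#' correlations contribute `H * (H - 1) / 2` for every variant.  Interviewer
#' terms add `J * (P - 1)` effects for `model1` and `P - 1` for `model2` and
#' `model3` (one interviewer is the dummy-coding reference).
#'
#' @param design a [design_summary()].
#' @param variant model variant.
#' @return integer count.
#' @export
count_free_parameters <- function(design, variant) {
  variant <- model_variant(variant)
  K <- as.integer(names(design$items_by_categories))
  n_K <- as.integer(design$items_by_categories)
  k <- sum(n_K * K)                      # a_j plus K - 1 thresholds per item
  k <- k + design$H * (design$H - 1L) / 2L
  if (variant_uses_rt(variant)) {
    k <- k + 3L * design$J + design$H    # lam, phi, sigma per item; rho per dim
  }
  if (variant == "model1") k <- k + design$J * (design$P - 1L)
  if (variant %in% c("model2", "model3")) k <- k + (design$P - 1L)
  as.integer(k)
}

#' Information criteria from a deviance
#'
#' `AIC = -2LL + 2k`; `BIC = -2LL + k * log(n)` with `n` the number of
#' respondents entering the likelihood.
#'
#' @param minus2ll deviance (-2 log-likelihood).
#' @param k number of free parameters.
#' @param n number of respondents.
#' @return list with `aic` and `bic`.
#' @export
information_criteria <- function(minus2ll, k, n) {
  if (n < 1) stop("n must be at least 1")
  list(aic = minus2ll + 2 * k, bic = minus2ll + k * log(n))
}

# is `nested` nested within `full`?
variant_nested_in <- function(nested, full) {
  if (nested == full) return(TRUE)
  if (nested == "model0") return(full %in% c("model1", "model2", "model3"))
  if (nested %in% c("model2", "model3")) return(full == "model1")
  FALSE
}

#' Likelihood-ratio (deviance) test of nested model variants
#'
#' @param fit_full,fit_nested fitted models (see [fit_mml()]) of nested
#'   variants estimated on the same dataset.
#' @return list with `delta_deviance`, `df` and the chi-square `p` value.
#' @export
deviance_test <- function(fit_full, fit_nested) {
  if (!variant_nested_in(fit_nested$variant, fit_full$variant)) {
    stop("'", fit_nested$variant, "' is not nested within '",
         fit_full$variant, "'")
  }
  delta <- fit_nested$minus2ll - fit_full$minus2ll
  df <- fit_full$n_free_params - fit_nested$n_free_params
  p <- if (df == 0L) {
    if (abs(delta) < 1e-8) 1 else NA_real_
  } else {
    pchisq(delta, df = df, lower.tail = FALSE)
  }
  list(delta_deviance = delta, df = df, p = p)
}

#' EM control options
#'
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the relative change of -2LL between
#'   iterations.
#' @param par_tol additional convergence requirement on the largest absolute
#'   parameter change between iterations (guards against declaring
#'   convergence while slowly-moving structural parameters still drift).
#' @param verbose print the deviance trace.
#' @export
fit_control <- function(max_iter = 500L, tol = 1e-5, par_tol = 1e-3,
                        verbose = FALSE) {
  list(max_iter = as.integer(max_iter), tol = tol, par_tol = par_tol,
       verbose = isTRUE(verbose))
}

# ---- starting values ---------------------------------------------------

start_items <- function(wide, items) {
  q_eps <- 0.02
  for (j in seq_len(nrow(items))) {
    r <- wide$resp[j, ]
    r <- r[!is.na(r)]
    K <- items$n_categories[j]
    if (!is.na(items$a[j])) next
    items$a[j] <- 1
    pk <- vapply(2:K, function(k) mean(r >= k), 0)
    pk <- pmin(pmax(pk, q_eps), 1 - q_eps)
    b <- qlogis(1 - pk)
    b <- b + seq(0, 1e-3, length.out = K - 1L)   # break exact ties
    b <- cummax_strict(b)
    items <- set_item_thresholds(items, j, b)
    items$a[j] <- 1
  }
  mlnt <- rowMeans(wide$lnt, na.rm = TRUE)
  items$lam <- ifelse(is.na(items$lam), ifelse(is.nan(mlnt), 0, mlnt),
                      items$lam)
  items$phi <- ifelse(is.na(items$phi), 1, items$phi)
  items$sigma_omega <- ifelse(is.na(items$sigma_omega), 1,
                              items$sigma_omega)
  items
}

cummax_strict <- function(b, gap = 1e-3) {
  for (k in seq_along(b)[-1L]) b[k] <- max(b[k], b[k - 1L] + gap)
  b
}

start_correlations <- function(wide, domains_by_item, H) {
  if (H == 1L) return(diag(1L))
  scores <- matrix(NA_real_, length(wide$person_ids), H)
  for (d in seq_len(H)) {
    jd <- which(domains_by_item == d)
    if (length(jd)) {
      scores[, d] <- colMeans(wide$resp[jd, , drop = FALSE], na.rm = TRUE)
    }
  }
  R <- suppressWarnings(cor(scores, use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0.3
  diag(R) <- 1
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-4) {          # ridge toward identity if indefinite
    R <- 0.8 * R + 0.2 * diag(H)
  }
  R
}

# ---- M-step pieces -----------------------------------------------------

resp_item_negll <- function(par, r, x) {
  a <- exp(par[1L])
  b <- cumsum(c(par[2L], exp(par[-(1:2)])))
  -sum(r * item_logprob_grid(a, b, x))
}

update_resp_item <- function(r, a, b, x) {
  par <- c(log(a), b[1L], if (length(b) > 1L) log(pmax(diff(b), 1e-4)))
  fit <- nlminb(par, resp_item_negll, r = r, x = x,
                lower = c(log(0.05), -8, rep(log(1e-4), length(b) - 1L)),
                upper = c(log(8), 8, rep(log(12), length(b) - 1L)),
                control = list(iter.max = 60L))
  list(a = exp(fit$par[1L]),
       b = cumsum(c(fit$par[2L], exp(fit$par[-(1:2)]))))
}

# exact conditional maximizer of log|R| + tr(R^-1 S) over unit-diagonal R
update_correlations <- function(S, R_now) {
  H <- nrow(S)
  if (H == 1L) return(R_now)
  low <- lower.tri(S)
  obj <- function(r) {
    R <- diag(H)
    R[low] <- r
    R <- R + t(R) - diag(H)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) + sum(diag(chol2inv(ch) %*% S))
  }
  fit <- nlminb(R_now[low], obj, lower = -0.995, upper = 0.995,
                control = list(iter.max = 100L))
  R <- diag(H)
  R[low] <- fit$par
  R + t(R) - diag(H)
}

# ---- the fitter --------------------------------------------------------

#' Fit a joint response / response-time model by marginal maximum likelihood
#'
#' Estimates item, population and interviewer parameters of the chosen model
#' variant by an EM algorithm.  The latent traits are fixed to mean 0 and
#' variance 1 with a freely estimated correlation matrix; the latent speed
#' (the residual speed for `model2`) is standard normal and uncorrelated
#' with the traits.  Missing responses and missing RTs are skipped (missing
#' at random); persons appear in the likelihood with whatever they have.
#'
#' @param table long-format data.frame (`person_id`, `item_id`, `response`,
#'   `rt`, `interviewer_id`, `batch_id`).  Responses must use contiguous
#'   codes `1..K` per item (run [preprocess_data()] first if not).
#' @param domains named integer vector mapping `item_id` to the dimension
#'   (1..H) the item measures.
#' @param variant model variant, see [model_variant()].
#' @param H number of dimensions (default `max(domains)`).
#' @param quad a [quadrature_spec()].
#' @param control a [fit_control()] list.
#' @param reference_interviewer interviewer id used as dummy-coding
#'   reference; default the first in sorted order.
#' @param start optional item bank of starting values.
#' @param fixed optional item bank whose rows freeze the discrimination,
#'   thresholds, time intensity and time discrimination of those items at
#'   the given values (fixed-parameter calibration); their residual SDs and
#'   all population parameters remain free.
#' @return object of class `grt_fit`: estimated `items`, `population`,
#'   `design`, `loglik`, `minus2ll`, `n_free_params`, `converged`,
#'   `n_iterations`, `n_persons`, `variant` and the deviance `history`.
#' @export
fit_mml <- function(table, domains, variant = "model0",
                    H = max(domains), quad = quadrature_spec(),
                    control = fit_control(), reference_interviewer = NULL,
                    start = NULL, fixed = NULL) {
  variant <- model_variant(variant)
  table <- check_raw_table(table)
  H <- as.integer(H)
  use_rt <- variant_uses_rt(variant)
  use_iv <- variant_uses_interviewer(variant)

  ids <- sort(unique(table$item_id))
  if (!all(ids %in% names(domains))) {
    stop("domains must name every item in the data")
  }
  dom <- as.integer(domains[ids])
  obs_resp <- table[!is.na(table$response), c("item_id", "response")]
  Kmax <- tapply(obs_resp$response, obs_resp$item_id, max)[ids]
  if (anyNA(Kmax)) stop("some items have no observed responses")
  for (id in ids) {
    seen <- sort(unique(obs_resp$response[obs_resp$item_id == id]))
    if (!identical(as.integer(seen), seq_len(Kmax[[id]]))) {
      stop("item ", id, " has non-contiguous response categories; ",
           "collapse and recode them first")
    }
  }

  items <- data.frame(item_id = ids, domain = dom, a = NA_real_,
                      n_categories = as.integer(Kmax), b1 = NA_real_,
                      b2 = NA_real_, b3 = NA_real_, lam = NA_real_,
                      phi = NA_real_, sigma_omega = NA_real_,
                      stringsAsFactors = FALSE)
  fixed_ids <- character(0)
  if (!is.null(fixed)) {
    fixed <- item_bank(fixed)
    fixed_ids <- intersect(fixed$item_id, ids)
    absent <- setdiff(fixed$item_id, ids)
    if (length(absent)) {
      stop("fixed items absent from data: ", paste(absent, collapse = ", "))
    }
    for (id in fixed_ids) {
      fi <- which(fixed$item_id == id)
      ti <- which(items$item_id == id)
      K_obs <- items$n_categories[ti]
      K_fix <- fixed$n_categories[fi]
      if (K_obs > K_fix) {
        stop("item ", id, " shows more categories than its frozen values")
      }
      b <- item_thresholds(fixed, fi)
      if (K_obs < K_fix) {             # collapsed in the new data: keep the
        b <- b[(K_fix - K_obs + 1L):(K_fix - 1L)]  # top thresholds
      }
      items$a[ti] <- fixed$a[fi]
      items <- set_item_thresholds(items, ti, b)
      if (use_rt) {
        items$lam[ti] <- fixed$lam[fi]
        items$phi[ti] <- fixed$phi[fi]
      }
    }
  }
  if (!is.null(start)) {
    start <- item_bank(start)
    keep <- setdiff(intersect(start$item_id, ids), fixed_ids)
    for (id in keep) {
      si <- which(start$item_id == id); ti <- which(items$item_id == id)
      items$a[ti] <- start$a[si]
      items <- set_item_thresholds(items, ti, item_thresholds(start, si))
      items$lam[ti] <- start$lam[si]
      items$phi[ti] <- start$phi[si]
      items$sigma_omega[ti] <- start$sigma_omega[si]
    }
  }

  wide <- build_wide(table, item_bank_quiet(items), NULL)
  items <- start_items(wide, items)
  if (!use_rt) items[, c("lam", "phi", "sigma_omega")] <- NA_real_
  items <- item_bank(items)

  design <- NULL
  if (use_iv) {
    lev <- wide$interviewer_levels
    if (!length(lev)) stop(variant, " requires interviewer identifiers")
    ref <- if (is.null(reference_interviewer)) 1L else {
      r <- match(as.character(reference_interviewer), lev)
      if (is.na(r)) stop("reference interviewer not found in the data")
      r
    }
    P <- length(lev)
    gamma0 <- if (variant == "model1") matrix(0, nrow(items), P) else rep(0, P)
    design <- interviewer_design(P, reference = ref, gamma = gamma0,
                                 levels = lev)
  }
  pop <- population_structure(H, start_correlations(wide, items$domain, H),
                              rho = rep(0, H))

  free_resp <- !(items$item_id %in% fixed_ids)
  free_rt <- free_resp
  # Parameter-expanded EM requires a free latent scale; anchored fits keep
  # the scale pinned by the frozen items and use constrained updates
  # throughout.  Unanchored fits start in a PX phase (fast progress on the
  # structural parameters, which plain EM moves extremely slowly) and then
  # polish with exact constrained conditional-maximization updates.
  px_allowed <- length(fixed_ids) == 0L
  px <- px_allowed
  N <- length(wide$person_ids)
  history <- numeric(0)
  converged <- FALSE
  m2ll_prev <- Inf
  par_prev <- NULL
  snapshot <- function() {
    c(items$a, items$b1, items$b2, items$b3, items$lam, items$phi,
      items$sigma_omega, pop$rho, pop$R_theta[lower.tri(pop$R_theta)],
      if (!is.null(design)) as.numeric(design$gamma))
  }

  for (iter in seq_len(control$max_iter)) {
    es <- estep(wide, items, pop, design, variant, quad, moments = TRUE)
    m2ll <- -2 * es$loglik
    history <- c(history, m2ll)
    if (control$verbose) {
      message(sprintf("iter %3d  -2LL = %.4f", iter, m2ll))
    }
    par_now <- snapshot()
    rel_change <- if (is.finite(m2ll_prev)) {
      abs(m2ll_prev - m2ll) / (abs(m2ll) + 1)
    } else {
      Inf
    }
    if (!px && rel_change < control$tol &&
        max(abs(par_now - par_prev), na.rm = TRUE) < control$par_tol) {
      converged <- TRUE
      break
    }
    if (px && rel_change < 1e-4) px <- FALSE   # hand over to exact updates
    m2ll_prev <- m2ll
    par_prev <- par_now

    # --- response parameters -------------------------------------------
    for (j in which(free_resp)) {
      d <- items$domain[j]
      obs <- which(!is.na(wide$resp[j, ]))
      if (!length(obs)) next
      K <- items$n_categories[j]
      ind <- matrix(0, length(obs), K)
      ind[cbind(seq_along(obs), wide$resp[j, obs])] <- 1
      r <- es$p_marg[[d]][, obs, drop = FALSE] %*% ind
      upd <- update_resp_item(r, items$a[j], item_thresholds(items, j),
                              es$grid$x)
      items$a[j] <- upd$a
      items <- set_item_thresholds(items, j, upd$b)
    }

    if (use_rt) {
      g_person <- if (use_iv && variant == "model2") {
        design$gamma[wide$interviewer]
      } else {
        rep(0, N)
      }
      # E[u], E[u^2] with u = tau - rho theta_d (+ gamma_p for model2)
      Eu <- matrix(0, nrow(items), N)
      Eu2 <- matrix(0, nrow(items), N)
      for (d in seq_len(H)) {
        jd <- which(items$domain == d)
        r <- pop$rho[d]
        eu <- es$Etau - r * es$Eth[, d] + g_person
        eu2 <- es$Etau2 - 2 * r * es$Etauth[, d] + r^2 * es$Eth2[, d] +
          2 * g_person * (es$Etau - r * es$Eth[, d]) + g_person^2
        Eu[jd, ] <- rep(eu, each = length(jd))
        Eu2[jd, ] <- rep(eu2, each = length(jd))
      }
      # intercept-style interviewer shift (models 1 and 3)
      S_int <- matrix(0, nrow(items), N)
      if (use_iv && variant == "model1") {
        S_int[] <- design$gamma[, wide$interviewer]
      } else if (use_iv && variant == "model3") {
        S_int[] <- rep(design$gamma[wide$interviewer], each = nrow(items))
      }
      O <- !is.na(wide$lnt)
      Y <- ifelse(O, wide$lnt - S_int, 0)

      for (j in seq_len(nrow(items))) {
        obs <- which(O[j, ])
        if (length(obs) < 3L) next
        y <- Y[j, obs]; eu <- Eu[j, obs]; eu2 <- Eu2[j, obs]
        n <- length(obs)
        if (free_rt[j]) {
          A <- matrix(c(n, sum(eu), sum(eu), sum(eu2)), 2L)
          sol <- tryCatch(solve(A, c(sum(y), sum(y * eu))),
                          error = function(e) c(mean(y), items$phi[j]))
          items$lam[j] <- sol[1L]
          items$phi[j] <- max(sol[2L], 1e-3)   # positivity constraint
        }
        lam <- items$lam[j]; phi <- items$phi[j]
        s2 <- mean(y^2 - 2 * y * (lam + phi * eu) + lam^2 +
                     2 * lam * phi * eu + phi^2 * eu2)
        items$sigma_omega[j] <- sqrt(max(s2, 1e-6))
      }

      # --- interviewer effects -------------------------------------------
      if (use_iv) {
        s2 <- items$sigma_omega^2
        if (variant == "model3") {
          # residual after lam and phi * E[u]; u here excludes gamma
          Rres <- (ifelse(O, wide$lnt, 0) - items$lam - items$phi * Eu) / s2
          W <- O / s2
          for (p in seq_len(design$P)[-design$reference]) {
            sel <- which(wide$interviewer == p)
            if (!length(sel)) next
            design$gamma[p] <- sum(Rres[, sel]) / sum(W[, sel])
          }
        } else if (variant == "model1") {
          Rres <- (ifelse(O, wide$lnt, 0) - items$lam - items$phi * Eu) / s2
          W <- O / s2
          for (p in seq_len(design$P)[-design$reference]) {
            sel <- which(wide$interviewer == p)
            if (!length(sel)) next
            num <- rowSums(Rres[, sel, drop = FALSE])
            den <- rowSums(W[, sel, drop = FALSE])
            design$gamma[, p] <- ifelse(den > 0, num / den, 0)
          }
        } else {                                  # model2
          # E[u0] with u0 = eps - rho theta (gamma excluded)
          Eu0 <- Eu - rep(g_person, each = nrow(items))
          Rres <- items$phi * (ifelse(O, wide$lnt, 0) - items$lam -
                                 items$phi * Eu0) / s2
          W <- O * items$phi^2 / s2
          for (p in seq_len(design$P)[-design$reference]) {
            sel <- which(wide$interviewer == p)
            if (!length(sel)) next
            design$gamma[p] <- sum(Rres[, sel]) / sum(W[, sel])
          }
        }
      }

      # --- cross-relations ----------------------------------------------
      Z <- ifelse(O, wide$lnt, 0) - items$lam - S_int
      if (use_iv && variant == "model2") {
        Z <- Z - items$phi * rep(g_person, each = nrow(items))
      }
      Z[!O] <- 0
      s2 <- items$sigma_omega^2
      for (d in seq_len(H)) {
        jd <- which(items$domain == d)
        cphi <- colSums(O[jd, , drop = FALSE] * (items$phi[jd]^2 / s2[jd]))
        zw <- colSums((items$phi[jd] / s2[jd]) * Z[jd, , drop = FALSE])
        num <- sum(cphi * es$Etauth[, d]) - sum(zw * es$Eth[, d])
        den <- sum(cphi * es$Eth2[, d])
        if (den > 0) pop$rho[d] <- num / den
      }
    }

    # --- population structure --------------------------------------------
    if (px) {
      # PX-EM: refit the latent location/scale unconstrained, then map the
      # expanded model back to the identified metric.  This removes the
      # slow EM crawl of parameters that trade off against well-measured
      # latent variables (notably gamma and rho against the speed factor).
      if (use_rt) {
        if (variant == "model2") {
          mu_p <- vapply(seq_len(design$P), function(p) {
            sel <- wide$interviewer == p
            if (any(sel)) mean(es$Etau[sel]) else 0
          }, 0)
          m_i <- mu_p[wide$interviewer]
          s_tau <- sqrt(max(mean(es$Etau2 - 2 * m_i * es$Etau + m_i^2),
                            1e-8))
          gam <- (design$gamma + mu_p) / s_tau
          delta <- gam[design$reference]
          items$phi <- items$phi * s_tau
          design$gamma <- gam - delta
          items$lam <- items$lam + items$phi * delta
        } else {
          mu <- mean(es$Etau)
          s_tau <- sqrt(max(mean(es$Etau2) - mu^2, 1e-8))
          items$lam <- items$lam + items$phi * mu
          items$phi <- items$phi * s_tau
        }
        pop$rho <- pop$rho / s_tau
      }
      m_th <- colMeans(es$Eth)
      S <- apply(es$Ethth, c(2L, 3L), mean) - outer(m_th, m_th)
      sd_th <- sqrt(pmax(diag(S), 1e-8))
      for (j in seq_len(nrow(items))) {
        d <- items$domain[j]
        b <- (item_thresholds(items, j) - m_th[d]) / sd_th[d]
        items <- set_item_thresholds(items, j, b)
        items$a[j] <- items$a[j] * sd_th[d]
      }
      if (use_rt) {
        items$lam <- items$lam - items$phi * pop$rho[items$domain] *
          m_th[items$domain]
        pop$rho <- pop$rho * sd_th
      }
      if (H > 1L) {
        Dinv <- diag(1 / sd_th, H)
        R <- Dinv %*% S %*% Dinv
        pop$R_theta <- (R + t(R)) / 2
        diag(pop$R_theta) <- 1
      }
    } else if (H > 1L) {
      Smat <- apply(es$Ethth, c(2L, 3L), mean)
      pop$R_theta <- update_correlations(Smat, pop$R_theta)
    }
  }

  es <- estep(wide, items, pop, design, variant, quad)
  ds <- design_summary_of_items(items, H = H,
                                P = if (use_iv) design$P else 0L,
                                n_persons = N)
  k <- count_free_parameters(ds, variant)
  if (length(fixed_ids)) {
    fi <- items$item_id %in% fixed_ids
    k <- k - sum(items$n_categories[fi])            # a_j and thresholds
    if (use_rt) k <- k - 2L * sum(fi)               # lam and phi
  }
  if (!converged) {
    warning("EM did not converge in ", control$max_iter, " iterations")
  }
  structure(list(items = items, population = pop, design = design,
                 variant = variant, loglik = es$loglik,
                 minus2ll = -2 * es$loglik, n_free_params = as.integer(k),
                 converged = converged, n_iterations = length(history),
                 history = history, n_persons = N, quad = quad,
                 domains = setNames(items$domain, items$item_id),
                 fixed_item_ids = fixed_ids,
                 design_summary = ds),
            class = "grt_fit")
}

# item_bank() but tolerant of NA a/thresholds (pre-start scaffold)
item_bank_quiet <- function(items) {
  out <- items
  out$a[is.na(out$a)] <- 1
  for (i in seq_len(nrow(out))) {
    b <- as.numeric(out[i, paste0("b", seq_len(out$n_categories[i] - 1L))])
    if (anyNA(b)) {
      out[i, paste0("b", seq_len(out$n_categories[i] - 1L))] <-
        seq(-1, 1, length.out = out$n_categories[i] - 1L)
    }
  }
  item_bank(out)
}

#' @export
print.grt_fit <- function(x, ...) {
  cat("Joint graded response / response time fit (", x$variant, ")\n",
      sep = "")
  cat("  items:", nrow(x$items), " persons:", x$n_persons,
      " dimensions:", x$population$H, "\n")
  cat(sprintf("  -2LL = %.2f  free parameters = %d  %s after %d iterations\n",
              x$minus2ll, x$n_free_params,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  ic <- information_criteria(x$minus2ll, x$n_free_params, x$n_persons)
  cat(sprintf("  AIC = %.1f  BIC = %.1f\n", ic$aic, ic$bic))
  invisible(x)
}

# ---- standard errors ---------------------------------------------------

# pack the free parameters of a fit into a named vector
pack_params <- function(fit) {
  items <- fit$items
  use_rt <- variant_uses_rt(fit$variant)
  par <- c(); nm <- c()
  for (j in seq_len(nrow(items))) {
    id <- items$item_id[j]
    frozen <- id %in% fit$fixed_item_ids
    if (!frozen) {
      b <- item_thresholds(items, j)
      par <- c(par, items$a[j], b)
      nm <- c(nm, paste0("a[", id, "]"),
              paste0("b", seq_along(b), "[", id, "]"))
    }
    if (use_rt) {
      if (!frozen) {
        par <- c(par, items$lam[j], items$phi[j])
        nm <- c(nm, paste0("lam[", id, "]"), paste0("phi[", id, "]"))
      }
      par <- c(par, items$sigma_omega[j])
      nm <- c(nm, paste0("sigma_omega[", id, "]"))
    }
  }
  H <- fit$population$H
  if (use_rt) {
    par <- c(par, fit$population$rho)
    nm <- c(nm, paste0("rho[", seq_len(H), "]"))
  }
  if (H > 1L) {
    low <- which(lower.tri(fit$population$R_theta), arr.ind = TRUE)
    par <- c(par, fit$population$R_theta[low])
    nm <- c(nm, paste0("R[", low[, 1L], ",", low[, 2L], "]"))
  }
  if (variant_uses_interviewer(fit$variant)) {
    g <- fit$design$gamma
    if (is.matrix(g)) {
      for (p in seq_len(ncol(g))[-fit$design$reference]) {
        par <- c(par, g[, p])
        nm <- c(nm, paste0("gamma[", fit$items$item_id, ",", p, "]"))
      }
    } else {
      idx <- seq_along(g)[-fit$design$reference]
      par <- c(par, g[idx])
      nm <- c(nm, paste0("gamma[", idx, "]"))
    }
  }
  setNames(par, nm)
}

unpack_params <- function(par, fit) {
  items <- fit$items
  pop <- fit$population
  design <- fit$design
  use_rt <- variant_uses_rt(fit$variant)
  k <- 0L
  take <- function(n) {
    v <- par[(k + 1L):(k + n)]
    k <<- k + n
    v
  }
  for (j in seq_len(nrow(items))) {
    frozen <- items$item_id[j] %in% fit$fixed_item_ids
    K <- items$n_categories[j]
    if (!frozen) {
      items$a[j] <- take(1L)
      items <- set_item_thresholds(items, j, take(K - 1L))
    }
    if (use_rt) {
      if (!frozen) {
        items$lam[j] <- take(1L)
        items$phi[j] <- take(1L)
      }
      items$sigma_omega[j] <- take(1L)
    }
  }
  if (use_rt) pop$rho <- as.numeric(take(pop$H))
  if (pop$H > 1L) {
    low <- lower.tri(pop$R_theta)
    R <- diag(pop$H)
    R[low] <- take(sum(low))
    pop$R_theta <- R + t(R) - diag(pop$H)
  }
  if (variant_uses_interviewer(fit$variant)) {
    if (is.matrix(design$gamma)) {
      for (p in seq_len(ncol(design$gamma))[-design$reference]) {
        design$gamma[, p] <- take(nrow(items))
      }
    } else {
      idx <- seq_along(design$gamma)[-design$reference]
      design$gamma[idx] <- take(length(idx))
    }
  }
  list(items = items, population = pop, design = design)
}

#' Standard errors of a fitted model
#'
#' Square roots of the diagonal of the inverse observed information matrix,
#' with the information obtained as the numerical Hessian of the marginal
#' log-likelihood at the estimates.  Parameters fixed by constraint (the
#' reference interviewer's effect, frozen anchor parameters) are absent from
#' the table.  Intended for modest parameter counts; the Hessian costs
#' O(p^2) likelihood evaluations.
#'
#' @param fit a converged [fit_mml()] result.
#' @param table the dataset the model was fitted to.
#' @param h relative finite-difference step.
#' @return data.frame with `parameter`, `estimate`, `se`.
#' @export
standard_errors <- function(fit, table, h = 1e-4) {
  if (!fit$converged) stop("standard errors require a converged fit")
  wide <- build_wide(check_raw_table(table), fit$items,
                     interviewer_levels = if (!is.null(fit$design))
                       fit$design$levels)
  par0 <- pack_params(fit)
  f <- function(par) {
    cfg <- unpack_params(par, fit)
    es <- tryCatch(
      estep(wide, cfg$items, cfg$population, cfg$design, fit$variant,
            fit$quad),
      error = function(e) NULL)
    if (is.null(es) || !is.finite(es$loglik)) return(NA_real_)
    es$loglik
  }
  p <- length(par0)
  hh <- h * (abs(par0) + 1)
  Hm <- matrix(NA_real_, p, p)
  f0 <- f(par0)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p)
      ei[i] <- hh[i]; ej[j] <- hh[j]
      if (i == j) {
        Hm[i, i] <- (f(par0 + 2 * ei) - 2 * f0 + f(par0 - 2 * ei)) /
          (4 * hh[i]^2)
      } else {
        Hm[i, j] <- Hm[j, i] <-
          (f(par0 + ei + ej) - f(par0 + ei - ej) -
             f(par0 - ei + ej) + f(par0 - ei - ej)) / (4 * hh[i] * hh[j])
      }
    }
  }
  info <- -Hm
  se <- rep(NA_real_, p)
  inv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(inv)) {
    warning("information matrix is singular; standard errors unavailable")
  } else {
    dg <- diag(inv)
    if (any(dg <= 0)) {
      warning("non-positive variance estimates for some parameters")
    }
    se <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
  }
  data.frame(parameter = names(par0), estimate = unname(par0), se = se,
             stringsAsFactors = FALSE)
}
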