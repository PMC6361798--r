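# Shared fixtures: small simulated datasets built in code.

# a compact config for quick simulation-based tests
quick_config <- function(seed, N = 200L, J = 10L, H = 2L, P = 3L,
                         n_categories = 3L, contamination = 0,
                         missing = 0) {
  simulation_config(seed = seed, n_persons = N, n_unique_items = J,
                    n_linking = 0L, H = H, n_categories = n_categories,
                    P = P, contamination_fraction = contamination,
                    missing_rate = missing,
                    R_theta = default_R_theta(H), rho = default_rho(H))
}

# bank + persons + long table in one call
quick_sim <- function(seed, N = 200L, J = 10L, H = 2L, P = 3L,
                      variant = "model0", gamma = NULL,
                      n_categories = 3L, contamination = 0, missing = 0) {
  cfg <- quick_config(seed, N, J, H, P, n_categories, contamination,
                      missing)
  bank <- generate_item_bank(cfg, J = J)
  roster <- paste0("I", seq_len(P))
  pers <- generate_persons(cfg, N = N, roster = roster, seed = NULL)
  design <- NULL
  if (variant %in% c("model1", "model2", "model3")) {
    if (is.null(gamma)) gamma <- c(seq(0.8, -0.8, length.out = P - 1L), 0)
    design <- interviewer_design(P, reference = P, gamma = gamma,
                                 levels = roster)
  }
  dat <- simulate_dataset(bank, pers, cfg, variant = variant,
                          design = design, seed = NULL)
  # small samples can leave a category unobserved; recode as the cleaning
  # pipeline would so the data are always fittable
  for (id in unique(dat$item_id)) {
    sel <- dat$item_id == id & !is.na(dat$response)
    if (!any(sel) || max(dat$response[sel]) < 2L) next
    counts <- tabulate(dat$response[sel], max(dat$response[sel]))
    map <- collapse_and_recode(counts)
    if (any(map$old_to_new != seq_along(map$old_to_new))) {
      dat$response[sel] <- map$old_to_new[dat$response[sel]]
    }
  }
  list(config = cfg, bank = bank, persons = pers, design = design,
       data = dat, domains = setNames(bank$domain, bank$item_id),
       population = population_structure(H, cfg$R_theta, cfg$rho))
}

# brute-force Monte Carlo marginal likelihood of one person's records
mc_person_loglik <- function(records, bank, pop, design = NULL,
                             variant = "model0", n_draws = 1e6,
                             seed = 123) {
  set.seed(seed)
  H <- pop$H
  theta <- MASS::mvrnorm(n_draws, rep(0, H), pop$R_theta)
  theta <- matrix(theta, n_draws, H)
  tau <- rnorm(n_draws)
  lw <- rep(0, n_draws)
  for (r in seq_len(nrow(records))) {
    j <- match(records$item_id[r], bank$item_id)
    d <- bank$domain[j]
    K <- bank$n_categories[j]
    b <- as.numeric(bank[j, paste0("b", seq_len(K - 1L))])
    if (!is.na(records$response[r])) {
      cum <- cbind(1, plogis(bank$a[j] * outer(theta[, d], b, "-")), 0)
      k <- records$response[r]
      lw <- lw + log(cum[, k] - cum[, k + 1L])
    }
    if (!is.na(records$rt[r]) && variant != "mgrm") {
      mu <- bank$lam[j] + bank$phi[j] * tau -
        bank$phi[j] * pop$rho[d] * theta[, d]
      if (!is.null(design) && variant != "model0") {
        p <- match(records$interviewer_id[r], design$levels)
        mu <- mu + switch(variant,
                          model1 = design$gamma[j, p],
                          model2 = bank$phi[j] * design$gamma[p],
                          model3 = design$gamma[p])
      }
      lw <- lw + dnorm(log(records$rt[r]), mu, bank$sigma_omega[j],
                       log = TRUE) - log(records$rt[r])
    }
  }
  m <- max(lw)
  m + log(mean(exp(lw - m)))
}
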