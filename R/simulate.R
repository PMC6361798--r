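# Synthetic data with the structure of an interviewer-administered,
# multi-batch graded item bank: correlated trait dimensions, lognormal RTs
# with cross-relation and interviewer speed effects, outlier contamination,
# and missing-by-design across batches.

#' Simulation configuration
#'
#' Defaults emulate a four-batch field calibration of a ~324-item bank over
#' three correlated domains: batches of 85/72/72/71 unique items plus 24
#' linking items (8 per domain), pre-cleaning samples of 630/542/555/543
#' respondents, six interviewers in batch 1 (three shared with the common
#' roster of five used in batches 2-4), item time intensities around
#' `log(8)` seconds, trait correlations of moderate-to-high size and
#' cross-relations around 0.4-0.5.  Response times are contaminated with a
#' small fraction of implausibly fast and very slow outliers to exercise the
#' trimming rules.
#'
#' @param seed integer seed (required; every generator draw flows from it).
#' @param n_persons respondents per batch.
#' @param n_unique_items unique (non-linking) items per batch.
#' @param n_linking number of linking items shared by all batches.
#' @param H trait dimensions.
#' @param n_categories response categories per item (scalar, or vector over
#'   items of the full bank).
#' @param a_range uniform range for discriminations.
#' @param threshold_sd,threshold_gap SD of raw threshold draws and the
#'   minimum enforced spacing between adjacent thresholds.
#' @param lam_mean,lam_sd normal parameters for time intensities
#'   (log seconds).
#' @param phi_range,sigma_range uniform ranges for time discriminations and
#'   residual SDs.
#' @param R_theta trait correlation matrix.
#' @param rho cross-relation coefficients per dimension.
#' @param P interviewers per batch.
#' @param roster_overlap how many of batch 1's interviewers also belong to
#'   the common roster used by the other batches.
#' @param gamma_range uniform range for non-reference interviewer effects
#'   (on the latent-speed scale for `model2`).
#' @param contamination_fraction fraction of RTs replaced by outliers (half
#'   implausibly fast at 0.5-3 s, half very slow at 10-50 times the
#'   generated RT).
#' @param rt_floor minimum clean response time in seconds.  Reading an item
#'   aloud and answering takes a few seconds, so clean RTs are floored here;
#'   only contamination produces faster values.
#' @param missing_rate fraction of responses set missing at random.
#' @return list of class `grt_simconfig`.
#' @export
simulation_config <- function(seed,
                              n_persons = c(630L, 542L, 555L, 543L),
                              n_unique_items = c(85L, 72L, 72L, 71L),
                              n_linking = 24L,
                              H = 3L,
                              n_categories = 4L,
                              a_range = c(0.8, 2.5),
                              threshold_sd = 1.2,
                              threshold_gap = 0.3,
                              lam_mean = log(8),
                              lam_sd = 0.25,
                              phi_range = c(0.25, 0.5),
                              sigma_range = c(0.25, 0.45),
                              R_theta = default_R_theta(H),
                              rho = default_rho(H),
                              P = c(6L, 5L, 5L, 5L),
                              roster_overlap = 3L,
                              gamma_range = c(-1, 1),
                              contamination_fraction = 0.04,
                              rt_floor = 3,
                              missing_rate = 0.02) {
  if (missing(seed)) stop("a seed is required")
  if (length(n_unique_items) != length(n_persons)) {
    stop("n_persons and n_unique_items must have one entry per batch")
  }
  cfg <- list(seed = as.integer(seed), n_persons = as.integer(n_persons),
              n_unique_items = as.integer(n_unique_items),
              n_linking = as.integer(n_linking), H = as.integer(H),
              n_categories = n_categories, a_range = a_range,
              threshold_sd = threshold_sd, threshold_gap = threshold_gap,
              lam_mean = lam_mean, lam_sd = lam_sd, phi_range = phi_range,
              sigma_range = sigma_range, R_theta = as.matrix(R_theta),
              rho = rho, P = as.integer(P),
              roster_overlap = as.integer(roster_overlap),
              gamma_range = gamma_range,
              contamination_fraction = contamination_fraction,
              rt_floor = rt_floor, missing_rate = missing_rate)
  population_structure(cfg$H, cfg$R_theta, cfg$rho)  # validates
  if (cfg$n_linking > 0 && cfg$n_linking %% cfg$H != 0) {
    stop("n_linking must be divisible by H for balanced linking sets")
  }
  if (cfg$contamination_fraction < 0 || cfg$contamination_fraction >= 1) {
    stop("contamination_fraction must be in [0, 1)")
  }
  structure(cfg, class = "grt_simconfig")
}

#' @rdname simulation_config
#' @export
default_R_theta <- function(H = 3L) {
  if (H == 3L) {
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- 0.62
    R[1, 3] <- R[3, 1] <- 0.47
    R[2, 3] <- R[3, 2] <- 0.85
    R
  } else {
    R <- matrix(0.5, H, H)
    diag(R) <- 1
    R
  }
}

#' @rdname simulation_config
#' @export
default_rho <- function(H = 3L) rep_len(c(0.43, 0.46, 0.42), H)

#' Generate an item bank
#'
#' Discriminations, thresholds and RT parameters are drawn from the ranges
#' in the configuration; thresholds are drawn, sorted and spread to the
#' configured minimum gap; domains are assigned in near-equal parts.
#'
#' @param config a [simulation_config()].
#' @param J number of items (default: the full bank implied by the config).
#' @param item_prefix prefix for item identifiers.
#' @param seed seed (default the config's); `NULL` to use the current RNG
#'   state.
#' @return a `grt_items` bank.
#' @export
generate_item_bank <- function(config, J = NULL, item_prefix = "item",
                               seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(J)) J <- sum(config$n_unique_items) + config$n_linking
  H <- config$H
  domain <- sort(rep_len(seq_len(H), J))
  K <- rep_len(config$n_categories, J)
  rows <- lapply(seq_len(J), function(j) {
    b <- sort(rnorm(K[j] - 1L, 0, config$threshold_sd))
    b <- cummax_strict(b, gap = config$threshold_gap)
    item_parameters(
      item_id = sprintf("%s%03d", item_prefix, j),
      domain = domain[j],
      a = runif(1L, config$a_range[1L], config$a_range[2L]),
      thresholds = b,
      lam = rnorm(1L, config$lam_mean, config$lam_sd),
      phi = runif(1L, config$phi_range[1L], config$phi_range[2L]),
      sigma_omega = runif(1L, config$sigma_range[1L], config$sigma_range[2L]))
  })
  item_bank(do.call(rbind, rows))
}

#' Generate persons with latent traits, speed and interviewer assignment
#'
#' Traits are multivariate normal with the configured correlation matrix;
#' latent speed is standard normal, independent of the traits.  Interviewers
#' are assigned in contiguous blocks, emulating a design where each
#' interviewer works through their share of the sample.
#'
#' @param config a [simulation_config()].
#' @param N number of persons (default: the config's first batch).
#' @param roster character vector of interviewer identifiers.
#' @param id_prefix prefix for person identifiers.
#' @param batch_id batch label attached to the persons.
#' @param seed seed; `NULL` to use the current RNG state.
#' @return data.frame: `person_id`, `theta1..H`, `tau`, `interviewer_id`,
#'   `batch_id`.
#' @export
generate_persons <- function(config, N = config$n_persons[1L],
                             roster = paste0("I", seq_len(config$P[1L])),
                             id_prefix = "P", batch_id = "1",
                             seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  H <- config$H
  theta <- MASS::mvrnorm(N, mu = rep(0, H), Sigma = config$R_theta)
  theta <- matrix(theta, N, H)
  tau <- rnorm(N)
  P <- length(roster)
  blocks <- rep(seq_len(P), each = ceiling(N / P))[seq_len(N)]
  out <- data.frame(person_id = sprintf("%s%04d", id_prefix, seq_len(N)),
                    stringsAsFactors = FALSE)
  for (d in seq_len(H)) out[[paste0("theta", d)]] <- theta[, d]
  out$tau <- tau
  out$interviewer_id <- roster[blocks]
  out$batch_id <- batch_id
  out
}

#' Simulate a long-format response + RT dataset
#'
#' Responses are drawn from the graded category probabilities at each
#' person's traits; log RTs are the model-implied expectation plus normal
#' residual noise.  Optional contamination replaces a configured fraction of
#' RTs with implausibly fast (uniform 0.5-3 s) or very slow (10-50 times the
#' generated value) outliers; optional missingness blanks responses at
#' random.
#'
#' @param bank a `grt_items` bank.
#' @param persons output of [generate_persons()].
#' @param config a [simulation_config()].
#' @param variant generative variant (`"mgrm"` draws responses only).
#' @param design an [interviewer_design()] with the generating interviewer
#'   effects; required for `model1`--`model3`.
#' @param seed seed; `NULL` to use the current RNG state.
#' @return long-format data.frame (`person_id`, `item_id`, `response`, `rt`,
#'   `interviewer_id`, `batch_id`).
#' @export
simulate_dataset <- function(bank, persons, config, variant = "model0",
                             design = NULL, seed = config$seed) {
  variant <- model_variant(variant)
  if (!is.null(seed)) set.seed(seed)
  bank <- item_bank(bank)
  H <- config$H
  N <- nrow(persons)
  J <- nrow(bank)
  theta <- as.matrix(persons[, paste0("theta", seq_len(H)), drop = FALSE])
  tau <- persons$tau
  use_rt <- variant_uses_rt(variant)
  iv_idx <- NULL
  if (variant_uses_interviewer(variant)) {
    if (is.null(design)) stop(variant, " requires an interviewer design")
    iv_idx <- match(persons$interviewer_id, design$levels)
    if (anyNA(iv_idx)) stop("persons reference interviewers not in design")
  }
  rows <- vector("list", J)
  for (j in seq_len(J)) {
    d <- bank$domain[j]
    b <- item_thresholds(bank, j)
    cum <- plogis(bank$a[j] * outer(theta[, d], b, "-"))  # P(X >= k+1)
    u <- runif(N)
    resp <- 1L + rowSums(u < cum)
    rt <- NA_real_
    if (use_rt) {
      mu <- bank$lam[j] + bank$phi[j] * tau -
        bank$phi[j] * config$rho[d] * theta[, d]
      if (!is.null(iv_idx)) {
        mu <- mu + vapply(iv_idx, function(p)
          interviewer_shift(design, variant, j, p, phi = bank$phi[j]), 0)
      }
      rt <- pmax(exp(mu + rnorm(N, 0, bank$sigma_omega[j])),
                 config$rt_floor)
    }
    rows[[j]] <- data.frame(person_id = persons$person_id,
                            item_id = bank$item_id[j],
                            response = resp, rt = rt,
                            interviewer_id = persons$interviewer_id,
                            batch_id = persons$batch_id,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n <- nrow(out)
  if (use_rt && config$contamination_fraction > 0) {
    n_bad <- round(config$contamination_fraction * n)
    bad <- sample.int(n, n_bad)
    fast <- bad[seq_len(floor(n_bad / 2))]
    slow <- setdiff(bad, fast)
    out$rt[fast] <- runif(length(fast), 0.5, 3)
    out$rt[slow] <- out$rt[slow] * runif(length(slow), 10, 50)
  }
  if (config$missing_rate > 0) {
    out$response[runif(n) < config$missing_rate] <- NA_integer_
  }
  rownames(out) <- NULL
  out
}

#' Generate linked multi-batch datasets from one common bank
#'
#' Builds a single item bank, designates a balanced linking set shared
#' verbatim by every batch, splits the remaining items across batches,
#' samples disjoint persons per batch with batch-specific interviewer
#' rosters (batch 1's roster only partially overlaps the common roster),
#' and simulates each batch under the requested variant.
#'
#' @param config a [simulation_config()].
#' @param variant generative variant.
#' @return list of class `grt_sim`: `batched` (a [batched_dataset()]),
#'   `bank` (generating parameters), `designs` and `rosters` per batch,
#'   `persons` per batch, `domains` (named map), and `config`.
#' @export
make_linked_batches <- function(config, variant = "model2") {
  variant <- model_variant(variant)
  set.seed(config$seed)
  B <- length(config$n_persons)
  H <- config$H
  if (config$n_linking > sum(config$n_unique_items) + config$n_linking) {
    stop("linking count exceeds the bank size")
  }
  bank <- generate_item_bank(config, seed = NULL)
  # balanced linking set: first n_linking / H items of each domain
  per_dom <- config$n_linking / H
  linking <- unlist(lapply(seq_len(H), function(d) {
    head(bank$item_id[bank$domain == d], per_dom)
  }))
  pool <- setdiff(bank$item_id, linking)
  if (sum(config$n_unique_items) != length(pool)) {
    stop("bank size inconsistent with per-batch unique-item counts")
  }
  # deal the remaining items to batches round-robin over the domain-ordered
  # pool (keeps each batch's domain mix near-balanced), honouring exact
  # per-batch counts
  counts <- config$n_unique_items
  pool_seq <- pool[order(bank$domain[match(pool, bank$item_id)])]
  need <- counts
  batch_items <- rep(list(character(0)), B)
  b <- 1L
  for (id in pool_seq) {
    while (need[b] == 0L) b <- if (b == B) 1L else b + 1L
    batch_items[[b]] <- c(batch_items[[b]], id)
    need[b] <- need[b] - 1L
    b <- if (b == B) 1L else b + 1L
  }

  common <- paste0("I", seq_len(max(config$P[-1L], config$P[1L])))
  rosters <- lapply(seq_len(B), function(b) {
    if (b == 1L && B > 1L && config$P[1L] != config$P[2L]) {
      c(head(common, config$roster_overlap),
        paste0("I", max(config$P) + seq_len(config$P[1L] -
                                              config$roster_overlap)))
    } else {
      paste0("I", seq_len(config$P[min(b, length(config$P))]))
    }
  })
  designs <- lapply(seq_len(B), function(b) {
    P <- length(rosters[[b]])
    gamma <- c(runif(P - 1L, config$gamma_range[1L], config$gamma_range[2L]),
               0)
    interviewer_design(P, reference = P, gamma = gamma,
                       levels = rosters[[b]])
  })

  batches <- list()
  persons <- list()
  for (b in seq_len(B)) {
    pers <- generate_persons(config, N = config$n_persons[b],
                             roster = rosters[[b]],
                             id_prefix = sprintf("B%dP", b),
                             batch_id = as.character(b), seed = NULL)
    sub_bank <- bank[bank$item_id %in% c(linking, batch_items[[b]]), ,
                     drop = FALSE]
    batches[[as.character(b)]] <-
      simulate_dataset(sub_bank, pers, config, variant,
                       design = designs[[b]], seed = NULL)
    persons[[as.character(b)]] <- pers
  }
  structure(list(batched = batched_dataset(batches, linking),
                 bank = bank,
                 designs = designs, rosters = rosters, persons = persons,
                 domains = setNames(bank$domain, bank$item_id),
                 linking_item_ids = linking,
                 config = config),
            class = "grt_sim")
}
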