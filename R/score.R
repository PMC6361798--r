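# Expected a posteriori (EAP) scoring of persons with posterior SDs.

#' EAP scores for one person
#'
#' Posterior mean and SD of each trait dimension (and of the latent speed
#' for RT variants) given the person's observed responses and RTs under
#' calibrated parameters.  The posterior SD is reported as the standard
#' error.  A person with no observed data receives the prior mean 0 and
#' prior SD 1, flagged in the output.
#'
#' For `model2` the latent speed reported is the person's total speed, i.e.
#' the interviewer effect plus the posterior mean of the residual speed; its
#' SE is the posterior SD of the residual speed.
#'
#' @param records long-format rows of one person.
#' @param items calibrated item bank.
#' @param structure a [population_structure()].
#' @param design an [interviewer_design()] (for `model1`--`model3`).
#' @param variant model variant.
#' @param quad a [quadrature_spec()].
#' @return one-row data.frame: `person_id`, `theta1..H`, `se_theta1..H`,
#'   `tau`, `se_tau` (NA for `mgrm`), `no_data`, `variant`.
#' @export
eap_score <- function(records, items, structure, design = NULL,
                      variant = "model0", quad = quadrature_spec()) {
  score_dataset(records, items, structure, design, variant, quad)
}

#' EAP scores for every person in a dataset
#'
#' @inheritParams eap_score
#' @param table long-format data.frame.
#' @return data.frame with one row per person (see [eap_score()]).
#' @export
score_dataset <- function(table, items, structure, design = NULL,
                          variant = "model0", quad = quadrature_spec()) {
  variant <- model_variant(variant)
  items <- item_bank(items)
  table <- check_raw_table(table)
  use_rt <- variant_uses_rt(variant)
  lv <- if (!is.null(design)) design$levels
  wide <- build_wide(table, items, interviewer_levels = lv)
  es <- estep(wide, items, structure, design, variant, quad, moments = TRUE)
  H <- structure$H
  theta <- es$Eth
  se_theta <- sqrt(pmax(es$Eth2 - es$Eth^2, 0))
  out <- data.frame(person_id = wide$person_ids, stringsAsFactors = FALSE)
  for (d in seq_len(H)) out[[paste0("theta", d)]] <- theta[, d]
  for (d in seq_len(H)) out[[paste0("se_theta", d)]] <- se_theta[, d]
  if (use_rt) {
    tau <- es$Etau
    if (variant == "model2") {
      tau <- tau + design$gamma[wide$interviewer]
    }
    out$tau <- tau
    out$se_tau <- sqrt(pmax(es$Etau2 - es$Etau^2, 0))
  } else {
    out$tau <- NA_real_
    out$se_tau <- NA_real_
  }
  out$no_data <- es$no_data
  if (any(es$no_data)) {             # posterior equals the prior
    for (d in seq_len(H)) {
      out[[paste0("theta", d)]][es$no_data] <- 0
      out[[paste0("se_theta", d)]][es$no_data] <- 1
    }
    if (use_rt) {
      out$tau[es$no_data] <- if (variant == "model2") {
        design$gamma[wide$interviewer[es$no_data]]
      } else 0
      out$se_tau[es$no_data] <- 1
    }
  }
  out$variant <- variant
  out
}

#' Compare score precision between two scorings of the same persons
#'
#' Per-dimension mean and SD of the posterior SEs of two score tables, with
#' a paired t-test of the SE difference (`b - a`; a negative mean difference
#' means scoring `b` is more precise).
#'
#' @param scores_a,scores_b outputs of [score_dataset()] over the same
#'   persons.
#' @return data.frame with one row per dimension: mean/SD of SE under each
#'   scoring, `mean_diff`, and the paired `p` value.
#' @export
se_summary_compare <- function(scores_a, scores_b) {
  if (!setequal(scores_a$person_id, scores_b$person_id)) {
    stop("the two score tables must contain the same persons")
  }
  scores_b <- scores_b[match(scores_a$person_id, scores_b$person_id), ]
  dims <- grep("^se_theta", names(scores_a), value = TRUE)
  rows <- lapply(dims, function(col) {
    a <- scores_a[[col]]
    b <- scores_b[[col]]
    d <- b - a
    p <- if (sd(d) > 0) t.test(b, a, paired = TRUE)$p.value else 1
    data.frame(dimension = as.integer(sub("se_theta", "", col)),
               mean_se_a = mean(a), sd_se_a = sd(a),
               mean_se_b = mean(b), sd_se_b = sd(b),
               mean_diff = mean(d), p = p)
  })
  do.call(rbind, rows)
}
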