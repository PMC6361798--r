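# Synthetic-data generator: determinism, design arithmetic, latent and
# observed moments, linked-batch structure, pipeline closure.

test_that("the generator is deterministic given its seed", {
  cfg <- quick_config(601, N = 30, J = 12, H = 3)
  b1 <- generate_item_bank(cfg, J = 12)
  b2 <- generate_item_bank(cfg, J = 12)
  expect_identical(b1, b2)
  p1 <- generate_persons(cfg, N = 30)
  p2 <- generate_persons(cfg, N = 30)
  expect_identical(p1, p2)
  sim1 <- quick_sim(602, N = 25, J = 6)
  sim2 <- quick_sim(602, N = 25, J = 6)
  expect_identical(sim1$data, sim2$data)
})

test_that("domains split in near-equal thirds and thresholds increase", {
  cfg <- quick_config(603, H = 3)
  bank <- generate_item_bank(cfg, J = 96)
  expect_equal(as.integer(table(bank$domain)), rep(32L, 3))
  for (j in seq_len(nrow(bank))) {
    b <- item_thresholds(bank, j)
    if (length(b) > 1) expect_true(all(diff(b) > 0))
  }
})

test_that("persons have the configured latent moments and block assignment", {
  cfg <- simulation_config(seed = 604, n_persons = 10000,
                           n_unique_items = 10, n_linking = 0, H = 3,
                           P = 5, contamination_fraction = 0,
                           missing_rate = 0)
  pers <- generate_persons(cfg, N = 10000, roster = paste0("I", 1:5))
  th <- as.matrix(pers[, c("theta1", "theta2", "theta3")])
  expect_lt(max(abs(cor(th) - cfg$R_theta)), 0.03)
  expect_lt(max(abs(cor(th, pers$tau))), 0.03)
  expect_lt(max(abs(colMeans(th))), 0.05)
  # contiguous one-interviewer blocks
  expect_equal(length(unique(pers$interviewer_id)), 5)
  runs <- rle(pers$interviewer_id)
  expect_equal(length(runs$lengths), 5)
})

test_that("simulated responses match the model probabilities", {
  cfg <- quick_config(605, H = 1, n_categories = 4L)
  bank <- generate_item_bank(cfg, J = 1)
  pers <- generate_persons(cfg, N = 40000, roster = "I1")
  dat <- simulate_dataset(bank, pers, cfg, "model0", seed = NULL)
  freq <- tabulate(dat$response, 4) / nrow(dat)
  # expected frequencies under the standard-normal trait distribution
  grid <- statmod::gauss.quad.prob(41, dist = "normal")
  expected <- rowSums(vapply(seq_along(grid$nodes), function(g) {
    category_probs(bank, grid$nodes[g]) * grid$weights[g]
  }, numeric(4)))
  expect_lt(max(abs(freq - expected)), 0.01)
})

test_that("mean observed log RT per item is close to its time intensity", {
  # slow items and tight residuals keep the 3 s administration floor
  # out of play so the raw moment identity is visible
  cfg <- simulation_config(seed = 606, n_persons = 20000,
                           n_unique_items = 6, n_linking = 0, H = 2,
                           lam_mean = log(14), lam_sd = 0.1,
                           sigma_range = c(0.2, 0.3), P = 1,
                           R_theta = default_R_theta(2),
                           rho = default_rho(2),
                           contamination_fraction = 0, missing_rate = 0)
  bank <- generate_item_bank(cfg, J = 6)
  pers <- generate_persons(cfg, N = 20000, roster = "I1")
  dat <- simulate_dataset(bank, pers, cfg, "model0", seed = NULL)
  mlog <- tapply(log(dat$rt), dat$item_id, mean)[bank$item_id]
  expect_lt(max(abs(mlog - bank$lam)), 0.02)
})

test_that("without contamination every RT survives the lower trim rule", {
  sim <- quick_sim(607, N = 150, J = 8, contamination = 0)
  expect_true(all(sim$data$rt >= 3))
  out <- trim_rts(sim$data)
  # every removal comes from the upper-tail rule
  removed <- sim$data$rt[is.na(out$table$rt) & !is.na(sim$data$rt)]
  expect_true(all(removed > out$report$rt_cuts[["1"]]$upper))
})

test_that("contaminated RTs show large positive skewness that trimming cuts", {
  sim <- quick_sim(608, N = 300, J = 10, contamination = 0.05)
  out <- trim_rts(sim$data)
  expect_gt(out$report$skewness_before, 5)
  expect_lt(out$report$skewness_after, 2.5)
})

test_that("linked batches reproduce the configured design shape", {
  cfg <- simulation_config(seed = 609, n_persons = c(40, 30, 30, 30),
                           n_unique_items = c(85, 72, 72, 71),
                           n_linking = 24, H = 3, P = c(6, 5, 5, 5),
                           contamination_fraction = 0, missing_rate = 0)
  sim <- make_linked_batches(cfg, variant = "model2")
  sizes <- vapply(sim$batched$batches,
                  function(b) length(unique(b$item_id)), 0L)
  expect_equal(unname(sizes), c(109L, 96L, 96L, 95L))
  # every batch contains all 24 linking items, 8 per domain
  for (b in sim$batched$batches) {
    expect_true(all(sim$linking_item_ids %in% b$item_id))
  }
  link_dom <- sim$bank$domain[match(sim$linking_item_ids,
                                    sim$bank$item_id)]
  expect_equal(as.integer(table(link_dom)), rep(8L, 3))
  # batch 1 roster: six interviewers, three shared with the common five
  expect_equal(length(sim$rosters[[1]]), 6L)
  expect_equal(length(intersect(sim$rosters[[1]], sim$rosters[[2]])), 3L)
  expect_equal(sim$rosters[[2]], sim$rosters[[3]])
  # stacking passes all structural checks
  st <- stack_batches(sim$batched)
  expect_equal(length(unique(st$item_id)), 324L)
})

test_that("the full pipeline runs end to end on generated batches", {
  cfg <- simulation_config(seed = 610, n_persons = c(150, 150),
                           n_unique_items = c(6, 6), n_linking = 4,
                           H = 2, n_categories = 3L, P = c(2, 2),
                           R_theta = default_R_theta(2),
                           rho = default_rho(2),
                           contamination_fraction = 0.03,
                           missing_rate = 0.02)
  sim <- make_linked_batches(cfg, variant = "model0")
  cleaned <- lapply(sim$batched$batches, function(b) {
    preprocess_data(b, max_missing_items = 8)$table
  })
  bd <- batched_dataset(cleaned, sim$linking_item_ids)
  fit <- concurrent_calibrate(bd, sim$domains, variant = "model0",
                              quad = quadrature_spec(7))
  expect_true(fit$converged)
  idx <- match(fit$items$item_id, sim$bank$item_id)
  expect_lt(mean(abs(fit$items$lam - sim$bank$lam[idx])), 0.15)
  scores <- score_dataset(stack_batches(bd), fit$items, fit$population,
                          variant = "model0", quad = quadrature_spec(7))
  expect_equal(nrow(scores), 300)
  expect_true(all(is.finite(scores$theta1)))
  truth <- do.call(rbind, sim$persons)
  m <- match(scores$person_id, truth$person_id)
  expect_gt(cor(scores$theta1, truth$theta1[m]), 0.6)
})
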