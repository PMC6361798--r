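# Multi-batch calibration: stacking, concurrent calibration, fixed-parameter
# calibration, linking diagnostics.

two_batch_sim <- function(seed, N = 10L, n_unique = 8L, n_linking = 4L,
                          variant = "model0", n_categories = 3L) {
  cfg <- simulation_config(seed = seed, n_persons = rep(N, 2),
                           n_unique_items = rep(n_unique, 2),
                           n_linking = n_linking, H = 2L,
                           n_categories = n_categories, P = c(2L, 2L),
                           R_theta = default_R_theta(2),
                           rho = default_rho(2),
                           contamination_fraction = 0, missing_rate = 0)
  make_linked_batches(cfg, variant = variant)
}

test_that("stacking produces missing-by-design with the expected row count", {
  sim <- two_batch_sim(501)
  st <- stack_batches(sim$batched)
  # 2 batches x 10 persons x (8 unique + 4 linking) observed rows
  expect_equal(nrow(st), 2 * 10 * 12)
  expect_equal(length(unique(st$item_id)), 2 * 8 + 4)
  expect_equal(length(unique(st$person_id)), 20)
  # every person has rows only for their batch's items
  b1_items <- unique(sim$batched$batches[["1"]]$item_id)
  p1 <- unique(sim$batched$batches[["1"]]$person_id)[1]
  expect_setequal(st$item_id[st$person_id == p1], b1_items)
})

test_that("single-batch stacking is the identity", {
  sim <- quick_sim(502, N = 8, J = 5)
  bd <- batched_dataset(list(only = sim$data), character(0))
  st <- stack_batches(bd)
  expect_equal(st$response, sim$data$response)
  expect_equal(st$rt, sim$data$rt)
  expect_true(all(st$batch_id == "only"))
})

test_that("structural violations of the batch design are errors", {
  sim <- two_batch_sim(503)
  b <- sim$batched$batches
  # linking item missing from one batch
  broken <- b
  drop_id <- sim$linking_item_ids[1]
  broken[["2"]] <- broken[["2"]][broken[["2"]]$item_id != drop_id, ]
  expect_error(batched_dataset(broken, sim$linking_item_ids), "absent from")
  # person in two batches
  dup <- b
  row <- dup[["1"]][1, ]
  row$item_id <- setdiff(unique(dup[["2"]]$item_id),
                         unique(dup[["1"]]$item_id))[1]
  dup[["2"]] <- rbind(dup[["2"]], row)
  expect_error(batched_dataset(dup, sim$linking_item_ids), "more than one")
  # a non-linking item shared by two batches
  shared <- b
  extra <- shared[["1"]][shared[["1"]]$item_id ==
                           setdiff(unique(shared[["1"]]$item_id),
                                   sim$linking_item_ids)[1], ]
  extra$person_id <- paste0("x", extra$person_id)
  shared[["2"]] <- rbind(shared[["2"]], extra)
  expect_error(batched_dataset(shared, sim$linking_item_ids),
               "more than one batch")
})

test_that("unlinked multi-batch calibration is refused", {
  sim <- two_batch_sim(504)
  b <- lapply(sim$batched$batches, function(x) {
    x[!x$item_id %in% sim$linking_item_ids, ]
  })
  bd <- batched_dataset(b, character(0))
  expect_error(concurrent_calibrate(bd, sim$domains), "share no items")
})

test_that("a thin linking fraction triggers a warning, not an error", {
  base <- quick_sim(505, N = 120, J = 13, H = 2, n_categories = 2L)
  ids <- sort(unique(base$data$item_id))
  persons <- sort(unique(base$data$person_id))
  b1 <- base$data[base$data$person_id %in% persons[1:60] &
                    base$data$item_id %in% ids[1:7], ]
  b2 <- base$data[base$data$person_id %in% persons[61:120] &
                    base$data$item_id %in% ids[7:13], ]
  sim <- list(batched = batched_dataset(list("1" = b1, "2" = b2), ids[7]),
              domains = base$domains)
  w <- capture_warnings(
    concurrent_calibrate(sim$batched, sim$domains, variant = "mgrm",
                         quad = quadrature_spec(5),
                         control = fit_control(max_iter = 3)))
  expect_true(any(grepl("linking fraction", w)))
})

test_that("concurrent calibration puts both batches' items on one scale", {
  sim <- two_batch_sim(506, N = 250, n_unique = 6, n_linking = 4,
                       variant = "model0")
  fit <- concurrent_calibrate(sim$batched, sim$domains, variant = "model0",
                              quad = quadrature_spec(9))
  expect_true(fit$converged)
  idx <- match(fit$items$item_id, sim$bank$item_id)
  expect_gt(cor(fit$items$a, sim$bank$a[idx]), 0.8)
  expect_gt(cor(fit$items$lam, sim$bank$lam[idx]), 0.98)
  expect_lt(mean(abs(fit$items$lam - sim$bank$lam[idx])), 0.1)
  # one parameter set per linking item, estimated from both batches
  expect_equal(sum(fit$items$item_id %in% sim$linking_item_ids), 4)
})

test_that("single-batch concurrent calibration equals a direct fit", {
  sim <- quick_sim(507, N = 100, J = 6, H = 2)
  bd <- batched_dataset(list("1" = sim$data), character(0))
  f1 <- concurrent_calibrate(bd, sim$domains, variant = "mgrm",
                             quad = quadrature_spec(7))
  f2 <- fit_mml(sim$data, sim$domains, variant = "mgrm",
                quad = quadrature_spec(7))
  expect_equal(f1$minus2ll, f2$minus2ll, tolerance = 1e-10)
  expect_equal(f1$items$a, f2$items$a, tolerance = 1e-10)
})

test_that("fixed-parameter calibration leaves frozen values bit-identical", {
  sim <- quick_sim(508, N = 200, J = 12, H = 2, n_categories = 3L)
  anchors <- sim$bank[1:4, ]
  fit <- fixed_parameter_calibrate(sim$data, anchors, sim$domains,
                                   variant = "model0",
                                   quad = quadrature_spec(7))
  i <- match(anchors$item_id, fit$items$item_id)
  expect_identical(fit$items$a[i], anchors$a)
  expect_identical(fit$items$b1[i], anchors$b1)
  expect_identical(fit$items$b2[i], anchors$b2)
  expect_identical(fit$items$lam[i], anchors$lam)
  expect_identical(fit$items$phi[i], anchors$phi)
  # frozen parameters are excluded from the free count
  full <- count_free_parameters(fit$design_summary, "model0")
  expect_equal(fit$n_free_params,
               full - sum(anchors$n_categories) - 2L * nrow(anchors))
  ld <- linking_diagnostics(anchors, fit, anchors$item_id)
  expect_equal(ld$max_abs_delta, 0)
})

test_that("freezing every item estimates only population parameters", {
  sim <- quick_sim(509, N = 150, J = 6, H = 2)
  fit <- fixed_parameter_calibrate(sim$data, sim$bank, sim$domains,
                                   variant = "model0",
                                   quad = quadrature_spec(7))
  expect_identical(fit$items$a, sim$bank$a)
  # free: sigma_omega per item, rho per dim, one correlation
  expect_equal(fit$n_free_params, 6L + 2L + 1L)
  expect_lt(max(abs(fit$population$rho - sim$config$rho)), 0.25)
})

test_that("anchors frozen with more categories than observed impose only the top thresholds", {
  sim <- quick_sim(510, N = 200, J = 6, H = 1, n_categories = 3L)
  # pick an item whose observed data kept all three categories
  obs_k <- tapply(sim$data$response, sim$data$item_id, max)
  target <- names(obs_k)[obs_k == 3L][1L]
  anchor <- sim$bank[sim$bank$item_id == target, ]
  # frozen values carry four categories; the new data only shows three
  anchor <- set_item_thresholds(anchor, 1L,
                                c(-2.5, item_thresholds(anchor, 1L)))
  fit <- suppressWarnings(
    fixed_parameter_calibrate(sim$data, anchor, sim$domains,
                              variant = "mgrm", quad = quadrature_spec(7),
                              control = fit_control(max_iter = 50)))
  i <- match(anchor$item_id, fit$items$item_id)
  expect_equal(fit$items$n_categories[i], 3L)
  expect_identical(fit$items$b1[i], anchor$b2)
  expect_identical(fit$items$b2[i], anchor$b3)
})

test_that("missing frozen items are reported as errors", {
  sim <- quick_sim(511, N = 20, J = 4)
  ghost <- item_parameters("nope", 1, 1, 0, lam = 2, phi = 0.4,
                           sigma_omega = 0.3)
  expect_error(fixed_parameter_calibrate(sim$data, ghost, sim$domains),
               "no frozen item")
})

test_that("two-stage calibration recovers held-out unique items", {
  sim <- two_batch_sim(512, N = 250, n_unique = 6, n_linking = 4,
                       variant = "model0")
  # stage 1: calibrate batch 2 alone; stage 2: fix its linking items and
  # estimate batch 1's unique items on that scale
  b2 <- sim$batched$batches[["2"]]
  dom <- sim$domains
  s1 <- fit_mml(b2, dom, variant = "model0", quad = quadrature_spec(9))
  anchors <- s1$items[s1$items$item_id %in% sim$linking_item_ids, ]
  b1 <- sim$batched$batches[["1"]]
  s2 <- fixed_parameter_calibrate(b1, anchors, dom, variant = "model0",
                                  quad = quadrature_spec(9))
  uniq <- setdiff(unique(b1$item_id), sim$linking_item_ids)
  i_fit <- match(uniq, s2$items$item_id)
  i_true <- match(uniq, sim$bank$item_id)
  expect_lt(mean(abs(s2$items$lam[i_fit] - sim$bank$lam[i_true])), 0.15)
  expect_gt(cor(s2$items$a[i_fit], sim$bank$a[i_true]), 0.6)
  ld <- linking_diagnostics(s1, s2, sim$linking_item_ids)
  expect_equal(ld$max_abs_delta, 0)
})
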