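# Cleaning pipeline: respondent exclusion, RT trimming, category
# collapsing, parameter remapping, log-normality diagnostics.

toy_table <- function(n_persons, n_items, batch = "1") {
  expand.grid(person_id = sprintf("p%02d", seq_len(n_persons)),
              item_id = sprintf("i%02d", seq_len(n_items)),
              stringsAsFactors = FALSE) |>
    transform(response = 1L, rt = 10, interviewer_id = "I1",
              batch_id = batch)
}

test_that("respondent filtering uses inclusive missing-count semantics", {
  tab <- toy_table(10, 20)
  tab$response[tab$person_id %in% c("p01", "p02")] <- NA
  out <- filter_respondents(tab, max_missing_items = 20)
  expect_equal(out$report$n_before, 10)
  expect_equal(out$report$n_after, 8)
  expect_equal(out$report$n_excluded_respondents, 2)
  expect_setequal(out$report$excluded_persons, c("p01", "p02"))
  expect_false(any(c("p01", "p02") %in% out$table$person_id))

  # threshold above any possible count: identity
  out2 <- filter_respondents(tab, max_missing_items = 21)
  expect_equal(nrow(out2$table), nrow(tab))
  # complete data: identity with zero exclusions
  out3 <- filter_respondents(toy_table(5, 6), max_missing_items = 1)
  expect_equal(out3$report$n_excluded_respondents, 0)
})

test_that("respondent filtering counts unseen items of the person's batch", {
  tab <- toy_table(4, 6)
  # p04 only has rows for two items; the other four count as missing
  tab <- tab[!(tab$person_id == "p04" & tab$item_id > "i02"), ]
  out <- filter_respondents(tab, max_missing_items = 4)
  expect_equal(out$report$excluded_persons, "p04")
})

test_that("per-batch thresholds apply to their own batches", {
  t1 <- toy_table(3, 4, batch = "1")
  t2 <- toy_table(3, 4, batch = "2")
  t2$person_id <- sub("^p", "q", t2$person_id)
  t1$response[t1$person_id == "p01" & t1$item_id %in% c("i01", "i02")] <- NA
  t2$response[t2$person_id == "q01" & t2$item_id %in% c("i01", "i02")] <- NA
  out <- filter_respondents(rbind(t1, t2),
                            max_missing_items = c("1" = 2, "2" = 3))
  expect_equal(out$report$excluded_persons, "p01")
})

test_that("RT trimming removes the sub-3s values and the upper 2.5% tail", {
  tab <- toy_table(1, 40)
  tab$rt <- 1:40
  out <- trim_rts(tab)
  kept <- out$table$rt[!is.na(out$table$rt)]
  expect_setequal(kept, 3:39)               # 1, 2 and 40 removed
  expect_equal(length(kept), 37)
  expect_equal(out$report$trimmed_rt_fraction, 3 / 40)
  expect_equal(out$report$rt_cuts[["1"]]$upper, 39.025)
  # responses untouched
  expect_equal(out$table$response, tab$response)

  # all values at or inside both cut-points: identity (the flat top sits
  # exactly on the upper percentile value and survives)
  tab2 <- toy_table(1, 10)
  tab2$rt <- c(3, 4, 5, rep(6, 7))
  out2 <- trim_rts(tab2)
  expect_equal(out2$table$rt, tab2$rt)
})

test_that("values exactly at the cut-points are retained", {
  tab <- toy_table(1, 5)
  tab$rt <- c(3, 4, 5, 6, 7)
  out <- trim_rts(tab, upper_percentile = 97.5)
  expect_true(3 %in% out$table$rt)
})

test_that("trimming reduces skewness of a contaminated lognormal sample", {
  set.seed(7)
  n <- 4000
  rt <- exp(rnorm(n, 2, 0.4))
  idx <- sample(n, 120)
  rt[idx[1:60]] <- runif(60, 0.5, 2.9)
  rt[idx[61:120]] <- rt[idx[61:120]] * runif(60, 10, 50)
  tab <- data.frame(person_id = sprintf("p%04d", seq_len(n)), item_id = "i1",
                    response = 1L, rt = rt, interviewer_id = "I1",
                    batch_id = "1")
  out <- trim_rts(tab)
  expect_lt(out$report$skewness_after, out$report$skewness_before)
  expect_gt(out$report$skewness_before, 5)
})

test_that("sparse categories merge upward, sparse top category merges down", {
  m1 <- collapse_and_recode(c(0, 1, 50, 49))
  expect_equal(m1$old_to_new, c(1, 1, 1, 2))
  expect_equal(m1$counts_new, c(51, 49))
  expect_true(m1$usable)

  m2 <- collapse_and_recode(c(5, 10, 20, 30))
  expect_equal(m2$old_to_new, 1:4)
  expect_equal(nrow(m2$merged_pairs), 0)

  m3 <- collapse_and_recode(c(40, 30, 1, 0))
  expect_equal(m3$old_to_new, c(1, 2, 2, 2))
  expect_equal(m3$counts_new, c(40, 31))

  # everything sparse: unusable
  m4 <- collapse_and_recode(c(1, 0, 1))
  expect_false(m4$usable)
})

test_that("collapse maps are monotone bijections onto 1..K'", {
  set.seed(11)
  for (rep in 1:30) {
    K <- sample(2:4, 1)
    counts <- rpois(K, lambda = sample(c(0.5, 3, 20), K, replace = TRUE))
    map <- collapse_and_recode(counts)
    expect_true(all(diff(map$old_to_new) >= 0))
    if (map$usable) {
      expect_equal(sort(unique(map$old_to_new)),
                   seq_len(max(map$old_to_new)))
      expect_true(all(map$counts_new[-length(map$counts_new)] >= 2) ||
                    sum(counts) < 4)
      expect_equal(sum(map$counts_new), sum(counts))
    }
  }
})

test_that("parameter remapping keeps the surviving boundaries unchanged", {
  it <- item_parameters("i", 1, 1.2, c(-1.5, -0.2, 0.9))
  map <- collapse_and_recode(c(1, 40, 30, 29))   # lowest two merge
  out <- remap_collapsed_parameters(it, map)
  expect_equal(out$a, 1.2)
  expect_equal(out$n_categories, 3L)
  expect_equal(unname(unlist(out[, c("b1", "b2")])), c(-0.2, 0.9))

  idmap <- collapse_and_recode(c(10, 20, 30, 40))
  expect_equal(remap_collapsed_parameters(it, idmap), it)

  expect_error(remap_collapsed_parameters(it, collapse_and_recode(c(2, 50))),
               "categories")
})

test_that("refitting a collapsed item recovers the retained parameters", {
  # simulate a 4-category item whose lowest category is almost never used;
  # fitting the collapsed 3-category version should recover a, b2, b3
  sim <- quick_sim(301, N = 800, J = 6, H = 1, n_categories = 4L)
  bank <- sim$bank
  bank$b1[1] <- -6       # category 1 practically empty for item 1
  dat <- simulate_dataset(bank, sim$persons, sim$config, "model0",
                          seed = 99)
  pre <- preprocess_data(dat, upper_percentile = 99.99)
  target <- bank$item_id[1]
  expect_equal(pre$collapse_maps[[target]]$old_to_new, c(1L, 1L, 2L, 3L))
  fit <- fit_mml(pre$table, sim$domains, variant = "mgrm",
                 quad = quadrature_spec(21))
  j <- match(target, fit$items$item_id)
  expect_equal(fit$items$n_categories[j], 3L)
  expect_equal(fit$items$a[j], bank$a[1], tolerance = 0.35)
  expect_equal(fit$items$b1[j], bank$b2[1], tolerance = 0.35)
  expect_equal(fit$items$b2[j], bank$b3[1], tolerance = 0.35)
})

test_that("K-S statistic equals the brute-force sup-difference", {
  x <- c(1.2, 0.4, -0.3, 2.1, 0.8, -1.5, 0.1, 0.6, 1.9, -0.7)
  d <- normality_diagnostics(x)
  xs <- sort(x)
  n <- length(xs)
  Fx <- pnorm(xs, mean(x), sd(x))
  manual <- max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
  expect_equal(d$ks_stat, manual, tolerance = 1e-12)
})

test_that("normality diagnostics accept normal data and flag skewed data", {
  set.seed(21)
  ok <- 0
  for (s in 1:10) {
    x <- rnorm(1000, 2, 0.5)
    d <- normality_diagnostics(x)
    expect_lt(d$ks_stat, 0.06)
    if (d$ks_p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 7)         # most draws not flagged
  y <- rexp(500)
  d2 <- normality_diagnostics(log(exp(y)))   # exponential: heavily skewed
  expect_lt(d2$sw_p, 0.05)
  expect_error(normality_diagnostics(rep(1, 20)), "constant")
  expect_error(normality_diagnostics(rnorm(5)), "at least 8")
})

test_that("the cleaning pipeline is idempotent", {
  sim <- quick_sim(77, N = 60, J = 8, contamination = 0.05, missing = 0.05)
  once <- preprocess_data(sim$data, max_missing_items = 6)
  twice <- preprocess_data(once$table, max_missing_items = 6)
  expect_equal(twice$table$response, once$table$response)
  expect_equal(twice$table$rt, once$table$rt)
  expect_equal(twice$report$n_excluded_respondents, 0)
  expect_equal(twice$report$trimmed_rt_fraction, 0)
})

test_that("trimming a clean batch removes about 2.5% (the upper rule only)", {
  sim <- quick_sim(55, N = 400, J = 12, contamination = 0)
  tab <- sim$data
  tab$rt <- pmax(tab$rt, 3.01)       # nothing below the lower cut
  out <- trim_rts(tab)
  n <- sum(!is.na(tab$rt))
  band <- 3 * sqrt(0.025 * 0.975 / n)
  expect_lt(abs(out$report$trimmed_rt_fraction - 0.025), band + 1e-3)
})
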