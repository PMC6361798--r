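# Data cleaning for interviewer-administered response + RT tables:
# respondent exclusion, RT trimming, log-normality diagnostics, and
# collapsing of sparse response categories.

# Validate a long-format raw table; returns it with canonical column types.
check_raw_table <- function(table, require_batch = FALSE) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  req <- c("person_id", "item_id", "response", "rt")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("raw table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"interviewer_id" %in% names(table)) table$interviewer_id <- NA
  if (!"batch_id" %in% names(table)) {
    if (require_batch) stop("raw table is missing column batch_id")
    table$batch_id <- 1L
  }
  table$person_id <- as.character(table$person_id)
  table$item_id <- as.character(table$item_id)
  key <- paste(table$person_id, table$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicated (person_id, item_id) pair: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }
  if (any(!is.na(table$rt) & table$rt <= 0)) {
    stop("response times must be positive where present")
  }
  table
}

# Moment skewness m3 / m2^(3/2).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

empty_clean_report <- function() {
  list(n_before = 0L, n_after = 0L, n_excluded_respondents = 0L,
       excluded_persons = character(0), trimmed_rt_fraction = 0,
       rt_cuts = NULL, skewness_before = NA_real_, skewness_after = NA_real_,
       collapse_maps = NULL)
}

#' Exclude respondents with too many missing responses
#'
#' Removes every person whose number of missing item responses (relative to
#' the full item set of their batch) is at least `max_missing_items`.
#'
#' @param table long-format data.frame with columns `person_id`, `item_id`,
#'   `response`, `rt`, and optionally `interviewer_id`, `batch_id`.
#' @param max_missing_items inclusive threshold: persons missing this many or
#'   more responses are dropped.  May be a single value or a named vector
#'   giving a threshold per batch.
#' @return list with the filtered `table` and a `report` recording
#'   `n_before`, `n_after` and `n_excluded_respondents`.
#' @export
filter_respondents <- function(table, max_missing_items) {
  table <- check_raw_table(table)
  rep <- empty_clean_report()
  if (nrow(table) == 0L) return(list(table = table, report = rep))
  if (any(max_missing_items < 0)) stop("max_missing_items must be >= 0")

  persons <- unique(table[, c("person_id", "batch_id")])
  n_items_batch <- tapply(table$item_id, table$batch_id,
                          function(x) length(unique(x)))
  n_obs <- tapply(!is.na(table$response), table$person_id, sum)
  n_missing <- n_items_batch[as.character(persons$batch_id)] -
    as.numeric(n_obs[persons$person_id])

  if (length(max_missing_items) == 1L && is.null(names(max_missing_items))) {
    thr <- rep(max_missing_items, nrow(persons))
  } else {
    thr <- max_missing_items[as.character(persons$batch_id)]
    if (anyNA(thr)) stop("no missing-item threshold for some batch")
  }
  drop <- persons$person_id[n_missing >= thr]
  out <- table[!table$person_id %in% drop, , drop = FALSE]
  rownames(out) <- NULL
  rep$n_before <- nrow(persons)
  rep$n_after <- rep$n_before - length(drop)
  rep$n_excluded_respondents <- length(drop)
  rep$excluded_persons <- sort(drop)
  list(table = out, report = rep)
}

#' Trim extreme response times
#'
#' Marks as missing every RT below `min_seconds` or above the batch's upper
#' percentile.  Both cut-points are computed from the pooled, pre-trim RT
#' distribution of the batch; the associated responses are retained.  Values
#' exactly equal to `min_seconds` or to the percentile cut survive.
#'
#' @param table long-format raw table.
#' @param min_seconds lower cut in seconds (default 3).
#' @param upper_percentile percentile (0--100, default 97.5) above which RTs
#'   are removed; computed with the linear-interpolation quantile convention.
#' @param cuts optional list of previously computed per-batch cut-points (as
#'   stored in a trim report), reused instead of recomputing so that the
#'   cleaning pipeline is idempotent.
#' @return list with the trimmed `table` and a `report` containing the
#'   trimmed fraction, the per-batch cut-points and the pooled skewness of
#'   the RTs before and after trimming.
#' @export
trim_rts <- function(table, min_seconds = 3, upper_percentile = 97.5,
                     cuts = NULL) {
  table <- check_raw_table(table)
  rep <- empty_clean_report()
  if (upper_percentile <= 0 || upper_percentile >= 100) {
    stop("upper_percentile must be strictly between 0 and 100")
  }
  obs <- !is.na(table$rt)
  if (!any(obs)) {
    warning("no observed response times; nothing to trim")
    return(list(table = table, report = rep))
  }
  rep$skewness_before <- sample_skewness(table$rt[obs])
  batches <- sort(unique(table$batch_id))
  if (is.null(cuts)) {
    cuts <- lapply(setNames(batches, batches), function(bt) {
      x <- table$rt[obs & table$batch_id == bt]
      list(lower = min_seconds,
           upper = unname(quantile(x, upper_percentile / 100, type = 7,
                                   names = FALSE)))
    })
  }
  drop <- logical(nrow(table))
  for (bt in batches) {
    cut <- cuts[[as.character(bt)]]
    if (is.null(cut)) stop("no stored cut-points for batch ", bt)
    sel <- obs & table$batch_id == bt
    drop[sel] <- table$rt[sel] < cut$lower | table$rt[sel] > cut$upper
  }
  table$rt[drop] <- NA_real_
  rep$n_before <- rep$n_after <- length(unique(table$person_id))
  rep$trimmed_rt_fraction <- sum(drop) / sum(obs)
  rep$rt_cuts <- cuts
  rep$skewness_after <- sample_skewness(table$rt[!is.na(table$rt)])
  list(table = table, report = rep)
}

#' Collapse sparse response categories of one item
#'
#' Any category observed at most once is merged into the next higher
#' category; a sparse top category merges downward into the next lower one.
#' Surviving category groups are recoded to contiguous codes starting at 1.
#'
#' @param counts vector of response counts per original category (category
#'   codes `1..K` in order).
#' @return list of class `grt_collapse_map` with `old_to_new` (integer vector
#'   over original codes), `merged_pairs` (each row a merged source category
#'   and the category absorbing it), `counts_new`, and `usable` (`FALSE` when
#'   fewer than two categories remain).
#' @export
collapse_and_recode <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  K <- length(counts)
  if (K < 2L) stop("need at least two categories")
  # consecutive groups of original categories, merged until none is sparse
  groups <- lapply(seq_len(K), function(k) list(members = k,
                                                count = as.numeric(counts[k])))
  merged <- matrix(integer(0), ncol = 2L,
                   dimnames = list(NULL, c("source", "absorbed_into")))
  repeat {
    if (length(groups) < 2L) break
    low <- which(vapply(groups, function(g) g$count, 0) <= 1)
    if (!length(low)) break
    i <- low[1L]
    j <- if (i < length(groups)) i + 1L else i - 1L  # top group merges down
    merged <- rbind(merged, c(max(groups[[i]]$members),
                              if (j > i) min(groups[[j]]$members)
                              else max(groups[[j]]$members)))
    groups[[j]]$members <- sort(c(groups[[j]]$members, groups[[i]]$members))
    groups[[j]]$count <- groups[[j]]$count + groups[[i]]$count
    groups[[i]] <- NULL
  }
  old_to_new <- integer(K)
  for (g in seq_along(groups)) old_to_new[groups[[g]]$members] <- g
  structure(list(old_to_new = old_to_new,
                 merged_pairs = merged,
                 counts_new = vapply(groups, function(g) g$count, 0),
                 usable = length(groups) >= 2L),
            class = "grt_collapse_map")
}

#' Remap item parameters after category collapsing
#'
#' Because the graded model is a difference model, merging categories leaves
#' the discrimination and the surviving boundary locations essentially
#' unchanged: the boundaries internal to a merged group are dropped and the
#' remaining thresholds are kept as-is.
#'
#' @param item one-row item bank.
#' @param map a [collapse_and_recode()] result for this item.
#' @return the item with thresholds reduced to the surviving boundaries.
#' @export
remap_collapsed_parameters <- function(item, map) {
  item <- item_bank(item)
  if (nrow(item) != 1L) stop("expected a single item")
  K <- item$n_categories[1L]
  if (length(map$old_to_new) != K) {
    stop("collapse map has ", length(map$old_to_new),
         " categories but item has ", K)
  }
  if (!map$usable) stop("item flagged unusable by the collapse map")
  b <- item_thresholds(item, 1L)
  keep <- map$old_to_new[-K] != map$old_to_new[-1L]  # boundary k between k,k+1
  item <- set_item_thresholds(item, 1L, b[keep])
  item
}

#' Log-normality diagnostics for item response times
#'
#' One-sample Kolmogorov-Smirnov test of the log RTs against a normal
#' distribution with the sample mean and SD (plain K-S, no small-sample
#' correction), plus the Shapiro-Wilk test.
#'
#' @param log_rts vector of log response times for one item (>= 8 values).
#' @return named list: `ks_stat`, `ks_p`, `sw_stat`, `sw_p`.
#' @export
normality_diagnostics <- function(log_rts) {
  x <- log_rts[is.finite(log_rts)]
  if (length(x) < 8L) stop("need at least 8 observations")
  if (sd(x) == 0) stop("constant log RTs: diagnostics undefined")
  ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  xs <- if (length(x) > 5000L) x[seq(1L, length(x), length.out = 5000L)] else x
  sw <- shapiro.test(xs)
  list(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       sw_stat = unname(sw$statistic), sw_p = sw$p.value)
}

#' Per-item log-normality diagnostic table
#'
#' @param table long-format raw table (post-trimming).
#' @param min_n minimum observed RTs per item.
#' @return data.frame with one row per item (by batch).
#' @export
normality_diagnostics_table <- function(table, min_n = 8L) {
  table <- check_raw_table(table)
  keep <- !is.na(table$rt)
  split_key <- interaction(table$batch_id[keep], table$item_id[keep],
                           drop = TRUE)
  parts <- split(table$rt[keep], split_key)
  rows <- lapply(names(parts), function(nm) {
    x <- parts[[nm]]
    if (length(x) < min_n || sd(log(x)) == 0) return(NULL)
    d <- normality_diagnostics(log(x))
    key <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    data.frame(batch_id = key[1L],
               item_id = paste(key[-1L], collapse = "."),
               n = length(x), ks_stat = d$ks_stat, ks_p = d$ks_p,
               sw_stat = d$sw_stat, sw_p = d$sw_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Run the full cleaning pipeline
#'
#' Applies respondent exclusion, RT trimming and per-item category
#' collapsing, in that order.  The trim cut-points are computed once from
#' the raw distribution and recorded on the output, so running the pipeline
#' on its own output changes nothing.
#'
#' @param table long-format raw table.
#' @param max_missing_items respondent-exclusion threshold (scalar or named
#'   per batch), see [filter_respondents()].
#' @param min_seconds,upper_percentile RT trim rules, see [trim_rts()].
#' @param collapse whether to collapse sparse response categories.
#' @return list with the cleaned `table` (responses recoded where collapsed),
#'   `report`, and `collapse_maps` (per item).
#' @export
preprocess_data <- function(table, max_missing_items = Inf,
                            min_seconds = 3, upper_percentile = 97.5,
                            collapse = TRUE) {
  table <- check_raw_table(table)
  prior <- attr(table, "grt_preprocessed")
  f <- filter_respondents(table, max_missing_items)
  t <- trim_rts(f$table, min_seconds, upper_percentile,
                cuts = if (!is.null(prior)) prior$rt_cuts)
  out <- t$table
  maps <- list()
  if (collapse) {
    for (id in sort(unique(out$item_id))) {
      sel <- out$item_id == id & !is.na(out$response)
      if (!any(sel)) next
      K <- max(out$response[sel])
      counts <- tabulate(out$response[sel], nbins = K)
      map <- collapse_and_recode(counts)
      if (any(map$old_to_new != seq_along(map$old_to_new))) {
        out$response[sel] <- map$old_to_new[out$response[sel]]
      }
      maps[[id]] <- map
    }
  }
  report <- t$report
  report$n_before <- f$report$n_before
  report$n_after <- f$report$n_after
  report$n_excluded_respondents <- f$report$n_excluded_respondents
  report$excluded_persons <- f$report$excluded_persons
  report$collapse_maps <- maps
  attr(out, "grt_preprocessed") <- list(rt_cuts = report$rt_cuts)
  list(table = out, report = report, collapse_maps = maps)
}
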