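# Multi-batch calibration: stacking with missing-by-design, concurrent
# calibration through linking (anchor) items, and fixed-parameter
# calibration against a frozen anchor set.

#' Bundle per-batch datasets with their linking structure
#'
#' @param batches named list of long-format tables, one per batch.
#' @param linking_item_ids items administered in every batch; all other
#'   items must appear in exactly one batch.
#' @return list of class `grt_batches`.
#' @export
batched_dataset <- function(batches, linking_item_ids) {
  if (is.null(names(batches)) || any(names(batches) == "")) {
    stop("batches must be a named list")
  }
  linking_item_ids <- as.character(linking_item_ids)
  batches <- lapply(batches, check_raw_table)
  item_sets <- lapply(batches, function(b) unique(b$item_id))
  for (nm in names(batches)) {
    missing_links <- setdiff(linking_item_ids, item_sets[[nm]])
    if (length(missing_links)) {
      stop("linking item(s) absent from batch ", nm, ": ",
           paste(head(missing_links, 5L), collapse = ", "))
    }
  }
  unique_items <- lapply(item_sets, setdiff, y = linking_item_ids)
  tab <- table(unlist(unique_items))
  if (any(tab > 1L)) {
    stop("non-linking item(s) appear in more than one batch: ",
         paste(head(names(tab)[tab > 1L], 5L), collapse = ", "))
  }
  person_sets <- lapply(batches, function(b) unique(b$person_id))
  ptab <- table(unlist(person_sets))
  if (any(ptab > 1L)) {
    stop("person(s) appear in more than one batch: ",
         paste(head(names(ptab)[ptab > 1L], 5L), collapse = ", "))
  }
  structure(list(batches = batches, linking_item_ids = linking_item_ids),
            class = "grt_batches")
}

#' Stack batches into one long table with missing-by-design
#'
#' Persons keep observed rows only for their own batch's items; every other
#' person-item combination is structurally missing (simply absent from the
#' long table).  Batch labels are rewritten to the batch names.
#'
#' @param batched a [batched_dataset()].
#' @return single long-format data.frame.
#' @export
stack_batches <- function(batched) {
  if (!inherits(batched, "grt_batches")) {
    stop("stack_batches expects a batched_dataset()")
  }
  parts <- lapply(names(batched$batches), function(nm) {
    b <- batched$batches[[nm]]
    b$batch_id <- nm
    b
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  check_raw_table(out)
}

# fraction of each batch's items that are linking items
linking_fractions <- function(batched) {
  vapply(batched$batches, function(b) {
    ids <- unique(b$item_id)
    mean(ids %in% batched$linking_item_ids)
  }, 0)
}

#' Concurrent calibration of linked batches
#'
#' One joint marginal maximum likelihood fit over the stacked batches;
#' linking items receive a single parameter set, which places all batches'
#' items on a common scale in a single stage.
#'
#' @param batched a [batched_dataset()].
#' @param domains named domain map covering all items.
#' @param variant model variant.
#' @param min_linking_fraction warn when a batch shares fewer than this
#'   fraction of its items (default 0.2, the usual anchor-share rule of
#'   thumb).
#' @param ... passed to [fit_mml()].
#' @return a `grt_fit`.
#' @export
concurrent_calibrate <- function(batched, domains, variant = "model0",
                                 min_linking_fraction = 0.2, ...) {
  if (!inherits(batched, "grt_batches")) {
    stop("concurrent_calibrate expects a batched_dataset()")
  }
  if (length(batched$batches) > 1L && !length(batched$linking_item_ids)) {
    stop("cannot link batches that share no items")
  }
  fr <- linking_fractions(batched)
  if (length(batched$batches) > 1L && any(fr < min_linking_fraction)) {
    warning("batches with linking fraction below ",
            min_linking_fraction, ": ",
            paste(names(fr)[fr < min_linking_fraction], collapse = ", "))
  }
  fit_mml(stack_batches(batched), domains = domains, variant = variant, ...)
}

#' Fixed-parameter calibration against frozen anchors
#'
#' Estimates the free items of a dataset while the anchor items'
#' discrimination, thresholds, time intensity and time discrimination stay
#' frozen at previously estimated values, so the new items land on the
#' anchors' scale and no further linking step is needed.  When an anchor
#' shows fewer response categories in the new data than its frozen values
#' carry (category collapsing), only the corresponding top thresholds are
#' imposed.
#'
#' @param table long-format dataset containing the anchor items.
#' @param fixed item bank (or `grt_fit`) supplying the frozen values.
#' @param domains named domain map.
#' @param variant model variant.
#' @param ... passed to [fit_mml()].
#' @return a `grt_fit`; frozen values are returned bit-identical.
#' @export
fixed_parameter_calibrate <- function(table, fixed, domains,
                                      variant = "model0", ...) {
  if (inherits(fixed, "grt_fit")) fixed <- fixed$items
  fixed <- item_bank(fixed)
  present <- intersect(fixed$item_id, unique(table$item_id))
  if (!length(present)) stop("no frozen item appears in the dataset")
  fixed <- fixed[fixed$item_id %in% present, , drop = FALSE]
  fit_mml(table, domains = domains, variant = variant, fixed = fixed, ...)
}

#' Anchor-stability diagnostics between two calibration stages
#'
#' Per-anchor differences of the shared parameters between two fits (or item
#' banks), and the largest absolute difference.  After a fixed-parameter
#' calibration all deltas are exactly zero by construction.
#'
#' @param stage1,stage2 `grt_fit` objects or item banks.
#' @param linking_ids the anchor item ids to compare.
#' @return list with `deltas` (data.frame) and `max_abs_delta`.
#' @export
linking_diagnostics <- function(stage1, stage2, linking_ids) {
  if (inherits(stage1, "grt_fit")) stage1 <- stage1$items
  if (inherits(stage2, "grt_fit")) stage2 <- stage2$items
  stage1 <- item_bank(stage1)
  stage2 <- item_bank(stage2)
  shared <- intersect(intersect(stage1$item_id, stage2$item_id),
                      as.character(linking_ids))
  if (!length(shared)) stop("no shared linking items between the stages")
  cols <- c("a", "b1", "b2", "b3", "lam", "phi")
  i1 <- match(shared, stage1$item_id)
  i2 <- match(shared, stage2$item_id)
  deltas <- data.frame(item_id = shared, stringsAsFactors = FALSE)
  for (cl in cols) {
    deltas[[paste0("d_", cl)]] <- stage2[[cl]][i2] - stage1[[cl]][i1]
  }
  dmat <- as.matrix(deltas[, -1L])
  list(deltas = deltas,
       max_abs_delta = max(abs(dmat[is.finite(dmat)]), 0))
}
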