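# File interchange: long-format CSV datasets, parameter tables (CSV),
# population/interviewer structures and fit summaries (JSON), simulation
# configurations (YAML), and a model-comparison table.

#' Read a long-format dataset from CSV
#'
#' Expects columns `person_id`, `item_id`, `response`, `rt`,
#' `interviewer_id`, `batch_id` (missing values encoded as empty fields).
#'
#' @param path CSV file.
#' @return validated long-format data.frame.
#' @export
read_dataset <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("person_id", "item_id", "interviewer_id", "batch_id")) {
    if (col %in% names(raw)) raw[[col]] <- as.character(raw[[col]])
  }
  if (nrow(raw) == 0L) {
    warning("dataset at ", path, " is empty")
  }
  check_raw_table(raw)
}

#' Write a long-format dataset to CSV
#'
#' @param table long-format data.frame.
#' @param path output CSV file.
#' @export
write_dataset <- function(table, path) {
  write.csv(check_raw_table(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write an item parameter table
#'
#' CSV with columns `item_id`, `domain`, `a`, `b1`, `b2`, `b3` (blank where
#' absent), `lam`, `phi`, `sigma_omega`.
#'
#' @param path CSV file.
#' @return a `grt_items` bank.
#' @export
read_item_parameters <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(item_id = "character"))
  if (!"n_categories" %in% names(df)) {
    bcols <- intersect(paste0("b", 1:3), names(df))
    df$n_categories <- 1L + rowSums(!is.na(df[, bcols, drop = FALSE]))
  }
  item_bank(df)
}

#' @rdname read_item_parameters
#' @param items a `grt_items` bank.
#' @export
write_item_parameters <- function(items, path) {
  items <- item_bank(items)
  cols <- c("item_id", "domain", "a", "b1", "b2", "b3", "lam", "phi",
            "sigma_omega")
  write.csv(as.data.frame(items)[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

# deterministic polynomial hash of a configuration echo, for run provenance
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Model-comparison table
#'
#' One row per fitted variant with the free-parameter count, AIC, BIC and
#' deviance, sorted by BIC.
#'
#' @param fits list of `grt_fit` objects.
#' @return data.frame with columns `model`, `n_free_params`, `AIC`, `BIC`,
#'   `minus2LL`.
#' @export
comparison_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    ic <- information_criteria(f$minus2ll, f$n_free_params, f$n_persons)
    data.frame(model = f$variant, n_free_params = f$n_free_params,
               AIC = ic$aic, BIC = ic$bic, minus2LL = f$minus2ll,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$BIC), , drop = FALSE]
}

#' Write fit results to a directory
#'
#' Emits the item parameter CSV, a JSON summary (population structure,
#' interviewer effects, fit statistics, configuration hash and seed), and —
#' when several fits are given — a model-comparison CSV.
#'
#' @param fit a `grt_fit`, or a list of them.
#' @param out_dir output directory (created if needed).
#' @param seed seed to record in the run log.
#' @return invisibly, the paths written.
#' @export
write_results <- function(fit, out_dir, seed = NA_integer_) {
  if (inherits(fit, "grt_fit")) fit <- list(fit)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (f in fit) {
    stem <- file.path(out_dir, paste0("fit_", f$variant))
    write_item_parameters(f$items, paste0(stem, "_items.csv"))
    ic <- information_criteria(f$minus2ll, f$n_free_params, f$n_persons)
    summ <- list(variant = f$variant,
                 loglik = f$loglik, minus2ll = f$minus2ll,
                 n_free_params = f$n_free_params, aic = ic$aic,
                 bic = ic$bic, converged = f$converged,
                 n_iterations = f$n_iterations, n_persons = f$n_persons,
                 H = f$population$H,
                 R_theta = f$population$R_theta,
                 rho = f$population$rho,
                 gamma = if (!is.null(f$design)) f$design$gamma,
                 reference_interviewer = if (!is.null(f$design))
                   f$design$levels[f$design$reference],
                 seed = seed,
                 config_hash = config_hash(list(f$variant, f$quad,
                                                f$domains, seed)))
    jsonlite::write_json(summ, paste0(stem, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, paste0(stem, "_items.csv"),
               paste0(stem, "_summary.json"))
  }
  if (length(fit) > 1L) {
    cmp <- file.path(out_dir, "model_comparison.csv")
    write.csv(comparison_table(fit), cmp, row.names = FALSE)
    paths <- c(paths, cmp)
  }
  invisible(paths)
}

#' Read / write a simulation configuration as YAML
#'
#' @param config a [simulation_config()].
#' @param path YAML file.
#' @export
write_simulation_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$R_theta <- as.vector(cfg$R_theta)
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$R_theta <- matrix(unlist(cfg$R_theta), cfg$H, cfg$H)
  do.call(simulation_config, cfg)
}
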