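# Run configuration, schema validation and the command-level entry points
# behind the CLI script (inst/cli/rpbci).

RUN_CONFIG_KEYS <- c("simulate", "method", "methods", "ddag_order",
                     "algorithm", "odcs", "pstf", "classifiers", "protocol",
                     "seed")

#' Validate a run configuration
#'
#' Checks the configuration tree against the known schema before any
#' computation; unknown keys are rejected by name.
#'
#' @param cfg Named list (typically parsed from YAML or JSON).
#' @return The validated configuration, with defaults filled in, class
#'   `run_config`.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  check_sub <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown config key(s) under '", where, "': ",
           paste(bad, collapse = ", "))
    }
  }
  check_sub(cfg$simulate, setdiff(names(formals(sim_config)), ""), "simulate")
  check_sub(cfg$odcs, c("enabled", "m_best", "val_folds"), "odcs")
  check_sub(cfg$pstf, c("low_pass", "high_pass", "gamma", "window",
                        "inner_folds", "fs_target"), "pstf")
  check_sub(cfg$classifiers, c("algorithms", "rls_lambda"), "classifiers")
  check_sub(cfg$protocol, c("n_chunks", "shuffle"), "protocol")
  if (!is.null(cfg[["method"]])) {
    cfg[["method"]] <- match.arg(cfg[["method"]], TERNARY_METHODS)
  }
  if (!is.null(cfg$methods)) {
    cfg$methods <- vapply(cfg$methods, match.arg, character(1),
                          choices = TERNARY_METHODS)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$ddag_order <- cfg$ddag_order %||% "RIL"
  cfg$algorithm <- cfg$algorithm %||% "FLDA"
  structure(cfg, class = "run_config")
}

#' Read and validate a run configuration file
#'
#' @param path YAML (`.yaml`/`.yml`, requires the `yaml` package) or JSON
#'   configuration file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE)
  }
  validate_run_config(cfg)
}

config_grid <- function(cfg) {
  p <- cfg$pstf
  if (is.null(p)) return(pstf_grid())
  hp <- p$high_pass
  if (!is.null(hp)) {
    hp <- vapply(hp, function(v) {
      if (is.null(v) || (is.character(v) && v %in% c("none", "null")))
        NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  pstf_grid(low_pass = p$low_pass %||% 1:7,
            high_pass = hp %||% c(NA, 0.1, 0.3, 0.5),
            gamma = p$gamma %||% c(0, 1, 10, 1e3, 1e4, 1e5, 1e6),
            window = p$window %||% c(5L, 10L, 25L))
}

#' Simulate a dataset and write it as an epoch container
#'
#' @param cfg A validated `run_config` whose `simulate` block parameterizes
#'   [sim_config()]; `cfg$seed` seeds the generator.
#' @param out Output directory for the epoch container; the ground truth is
#'   written alongside as `ground_truth.json`.
#' @return The container path, invisibly.
#' @export
cmd_simulate <- function(cfg, out) {
  cfg <- validate_run_config(unclass(cfg))
  sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
  sim <- simulate_epochs(sc)
  write_epoch_container(sim$epochs, out)
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(pattern_left = gt$pattern_left, pattern_right = gt$pattern_right,
         eog_mixing = gt$eog_mixing,
         screening = sim$report[c("n_input", "n_rejected_reactive",
                                  "n_rejected_multipress")]),
    file.path(out, "ground_truth.json"), digits = NA)
  invisible(out)
}

#' Run the evaluation protocol on a dataset
#'
#' @param cfg A validated `run_config` (`method`, optional `odcs`, `pstf`,
#'   `protocol` blocks).
#' @param data Path to an epoch container.
#' @param out Output directory for result CSVs and the run log.
#' @return The `result_table`, invisibly.
#' @export
cmd_run <- function(cfg, data, out) {
  cfg <- validate_run_config(unclass(cfg))
  if (is.null(cfg[["method"]])) stop("config must set 'method'")
  es <- read_epoch_container(data)
  m_best <- if (isTRUE(cfg$odcs$enabled)) as.integer(cfg$odcs$m_best %||% 3L)
  rt <- run_protocol(
    es, method = cfg[["method"]], algorithm = cfg$algorithm,
    odcs_m_best = m_best, ddag_order = cfg$ddag_order,
    grid = config_grid(cfg),
    fs_target = cfg$pstf$fs_target %||% 100,
    n_chunks = cfg$protocol$n_chunks %||% 10L,
    seed = cfg$seed, shuffle = isTRUE(cfg$protocol$shuffle))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_results(rt, out)
  jsonlite::write_json(
    list(config = unclass(cfg), mean_kappa = rt$mean_kappa,
         sd_kappa = rt$sd_kappa, pooled_kappa = rt$pooled_kappa),
    file.path(out, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(rt)
}

#' Compare several classification methods on one dataset
#'
#' Runs the protocol once per listed method; a single method's failure is
#' recorded and the comparison continues.
#'
#' @param cfg A validated `run_config` with a `methods` list.
#' @param data Path to an epoch container.
#' @param out Output directory for the summary CSV.
#' @return Data frame with one row per method (mean/SD fold kappa, pooled
#'   kappa, or the error message), invisibly.
#' @export
cmd_compare <- function(cfg, data, out) {
  cfg <- validate_run_config(unclass(cfg))
  if (length(cfg$methods) < 2L) stop("usage error: need at least 2 methods")
  es <- read_epoch_container(data)
  m_best <- if (isTRUE(cfg$odcs$enabled)) as.integer(cfg$odcs$m_best %||% 3L)
  rows <- lapply(cfg$methods, function(method) {
    res <- tryCatch({
      rt <- run_protocol(es, method = method, algorithm = cfg$algorithm,
                         odcs_m_best = m_best, ddag_order = cfg$ddag_order,
                         grid = config_grid(cfg),
                         fs_target = cfg$pstf$fs_target %||% 100,
                         n_chunks = cfg$protocol$n_chunks %||% 10L,
                         seed = cfg$seed)
      data.frame(participant = es$participant_id, method = method,
                 mean_kappa = rt$mean_kappa, sd_kappa = rt$sd_kappa,
                 pooled_kappa = rt$pooled_kappa, error = NA_character_)
    }, error = function(e) {
      data.frame(participant = es$participant_id, method = method,
                 mean_kappa = NA_real_, sd_kappa = NA_real_,
                 pooled_kappa = NA_real_, error = conditionMessage(e))
    })
    res
  })
  summary <- do.call(rbind, rows)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(summary, file.path(out, "method_comparison.csv"))
  invisible(summary)
}
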