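RUN_CONFIG_KEYS <- c("mode", "weighting", "rounds", "epochs_per_round", "seed",
                     "n_classes", "match_mode", "clients", "hyperparams", "out_dir")
CLIENT_KEYS <- c("name", "dir", "max_patch_voxels", "max_batch")
HP_KEYS <- c("lr0", "momentum", "nesterov", "iterations_per_epoch", "batch_size",
             "oversample_fg")

#' Read and validate a YAML run configuration
#'
#' The schema has a fixed key set (unknown keys are rejected) and is fully
#' serializable back to an equivalent file with [write_run_config()]. Each
#' `clients` entry names a dataset directory and its resource budget.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), RUN_CONFIG_KEYS)
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  if (is.null(x$mode) || is.null(x$clients)) stopf("config requires 'mode' and 'clients'")
  for (cl in x$clients) {
    unk <- setdiff(names(cl), CLIENT_KEYS)
    if (length(unk)) stopf("unknown client keys: %s", paste(unk, collapse = ", "))
    if (is.null(cl$dir)) stopf("each client requires a 'dir'")
  }
  if (!is.null(x$hyperparams)) {
    unk <- setdiff(names(x$hyperparams), HP_KEYS)
    if (length(unk)) stopf("unknown hyperparams keys: %s", paste(unk, collapse = ", "))
  }
  x$weighting <- x$weighting %||% "proportional"
  x$rounds <- as.integer(x$rounds %||% 10L)
  x$epochs_per_round <- as.integer(x$epochs_per_round %||% 1L)
  x$seed <- as.integer(x$seed %||% 0L)
  x$n_classes <- as.integer(x$n_classes %||% 2L)
  x$match_mode <- x$match_mode %||% "strict"
  x
}

#' @rdname read_run_config
#' @param config a config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[intersect(RUN_CONFIG_KEYS, names(config))], path)
  invisible(path)
}

#' Execute a run configuration
#'
#' Builds clients from the configured dataset directories and dispatches to
#' the mode's orchestrator. If `out_dir` is set, final checkpoints, plans
#' and a JSONL round log are written there.
#'
#' @param config a validated config list (see [read_run_config()]).
#' @return a `fedseg_run`.
#' @export
execute_run_config <- function(config) {
  clients <- lapply(config$clients, function(cl) {
    fed_client_from_dir(cl$dir, cl$name %||% basename(cl$dir),
                        resource_budget(cl$max_patch_voxels %||% 512^2,
                                        cl$max_batch %||% 48L))
  })
  hp <- do.call(train_hyperparams, config$hyperparams %||% list())
  cfg <- fed_config(mode = config$mode, weighting = config$weighting,
                    n_rounds = config$rounds,
                    epochs_per_round = config$epochs_per_round,
                    seed = config$seed, hyperparams = hp,
                    match_mode = config$match_mode, n_classes = config$n_classes)
  run <- run_federation(clients, cfg)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(run$states)) {
      write_checkpoint(run$states[[k]],
                       file.path(config$out_dir, sprintf("client%02d_final.ckpt", k)))
    }
    for (k in seq_along(run$plans)) {
      write_plan(run$plans[[k]],
                 file.path(config$out_dir, sprintf("client%02d_plan.json", k)))
    }
    log_lines <- vapply(run$logs, function(l) as.character(canonical_json(l)), "")
    header <- canonical_json(list(config = config[setdiff(names(config), "out_dir")],
                                  package_version = as.character(utils::packageVersion("fedseg"))))
    writeLines(c(header, log_lines), file.path(config$out_dir, "rounds.jsonl"))
  }
  run
}
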