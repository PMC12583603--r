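#' Federated clients and run configuration
#'
#' A client bundles a private dataset with its local resource budget. The
#' orchestration below simulates the federation in-process; the only
#' objects that ever cross a client boundary are fingerprints (FFE setup
#' phase) and model states / aggregated partial states (training rounds) —
#' every exchange is recorded in the run's `exchanged` audit trail.
#'
#' @param cases list of cases (as from [read_dataset()] or
#'   [generate_center()]).
#' @param name client name.
#' @param budget the client's `fedseg_budget`.
#' @return a `fedseg_client`.
#' @export
fed_client <- function(cases, name, budget = resource_budget()) {
  if (!length(cases)) stopf("empty client")
  structure(list(cases = cases, name = name, budget = budget,
                 n_cases = length(cases)),
            class = "fedseg_client")
}

#' @rdname fed_client
#' @param dir dataset directory of NIfTI pairs.
#' @export
fed_client_from_dir <- function(dir, name = basename(dir), budget = resource_budget()) {
  fed_client(read_dataset(dir), name, budget)
}

#' @rdname fed_client
#' @param mode one of `"local"`, `"centralized"`, `"ffe"`, `"asymfedavg"`.
#' @param weighting `"proportional"` (dataset-size weights) or
#'   `"equal_center"`.
#' @param n_rounds federation rounds (aggregation happens after each round).
#' @param epochs_per_round local epochs per round (default 1: models are
#'   aggregated after each epoch).
#' @param seed run seed; all substreams derive from it.
#' @param hyperparams from [train_hyperparams()]; `total_epochs` is forced
#'   to `n_rounds * epochs_per_round` so the learning-rate schedule is
#'   identical and lockstep across clients.
#' @param match_mode layer-matching mode for asymmetric aggregation
#'   (`"strict"` or `"partial"`).
#' @param n_classes segmentation classes (background included).
#' @export
fed_config <- function(mode = c("local", "centralized", "ffe", "asymfedavg"),
                       weighting = c("proportional", "equal_center"),
                       n_rounds = 10L, epochs_per_round = 1L, seed = 0L,
                       hyperparams = train_hyperparams(),
                       match_mode = "strict", n_classes = 2L) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  stopifnot(n_rounds >= 1L, epochs_per_round >= 1L)
  hyperparams$total_epochs <- as.integer(n_rounds * epochs_per_round)
  structure(list(mode = mode, weighting = weighting,
                 n_rounds = as.integer(n_rounds),
                 epochs_per_round = as.integer(epochs_per_round),
                 seed = as.integer(seed), hyperparams = hyperparams,
                 match_mode = match_mode, n_classes = as.integer(n_classes)),
            class = "fedseg_config")
}

client_fingerprints <- function(clients, seed) {
  lapply(clients, function(cl) fingerprint_from_cases(cl$cases, seed = seed))
}

train_rounds <- function(state, pp_cases, plan, config, n_epochs) {
  opt <- new_opt_state()
  losses <- numeric(0)
  for (e in seq_len(n_epochs)) {
    r <- train_one_epoch(state, pp_cases, plan, config$hyperparams, opt,
                         seed = derive_seed(config$seed, "train"))
    state <- r$state
    losses <- c(losses, r$losses)
  }
  list(state = state, opt = opt, losses = losses)
}

#' Run the local (non-collaborative) baseline
#'
#' Each client independently derives a plan from its own fingerprint and
#' trains on its own data; nothing crosses the client boundary.
#'
#' @param clients list of `fedseg_client`.
#' @param config a `fedseg_config`.
#' @return a `fedseg_run`: per-client `states`, `plans`, `fingerprints`,
#'   round `logs`, and the `exchanged` audit trail (empty here).
#' @export
run_local <- function(clients, config) {
  fps <- client_fingerprints(clients, config$seed)
  plans <- lapply(seq_along(clients), function(k) make_plan(fps[[k]], clients[[k]]$budget))
  states <- vector("list", length(clients))
  pps <- lapply(seq_along(clients), function(k) {
    lapply(clients[[k]]$cases, preprocess_case, plan = plans[[k]])
  })
  for (k in seq_along(clients)) {
    arch <- build_architecture(plans[[k]], 1L, config$n_classes)
    states[[k]] <- init_state(arch, derive_seed(config$seed, "init"))
  }
  logs <- list()
  total <- config$n_rounds * config$epochs_per_round
  for (k in seq_along(clients)) {
    r <- train_rounds(states[[k]], pps[[k]], plans[[k]], config, total)
    states[[k]] <- r$state
    logs[[k]] <- list(client = clients[[k]]$name, losses = r$losses)
  }
  structure(list(mode = "local", states = states, plans = plans,
                 fingerprints = fps, logs = logs, exchanged = character(0),
                 config = config),
            class = "fedseg_run")
}

#' Run the centralized (pooled-data) baseline
#'
#' All data is pooled into a single dataset; the fingerprint is the
#' aggregation of the per-client fingerprints (equivalently, the pooled
#' dataset's fingerprint), and one model is trained. Requires a shared
#' budget (the first client's is used; a warning is raised if budgets
#' differ).
#'
#' @inheritParams run_local
#' @return a `fedseg_run` with a single state/plan.
#' @export
run_centralized <- function(clients, config) {
  fps <- client_fingerprints(clients, config$seed)
  fp <- aggregate_fingerprints(fps)
  if (length(unique(vapply(clients, function(cl) object_md5(cl$budget), ""))) > 1) {
    warning("clients have differing budgets; using the first client's for the pooled plan")
  }
  plan <- make_plan(fp, clients[[1]]$budget)
  cases <- do.call(c, lapply(clients, function(cl) cl$cases))
  pp <- lapply(cases, preprocess_case, plan = plan)
  arch <- build_architecture(plan, 1L, config$n_classes)
  state <- init_state(arch, derive_seed(config$seed, "init"))
  r <- train_rounds(state, pp, plan, config, config$n_rounds * config$epochs_per_round)
  structure(list(mode = "centralized", states = list(r$state), plans = list(plan),
                 fingerprints = list(fp), logs = list(list(losses = r$losses)),
                 exchanged = character(0), config = config),
            class = "fedseg_run")
}

#' Run federated-fingerprint training (global fingerprint + FedAvg)
#'
#' Setup phase: clients share their local fingerprints, the server
#' concatenates them into the global fingerprint and redistributes it; each
#' client then derives its plan from the global fingerprint and its own
#' budget. If the resulting plans are not identical the run aborts with a
#' plan-divergence report. Training: after each round the clients' states
#' are averaged with classical FedAvg and the average is broadcast back, so
#' all clients hold bitwise-equal states at every round boundary.
#'
#' @inheritParams run_local
#' @return a `fedseg_run`; `states` holds the shared final state first,
#'   followed by the per-client copies (all identical).
#' @export
run_ffe <- function(clients, config) {
  exchanged <- character(0)
  local_fps <- client_fingerprints(clients, config$seed)
  exchanged <- c(exchanged, rep("fedseg_fingerprint", length(clients)))  # upload
  global_fp <- aggregate_fingerprints(local_fps)
  exchanged <- c(exchanged, rep("fedseg_fingerprint", length(clients)))  # broadcast
  plans <- lapply(clients, function(cl) make_plan(global_fp, cl$budget))
  hashes <- vapply(plans, plan_hash, "")
  if (length(unique(hashes)) != 1) {
    diff <- paste(vapply(seq_along(clients), function(k) {
      sprintf("%s: patch [%s], stages %d", clients[[k]]$name,
              paste(plans[[k]]$patch_size, collapse = ","), plans[[k]]$n_stages)
    }, ""), collapse = "; ")
    stopf("FFE plan divergence: %s", diff)
  }
  plan <- plans[[1]]
  pps <- lapply(clients, function(cl) lapply(cl$cases, preprocess_case, plan = plan))
  arch <- build_architecture(plan, 1L, config$n_classes)
  shared <- init_state(arch, derive_seed(config$seed, "init"))
  opts <- lapply(clients, function(cl) new_opt_state())
  w <- aggregation_weights(vapply(clients, function(cl) cl$n_cases, integer(1)),
                           config$weighting)
  logs <- vector("list", config$n_rounds)
  states <- lapply(seq_along(clients), function(k) shared)
  for (t in seq_len(config$n_rounds)) {
    losses <- numeric(length(clients))
    for (k in seq_along(clients)) {
      st <- states[[k]]
      for (e in seq_len(config$epochs_per_round)) {
        r <- train_one_epoch(st, pps[[k]], plan, config$hyperparams, opts[[k]],
                             seed = derive_seed(config$seed, "train"))
        st <- r$state
      }
      losses[k] <- mean(r$losses)
      states[[k]] <- st
    }
    exchanged <- c(exchanged, rep("fedseg_state", length(clients)))  # upload
    avg <- fedavg(states, w)
    states <- lapply(seq_along(clients), function(k) avg)
    exchanged <- c(exchanged, rep("fedseg_state", length(clients)))  # broadcast
    logs[[t]] <- list(round = t, losses = losses,
                      compat_size = length(avg$params),
                      weights = w / sum(w),
                      checksum = object_md5(avg$params))
  }
  structure(list(mode = "ffe", states = c(list(avg), states),
                 plans = lapply(seq_along(clients), function(k) plan),
                 fingerprints = c(list(global_fp), local_fps),
                 logs = logs, exchanged = exchanged, config = config),
            class = "fedseg_run")
}

#' Run asymmetric federated averaging
#'
#' Clients keep the architectures derived from their own local fingerprints
#' (no fingerprint exchange). Each round, every client trains locally, the
#' server matches layers by name and shape across the uploaded states,
#' averages the compatible set with restricted-renormalized weights, and
#' sends the aggregated layers back; incompatible layers evolve only
#' locally. An empty compatibility set degenerates to local training (with
#' a warning).
#'
#' @inheritParams run_local
#' @return a `fedseg_run` with per-client `states` and round `logs`
#'   recording the compatibility-set size and broadcast checksum.
#' @export
run_asymfedavg <- function(clients, config) {
  exchanged <- character(0)
  fps <- client_fingerprints(clients, config$seed)
  plans <- lapply(seq_along(clients), function(k) make_plan(fps[[k]], clients[[k]]$budget))
  pps <- lapply(seq_along(clients), function(k) {
    lapply(clients[[k]]$cases, preprocess_case, plan = plans[[k]])
  })
  states <- lapply(seq_along(clients), function(k) {
    init_state(build_architecture(plans[[k]], 1L, config$n_classes),
               derive_seed(config$seed, "init"))
  })
  opts <- lapply(clients, function(cl) new_opt_state())
  w <- aggregation_weights(vapply(clients, function(cl) cl$n_cases, integer(1)),
                           config$weighting)
  logs <- vector("list", config$n_rounds)
  for (t in seq_len(config$n_rounds)) {
    losses <- numeric(length(clients))
    for (k in seq_along(clients)) {
      st <- states[[k]]
      for (e in seq_len(config$epochs_per_round)) {
        r <- train_one_epoch(st, pps[[k]], plans[[k]], config$hyperparams, opts[[k]],
                             seed = derive_seed(config$seed, "train"))
        st <- r$state
      }
      losses[k] <- mean(r$losses)
      states[[k]] <- st
    }
    exchanged <- c(exchanged, rep("fedseg_state", length(clients)))  # upload
    compat <- compatible_layers(states, mode = config$match_mode)
    if (!length(compat$layers)) {
      warning("empty compatibility set: round degenerates to local training")
      shared <- list()
    } else {
      shared <- aggregate_states(states, w, compat)
      states <- lapply(states, apply_update, shared = shared)
      exchanged <- c(exchanged, rep("fedseg_shared_state", length(clients)))  # broadcast
    }
    logs[[t]] <- list(round = t, losses = losses,
                      compat_size = length(compat$layers),
                      weights = w / sum(w),
                      checksum = object_md5(shared))
  }
  structure(list(mode = "asymfedavg", states = states, plans = plans,
                 fingerprints = fps, logs = logs, exchanged = exchanged,
                 config = config),
            class = "fedseg_run")
}

#' Dispatch a federated run by config mode
#'
#' @param clients list of `fedseg_client`.
#' @param config a `fedseg_config`.
#' @return a `fedseg_run`.
#' @export
run_federation <- function(clients, config) {
  switch(config$mode,
         local = run_local(clients, config),
         centralized = run_centralized(clients, config),
         ffe = run_ffe(clients, config),
         asymfedavg = run_asymfedavg(clients, config))
}

#' Round logs as a data frame
#'
#' @param run a `fedseg_run`.
#' @return data.frame with one row per round (federated modes) or per
#'   client (local mode).
#' @export
round_log_table <- function(run) {
  if (run$mode %in% c("local", "centralized")) {
    return(do.call(rbind, lapply(run$logs, function(l) {
      data.frame(client = l$client %||% "pooled", mean_loss = mean(l$losses))
    })))
  }
  do.call(rbind, lapply(run$logs, function(l) {
    data.frame(round = l$round, mean_loss = mean(l$losses),
               compat_size = l$compat_size, checksum = l$checksum)
  }))
}
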