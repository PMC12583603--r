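#' Scaled-down multi-center federation experiment
#'
#' The package's end-to-end benchmark: generate a synthetic multi-center
#' dataset, split each center 80/20 into train/held-out, run the requested
#' training modes under matched seeds and budgets, and score per-center
#' held-out mean DSC. For the local mode a cross-center matrix (each
#' center's model evaluated on every center's held-out cases) is also
#' produced.
#'
#' Budgets follow the preset's per-center defaults for `local` and
#' `asymfedavg` (each site trains the architecture its own hardware and
#' fingerprint yield); `ffe` and `centralized` use the preset's largest
#' budget on every client, since those modes presuppose a shared
#' configuration.
#'
#' @param preset benchmark preset name (see [benchmark_presets()]).
#' @param seed experiment seed (drives data generation and training).
#' @param modes training modes to run.
#' @param n_rounds federation rounds (= total epochs at 1 epoch/round).
#' @param n_cases per-center case count (NULL: preset default).
#' @param weighting aggregation weighting mode.
#' @param hyperparams training hyperparameters; `total_epochs` is set from
#'   `n_rounds`.
#' @param cross_center compute the local-mode cross-center DSC matrix.
#' @return list with `dsc` (data.frame: mode, center, mean held-out DSC),
#'   `cross_center` (matrix or NULL), `runs` (the `fedseg_run` objects).
#' @export
run_benchmark_experiment <- function(preset = "heterogeneous3", seed = 0L,
                                     modes = c("local", "ffe", "asymfedavg"),
                                     n_rounds = 30L, n_cases = NULL,
                                     weighting = "proportional",
                                     hyperparams = train_hyperparams(iterations_per_epoch = 8L,
                                                                     batch_size = 2L),
                                     cross_center = TRUE) {
  bm <- benchmark_presets(preset, seed = seed, n_cases = n_cases)
  centers <- lapply(bm$specs, generate_center)
  names(centers) <- vapply(bm$specs, function(s) s$name, "")
  n_tr <- vapply(centers, function(cs) max(1L, as.integer(length(cs) * 0.8)), integer(1))
  train_cases <- lapply(seq_along(centers), function(i) centers[[i]][seq_len(n_tr[i])])
  test_cases <- lapply(seq_along(centers), function(i) {
    centers[[i]][setdiff(seq_along(centers[[i]]), seq_len(n_tr[i]))]
  })
  shared_budget <- bm$budgets[[which.max(vapply(bm$budgets, function(b) b$max_patch_voxels, 0))]]

  make_clients <- function(budgets) {
    lapply(seq_along(centers), function(i) {
      fed_client(train_cases[[i]], names(centers)[i], budgets[[i]])
    })
  }
  runs <- list()
  rows <- list()
  for (mode in modes) {
    budgets <- if (mode %in% c("ffe", "centralized")) {
      rep(list(shared_budget), length(centers))
    } else bm$budgets
    cfg <- fed_config(mode = mode, weighting = weighting, n_rounds = n_rounds,
                      seed = seed, hyperparams = hyperparams)
    run <- run_federation(make_clients(budgets), cfg)
    runs[[mode]] <- run
    for (i in seq_along(centers)) {
      st <- switch(mode,
                   local = run$states[[i]],
                   asymfedavg = run$states[[i]],
                   ffe = run$states[[1]],
                   centralized = run$states[[1]])
      pl <- switch(mode,
                   local = run$plans[[i]],
                   asymfedavg = run$plans[[i]],
                   ffe = run$plans[[1]],
                   centralized = run$plans[[1]])
      ev <- evaluate_cases(st, test_cases[[i]], pl)
      rows[[length(rows) + 1L]] <- data.frame(mode = mode, center = names(centers)[i],
                                              dsc = mean(ev$dsc), hd95 = mean(ev$hd95))
    }
  }
  cc <- NULL
  if (cross_center && "local" %in% modes) {
    lr <- runs[["local"]]
    cc <- cross_center_matrix(lr$states, lr$plans, test_cases, names(centers))
  }
  list(dsc = do.call(rbind, rows), cross_center = cc, runs = runs,
       test_cases = test_cases)
}
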