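mk_clients <- function(n = 2L, n_cases = 3L, seed0 = 30L, budget = tiny_budget(),
                       same_data = FALSE) {
  lapply(seq_len(n), function(k) {
    cases <- generate_center(easy_center(n_cases, seed = if (same_data) seed0 else seed0 + k))
    fed_client(cases, paste0("c", k), budget)
  })
}

fast_cfg <- function(mode, n_rounds = 2L, seed = 5L, ...) {
  fed_config(mode = mode, n_rounds = n_rounds, seed = seed,
             hyperparams = tiny_hp(total_epochs = n_rounds, iters = 2L), ...)
}

test_that("a single-client federation equals direct local training", {
  cl <- mk_clients(1L)[[1]]
  run <- run_local(list(cl), fast_cfg("local"))
  # replay the same pipeline by hand
  fp <- fingerprint_from_cases(cl$cases, seed = 5L)
  plan <- make_plan(fp, cl$budget)
  pp <- lapply(cl$cases, preprocess_case, plan = plan)
  st <- init_state(build_architecture(plan), fedseg:::derive_seed(5L, "init"))
  opt <- new_opt_state()
  for (e in 1:2) {
    st <- train_one_epoch(st, pp, plan, run$config$hyperparams, opt,
                          seed = fedseg:::derive_seed(5L, "train"))$state
  }
  expect_identical(run$states[[1]]$params, st$params)
  expect_identical(run$exchanged, character(0))
})

test_that("local mode is deterministic: same data and seed, same states", {
  clients <- mk_clients(2L, same_data = TRUE)
  run <- run_local(clients, fast_cfg("local"))
  expect_identical(run$states[[1]]$params, run$states[[2]]$params)
})

test_that("local plans equal independently recomputed planner output", {
  clients <- mk_clients(2L, seed0 = 40L)
  clients[[2]]$cases <- lapply(clients[[2]]$cases, function(cs) {
    cs$spacing <- c(2, 2); cs
  })
  run <- run_local(clients, fast_cfg("local", n_rounds = 1L))
  for (k in 1:2) {
    fp <- fingerprint_from_cases(clients[[k]]$cases, seed = 5L)
    expect_identical(plan_hash(run$plans[[k]]),
                     plan_hash(make_plan(fp, clients[[k]]$budget)))
  }
  expect_false(identical(plan_hash(run$plans[[1]]), plan_hash(run$plans[[2]])))
})

test_that("centralized training on one client equals local training", {
  cl <- mk_clients(1L)
  a <- run_local(cl, fast_cfg("local"))
  b <- run_centralized(cl, fast_cfg("centralized"))
  expect_identical(a$states[[1]]$params, b$states[[1]]$params)
})

test_that("the pooled fingerprint is the aggregate of the locals, order-invariantly", {
  clients <- mk_clients(3L, seed0 = 50L)
  cfg <- fast_cfg("centralized", n_rounds = 1L)
  run <- run_centralized(clients, cfg)
  locals <- lapply(clients, function(cl) fingerprint_from_cases(cl$cases, seed = cfg$seed))
  expect_equal(run$fingerprints[[1]], aggregate_fingerprints(locals))
  run_perm <- run_centralized(clients[c(2, 3, 1)], cfg)
  expect_identical(plan_hash(run$plans[[1]]), plan_hash(run_perm$plans[[1]]))
})

test_that("FFE with one client reduces to local training", {
  cl <- mk_clients(1L)
  a <- run_local(cl, fast_cfg("local"))
  b <- run_ffe(cl, fast_cfg("ffe"))
  expect_identical(b$states[[1]]$params, a$states[[1]]$params)
})

test_that("averaging identical FFE clients returns their common state", {
  clients <- mk_clients(2L, same_data = TRUE)
  run <- run_ffe(clients, fast_cfg("ffe", n_rounds = 1L))
  # both clients trained identically; the broadcast equals either client
  expect_identical(run$states[[1]]$params, run$states[[2]]$params)
  expect_identical(run$states[[2]]$params, run$states[[3]]$params)
})

test_that("FFE keeps every client on one plan; divergent budgets abort", {
  bm <- benchmark_presets("heterogeneous3", seed = 7L, n_cases = 3L)
  clients <- lapply(seq_along(bm$specs), function(i) {
    fed_client(generate_center(bm$specs[[i]]), bm$specs[[i]]$name, tiny_budget())
  })
  run <- run_ffe(clients, fast_cfg("ffe"))
  hashes <- vapply(run$plans, plan_hash, "")
  expect_length(unique(hashes), 1L)
  # offline recomputation from the global fingerprint matches the broadcast plan
  locals <- lapply(clients, function(cl) fingerprint_from_cases(cl$cases, seed = 5L))
  offline <- make_plan(aggregate_fingerprints(locals), tiny_budget())
  expect_identical(plan_hash(offline), hashes[1])

  clients[[1]]$budget <- resource_budget(8^2, 2L)
  expect_error(run_ffe(clients, fast_cfg("ffe")), "FFE plan divergence")
})

test_that("asymmetric aggregation with shared architectures reduces to FedAvg", {
  clients <- mk_clients(3L, seed0 = 60L)
  a <- run_ffe(clients, fast_cfg("ffe", n_rounds = 2L))
  b <- run_asymfedavg(clients, fast_cfg("asymfedavg", n_rounds = 2L))
  # identical plans (same geometry): round-for-round bitwise equality
  expect_identical(b$states[[1]]$params, a$states[[2]]$params)
  expect_identical(b$states[[2]]$params, b$states[[1]]$params)
  expect_equal(b$logs[[1]]$compat_size, length(b$states[[1]]$params))
})

test_that("heterogeneous asym clients share exactly the offline intersection", {
  bm <- benchmark_presets("heterogeneous3", seed = 8L, n_cases = 3L)
  clients <- lapply(seq_along(bm$specs), function(i) {
    fed_client(generate_center(bm$specs[[i]]), bm$specs[[i]]$name, bm$budgets[[i]])
  })
  run <- run_asymfedavg(clients, fast_cfg("asymfedavg"))
  oracle <- oracle_intersection(run$states, min_clients = length(clients))
  for (lg in run$logs) expect_equal(lg$compat_size, length(oracle$layers))
  # at least two distinct architectures were in play
  expect_gte(length(unique(vapply(run$plans, function(p) p$n_stages, integer(1)))), 2L)
  # non-common layers exist and differ across clients (evolved locally)
  only2 <- setdiff(names(run$states[[2]]$params), names(run$states[[1]]$params))
  expect_gt(length(only2), 0L)
})

test_that("degenerate weights copy the heavy client's shared layers", {
  clients <- mk_clients(2L, seed0 = 70L)
  cfg <- fast_cfg("asymfedavg", n_rounds = 1L)
  fps <- lapply(clients, function(cl) fingerprint_from_cases(cl$cases, seed = cfg$seed))
  plans <- lapply(seq_along(clients), function(k) make_plan(fps[[k]], clients[[k]]$budget))
  sts <- lapply(seq_along(clients), function(k) {
    st <- init_state(build_architecture(plans[[k]]), fedseg:::derive_seed(cfg$seed, "init"))
    pp <- lapply(clients[[k]]$cases, preprocess_case, plan = plans[[k]])
    train_one_epoch(st, pp, plans[[k]], cfg$hyperparams,
                    seed = fedseg:::derive_seed(cfg$seed, "train"))$state
  })
  cs <- compatible_layers(sts)
  shared <- aggregate_states(sts, c(1, 0), cs)
  upd2 <- apply_update(sts[[2]], shared)
  for (nm in cs$layers) expect_identical(upd2$params[[nm]], sts[[1]]$params[[nm]])
})

test_that("only fingerprints and states ever cross the client boundary", {
  clients <- mk_clients(2L, seed0 = 80L)
  locl <- run_local(clients, fast_cfg("local", n_rounds = 1L))
  expect_identical(locl$exchanged, character(0))
  ffe <- run_ffe(clients, fast_cfg("ffe", n_rounds = 1L))
  expect_setequal(unique(ffe$exchanged), c("fedseg_fingerprint", "fedseg_state"))
  asym <- run_asymfedavg(clients, fast_cfg("asymfedavg", n_rounds = 1L))
  expect_true(all(unique(asym$exchanged) %in%
                    c("fedseg_state", "fedseg_shared_state")))
  expect_false("fedseg_fingerprint" %in% asym$exchanged)
})

test_that("empty clients are rejected and logs carry one entry per round", {
  expect_error(fed_client(list(), "empty"), "empty client")
  clients <- mk_clients(2L, seed0 = 90L)
  run <- run_asymfedavg(clients, fast_cfg("asymfedavg", n_rounds = 3L))
  expect_length(run$logs, 3L)
  expect_equal(vapply(run$logs, function(l) l$round, integer(1)), 1:3)
  tab <- round_log_table(run)
  expect_equal(nrow(tab), 3L)
  # epoch counters advanced once per round
  expect_equal(run$states[[1]]$metadata$epoch, 3L)
})
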