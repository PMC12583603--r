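test_that("identical architectures match on every layer", {
  shapes <- list(a = c(3L, 3L, 2L, 4L), b = 4L, c = c(2L, 2L, 4L, 8L))
  s1 <- toy_state(shapes, 1L); s2 <- toy_state(shapes, 2L)
  cs <- compatible_layers(list(s1, s2))
  expect_setequal(cs$layers, names(shapes))
  expect_true(all(vapply(cs$contributors, identical, logical(1), 1:2)))
})

test_that("a shared name with differing shapes is excluded", {
  s1 <- toy_state(list(w = c(3L, 3L, 1L, 32L), h = 2L), 1L)
  s2 <- toy_state(list(w = c(3L, 3L, 1L, 64L), h = 2L), 2L)
  cs <- compatible_layers(list(s1, s2))
  expect_false("w" %in% cs$layers)
  expect_true("h" %in% cs$layers)
  rep_ <- aggregation_report(list(s1, s2))
  expect_equal(rep_$shape_excluded, "w")
  expect_equal(rep_$matched, "h")
})

test_that("strict and partial matching equal the exhaustive intersection oracle", {
  st7 <- init_state(build_architecture(plan_for_patch(320L)), 1L)
  st8 <- init_state(build_architecture(plan_for_patch(512L)), 2L)
  strict <- compatible_layers(list(st7, st8), "strict")
  oracle <- oracle_intersection(list(st7, st8), min_clients = 2L)
  expect_setequal(strict$layers, oracle$layers)
  expect_gt(length(strict$layers), 0L)
  expect_lt(length(strict$layers), length(st8$params))
  # partial mode with a third, smaller model
  st3 <- init_state(build_architecture(make_plan(fp_for_patch(16L, 1), tiny_budget())), 3L)
  partial <- compatible_layers(list(st7, st8, st3), "partial", min_clients = 2L)
  oracle_p <- oracle_intersection(list(st7, st8, st3), min_clients = 2L)
  expect_setequal(partial$layers, oracle_p$layers)
  for (nm in partial$layers) {
    expect_identical(sort(partial$contributors[[nm]]), sort(oracle_p$contributors[[nm]]))
  }
  strict3 <- compatible_layers(list(st7, st8, st3), "strict")
  expect_true(all(strict3$layers %in% partial$layers))
})

test_that("aggregation reproduces the weighted-mean definitions", {
  s1 <- toy_state(list(v = 1L)); s1$params$v <- 1.0
  s2 <- toy_state(list(v = 1L)); s2$params$v <- 3.0
  cs <- compatible_layers(list(s1, s2))
  # equal-center: plain mean
  expect_equal(aggregate_states(list(s1, s2), aggregation_weights(c(100, 300), "equal_center"), cs)$v, 2.0)
  # proportional to 100 vs 300 cases: 0.25 * 1 + 0.75 * 3
  expect_equal(aggregate_states(list(s1, s2), aggregation_weights(c(100, 300), "proportional"), cs)$v, 2.5)
})

test_that("aggregated elements equal an independent brute-force loop (5 clients)", {
  set.seed(42)
  shapes <- list(shared = c(3L, 3L), also = 5L)
  states <- lapply(1:5, function(k) {
    sh <- shapes
    if (k %% 2 == 0) sh$even_only <- c(2L, 2L)  # heterogeneous extras
    toy_state(sh, seed = k)
  })
  w <- runif(5, 0.5, 2)
  cs <- compatible_layers(states, "partial", min_clients = 2L)
  agg <- aggregate_states(states, w, cs)
  for (nm in cs$layers) {
    ks <- sort(cs$contributors[[nm]])
    wk <- w[ks] / sum(w[ks])
    # independent element-wise loop
    ref <- 0 * states[[ks[1]]]$params[[nm]]
    for (i in seq_along(ks)) ref <- ref + wk[i] * states[[ks[i]]]$params[[nm]]
    expect_lt(max(abs(agg[[nm]] - ref)), 1e-12)
  }
  expect_true("even_only" %in% cs$layers)
})

test_that("apply_update replaces exactly the shared layers", {
  shapes <- list(a = c(3L, 3L), b = 4L, c = c(2L, 2L))
  local <- toy_state(shapes, 1L, epoch = 7L)
  # empty shared set: no-op
  expect_identical(apply_update(local, list()), local)
  # full replacement
  other <- toy_state(shapes, 2L)
  cs <- compatible_layers(list(local, other))
  full <- aggregate_states(list(local, other), c(0, 1), cs)
  upd <- apply_update(local, full)
  for (nm in names(shapes)) expect_identical(upd$params[[nm]], other$params[[nm]])
  # mixed: non-shared layers bitwise untouched, epoch preserved
  part <- full[c("a")]
  upd2 <- apply_update(local, part)
  expect_identical(object_md5(upd2$params[c("b", "c")]),
                   object_md5(local$params[c("b", "c")]))
  expect_identical(upd2$metadata$epoch, 7L)
  # stale set: shape clash
  bad <- list(a = array(0, c(2, 2)))
  expect_error(apply_update(local, bad), "stale compatibility set")
})

test_that("fedavg is a fixed point on identical states and honors degenerate weights", {
  shapes <- list(a = c(3L, 3L, 1L, 8L), b = 8L)
  s <- toy_state(shapes, 3L)
  same <- fedavg(list(s, s, s), c(1, 1, 1))
  expect_equal(same$params, s$params, tolerance = 1e-14)
  s2 <- toy_state(shapes, 4L)
  picked <- fedavg(list(s, s2), c(1, 0))
  expect_identical(picked$params, s$params)
  s3 <- toy_state(list(a = c(3L, 3L, 1L, 8L), b = 9L), 5L)
  expect_error(fedavg(list(s, s3), c(1, 1)), "architecture mismatch")
})

test_that("fedavg equals full-set asymmetric aggregation per layer", {
  shapes <- list(a = c(3L, 3L, 2L, 4L), b = 4L)
  states <- lapply(1:4, function(k) toy_state(shapes, k))
  w <- c(2, 1, 4, 3)
  fa <- fedavg(states, w)
  cs <- compatible_layers(states)
  ag <- aggregate_states(states, w, cs)
  for (nm in names(shapes)) expect_identical(fa$params[[nm]], ag[[nm]])
})

test_that("aggregated values are convex combinations of client values", {
  set.seed(8)
  shapes <- list(a = c(4L, 4L), b = 6L)
  states <- lapply(1:3, function(k) toy_state(shapes, k + 10L))
  w <- runif(3)
  ag <- aggregate_states(states, w, compatible_layers(states))
  for (nm in names(shapes)) {
    mn <- pmin(states[[1]]$params[[nm]], states[[2]]$params[[nm]], states[[3]]$params[[nm]])
    mx <- pmax(states[[1]]$params[[nm]], states[[2]]$params[[nm]], states[[3]]$params[[nm]])
    expect_true(all(ag[[nm]] >= mn - 1e-15 & ag[[nm]] <= mx + 1e-15))
  }
})

test_that("client permutation changes results only by summation order", {
  set.seed(12)
  shapes <- list(a = c(5L, 5L))
  states <- lapply(1:4, function(k) toy_state(shapes, k + 20L))
  w <- runif(4)
  a <- aggregate_states(states, w, compatible_layers(states))
  perm <- c(3, 1, 4, 2)
  b <- aggregate_states(states[perm], w[perm], compatible_layers(states[perm]))
  expect_lt(max(abs(a$a - b$a)), 1e-12)
})

test_that("restricted weights renormalize to one", {
  # constant unit layer: any proper weighted mean returns exactly 1
  states <- lapply(1:5, function(k) {
    s <- toy_state(list(ones = c(3L, 3L)), k)
    s$params$ones[] <- 1
    if (k > 2) s$params$extra <- array(1, c(2, 2))
    s
  })
  w <- c(0.123, 4.5, 0.001, 2.2, 9.9)
  cs <- compatible_layers(states, "partial", min_clients = 2L)
  ag <- aggregate_states(states, w, cs)
  expect_lt(max(abs(ag$ones - 1)), 1e-15)
  expect_lt(max(abs(ag$extra - 1)), 1e-15)
})
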