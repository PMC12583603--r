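# Programmatic fixtures shared across the suite. Everything is generated in
# code; nothing is stored on disk.

# a case with uniform nonzero intensity (no crop)
flat_case <- function(shape = c(64L, 64L), value = 1, spacing = c(1, 1),
                      name = "flat") {
  list(image = array(value, shape),
       mask = array(0L, shape),
       spacing = spacing, name = name)
}

# nonzero region confined to rows/cols lo..hi (inclusive, 1-based)
boxed_case <- function(shape = c(64L, 64L), lo = 11L, hi = 42L,
                       spacing = c(1, 1), name = "boxed") {
  img <- array(0, shape)
  img[lo:hi, lo:hi] <- 1
  list(image = img, mask = array(0L, shape), spacing = spacing, name = name)
}

# fingerprint resolving to a given square patch size under a generous budget
fp_for_patch <- function(px, spacing = 0.7, n = 5L) {
  fingerprint_from_cases(
    lapply(seq_len(n), function(i) flat_case(c(px, px), spacing = c(spacing, spacing),
                                             name = sprintf("c%d", i))),
    include_intensity = FALSE)
}

plan_for_patch <- function(px, spacing = 0.7) {
  make_plan(fp_for_patch(px, spacing), resource_budget(512^2, 48L))
}

# small trainable setup: easy high-contrast synthetic center
easy_center <- function(n_cases = 8L, seed = 7L, shape = 64L, spacing = 1) {
  center_spec("easy", shape_min = c(shape, shape), spacing = c(spacing, spacing),
              fg_mean = 0.8, bg_mean = 0.2, bg_sd = 0.08, fg_sd = 0.08,
              bias_amplitude = 0.1, n_cases = n_cases, seed = seed)
}

tiny_budget <- function(px = 16L) resource_budget(px^2, 2L)

tiny_hp <- function(total_epochs = 4L, iters = 2L) {
  train_hyperparams(total_epochs = total_epochs, iterations_per_epoch = iters,
                    batch_size = 2L)
}

# toy model states: named parameter lists with explicit shapes
toy_state <- function(shapes, seed = 1L, epoch = 0L) {
  set.seed(seed)
  params <- lapply(shapes, function(s) {
    if (length(s) == 1L) stats::rnorm(s) else array(stats::rnorm(prod(s)), s)
  })
  structure(list(params = params,
                 metadata = list(plan_hash = "toy", epoch = epoch,
                                 n_classes = 2L, in_channels = 1L)),
            class = "fedseg_state")
}

# independent exhaustive name/shape intersection (oracle for layer matching)
oracle_intersection <- function(states, min_clients = length(states)) {
  shp <- function(p) if (is.null(dim(p))) length(p) else dim(p)
  nms <- unique(unlist(lapply(states, function(s) names(s$params))))
  keep <- character(0)
  holders <- list()
  for (nm in nms) {
    hs <- Filter(function(k) nm %in% names(states[[k]]$params), seq_along(states))
    if (length(hs) < min_clients) next
    sh <- lapply(hs, function(k) shp(states[[k]]$params[[nm]]))
    if (all(vapply(sh, identical, logical(1), sh[[1]]))) {
      keep <- c(keep, nm)
      holders[[nm]] <- hs
    }
  }
  list(layers = keep, contributors = holders)
}

# independent brute-force HD95: all boundary-pixel pairs, pooled directed
# distances, linear-interpolation percentile
oracle_hd95 <- function(a, b, spacing = c(1, 1), q = 0.95) {
  bound <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE,
              if (i < d[1]) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE,
              if (j < d[2]) m[i, j + 1] else FALSE)
      if (!all(nb)) out <- rbind(out, c(i, j))
    }
    out
  }
  A <- bound(a > 0); B <- bound(b > 0)
  As <- sweep(A, 2, spacing, `*`); Bs <- sweep(B, 2, spacing, `*`)
  d1 <- apply(As, 1, function(p) min(sqrt(rowSums(sweep(Bs, 2, p)^2))))
  d2 <- apply(Bs, 1, function(p) min(sqrt(rowSums(sweep(As, 2, p)^2))))
  unname(quantile(c(d1, d2), q, type = 7))
}

# single-pass flood fill; number of 4-connected foreground components
n_components <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  ncomp <- 0L
  for (s in which(mask > 0)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    stack <- s
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[cur]) next
      seen[cur] <- TRUE
      ij <- arrayInd(cur, d)
      for (df in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- ij[1] + df[1]; nj <- ij[2] + df[2]
        if (ni >= 1 && ni <= d[1] && nj >= 1 && nj <= d[2] &&
            mask[ni, nj] > 0 && !seen[ni, nj]) {
          stack <- c(stack, (nj - 1L) * d[1] + ni)
        }
      }
    }
  }
  ncomp
}
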