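#' Build a dynamic U-Net architecture description from a training plan
#'
#' Produces the canonical, shape-annotated layer list that the federated
#' aggregation operates on. The naming schema is fixed:
#' `encoder.stages.<i>.convs.<j>.{weight,bias}`,
#' `encoder.stages.<i>.norms.<j>.{weight,bias}`,
#' `decoder.stages.<d>.upconv.{weight,bias}`,
#' `decoder.stages.<d>.{convs,norms}.<j>.{weight,bias}` and
#' `head.{weight,bias}`. Encoder stages are indexed from the input inward;
#' decoder stages are indexed from the bottleneck outward
#' (`decoder.stages.0` is deepest), which determines which decoder layers
#' shape-match across models of different depth.
#'
#' Each encoder stage holds two 3x3 conv + instance-norm + leaky-ReLU
#' blocks; stages after the first downsample via a stride-2 entry conv
#' (stride 1 on axes whose pooling budget is exhausted). The decoder mirrors
#' the encoder with kernel==stride transposed convs and skip concatenation;
#' a 1x1 conv head maps to class scores.
#'
#' Conv weights are stored `(k1, k2, in, out)`; transposed-conv weights
#' `(s1, s2, in, out)`; norm weight/bias are per-channel vectors.
#'
#' @param plan a 2D `fedseg_plan` with at least 2 stages.
#' @param in_channels number of image channels.
#' @param n_classes number of segmentation classes (background included).
#' @return a `fedseg_arch`: `$layers` named list of parameter shapes in
#'   deterministic order, plus structural metadata.
#' @export
build_architecture <- function(plan, in_channels = 1L, n_classes = 2L) {
  if (plan$dimensionality != 2L) {
    stopf("only 2D architectures are supported (plan is %dD)", plan$dimensionality)
  }
  if (plan$n_stages < 2L) stopf("degenerate plan")
  ns <- plan$n_stages
  f <- plan$features_per_stage
  pool <- plan$n_poolings_per_axis
  k <- plan$conv_kernel %||% 3L

  layers <- list()
  add <- function(name, shape) layers[[name]] <<- as.integer(shape)

  # per-axis entry stride of (0-based) encoder stage i: axis a is halved by
  # stages 1..pool[a], so stride 2 iff i <= pool[a]
  stage_stride <- function(i) ifelse(i <= pool & i >= 1L, 2L, 1L)

  for (i in seq_len(ns) - 1L) {
    cin <- if (i == 0L) in_channels else f[i]
    cout <- f[i + 1L]
    pre <- sprintf("encoder.stages.%d", i)
    for (j in 0:1) {
      cj <- if (j == 0L) cin else cout
      add(sprintf("%s.convs.%d.weight", pre, j), c(k, k, cj, cout))
      add(sprintf("%s.convs.%d.bias", pre, j), cout)
      add(sprintf("%s.norms.%d.weight", pre, j), cout)
      add(sprintf("%s.norms.%d.bias", pre, j), cout)
    }
  }
  for (d in seq_len(ns - 1L) - 1L) {
    e_hi <- ns - 1L - d          # deeper encoder level being upsampled
    e_lo <- e_hi - 1L            # skip-connection level
    st <- stage_stride(e_hi)
    pre <- sprintf("decoder.stages.%d", d)
    add(sprintf("%s.upconv.weight", pre), c(st[1], st[2], f[e_hi + 1L], f[e_lo + 1L]))
    add(sprintf("%s.upconv.bias", pre), f[e_lo + 1L])
    for (j in 0:1) {
      cj <- if (j == 0L) 2L * f[e_lo + 1L] else f[e_lo + 1L]
      add(sprintf("%s.convs.%d.weight", pre, j), c(k, k, cj, f[e_lo + 1L]))
      add(sprintf("%s.convs.%d.bias", pre, j), f[e_lo + 1L])
      add(sprintf("%s.norms.%d.weight", pre, j), f[e_lo + 1L])
      add(sprintf("%s.norms.%d.bias", pre, j), f[e_lo + 1L])
    }
  }
  add("head.weight", c(1L, 1L, f[1], n_classes))
  add("head.bias", n_classes)

  structure(list(
    layers = layers,
    n_stages = ns,
    features = f,
    in_channels = as.integer(in_channels),
    n_classes = as.integer(n_classes),
    conv_kernel = as.integer(k),
    n_poolings_per_axis = as.integer(pool),
    patch_size = plan$patch_size,
    plan_hash = plan_hash(plan)
  ), class = "fedseg_arch")
}

#' @export
print.fedseg_arch <- function(x, ...) {
  np <- sum(vapply(x$layers, prod, numeric(1)))
  cat(sprintf("<fedseg_arch> %d stages, features %s, %d layers, %s parameters\n",
              x$n_stages, paste(x$features, collapse = "-"),
              length(x$layers), format(np, big.mark = ",")))
  invisible(x)
}

#' Initialize a model state from an architecture
#'
#' He-normal initialization for conv and transposed-conv weights (fan-in =
#' `k1*k2*in`), zero biases, unit/zero instance-norm affine parameters.
#' Deterministic given `seed`; iteration order of the state equals the
#' architecture's layer order.
#'
#' @param arch a `fedseg_arch`.
#' @param seed integer seed.
#' @return a `fedseg_state`: ordered named list of parameter arrays plus
#'   `metadata` (`plan_hash`, `epoch`, `seed`, `n_classes`, `in_channels`).
#' @export
init_state <- function(arch, seed = 0L) {
  params <- with_seed(derive_seed(seed, "init"), {
    lapply(seq_along(arch$layers), function(i) {
      nm <- names(arch$layers)[i]
      shape <- arch$layers[[i]]
      if (grepl("\\.weight$", nm) && length(shape) == 4L) {
        fan_in <- prod(shape[1:3])
        array(stats::rnorm(prod(shape), 0, sqrt(2 / fan_in)), shape)
      } else if (grepl("norms\\.[0-9]+\\.weight$", nm)) {
        rep(1, shape)
      } else {
        rep(0, shape)  # biases and norm offsets
      }
    })
  })
  names(params) <- names(arch$layers)
  structure(list(
    params = params,
    metadata = list(plan_hash = arch$plan_hash, epoch = 0L, seed = as.integer(seed),
                    n_classes = arch$n_classes, in_channels = arch$in_channels)
  ), class = "fedseg_state")
}

#' @export
print.fedseg_state <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<fedseg_state> %d layers, %s parameters, epoch %d\n",
              length(x$params), format(np, big.mark = ","), x$metadata$epoch))
  invisible(x)
}

#' Layer name/shape table of a state or architecture
#'
#' @param x a `fedseg_state` or `fedseg_arch`.
#' @return data.frame with columns `layer` and `shape` (list column of
#'   integer vectors), in iteration order.
#' @export
state_shapes <- function(x) {
  if (inherits(x, "fedseg_arch")) {
    shapes <- x$layers
  } else {
    shapes <- lapply(x$params, function(p) {
      if (is.null(dim(p))) length(p) else dim(p)
    })
  }
  data.frame(layer = names(shapes),
             shape = I(lapply(shapes, as.integer)),
             row.names = NULL)
}

#' Checkpoint IO for model states
#'
#' A checkpoint is a single-file archive (RDS) holding the ordered parameter
#' map, its metadata, a format version and an MD5 checksum verified on read.
#'
#' @param state a `fedseg_state`.
#' @param path checkpoint file path.
#' @return `read_checkpoint` returns a `fedseg_state`; `write_checkpoint`
#'   returns `path` invisibly.
#' @export
write_checkpoint <- function(state, path) {
  payload <- list(checkpoint_version = 1L,
                  params = state$params,
                  metadata = state$metadata)
  payload$checksum <- object_md5(payload[c("params", "metadata")])
  saveRDS(payload, path, version = 2)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$checkpoint_version)) stopf("not a checkpoint: '%s'", path)
  if (payload$checkpoint_version != 1L) {
    stopf("checkpoint version %s not supported", payload$checkpoint_version)
  }
  if (!identical(payload$checksum, object_md5(payload[c("params", "metadata")]))) {
    stopf("checksum failure reading '%s'", path)
  }
  structure(list(params = payload$params, metadata = payload$metadata),
            class = "fedseg_state")
}
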