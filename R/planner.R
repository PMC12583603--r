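#' Resource budget for planning
#'
#' Describes the local hardware envelope a node plans against: the maximum
#' number of voxels in a training patch (the proxy for accelerator memory)
#' and the maximum batch size.
#'
#' @param max_patch_voxels maximum voxels in a patch (default `512^2`, the
#'   reference 2D configuration).
#' @param max_batch maximum batch size.
#' @param dimensionality 2 or 3.
#' @return a `fedseg_budget` list.
#' @export
resource_budget <- function(max_patch_voxels = 512^2, max_batch = 48L,
                            dimensionality = 2L) {
  stopifnot(max_patch_voxels > 0, max_batch >= 1)
  structure(list(max_patch_voxels = as.numeric(max_patch_voxels),
                 max_batch = as.integer(max_batch),
                 dimensionality = as.integer(dimensionality)),
            class = "fedseg_budget")
}

# Number of times an axis extent can be halved before the feature map at the
# bottleneck would fall below the minimum size of 4. This single constant
# reproduces the published per-patch stage counts (256 -> 7, 320 -> 7,
# 512 -> 8 stages).
n_poolings_axis <- function(extent, min_size = 4L) {
  p <- 0L
  while (extent %/% 2L >= min_size) {
    extent <- extent %/% 2L
    p <- p + 1L
  }
  p
}

round_up_multiple <- function(x, m) as.integer(ceiling(x / m) * m)

#' Derive a training plan from a fingerprint and a resource budget
#'
#' Self-configuration approximating the upstream convention:
#' * `target_spacing`: per-axis lower median of the fingerprint spacings;
#' * `median_shape`: per-axis lower median of case shapes rescaled to the
#'   target spacing (rounded);
#' * `patch_size`: the median shape, scaled down isotropically if it exceeds
#'   `budget$max_patch_voxels`, then rounded up per axis to the nearest
#'   multiple of `2^poolings`, iterating until the pooling counts are
#'   consistent with the patch;
#' * `n_poolings_per_axis`: halvings until the axis would drop below the
#'   bottleneck minimum of 4; `n_stages` is the maximum over axes plus 1;
#' * `features_per_stage`: `min(32 * 2^i, cap)` with cap 512 in 2D, 320 in 3D;
#' * `batch_size`: inverse-proportional to patch voxels, anchored at 12
#'   samples for a 512x512 patch, clipped to `[2, budget$max_batch]`.
#'
#' The plan is a pure function of (fingerprint, budget): nodes that share a
#' budget and the same (global) fingerprint derive byte-identical plans.
#'
#' @param fp a `fedseg_fingerprint`.
#' @param budget a `fedseg_budget`.
#' @return a `fedseg_plan`.
#' @export
make_plan <- function(fp, budget = resource_budget()) {
  if (fp$n_cases < 1) stopf("no cases")
  d <- fp$dimensionality
  if (!is.null(budget$dimensionality) && budget$dimensionality != d) {
    stopf("budget dimensionality %d does not match fingerprint %dD",
          budget$dimensionality, d)
  }
  sp_mat <- do.call(rbind, fp$spacings)
  target_spacing <- apply(sp_mat, 2, median_low)
  shp_mat <- do.call(rbind, lapply(seq_len(fp$n_cases), function(i) {
    as.integer(round(fp$shapes_after_crop[[i]] * fp$spacings[[i]] / target_spacing))
  }))
  median_shape <- pmax(apply(shp_mat, 2, median_low), 4L)

  if (budget$max_patch_voxels < 4^d) stopf("budget infeasible")
  patch <- as.numeric(median_shape)
  if (prod(patch) > budget$max_patch_voxels) {
    f <- (budget$max_patch_voxels / prod(patch))^(1 / d)
    patch <- pmax(floor(patch * f), 4)
  }
  patch <- as.integer(patch)
  # fixed-point: pooling counts depend on the patch, the divisibility
  # rounding depends on the pooling counts
  repeat {
    pool <- vapply(patch, n_poolings_axis, integer(1))
    new_patch <- round_up_multiple(patch, 2L^pool)
    if (all(new_patch == patch)) break
    patch <- new_patch
  }
  n_stages <- max(pool) + 1L
  cap <- if (d == 2L) 512L else 320L
  features <- pmin(32L * 2L^(seq_len(n_stages) - 1L), cap)
  batch <- as.integer(min(max(round(12 * 512^2 / prod(patch)), 2), budget$max_batch))

  plan <- list(
    plan_version = 1L,
    dimensionality = as.integer(d),
    target_spacing = as.numeric(target_spacing),
    median_shape = as.integer(median_shape),
    patch_size = as.integer(patch),
    n_poolings_per_axis = as.integer(pool),
    n_stages = n_stages,
    features_per_stage = as.integer(features),
    batch_size = batch,
    normalization = "zscore",
    conv_kernel = 3L,
    pool_kernel = 2L
  )
  class(plan) <- "fedseg_plan"
  plan
}

#' Hash of a training plan
#'
#' MD5 over the canonical JSON encoding; equal plans give equal hashes on
#' every platform. Used to assert architecture identity across federated
#' clients.
#'
#' @param plan a `fedseg_plan`.
#' @return 32-character hex string.
#' @export
plan_hash <- function(plan) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(canonical_json(unclass(plan)), f)
  unname(tools::md5sum(f))
}

#' Write / read a training plan as canonical JSON
#'
#' @param plan a `fedseg_plan`.
#' @param path JSON file path.
#' @return `read_plan` returns a `fedseg_plan`; `write_plan` returns `path`
#'   invisibly.
#' @export
write_plan <- function(plan, path) {
  writeLines(canonical_json(unclass(plan)), path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$plan_version)) stopf("not a plan file: '%s'", path)
  if (x$plan_version != 1L) stopf("plan version %s not supported", x$plan_version)
  x$dimensionality <- as.integer(x$dimensionality)
  x$median_shape <- as.integer(x$median_shape)
  x$patch_size <- as.integer(x$patch_size)
  x$n_poolings_per_axis <- as.integer(x$n_poolings_per_axis)
  x$n_stages <- as.integer(x$n_stages)
  x$features_per_stage <- as.integer(x$features_per_stage)
  x$batch_size <- as.integer(x$batch_size)
  class(x) <- "fedseg_plan"
  x
}

#' @export
print.fedseg_plan <- function(x, ...) {
  cat(sprintf("<fedseg_plan> %dD\n", x$dimensionality))
  cat(sprintf("  target spacing : [%s] mm\n", paste(x$target_spacing, collapse = ", ")))
  cat(sprintf("  median shape   : [%s]\n", paste(x$median_shape, collapse = ", ")))
  cat(sprintf("  patch size     : [%s]\n", paste(x$patch_size, collapse = ", ")))
  cat(sprintf("  stages         : %d (features %s)\n", x$n_stages,
              paste(x$features_per_stage, collapse = "-")))
  cat(sprintf("  batch size     : %d\n", x$batch_size))
  invisible(x)
}
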