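#' Dataset fingerprints
#'
#' A dataset fingerprint is the compact per-center summary that drives
#' self-configuration: the list of case shapes after cropping to the nonzero
#' bounding box, the list of voxel spacings, and an intensity summary over a
#' bounded subsample of cropped-region voxel intensities. The federated
#' ("global") fingerprint is the same type, produced by concatenating the
#' locals' lists, so it is usable anywhere a local fingerprint is.
#'
#' @name fingerprint
NULL

new_fingerprint <- function(shapes_after_crop, spacings, intensity_samples,
                            n_cases, dimensionality) {
  fp <- list(
    fingerprint_version = 1L,
    dimensionality = as.integer(dimensionality),
    n_cases = as.integer(n_cases),
    shapes_after_crop = lapply(shapes_after_crop, as.integer),
    spacings = lapply(spacings, as.numeric),
    intensity_samples = if (is.null(intensity_samples)) NULL else as.numeric(intensity_samples),
    intensity_summary = intensity_summary(intensity_samples)
  )
  class(fp) <- "fedseg_fingerprint"
  fp
}

intensity_summary <- function(v) {
  if (is.null(v) || !length(v)) return(NULL)
  list(
    mean = mean(v),
    sd = if (length(v) > 1) stats::sd(v) else 0,
    p00_5 = unname(stats::quantile(v, 0.005, type = 7)),
    p99_5 = unname(stats::quantile(v, 0.995, type = 7))
  )
}

# Minimal axis-aligned bounding box of nonzero intensities; degenerate
# all-zero images fall back to the full extent.
nonzero_crop_box <- function(image) {
  nz <- image != 0
  d <- dim(image)
  if (!any(nz)) {
    return(lapply(d, function(n) c(1L, n)))
  }
  idx <- which(nz, arr.ind = TRUE)
  lapply(seq_along(d), function(a) c(min(idx[, a]), max(idx[, a])))
}

crop_to_box <- function(arr, box) {
  do.call(`[`, c(list(arr), lapply(box, function(b) b[1]:b[2]), list(drop = FALSE)))
}

#' Extract a local dataset fingerprint
#'
#' Walks a dataset directory of `<case>_img` / `<case>_seg` NIfTI pairs and
#' records, per case, the shape after cropping to the minimal bounding box of
#' nonzero image intensity and the voxel spacing. Intensities inside the
#' cropped region are subsampled (deterministically, given `seed`) to at most
#' `intensity_cap` values per fingerprint and summarized as mean / sd /
#' 0.5th / 99.5th percentiles.
#'
#' @param dataset_path directory of image+mask pairs.
#' @param intensity_cap maximum number of retained intensity samples.
#' @param include_intensity if `FALSE`, no intensity information is recorded
#'   (the exchanged fingerprint then carries spatial characteristics only).
#' @param seed RNG seed for intensity subsampling.
#' @return a `fedseg_fingerprint`.
#' @export
extract_local_fingerprint <- function(dataset_path, intensity_cap = 10000L,
                                      include_intensity = TRUE, seed = 0L) {
  fingerprint_from_cases(read_dataset(dataset_path), intensity_cap,
                         include_intensity, seed)
}

#' @rdname extract_local_fingerprint
#' @param cases list of in-memory cases (`image`, `mask`, `spacing`).
#' @export
fingerprint_from_cases <- function(cases, intensity_cap = 10000L,
                                   include_intensity = TRUE, seed = 0L) {
  if (!length(cases)) stopf("no cases")
  shapes <- list()
  spacings <- list()
  samples <- list()
  per_case_cap <- ceiling(intensity_cap / length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    if (!identical(dim(cs$image), dim(cs$mask))) stopf("inconsistent case")
    if (any(cs$spacing <= 0) || length(cs$spacing) != length(dim(cs$image))) {
      stopf("invalid metadata")
    }
    box <- nonzero_crop_box(cs$image)
    shapes[[i]] <- vapply(box, function(b) b[2] - b[1] + 1L, integer(1))
    spacings[[i]] <- cs$spacing
    if (include_intensity) {
      v <- as.numeric(crop_to_box(cs$image, box))
      if (length(v) > per_case_cap) {
        v <- with_seed(derive_seed(seed, "fp-intensity", cs$name %||% i),
                       v[sample.int(length(v), per_case_cap)])
      }
      samples[[i]] <- v
    }
  }
  dims <- lengths(shapes)
  if (length(unique(dims)) != 1) stopf("inconsistent case: mixed dimensionality")
  new_fingerprint(shapes, spacings,
                  if (include_intensity) unlist(samples) else NULL,
                  length(cases), dims[1])
}

#' Aggregate local fingerprints into a global fingerprint
#'
#' The federated fingerprint is the ordered concatenation of the locals'
#' `shapes_after_crop` and `spacings` lists; `n_cases` is the sum. The
#' intensity summary is recomputed over the pooled retained samples (each
#' local retains a bounded subsample, so pooling is transmissible). The
#' result is a plain fingerprint, usable for planning on any node.
#'
#' @param locals list of `fedseg_fingerprint` objects.
#' @return a `fedseg_fingerprint`.
#' @export
aggregate_fingerprints <- function(locals) {
  if (!length(locals)) stopf("no fingerprints")
  dims <- vapply(locals, function(f) f$dimensionality, integer(1))
  if (length(unique(dims)) != 1) stopf("dimensionality mismatch")
  samples <- unlist(lapply(locals, function(f) f$intensity_samples))
  new_fingerprint(
    do.call(c, lapply(locals, function(f) f$shapes_after_crop)),
    do.call(c, lapply(locals, function(f) f$spacings)),
    if (length(samples)) samples else NULL,
    sum(vapply(locals, function(f) f$n_cases, integer(1))),
    dims[1]
  )
}

#' Write / read a fingerprint as canonical JSON
#'
#' Files carry a `fingerprint_version` field; canonical key ordering makes
#' byte-identical files equivalent to equal fingerprints.
#'
#' @param fp a `fedseg_fingerprint`.
#' @param path JSON file path.
#' @return `read_fingerprint` returns a `fedseg_fingerprint`;
#'   `write_fingerprint` returns `path` invisibly.
#' @export
write_fingerprint <- function(fp, path) {
  writeLines(canonical_json(unclass(fp)), path)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (is.null(x$fingerprint_version)) stopf("not a fingerprint file: '%s'", path)
  if (x$fingerprint_version != 1L) stopf("fingerprint version %s not supported", x$fingerprint_version)
  new_fingerprint(x$shapes_after_crop, x$spacings, x$intensity_samples,
                  x$n_cases, x$dimensionality)
}

#' @export
print.fedseg_fingerprint <- function(x, ...) {
  cat(sprintf("<fedseg_fingerprint> %dD, %d cases\n", x$dimensionality, x$n_cases))
  if (!is.null(x$intensity_summary)) {
    cat(sprintf("  intensity: mean %.4g sd %.4g [p0.5 %.4g, p99.5 %.4g] (%d samples)\n",
                x$intensity_summary$mean, x$intensity_summary$sd,
                x$intensity_summary$p00_5, x$intensity_summary$p99_5,
                length(x$intensity_samples)))
  }
  invisible(x)
}
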