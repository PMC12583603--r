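#' Describe one synthetic imaging center
#'
#' A center is a generative recipe for 2D grayscale cases: a matrix-size
#' range, a fixed voxel spacing, an intensity profile (background and
#' foreground Gaussian components plus a smooth multiplicative bias field)
#' and a lesion model of random rotated ellipses parameterized in
#' millimeters — so spacing differences between centers induce genuine
#' resolution shift rather than mere rescaling.
#'
#' @param name center name.
#' @param shape_min,shape_max inclusive per-axis matrix-size range.
#' @param spacing mm per voxel (length 2).
#' @param bg_mean,bg_sd background intensity component.
#' @param fg_mean,fg_sd foreground (lesion) intensity component.
#' @param bias_amplitude amplitude of the multiplicative low-frequency bias
#'   field (0 disables).
#' @param lesion_count inclusive range of lesions per case.
#' @param lesion_radius_mm inclusive range of the lesion semi-major axis.
#' @param ellipticity inclusive range of the minor/major axis ratio.
#' @param n_labels 1 for binary lesions, 3 for the nested-ellipse variant
#'   (three concentric structures, cardiac-like).
#' @param n_cases number of cases the center holds.
#' @param seed center RNG seed; every case is fully determined by
#'   (seed, case index).
#' @return a `fedseg_center_spec`.
#' @export
center_spec <- function(name, shape_min, shape_max = shape_min, spacing,
                        bg_mean = 0.25, bg_sd = 0.12,
                        fg_mean = 0.55, fg_sd = 0.15,
                        bias_amplitude = 0.2,
                        lesion_count = c(1L, 3L),
                        lesion_radius_mm = c(4, 12),
                        ellipticity = c(0.6, 1),
                        n_labels = 1L, n_cases = 25L, seed = 0L) {
  if (fg_mean - bg_mean < 0.1) stopf("spec infeasible: foreground/background contrast below floor")
  sp <- structure(list(
    name = name, shape_min = as.integer(shape_min), shape_max = as.integer(shape_max),
    spacing = as.numeric(spacing), bg_mean = bg_mean, bg_sd = bg_sd,
    fg_mean = fg_mean, fg_sd = fg_sd, bias_amplitude = bias_amplitude,
    lesion_count = as.integer(lesion_count), lesion_radius_mm = as.numeric(lesion_radius_mm),
    ellipticity = as.numeric(ellipticity), n_labels = as.integer(n_labels),
    n_cases = as.integer(n_cases), seed = as.integer(seed)
  ), class = "fedseg_center_spec")
  ext <- sp$shape_min * sp$spacing
  if (2 * max(sp$lesion_radius_mm) > min(ext) * 0.8) stopf("spec infeasible: lesion radius vs image extent")
  sp
}

# smooth multiplicative bias field in [1-a, 1+a]
bias_field <- function(shape, amplitude) {
  if (amplitude <= 0) return(array(1, shape))
  u <- seq(0, 1, length.out = shape[1])
  v <- seq(0, 1, length.out = shape[2])
  a1 <- stats::runif(1, -1, 1); p1 <- stats::runif(1); k1 <- stats::runif(1, 0.5, 1.5)
  a2 <- stats::runif(1, -1, 1); p2 <- stats::runif(1); k2 <- stats::runif(1, 0.5, 1.5)
  f <- outer(a1 * cospi(2 * (p1 + k1 * u)), a2 * cospi(2 * (p2 + k2 * v)), `+`)
  1 + amplitude * f / max(abs(f))
}

# rasterize one rotated ellipse (mm-parameterized) into a logical mask
ellipse_mask <- function(shape, spacing, center_mm, r_major, r_minor, angle) {
  xi <- (seq_len(shape[1]) - 0.5) * spacing[1]
  yj <- (seq_len(shape[2]) - 0.5) * spacing[2]
  ca <- cos(angle); sa <- sin(angle)
  dx <- outer(xi - center_mm[1], rep(1, shape[2]))
  dy <- outer(rep(1, shape[1]), yj - center_mm[2])
  u <- (ca * dx + sa * dy) / r_major
  v <- (-sa * dx + ca * dy) / r_minor
  u^2 + v^2 <= 1
}

#' Generate one synthetic case
#'
#' Fully determined by `(spec$seed, idx)`.
#'
#' @param spec a `fedseg_center_spec`.
#' @param idx case index (1-based).
#' @return a case list: `image`, `mask`, `spacing`, `name`, `provenance`.
#' @export
generate_case <- function(spec, idx) {
  with_seed(derive_seed(spec$seed, "case", idx), {
    shape <- vapply(1:2, function(a) {
      if (spec$shape_max[a] > spec$shape_min[a]) {
        spec$shape_min[a] + sample.int(spec$shape_max[a] - spec$shape_min[a] + 1L, 1) - 1L
      } else spec$shape_min[a]
    }, integer(1))
    ext <- shape * spec$spacing
    mask <- array(0L, shape)
    n_les <- spec$lesion_count[1] +
      (if (spec$lesion_count[2] > spec$lesion_count[1])
        sample.int(spec$lesion_count[2] - spec$lesion_count[1] + 1L, 1) - 1L else 0L)
    for (l in seq_len(n_les)) {
      r1 <- stats::runif(1, spec$lesion_radius_mm[1], spec$lesion_radius_mm[2])
      r2 <- r1 * stats::runif(1, spec$ellipticity[1], spec$ellipticity[2])
      ang <- stats::runif(1, 0, pi)
      ctr <- c(stats::runif(1, r1, ext[1] - r1), stats::runif(1, r1, ext[2] - r1))
      if (spec$n_labels == 3L) {
        for (lab in 1:3) {
          f <- c(1, 0.7, 0.4)[lab]
          m <- ellipse_mask(shape, spec$spacing, ctr, r1 * f, r2 * f, ang)
          mask[m] <- lab
        }
      } else {
        m <- ellipse_mask(shape, spec$spacing, ctr, r1, r2, ang)
        mask[m] <- 1L
      }
    }
    img <- array(stats::rnorm(prod(shape), spec$bg_mean, spec$bg_sd), shape)
    fg <- mask > 0
    # deeper structures render slightly brighter in the nested variant
    img[fg] <- stats::rnorm(sum(fg), spec$fg_mean + 0.1 * (mask[fg] - 1L), spec$fg_sd)
    img <- img * bias_field(shape, spec$bias_amplitude)
    list(image = img, mask = mask, spacing = spec$spacing,
         name = sprintf("%s_%03d", spec$name, idx),
         provenance = list(center = spec$name, case = idx, seed = spec$seed))
  })
}

#' Generate a synthetic center's dataset
#'
#' @param spec a `fedseg_center_spec`.
#' @param out_dir if non-NULL, cases are also written as NIfTI pairs there.
#' @return list of cases (see [generate_case()]).
#' @export
generate_center <- function(spec, out_dir = NULL) {
  cases <- lapply(seq_len(spec$n_cases), function(i) generate_case(spec, i))
  if (!is.null(out_dir)) {
    for (cs in cases) write_case(cs, out_dir, cs$name)
  }
  cases
}

#' Benchmark presets
#'
#' Multi-center benchmark definitions used throughout the package's tests
#' and examples:
#' * `homogeneous3` — three centers with identical geometry and intensity
#'   profile (only the data differ): all clients derive identical plans, so
#'   asymmetric aggregation reduces to classical FedAvg.
#' * `heterogeneous3` — a low/high-resolution split (one coarse 64 px /
#'   1.5 mm center, one 96 px / 1.0 mm center, one fine 160 px / 0.5 mm
#'   center whose intensity profile also differs), emulating the kind of
#'   cross-site variability seen in multi-center ultrasound cohorts.
#' * `heterogeneous4` — four centers with a 2x spacing gap between the
#'   coarsest and finest sites and unequal dataset sizes, emulating
#'   multi-center MRI cohorts (makes proportional vs equal-center
#'   weighting meaningful).
#'
#' Each preset also carries per-center default resource budgets (the
#' simulated local hardware): heterogeneous presets assign budgets that
#' yield at least two distinct desk-scale architectures.
#'
#' @param preset preset name.
#' @param seed base seed; center c uses a seed derived from (seed, c).
#' @param n_cases per-center case count override (NULL keeps defaults).
#' @return list with `specs` (list of `fedseg_center_spec`) and `budgets`
#'   (list of `fedseg_budget`).
#' @export
benchmark_presets <- function(preset = c("homogeneous3", "heterogeneous3", "heterogeneous4"),
                              seed = 0L, n_cases = NULL) {
  preset <- match.arg(preset)
  cs <- function(name, shape, spacing, idx, n = 25L, ...) {
    center_spec(name, shape_min = c(shape, shape), spacing = c(spacing, spacing),
                n_cases = n_cases %||% n, seed = derive_seed(seed, "center", idx), ...)
  }
  if (preset == "homogeneous3") {
    specs <- list(cs("alpha", 96L, 1.0, 1), cs("beta", 96L, 1.0, 2), cs("gamma", 96L, 1.0, 3))
    budgets <- rep(list(resource_budget(16^2, 4L)), 3)
  } else if (preset == "heterogeneous3") {
    specs <- list(
      cs("lowres", 64L, 1.5, 1),
      cs("midres", 96L, 1.0, 2),
      cs("highres", 160L, 0.5, 3, fg_mean = 0.65, bias_amplitude = 0.3)
    )
    budgets <- list(resource_budget(8^2, 4L), resource_budget(16^2, 4L),
                    resource_budget(16^2, 4L))
  } else {
    specs <- list(
      cs("coarse_a", 96L, 1.4, 1, n = 15L),
      cs("mid_b", 112L, 1.2, 2, n = 40L),
      cs("fine_c", 160L, 0.7, 3, n = 25L),
      cs("coarse_d", 96L, 1.4, 4, n = 10L)
    )
    budgets <- list(resource_budget(8^2, 4L), resource_budget(16^2, 4L),
                    resource_budget(16^2, 4L), resource_budget(8^2, 4L))
  }
  list(specs = specs, budgets = budgets, preset = preset, seed = as.integer(seed))
}

#' Materialize a benchmark preset on disk
#'
#' Generates every center's cases, writes them as per-center directories of
#' NIfTI pairs plus a `manifest.json` describing the specs and budgets.
#'
#' @param preset preset name (see [benchmark_presets()]).
#' @param out_dir output directory.
#' @param seed base seed.
#' @param n_cases per-center case count override.
#' @return invisibly, the benchmark definition with `$dirs` added.
#' @export
make_benchmark <- function(preset, out_dir, seed = 0L, n_cases = NULL) {
  bm <- benchmark_presets(preset, seed, n_cases)
  dirs <- character(length(bm$specs))
  for (i in seq_along(bm$specs)) {
    dirs[i] <- file.path(out_dir, bm$specs[[i]]$name)
    generate_center(bm$specs[[i]], dirs[i])
  }
  bm$dirs <- dirs
  manifest <- list(
    preset = bm$preset, seed = bm$seed,
    centers = lapply(seq_along(bm$specs), function(i) {
      c(unclass(bm$specs[[i]]), list(dir = basename(dirs[i]),
                                     budget = unclass(bm$budgets[[i]])))
    })
  )
  writeLines(canonical_json(manifest), file.path(out_dir, "manifest.json"))
  invisible(bm)
}
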