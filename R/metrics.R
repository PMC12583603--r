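#' Dice similarity coefficient
#'
#' Per-label overlap `2|A n B| / (|A| + |B|)` between a predicted and a
#' reference integer label mask, plus the unweighted mean over foreground
#' labels. Convention: a label empty in both masks scores 1, empty in
#' exactly one scores 0.
#'
#' @param pred,ref integer label arrays of equal shape.
#' @param labels foreground labels to score; default: all labels > 0
#'   present in either mask (`1` if none).
#' @return list with `per_label` (named numeric) and `mean` (foreground
#'   mean).
#' @export
dsc <- function(pred, ref, labels = NULL) {
  if (!identical(dim(pred) %||% length(pred), dim(ref) %||% length(ref))) {
    stopf("incompatible masks")
  }
  if (is.null(labels)) {
    labels <- sort(unique(c(pred[pred > 0], ref[ref > 0])))
    if (!length(labels)) labels <- 1L
  }
  per <- vapply(labels, function(l) {
    a <- pred == l
    b <- ref == l
    na <- sum(a); nb <- sum(b)
    if (na == 0 && nb == 0) return(1)
    if (na == 0 || nb == 0) return(0)
    2 * sum(a & b) / (na + nb)
  }, numeric(1))
  names(per) <- labels
  list(per_label = per, mean = mean(per))
}

# boundary voxels: mask voxels with at least one background face-neighbor
# (the array border counts as background)
boundary_coords <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  # padded-array neighbor test, dimension-generic
  pad <- array(FALSE, d + 2L)
  idx <- lapply(d, function(n) seq_len(n) + 1L)
  pad <- do.call(`[<-`, c(list(pad), idx, list(mask)))
  interior <- array(TRUE, d)
  for (a in seq_len(nd)) {
    for (off in c(-1L, 1L)) {
      sh <- lapply(seq_len(nd), function(i) if (i == a) idx[[i]] + off else idx[[i]])
      nb <- do.call(`[`, c(list(pad), sh, list(drop = FALSE)))
      interior <- interior & array(nb, d)
    }
  }
  which(mask & !interior, arr.ind = TRUE)
}

directed_min_dists <- function(A, B) {
  # for each row of A, the minimum Euclidean distance to rows of B
  if (!nrow(A)) return(numeric(0))
  chunk <- 2048L
  out <- numeric(nrow(A))
  Bt2 <- rowSums(B^2)
  for (st in seq(1L, nrow(A), by = chunk)) {
    en <- min(st + chunk - 1L, nrow(A))
    Ai <- A[st:en, , drop = FALSE]
    D2 <- outer(rowSums(Ai^2), Bt2, `+`) - 2 * Ai %*% t(B)
    out[st:en] <- sqrt(pmax(apply(D2, 1, min), 0))
  }
  out
}

#' 95th-percentile Hausdorff distance
#'
#' Symmetric surface distance in physical units: boundary voxels (those
#' with a background face-neighbor) are extracted from both masks, voxel
#' centers are scaled by the spacing, directed nearest-neighbor distances
#' are computed in both directions, pooled, and summarized by the
#' linear-interpolation 95th percentile. Identical masks score 0.
#'
#' Conventions for degenerate inputs: both masks empty scores 0; exactly
#' one empty returns `empty_penalty` (default: the physical diagonal of the
#' mask extent), with attribute `empty = TRUE` so it can be reported
#' distinctly.
#'
#' @param pred,ref binary or label arrays of equal shape (compared as
#'   `> 0` unless `label` is given).
#' @param spacing mm per voxel, one entry per axis.
#' @param label optional single label to score.
#' @param q percentile in (0, 1]; 0.95 for HD95, 1 for the exact Hausdorff
#'   distance.
#' @param empty_penalty value returned when exactly one mask is empty.
#' @return distance (numeric scalar).
#' @export
hd95 <- function(pred, ref, spacing = rep(1, length(dim(pred))), label = NULL,
                 q = 0.95, empty_penalty = NULL) {
  if (!identical(dim(pred), dim(ref))) stopf("incompatible masks")
  pm <- if (is.null(label)) pred > 0 else pred == label
  rm_ <- if (is.null(label)) ref > 0 else ref == label
  if (!any(pm) && !any(rm_)) return(0)
  if (!any(pm) || !any(rm_)) {
    pen <- empty_penalty %||% sqrt(sum((dim(pred) * spacing)^2))
    return(structure(pen, empty = TRUE))
  }
  A <- boundary_coords(pm)
  B <- boundary_coords(rm_)
  As <- sweep(A, 2, spacing, `*`)
  Bs <- sweep(B, 2, spacing, `*`)
  pooled <- c(directed_min_dists(As, Bs), directed_min_dists(Bs, As))
  unname(stats::quantile(pooled, q, type = 7))
}

#' Evaluate a model on a set of cases
#'
#' Runs [predict_case()] on each case and scores DSC and HD95 against the
#' reference masks in native geometry.
#'
#' @param state a `fedseg_state`.
#' @param cases list of raw cases (with `mask`).
#' @param plan the matching plan.
#' @return data.frame with one row per case: `case`, `dsc`, `hd95`.
#' @export
evaluate_cases <- function(state, cases, plan) {
  rows <- lapply(cases, function(cs) {
    pred <- predict_case(state, cs, plan)
    data.frame(case = cs$name %||% NA_character_,
               dsc = dsc(pred, cs$mask)$mean,
               hd95 = as.numeric(hd95(pred, cs$mask, cs$spacing)))
  })
  do.call(rbind, rows)
}

#' Cross-center evaluation matrix
#'
#' Entry (i, j) is the mean foreground DSC of center i's model evaluated on
#' center j's cases: each model infers at its own plan's target spacing and
#' predictions are scored on the cases' native grids.
#'
#' @param states list of per-center `fedseg_state` objects.
#' @param plans list of matching per-center plans.
#' @param datasets list of per-center case lists (with masks).
#' @param center_names optional names for rows/columns.
#' @return numeric matrix (rows: training center, cols: evaluation center),
#'   class `fedseg_crosscenter`.
#' @export
cross_center_matrix <- function(states, plans, datasets, center_names = NULL) {
  n_mod <- length(states)
  n_dat <- length(datasets)
  M <- matrix(NA_real_, n_mod, n_dat)
  for (i in seq_len(n_mod)) {
    for (j in seq_len(n_dat)) {
      M[i, j] <- mean(evaluate_cases(states[[i]], datasets[[j]], plans[[i]])$dsc)
    }
  }
  if (!is.null(center_names)) dimnames(M) <- list(train = center_names, eval = center_names)
  class(M) <- c("fedseg_crosscenter", class(M))
  M
}

#' Write a cross-center matrix as CSV with center labels
#'
#' @param m a matrix from [cross_center_matrix()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_crosscenter_csv <- function(m, path) {
  df <- as.data.frame(unclass(m))
  utils::write.csv(cbind(train_center = rownames(m) %||% seq_len(nrow(m)), df),
                   path, row.names = FALSE)
  invisible(path)
}
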