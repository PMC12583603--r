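state_shape_of <- function(p) if (is.null(dim(p))) length(p) else dim(p)

#' Layer matching across client model states
#'
#' Identifies the compatible layer set: in `"strict"` mode a layer qualifies
#' iff it is present in every client's state with identical parameter
#' shapes (each layer's contributing set is then all clients). In
#' `"partial"` mode a layer qualifies iff at least `min_clients` clients
#' hold it and all holders agree on its shape; the contributing set is the
#' holders. Layers whose holders disagree on shape are excluded in both
#' modes.
#'
#' @param states list of >= 2 `fedseg_state` objects (ascending client id).
#' @param mode `"strict"` or `"partial"`.
#' @param min_clients minimum holders for partial mode.
#' @return a `fedseg_compat`: `$layers` (character, in client 1 order then
#'   first-appearance order), `$contributors` (named list of client index
#'   vectors), `$mode`.
#' @export
compatible_layers <- function(states, mode = c("strict", "partial"),
                              min_clients = 2L) {
  mode <- match.arg(mode)
  stopifnot(length(states) >= 2L)
  shapes <- lapply(states, function(s) lapply(s$params, state_shape_of))
  all_names <- unique(unlist(lapply(shapes, names)))
  layers <- character(0)
  contributors <- list()
  for (nm in all_names) {
    holders <- which(vapply(shapes, function(sh) !is.null(sh[[nm]]), logical(1)))
    shs <- lapply(holders, function(k) shapes[[k]][[nm]])
    agree <- all(vapply(shs, identical, logical(1), shs[[1]]))
    ok <- if (mode == "strict") {
      length(holders) == length(states) && agree
    } else {
      length(holders) >= min_clients && agree
    }
    if (ok) {
      layers <- c(layers, nm)
      contributors[[nm]] <- holders
    }
  }
  structure(list(layers = layers, contributors = contributors, mode = mode),
            class = "fedseg_compat")
}

#' @export
print.fedseg_compat <- function(x, ...) {
  cat(sprintf("<fedseg_compat> %s mode, %d layers\n", x$mode, length(x$layers)))
  invisible(x)
}

#' Aggregation weights
#'
#' `"proportional"` weights clients by case count; `"equal_center"` gives
#' every client the same weight regardless of dataset size. Raw weights are
#' normalized per layer over that layer's contributing clients.
#'
#' @param n_cases integer vector of per-client case counts.
#' @param mode `"proportional"` or `"equal_center"`.
#' @return numeric vector of non-negative raw weights (one per client).
#' @export
aggregation_weights <- function(n_cases, mode = c("proportional", "equal_center")) {
  mode <- match.arg(mode)
  if (mode == "equal_center") rep(1, length(n_cases)) else as.numeric(n_cases)
}

#' Aggregate compatible layers across client states
#'
#' For each layer `l` in the compatibility set, computes the weighted mean
#' over the layer's contributing clients, with the weights restricted to
#' the contributors and renormalized to sum to 1. Uniform weights recover
#' the plain mean over contributors. Summation runs in ascending client id
#' so results are bitwise reproducible.
#'
#' @param states list of `fedseg_state` (ascending client id).
#' @param weights raw per-client weights (see [aggregation_weights()]).
#' @param layers a `fedseg_compat` from [compatible_layers()].
#' @return named list (layer -> aggregated parameter array): the aggregated
#'   partial state.
#' @export
aggregate_states <- function(states, weights, layers) {
  stopifnot(inherits(layers, "fedseg_compat"), length(weights) == length(states))
  out <- list()
  for (nm in layers$layers) {
    ks <- sort(layers$contributors[[nm]])
    w <- weights[ks]
    if (sum(w) <= 0) stopf("degenerate weights for layer '%s'", nm)
    w <- w / sum(w)
    acc <- NULL
    for (i in seq_along(ks)) {
      th <- states[[ks[i]]]$params[[nm]]
      if (is.null(th)) stopf("inconsistent compatibility set: '%s' missing from client %d", nm, ks[i])
      acc <- if (is.null(acc)) w[i] * th else acc + w[i] * th
    }
    out[[nm]] <- acc
  }
  out
}

#' Apply an aggregated partial state to a local model
#'
#' Layers named in `shared` replace the local values; every other layer is
#' left bitwise unchanged, so architecture-specific components keep evolving
#' only locally. Metadata (including the epoch counter) is preserved.
#'
#' @param local a `fedseg_state`.
#' @param shared named list of aggregated parameters (from
#'   [aggregate_states()]).
#' @return the updated `fedseg_state`.
#' @export
apply_update <- function(local, shared) {
  for (nm in names(shared)) {
    cur <- local$params[[nm]]
    if (is.null(cur)) stopf("stale compatibility set: '%s' not in local model", nm)
    if (!identical(state_shape_of(cur), state_shape_of(shared[[nm]]))) {
      stopf("stale compatibility set: shape clash on '%s'", nm)
    }
    local$params[[nm]] <- shared[[nm]]
  }
  local
}

#' Classical federated averaging
#'
#' Requires all clients to share one architecture (identical layer
#' name/shape sets); returns the full-state weighted average. Implemented
#' as a direct weighted-mean loop (ascending client id), independent of
#' [aggregate_states()].
#'
#' @param states list of `fedseg_state` with identical architectures.
#' @param weights raw per-client weights.
#' @return a `fedseg_state` (metadata from client 1, epoch preserved).
#' @export
fedavg <- function(states, weights) {
  stopifnot(length(states) >= 1L, length(weights) == length(states))
  ref <- lapply(states[[1]]$params, state_shape_of)
  for (k in seq_along(states)[-1]) {
    sk <- lapply(states[[k]]$params, state_shape_of)
    if (!identical(names(ref), names(sk)) || !identical(unname(ref), unname(sk))) {
      stopf("architecture mismatch")
    }
  }
  w <- weights / sum(weights)
  out <- states[[1]]
  for (nm in names(out$params)) {
    acc <- w[1] * states[[1]]$params[[nm]]
    for (k in seq_along(states)[-1]) acc <- acc + w[k] * states[[k]]$params[[nm]]
    out$params[[nm]] <- acc
  }
  out
}

#' Aggregation report
#'
#' Classifies every layer name occurring in any client as matched,
#' shape-excluded (name shared by all, shapes differ) or name-excluded
#' (missing from at least one client), mirroring what strict matching acts
#' on.
#'
#' @param states list of `fedseg_state`.
#' @return list with character vectors `matched`, `shape_excluded`,
#'   `name_excluded`.
#' @export
aggregation_report <- function(states) {
  shapes <- lapply(states, function(s) lapply(s$params, state_shape_of))
  all_names <- unique(unlist(lapply(shapes, names)))
  matched <- shape_excl <- name_excl <- character(0)
  for (nm in all_names) {
    holders <- which(vapply(shapes, function(sh) !is.null(sh[[nm]]), logical(1)))
    if (length(holders) < length(states)) {
      name_excl <- c(name_excl, nm)
    } else {
      shs <- lapply(holders, function(k) shapes[[k]][[nm]])
      if (all(vapply(shs, identical, logical(1), shs[[1]]))) {
        matched <- c(matched, nm)
      } else {
        shape_excl <- c(shape_excl, nm)
      }
    }
  }
  list(matched = matched, shape_excluded = shape_excl, name_excluded = name_excl)
}
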