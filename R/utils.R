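`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical JSON serialization
#'
#' Serializes an R list to JSON with sorted keys, full numeric precision and
#' unboxed scalars, so that equal objects produce byte-identical files. Used
#' for every exchanged artifact (fingerprints, plans, manifests, logs).
#'
#' @param x a list.
#' @return a JSON string (class `json`).
#' @keywords internal
canonical_json <- function(x) {
  sort_keys <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v)) && length(v)) v <- v[order(names(v))]
      lapply(v, sort_keys)
    } else v
  }
  jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA, null = "null")
}

#' MD5 checksum of an arbitrary R object
#'
#' Canonical serialization (version 2, little-endian) written to a temporary
#' file and hashed with [tools::md5sum()].
#'
#' @param x any R object.
#' @return a 32-character hex string.
#' @export
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2, xdr = FALSE)
  close(con)
  unname(tools::md5sum(f))
}

# Deterministic 31-bit substream seed derived from a base seed and a label.
# Every source of randomness in the package flows through this, so any
# component (one center's data, one client's init, one round's patches) is
# independently reproducible.
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, ""))
  h <- 0
  for (ch in utf8ToInt(paste(parts, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Per-axis lower median: for even counts, the lower of the two middle values.
# Keeps derived plans integer-stable across platforms.
median_low <- function(v) {
  s <- sort(v)
  s[ceiling(length(s) / 2)]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
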