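# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate binary configurations
#'
#' Canonical enumeration of all `2^m` binary configurations of `m` nodes.
#' Row `i` holds the bits of `i - 1` with node 1 as the least-significant
#' bit, so state indices are stable across every module that enumerates
#' configurations.
#'
#' @param m Number of binary nodes (non-negative integer).
#' @param ids Optional character vector of column names (length `m`).
#' @return A `2^m` by `m` integer matrix with entries in `{0, 1}`.
#' @export
#' @examples
#' enumerate_configurations(2)
enumerate_configurations <- function(m, ids = NULL) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0, m == round(m))
  if (m == 0L) {
    out <- matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    out <- as.matrix(expand.grid(rep(list(0:1), m), KEEP.OUT.ATTRS = FALSE))
    dimnames(out) <- NULL
    storage.mode(out) <- "integer"
  }
  if (!is.null(ids)) colnames(out) <- ids
  out
}

# index (1-based) of a 0/1 vector under the canonical enumeration
config_index <- function(x) {
  if (length(x) == 0L) return(1L)
  as.integer(sum(x * 2^(seq_along(x) - 1L))) + 1L
}

stop_dimension <- function(msg) stop(msg, call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
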