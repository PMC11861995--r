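# Internal helpers shared across modules.

# Deterministic fan-out of one global seed into per-experiment streams.
# Documented counter scheme: seed_k = (seed + 7919 * k) mod (2^31 - 1), kept
# strictly positive so set.seed() always accepts it.
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  ((as.double(seed) %% 2147483647) + 7919 * as.double(k)) %% 2147483647 + 1
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

check_square_symmetric_nonneg <- function(A, tol = 1e-8, context = "adjacency") {
  if (!is.matrix(A) || !is.numeric(A)) {
    stop(sprintf("%s must be a numeric matrix", context), call. = FALSE)
  }
  if (nrow(A) != ncol(A)) {
    stop(sprintf("%s must be square, got %d x %d", context, nrow(A), ncol(A)),
         call. = FALSE)
  }
  if (any(!is.finite(A))) {
    bad <- which(!is.finite(A), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s contains a non-finite value at [%d, %d]",
                 context, bad[1L], bad[2L]), call. = FALSE)
  }
  asym <- abs(A - t(A))
  if (any(asym > tol)) {
    bad <- which(asym > tol, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s is not symmetric: entry [%d, %d] = %g but [%d, %d] = %g",
                 context, bad[1L], bad[2L], A[bad[1L], bad[2L]],
                 bad[2L], bad[1L], A[bad[2L], bad[1L]]), call. = FALSE)
  }
  if (any(A < 0)) {
    bad <- which(A < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s has a negative entry at [%d, %d]: %g",
                 context, bad[1L], bad[2L], A[bad[1L], bad[2L]]), call. = FALSE)
  }
  invisible(TRUE)
}
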