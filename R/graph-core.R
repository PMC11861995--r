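#' Symmetric normalization of a connectome adjacency matrix
#'
#' Computes the propagation operator used by GCN message passing,
#' \deqn{A^* = \tilde{D}^{-1/2} (A + I) \tilde{D}^{-1/2}}
#' with self-loops (the default), or \eqn{D^{-1/2} A D^{-1/2}} without. With
#' self-loops the spectral radius of the result is bounded by 1, which keeps
#' repeated propagation numerically stable. Isolated nodes (zero degree when
#' self-loops are off) map to zero rows rather than dividing by zero.
#'
#' @param adjacency Square, symmetric, non-negative, finite numeric matrix.
#' @param add_self_loops Add the identity before normalizing (default `TRUE`).
#' @return A symmetric numeric matrix of the same dimension.
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
#' @export
normalize_adjacency <- function(adjacency, add_self_loops = TRUE) {
  check_square_symmetric_nonneg(adjacency)
  A <- if (add_self_loops) adjacency + diag(nrow(adjacency)) else adjacency
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  A * outer(dinv, dinv)
}

#' One graph-convolution layer
#'
#' The message-passing update
#' \deqn{H^{(l)} = \sigma(A^* H^{(l-1)} W + b),}
#' where \eqn{A^*} is a normalized adjacency ([normalize_adjacency()]),
#' \eqn{H^{(l-1)}} the incoming node-embedding matrix (initialized with the
#' node features), `W` a `d_in x d_out` weight matrix and `b` a length-`d_out`
#' bias broadcast across nodes. \eqn{H^{(l-1)} W} forms each node's outgoing
#' message; left-multiplying by \eqn{A^*} aggregates messages over weighted
#' neighborhoods.
#'
#' @param H_prev Node embeddings, `n x d_in`.
#' @param A_star Normalized adjacency, `n x n`.
#' @param W Weight matrix, `d_in x d_out`.
#' @param b Bias vector of length `d_out` (or a scalar, recycled).
#' @param activation `"relu"`, `"tanh"` or `"identity"`.
#' @return Node embedding matrix, `n x d_out`.
#' @export
gcn_layer <- function(H_prev, A_star, W, b = 0,
                      activation = c("relu", "tanh", "identity")) {
  activation <- match.arg(activation)
  H_prev <- as.matrix(H_prev); A_star <- as.matrix(A_star); W <- as.matrix(W)
  if (ncol(A_star) != nrow(H_prev)) {
    stop(sprintf("A_star is %dx%d but H_prev has %d rows",
                 nrow(A_star), ncol(A_star), nrow(H_prev)), call. = FALSE)
  }
  if (nrow(W) != ncol(H_prev)) {
    stop(sprintf("W has %d rows but H_prev has %d columns",
                 nrow(W), ncol(H_prev)), call. = FALSE)
  }
  if (any(!is.finite(W)) || any(!is.finite(b))) {
    stop("non-finite weights", call. = FALSE)
  }
  b <- rep_len(as.numeric(b), ncol(W))
  Z <- A_star %*% H_prev %*% W
  Z <- sweep(Z, 2, b, "+")
  activate(Z, activation)
}

activate <- function(Z, activation) {
  switch(activation,
         relu = pmax(Z, 0),
         tanh = tanh(Z),
         identity = Z)
}

#' Global pooling of node embeddings into a graph embedding vector
#'
#' Column-wise `mean` or `max` over nodes; both are invariant to any node
#' permutation, which is what makes the downstream classifier well-defined on
#' unordered region sets.
#'
#' @param H Node embedding matrix (`n x s`), non-empty.
#' @param kind `"mean"` or `"max"`.
#' @return Numeric vector of length `s`.
#' @export
global_pool <- function(H, kind = c("mean", "max")) {
  kind <- match.arg(kind)
  H <- as.matrix(H)
  if (nrow(H) == 0 || ncol(H) == 0) stop("empty embedding", call. = FALSE)
  switch(kind, mean = colMeans(H), max = apply(H, 2, max))
}

#' Per-layer graph summary used between residual GCN layers
#'
#' The residual architecture lets the node-level stream run through stacked
#' layers while each layer also emits one `s`-vector graph summary (the
#' per-column `mean` or `max` over nodes). The readout concatenates these
#' per-layer summaries via [concat_skip()]; removing skip connections keeps
#' only the final layer's summary.
#'
#' @inheritParams global_pool
#' @return Numeric vector of length `s` (the layer's graph summary row).
#' @export
node_aggregate <- function(H, kind = c("mean", "max")) {
  global_pool(H, kind)
}

#' Concatenate per-layer graph summaries into a readout vector
#'
#' @param parts Non-empty list of finite numeric vectors, in layer order.
#' @param use_skips If `FALSE`, only the final layer's part is returned
#'   (the skip-ablated readout).
#' @return Numeric vector; with skips, length is the sum of part lengths.
#' @export
concat_skip <- function(parts, use_skips = TRUE) {
  if (!is.list(parts) || length(parts) == 0) {
    stop("parts must be a non-empty list", call. = FALSE)
  }
  if (any(vapply(parts, function(p) any(!is.finite(p)), logical(1)))) {
    stop("non-finite embedding part", call. = FALSE)
  }
  if (!use_skips) return(as.numeric(parts[[length(parts)]]))
  as.numeric(unlist(parts, use.names = FALSE))
}
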