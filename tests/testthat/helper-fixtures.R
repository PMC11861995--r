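# Shared fixtures and independent oracles, built in code at test time.

random_symmetric_adjacency <- function(n, density = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(runif(n * n), n)
  if (density < 1) A[matrix(runif(n * n) > density, n)] <- 0
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

random_graph <- function(n, label = 0L, cohort = "adult", id = "s1",
                         seed = NULL) {
  A <- random_symmetric_adjacency(n, seed = seed)
  connectome_graph(A, label, cohort, id, node_features = A)
}

# Small two-cohort dataset with a planted effect, cheap enough for unit tests.
tiny_dataset <- function(n_regions = 12, n_adult = 24, n_pediatric = 16,
                         sex_effect_size = 1.2, seed = 5, ...) {
  generate_dataset(synthetic_config(
    n_regions = n_regions, n_adult = n_adult, n_pediatric = n_pediatric,
    sex_effect_size = sex_effect_size, seed = seed, ...))
}

tiny_train_config <- function(epochs = 10, seed = 3) {
  train_config(epochs = epochs, early_stopping_patience = epochs, seed = seed)
}

# Independent per-node message-passing oracle for one GCN layer: for each
# node v, sum over u of A*[v,u] * (H[u,] %*% W), add the bias, apply the
# activation. Deliberately loop-based, no matrix products over nodes.
gcn_layer_oracle <- function(H, A_star, W, b, activation) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(W))
  for (v in seq_len(n)) {
    acc <- rep(0, ncol(W))
    for (u in seq_len(n)) {
      acc <- acc + A_star[v, u] * drop(H[u, , drop = FALSE] %*% W)
    }
    acc <- acc + b
    out[v, ] <- switch(activation,
                       relu = pmax(acc, 0),
                       tanh = tanh(acc),
                       identity = acc)
  }
  out
}

# Brute-force AUC: enumerate every positive-negative pair, ties counted half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Brute-force parameter count: walk every trainable array.
count_parameters_bruteforce <- function(model) {
  total <- 0L
  rec <- function(t) {
    for (el in t) {
      if (is.list(el)) rec(el) else total <<- total + length(el)
    }
  }
  rec(model$params)
  total
}

# Simultaneous node permutation: A -> P A P^T, X -> P X (rows only; the
# feature coordinates themselves are not relabeled).
permute_graph <- function(graph, perm) {
  A <- graph$adjacency[perm, perm]
  X <- graph$node_features
  if (!is.null(X)) X <- X[perm, , drop = FALSE]
  connectome_graph(A, graph$label, graph$cohort, graph$subject_id,
                   node_features = X)
}
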