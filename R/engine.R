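# Internal neural-network engine.
#
# Both GCN architectures share one code path: L graph-convolution layers
# propagate the node stream H_0 = X, H_l = act(A* H_{l-1} W_l + b_l); each
# layer can emit a pooled graph summary (B x s); the readout is either the
# final summary (simple GCN, skip-ablated residual) or the concatenation of
# all per-layer summaries (residual with skips). Dropout acts on the readout
# vector; a linear head plus sigmoid gives the score. The MLP operates on the
# flattened adjacency with dropout after each hidden activation. Gradients are
# hand-derived; adjacency blocks are applied with the C++ kernel
# block_adj_multiply (A* is symmetric, so the same kernel serves forward and
# backward propagation).

# ---- parameter-tree helpers -------------------------------------------------

glorot_init <- function(d_in, d_out) {
  lim <- sqrt(6 / (d_in + d_out))
  matrix(runif(d_in * d_out, -lim, lim), d_in, d_out)
}

init_params <- function(spec) {
  if (spec$name %in% c("gcn_simple", "gcn_residual")) {
    d_prev <- spec$feature_dim
    layers <- lapply(spec$gcn_widths, function(w) {
      l <- list(W = glorot_init(d_prev, w), b = rep(0, w))
      d_prev <<- w
      l
    })
    k <- readout_width(spec)
    list(layers = layers, head = list(W = glorot_init(k, 1), b = 0))
  } else if (spec$name == "mlp") {
    d_prev <- spec$n_regions^2
    layers <- lapply(spec$mlp_widths, function(w) {
      l <- list(W = glorot_init(d_prev, w), b = rep(0, w))
      d_prev <<- w
      l
    })
    list(layers = layers, head = list(W = glorot_init(d_prev, 1), b = 0))
  } else {
    stop("no trainable parameters for model '", spec$name, "'", call. = FALSE)
  }
}

readout_width <- function(spec) {
  if (spec$name == "gcn_residual" && isTRUE(spec$use_skips)) {
    sum(spec$gcn_widths)
  } else {
    spec$gcn_widths[length(spec$gcn_widths)]
  }
}

# ---- batched pooling --------------------------------------------------------

# H: (B*n) x s stacked node embeddings; returns B x s summaries.
batch_pool <- function(H, n, B, kind) {
  if (kind == "mean") {
    g <- rowsum(H, rep(seq_len(B), each = n), reorder = FALSE) / n
    list(g = g, argmax = NULL)
  } else {
    s <- ncol(H)
    g <- matrix(0, B, s)
    argmax <- matrix(0L, B, s)
    for (j in seq_len(s)) {
      Mj <- matrix(H[, j], nrow = n)
      idx <- max.col(t(Mj), ties.method = "first")
      argmax[, j] <- idx
      g[, j] <- Mj[cbind(idx, seq_len(B))]
    }
    list(g = g, argmax = argmax)
  }
}

batch_unpool <- function(dg, n, B, kind, argmax = NULL) {
  s <- ncol(dg)
  if (kind == "mean") {
    dg[rep(seq_len(B), each = n), , drop = FALSE] / n
  } else {
    dH <- matrix(0, B * n, s)
    for (j in seq_len(s)) {
      rows <- (seq_len(B) - 1L) * n + argmax[, j]
      dH[cbind(rows, j)] <- dg[, j]
    }
    dH
  }
}

# ---- GCN forward / backward -------------------------------------------------

# A: cube of normalized adjacencies; idx: 1-based slice indices for the batch;
# X: stacked (B*n) x d node features for the batch.
gcn_forward <- function(params, A, idx, X, n, spec, training = FALSE) {
  B <- length(idx)
  L <- length(params$layers)
  act <- spec$activation
  pool_kind <- if (spec$name == "gcn_simple") spec$pooling else spec$aggregation
  readout_all <- spec$name == "gcn_residual" && isTRUE(spec$use_skips)

  H <- X
  Ps <- vector("list", L); Gs <- vector("list", L); Hs <- vector("list", L)
  pools <- vector("list", L)
  for (l in seq_len(L)) {
    P <- block_adj_multiply(A, H, idx)
    Z <- P %*% params$layers[[l]]$W
    Z <- Z + rep(params$layers[[l]]$b, each = nrow(Z))
    if (act == "relu") {
      Gs[[l]] <- (Z > 0)          # activation mask, reused by the backward pass
      H <- Z * Gs[[l]]
    } else {
      H <- activate(Z, act)
    }
    Ps[[l]] <- P; Hs[[l]] <- H
    if (readout_all || l == L) pools[[l]] <- batch_pool(H, n, B, pool_kind)
  }
  r <- if (readout_all) {
    do.call(cbind, lapply(pools, `[[`, "g"))
  } else {
    pools[[L]]$g
  }
  mask <- NULL
  r_drop <- r
  if (training && spec$dropout > 0) {
    mask <- matrix(rbinom(length(r), 1, 1 - spec$dropout), nrow(r)) /
      (1 - spec$dropout)
    r_drop <- r * mask
  }
  logit <- drop(r_drop %*% params$head$W) + params$head$b
  list(logit = logit, score = plogis(logit),
       cache = list(Ps = Ps, Gs = Gs, Hs = Hs, pools = pools, r_drop = r_drop,
                    mask = mask, X = X, n = n, B = B, L = L,
                    pool_kind = pool_kind, readout_all = readout_all))
}

gcn_backward <- function(params, A, idx, spec, cache, dlogit, need_dX = FALSE) {
  n <- cache$n; B <- cache$B; L <- cache$L
  act <- spec$activation
  widths <- vapply(params$layers, function(l) length(l$b), integer(1))

  dlogit <- matrix(dlogit, ncol = 1)
  grad <- list(layers = vector("list", L),
               head = list(W = crossprod(cache$r_drop, dlogit),
                           b = sum(dlogit)))
  dr <- tcrossprod(dlogit, params$head$W)
  if (!is.null(cache$mask)) dr <- dr * cache$mask

  # per-layer summary gradients
  ds <- vector("list", L)
  if (cache$readout_all) {
    off <- 0L
    for (l in seq_len(L)) {
      ds[[l]] <- dr[, off + seq_len(widths[l]), drop = FALSE]
      off <- off + widths[l]
    }
  } else {
    ds[[L]] <- dr
  }

  dH_chain <- NULL
  for (l in rev(seq_len(L))) {
    dH <- if (is.null(dH_chain)) {
      matrix(0, B * n, widths[l])
    } else {
      dH_chain
    }
    if (!is.null(ds[[l]])) {
      dH <- dH + batch_unpool(ds[[l]], n, B, cache$pool_kind,
                              cache$pools[[l]]$argmax)
    }
    dZ <- switch(act,
      relu = dH * cache$Gs[[l]],
      tanh = dH * (1 - cache$Hs[[l]]^2),
      identity = dH)
    grad$layers[[l]] <- list(W = crossprod(cache$Ps[[l]], dZ),
                             b = colSums(dZ))
    if (l > 1 || need_dX) {
      dP <- tcrossprod(dZ, params$layers[[l]]$W)
      dH_chain <- block_adj_multiply(A, dP, idx)
    } else {
      dH_chain <- NULL
    }
  }
  list(grad = grad, dX = if (need_dX) dH_chain else NULL)
}

# ---- MLP forward / backward -------------------------------------------------

# X: B x (n_regions^2) flattened adjacency rows.
mlp_forward <- function(params, X, spec, training = FALSE) {
  L <- length(params$layers)
  H <- X
  Zs <- vector("list", L); Hs <- vector("list", L); masks <- vector("list", L)
  inputs <- vector("list", L)
  for (l in seq_len(L)) {
    inputs[[l]] <- H
    Z <- H %*% params$layers[[l]]$W
    Z <- Z + rep(params$layers[[l]]$b, each = nrow(Z))
    H <- Z * (Z > 0)
    if (training && spec$dropout > 0) {
      m <- matrix(rbinom(length(H), 1, 1 - spec$dropout), nrow(H)) /
        (1 - spec$dropout)
      H <- H * m
      masks[[l]] <- m
    }
    Zs[[l]] <- Z; Hs[[l]] <- H
  }
  logit <- drop(H %*% params$head$W) + params$head$b
  list(logit = logit, score = plogis(logit),
       cache = list(Zs = Zs, Hs = Hs, masks = masks, inputs = inputs,
                    X = X, L = L, H_last = H))
}

mlp_backward <- function(params, spec, cache, dlogit, need_dX = FALSE) {
  L <- cache$L
  dlogit <- matrix(dlogit, ncol = 1)
  grad <- list(layers = vector("list", L),
               head = list(W = crossprod(cache$H_last, dlogit),
                           b = sum(dlogit)))
  dH <- tcrossprod(dlogit, params$head$W)
  for (l in rev(seq_len(L))) {
    if (!is.null(cache$masks[[l]])) dH <- dH * cache$masks[[l]]
    dZ <- dH * (cache$Zs[[l]] > 0)
    grad$layers[[l]] <- list(W = crossprod(cache$inputs[[l]], dZ),
                             b = colSums(dZ))
    if (l > 1 || need_dX) {
      dH <- tcrossprod(dZ, params$layers[[l]]$W)
    }
  }
  list(grad = grad, dX = if (need_dX) dH else NULL)
}

# ---- Adam -------------------------------------------------------------------

# Depth-first list of leaf arrays; params and grads share tree structure, so
# the traversal order matches.
flatten_leaves <- function(tree) {
  out <- list()
  rec <- function(t) {
    for (el in t) {
      if (is.list(el)) rec(el) else out[[length(out) + 1L]] <<- el
    }
  }
  rec(tree)
  out
}

tree_deep_copy <- function(tree) unserialize(serialize(tree, NULL))

# Mutable Adam state over a parameter tree. The tree is deep-copied first so
# the in-place C++ update cannot touch shared or constant-pool memory; the
# flat views alias the copied tree's leaves, so updating them updates the
# tree used by the forward pass.
adam_init <- function(params) {
  params <- tree_deep_copy(params)
  flat <- flatten_leaves(params)
  list(params = params, flat = flat,
       m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0L)
}

adam_step <- function(state, grad, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  adam_update_inplace(state$flat, flatten_leaves(grad), state$m, state$v,
                      lr, weight_decay, state$t, beta1, beta2, eps)
  state
}

# ---- batch assembly ---------------------------------------------------------

# Normalized adjacency cube + stacked features for a set of graphs.
prepare_gcn_inputs <- function(graphs, spec) {
  n <- spec$n_regions
  B <- length(graphs)
  A <- array(0, dim = c(n, n, B))
  X <- matrix(0, B * n, spec$feature_dim)
  for (g in seq_len(B)) {
    gr <- graphs[[g]]
    if (nrow(gr$adjacency) != n) {
      stop(sprintf("graph %s has %d regions; model expects %d",
                   gr$subject_id, nrow(gr$adjacency), n), call. = FALSE)
    }
    A[, , g] <- normalize_adjacency(gr$adjacency)
    feats <- gr$node_features %||% gr$adjacency
    if (ncol(feats) != spec$feature_dim) {
      stop(sprintf("graph %s has feature dim %d; model expects %d",
                   gr$subject_id, ncol(feats), spec$feature_dim), call. = FALSE)
    }
    X[(g - 1L) * n + seq_len(n), ] <- feats
  }
  list(A = A, X = X, n = n, B = B,
       y = vapply(graphs, `[[`, integer(1), "label"))
}

flatten_adjacency <- function(graphs, n) {
  t(vapply(graphs, function(g) {
    if (nrow(g$adjacency) != n) {
      stop(sprintf("graph %s has %d regions; model expects %d",
                   g$subject_id, nrow(g$adjacency), n), call. = FALSE)
    }
    as.numeric(g$adjacency)
  }, numeric(n * n)))
}
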