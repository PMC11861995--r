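#' Declare a classifier architecture
#'
#' Declarative description of one of the five classifiers studied:
#' * `gcn_simple` — GCN layers (default two, 64 units, ReLU) propagating
#'   through the normalized adjacency, mean (or max) global pooling, dropout,
#'   linear head with sigmoid.
#' * `gcn_residual` — GCN layers (default three, 32 units, tanh); each layer
#'   emits a pooled graph summary (mean or max aggregation) and the readout
#'   concatenates the per-layer summaries via skip connections (or keeps only
#'   the final summary when `use_skips = FALSE`), then dropout, linear head,
#'   sigmoid.
#' * `mlp` — the flattened full adjacency (`n_regions^2` inputs) through
#'   hidden layers of 512, 256 and 128 ReLU units with dropout, linear head,
#'   sigmoid.
#' * `rf` / `svm` — flattened adjacency reduced to `pca_components` principal
#'   components (PCA fit on the training fold only), then a 100-tree random
#'   forest or an RBF-kernel support vector machine with Platt-calibrated
#'   probabilities.
#'
#' @param name One of `"gcn_simple"`, `"gcn_residual"`, `"mlp"`, `"rf"`,
#'   `"svm"`.
#' @param n_regions Number of graph nodes the model expects.
#' @param feature_dim Node feature dimension (defaults to `n_regions`, the
#'   connectivity-profile feature scheme).
#' @param gcn_widths Units per GCN layer; defaults `c(64, 64)` for the simple
#'   model and `c(32, 32, 32)` for the residual model.
#' @param activation GCN activation; defaults `"relu"` (simple) / `"tanh"`
#'   (residual).
#' @param pooling Global pooling for the simple GCN: `"mean"` or `"max"`.
#' @param aggregation Per-layer summary statistic for the residual GCN.
#' @param use_skips Keep the residual skip connections (default `TRUE`).
#' @param mlp_widths Hidden-layer widths of the MLP.
#' @param dropout Dropout probability on readout/hidden units (training only).
#' @param pca_components PCA dimension for the shallow baselines.
#' @param rf_estimators Number of random-forest trees.
#' @param svm_kernel Fixed to `"radial"` (RBF).
#' @return An object of class `braingcn_spec`.
#' @export
model_spec <- function(name = c("gcn_simple", "gcn_residual", "mlp", "rf", "svm"),
                       n_regions,
                       feature_dim = NULL,
                       gcn_widths = NULL,
                       activation = NULL,
                       pooling = c("mean", "max"),
                       aggregation = c("mean", "max"),
                       use_skips = TRUE,
                       mlp_widths = c(512, 256, 128),
                       dropout = 0.5,
                       pca_components = 100,
                       rf_estimators = 100,
                       svm_kernel = "radial") {
  name <- match.arg(name)
  pooling <- match.arg(pooling)
  aggregation <- match.arg(aggregation)
  assert_scalar_number(n_regions, "n_regions", lower = 2)
  assert_scalar_number(dropout, "dropout", 0, 1 - 1e-12)
  if (is.null(gcn_widths)) {
    gcn_widths <- if (name == "gcn_residual") c(32, 32, 32) else c(64, 64)
  }
  if (any(gcn_widths <= 0) || (length(mlp_widths) && any(mlp_widths <= 0))) {
    stop("layer widths must be positive", call. = FALSE)
  }
  if (is.null(activation)) {
    activation <- if (name == "gcn_residual") "tanh" else "relu"
  }
  activation <- match.arg(activation, c("relu", "tanh", "identity"))
  feature_dim <- as.integer(feature_dim %||% n_regions)
  if (feature_dim < 1) stop("feature_dim must be positive", call. = FALSE)
  if (svm_kernel != "radial") stop("svm_kernel is fixed to 'radial'", call. = FALSE)
  structure(list(
    name = name, n_regions = as.integer(n_regions), feature_dim = feature_dim,
    gcn_widths = as.integer(gcn_widths), activation = activation,
    pooling = pooling, aggregation = aggregation, use_skips = isTRUE(use_skips),
    mlp_widths = as.integer(mlp_widths), dropout = dropout,
    pca_components = as.integer(pca_components),
    rf_estimators = as.integer(rf_estimators), svm_kernel = svm_kernel
  ), class = "braingcn_spec")
}

#' @export
print.braingcn_spec <- function(x, ...) {
  cat(sprintf("<braingcn_spec> %s (%d regions)\n", x$name, x$n_regions))
  invisible(x)
}

is_deep <- function(spec) spec$name %in% c("gcn_simple", "gcn_residual", "mlp")

#' Build a classifier from its spec
#'
#' For the deep models this initializes trainable weights (Glorot-uniform,
#' seeded, with the seed recorded on the object); the shallow baselines return
#' an unfitted container that [train_model()] fits fold by fold.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `braingcn_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "braingcn_spec"))
  params <- NULL
  if (is_deep(spec)) {
    set.seed(derive_seed(seed, 0))
    params <- init_params(spec)
  }
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 class_weights = c(1, 1), learner = NULL, pca = NULL),
            class = "braingcn_model")
}

#' @export
print.braingcn_model <- function(x, ...) {
  cat(sprintf("<braingcn_model> %s (%d regions)%s\n", x$spec$name,
              x$spec$n_regions,
              if (is_deep(x$spec))
                sprintf(", %s parameters", format(count_parameters(x), big.mark = ","))
              else if (is.null(x$learner)) " [unfitted]" else " [fitted]"))
  invisible(x)
}

#' Count trainable parameters
#'
#' For a built model, enumerates every trainable array and sums element
#' counts; for a bare [model_spec()], computes the same count analytically
#' from the layer dimensions (useful for large architectures without
#' allocating their weights). The default 379-region MLP
#' (379^2 -> 512 -> 256 -> 128 -> 1, biases included) has 73,709,057
#' parameters, i.e. 7.37e7 to three significant figures.
#'
#' @param model A `braingcn_model` (deep) or `braingcn_spec`.
#' @return Integer-valued count of trainable scalars.
#' @export
count_parameters <- function(model) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.braingcn_model <- function(model) {
  if (is.null(model$params)) {
    stop("model '", model$spec$name, "' has no trainable scalar parameters",
         call. = FALSE)
  }
  leaves <- rapply(model$params, length, how = "unlist")
  sum(leaves)
}

#' @export
count_parameters.braingcn_fit <- function(model) {
  count_parameters.braingcn_model(model)
}

#' @export
count_parameters.braingcn_spec <- function(model) {
  spec <- model
  if (spec$name %in% c("gcn_simple", "gcn_residual")) {
    dims <- c(spec$feature_dim, spec$gcn_widths)
    n_layer <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
    n_layer + readout_width(spec) * 1 + 1
  } else if (spec$name == "mlp") {
    dims <- c(spec$n_regions^2, spec$mlp_widths, 1)
    sum(dims[-length(dims)] * dims[-1] + dims[-1])
  } else {
    stop("model '", spec$name, "' has no trainable scalar parameters",
         call. = FALSE)
  }
}

# Internal: probability scores for a list of graphs.
# features: optional list of per-subject feature matrices overriding the
# graphs' node features (GCN) or flattened input (MLP); the adjacency used for
# propagation is always the clean one.
predict_scores <- function(object, graphs, features = NULL) {
  spec <- object$spec
  if (inherits(graphs, "connectome_graph")) graphs <- list(graphs)
  if (spec$name %in% c("gcn_simple", "gcn_residual")) {
    inp <- prepare_gcn_inputs(graphs, spec)
    X <- inp$X
    if (!is.null(features)) {
      X <- do.call(rbind, features)
      stopifnot(nrow(X) == inp$B * inp$n)
    }
    fw <- gcn_forward(object$params, inp$A, seq_len(inp$B), X, inp$n, spec,
                      training = FALSE)
    fw$score
  } else if (spec$name == "mlp") {
    X <- if (!is.null(features)) {
      t(vapply(features, as.numeric, numeric(spec$n_regions^2)))
    } else {
      flatten_adjacency(graphs, spec$n_regions)
    }
    mlp_forward(object$params, X, spec, training = FALSE)$score
  } else {
    if (is.null(object$learner)) {
      stop("shallow model must be trained before prediction", call. = FALSE)
    }
    X <- flatten_adjacency(graphs, spec$n_regions)
    Z <- sweep(X, 2, object$pca$center, "-") %*% object$pca$rotation
    if (spec$name == "rf") {
      unname(stats::predict(object$learner, Z, type = "prob")[, "1"])
    } else {
      dv <- as.numeric(attr(stats::predict(object$learner, Z,
                                           decision.values = TRUE),
                            "decision.values"))
      unname(stats::predict(object$platt, data.frame(dv = dv),
                            type = "response"))
    }
  }
}

#' Predict sex labels for connectome graphs
#'
#' Deterministic inference (dropout disabled). Scores are probabilities of the
#' female label (coded 1); `label_hat = 1` when `score >= 0.5`.
#'
#' @param object A built or trained model.
#' @param newdata A `connectome_graph`, `connectome_dataset`, or list of
#'   graphs.
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `score`, `label_hat`.
#' @export
predict.braingcn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "connectome_graph")) newdata <- list(newdata)
  scores <- predict_scores(object, newdata)
  tibble::tibble(
    subject_id = vapply(newdata, `[[`, character(1), "subject_id"),
    score = as.numeric(scores),
    label_hat = as.integer(scores >= 0.5)
  )
}

#' @export
predict.braingcn_fit <- predict.braingcn_model

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file container holding the spec, seed and weight
#' arrays (or fitted shallow learner); loading restores bit-identical
#' predictions.
#'
#' @param model A `braingcn_model` or `braingcn_fit`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("braingcn_model", "braingcn_fit")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, c("braingcn_model", "braingcn_fit")))
  model
}
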