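#' Training hyperparameters
#'
#' Defaults follow the study protocol for the deep models: Adam with learning
#' rate 1e-3 for up to 100 epochs, weighted binary cross-entropy loss, weight
#' decay 5e-4, dropout 0.5 and early stopping on validation loss with a
#' patience of 35 epochs. Batch size 16 is the package's choice for these
#' small cohorts. Shallow models (RF/SVM) ignore everything except `seed`.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param weight_decay L2 penalty added to gradients.
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping (best-epoch weights are restored).
#' @param dropout Dropout probability used during training.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 100,
                         weight_decay = 5e-4, early_stopping_patience = 35,
                         dropout = 0.5, batch_size = 16, seed = 1L) {
  assert_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  assert_scalar_number(epochs, "epochs", lower = 1)
  assert_scalar_number(weight_decay, "weight_decay", lower = 0)
  assert_scalar_number(early_stopping_patience, "early_stopping_patience", 1)
  assert_scalar_number(dropout, "dropout", 0, 1 - 1e-12)
  assert_scalar_number(batch_size, "batch_size", lower = 1)
  if (early_stopping_patience > epochs) {
    stop("early_stopping_patience must be <= epochs", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 weight_decay = weight_decay,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Weighted binary cross-entropy
#'
#' \deqn{-\frac{1}{N}\sum_i w_{y_i}\,[\,y_i \log s_i + (1-y_i)\log(1-s_i)\,]}
#' with scores clamped to `[1e-12, 1 - 1e-12]`. During training the default
#' class weights are the inverse class frequencies of the training split,
#' normalized so the two weights average to 1 (see [class_weights_for()]).
#'
#' @param scores Predicted probabilities of label 1.
#' @param labels Binary labels (0/1).
#' @param class_weights Positive weights `c(w0, w1)` for labels 0 and 1.
#' @return Non-negative scalar loss.
#' @export
weighted_bce <- function(scores, labels, class_weights = c(1, 1)) {
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  if (length(class_weights) != 2 || any(class_weights <= 0)) {
    stop("class_weights must be two positive reals", call. = FALSE)
  }
  s <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  w <- class_weights[labels + 1]
  -mean(w * (labels * log(s) + (1 - labels) * log(1 - s)))
}

#' Inverse-frequency class weights
#'
#' Weights proportional to `1 / p_c`, normalized so `(w0 + w1) / 2 = 1`. Falls
#' back to `c(1, 1)` (with a warning) when a class is absent.
#'
#' @param labels Binary training labels.
#' @return Numeric vector `c(w0, w1)`.
#' @export
class_weights_for <- function(labels) {
  p1 <- mean(labels == 1)
  if (p1 == 0 || p1 == 1) {
    warning("training split contains a single class; using unit weights")
    return(c(1, 1))
  }
  w <- c(1 / (1 - p1), 1 / p1)
  w * 2 / sum(w)
}

#' Stratified five-fold split plan
#'
#' Builds five cross-validation folds whose 20% test sets partition the
#' dataset, stratified jointly by sex label and cohort (so in the enriched
#' regime the adult:pediatric ratio is held constant across sets to within one
#' subject per stratum). For deep models the remaining 80% is re-split 7:1
#' into training and validation (70/10/20 overall); shallow models use the
#' full 80% for training (80/20).
#'
#' @param dataset A `connectome_dataset` or list of `connectome_graph`s.
#' @param mode `"single_cohort"` or `"enriched"` (both cohorts pooled).
#' @param model_family `"deep"` (train/val/test) or `"shallow"` (train/test).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param n_folds Number of folds (default 5).
#' @return An object of class `split_plan`.
#' @export
make_splits <- function(dataset, mode = c("single_cohort", "enriched"),
                        model_family = c("deep", "shallow"), seed = 1L,
                        n_folds = 5L) {
  mode <- match.arg(mode)
  model_family <- match.arg(model_family)
  N <- length(dataset)
  if (N == 0) stop("dataset is empty", call. = FALSE)
  labels <- vapply(dataset, `[[`, integer(1), "label")
  cohorts <- vapply(dataset, `[[`, character(1), "cohort")
  if (mode == "enriched" && length(unique(cohorts)) < 2) {
    stop("enriched mode requires both cohorts", call. = FALSE)
  }
  strata <- paste(labels, cohorts, sep = ".")
  test_fold <- integer(N)
  set.seed(derive_seed(seed, 1))
  # Round-robin within each stratum, with a running offset across strata so
  # the leftover subjects of successive strata land on different folds: fold
  # sizes are then balanced to +-1 both per stratum and overall.
  offset <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < n_folds) {
      warning(sprintf("stratum '%s' has %d subjects (< %d folds); best-effort assignment",
                      s, length(idx), n_folds))
    }
    idx <- idx[sample.int(length(idx))]
    test_fold[idx] <- (seq_along(idx) - 1L + offset) %% n_folds + 1L
    offset <- offset + length(idx)
  }
  val_sets <- vector("list", n_folds)
  if (model_family == "deep") {
    for (f in seq_len(n_folds)) {
      set.seed(derive_seed(seed, 100 + f))
      pool <- which(test_fold != f)
      vs <- integer(0)
      for (s in unique(strata[pool])) {
        idx <- pool[strata[pool] == s]
        n_val <- round(length(idx) / 8)
        if (n_val > 0) vs <- c(vs, idx[sample.int(length(idx), n_val)])
      }
      val_sets[[f]] <- sort(vs)
    }
  } else {
    val_sets <- replicate(n_folds, integer(0), simplify = FALSE)
  }
  structure(list(
    n_folds = as.integer(n_folds), mode = mode, model_family = model_family,
    seed = as.integer(seed),
    assignments = tibble::tibble(
      index = seq_len(N),
      subject_id = vapply(dataset, `[[`, character(1), "subject_id"),
      label = labels, cohort = cohorts, test_fold = test_fold),
    val_sets = val_sets
  ), class = "split_plan")
}

#' Fold membership helpers
#'
#' @param plan A [make_splits()] plan.
#' @param fold Fold index in `1:n_folds`.
#' @return Integer indices into the dataset.
#' @export
test_indices <- function(plan, fold) {
  which(plan$assignments$test_fold == fold)
}

#' @rdname test_indices
#' @export
val_indices <- function(plan, fold) plan$val_sets[[fold]]

#' @rdname test_indices
#' @export
train_indices <- function(plan, fold) {
  setdiff(which(plan$assignments$test_fold != fold), plan$val_sets[[fold]])
}

# Early-stopping state machine: strict improvement resets the wait counter;
# training stops once `wait` reaches `patience`.
es_init <- function(patience) {
  list(best = Inf, best_epoch = 0L, wait = 0L, patience = patience,
       stop = FALSE, improved = FALSE)
}

es_update <- function(es, epoch, loss) {
  if (loss < es$best) {
    es$best <- loss; es$best_epoch <- epoch; es$wait <- 0L; es$improved <- TRUE
  } else {
    es$wait <- es$wait + 1L; es$improved <- FALSE
    if (es$wait >= es$patience) es$stop <- TRUE
  }
  es
}

# Pure replay of the monitor over a loss sequence (used by tests).
early_stop_trace <- function(val_losses, patience) {
  es <- es_init(patience)
  stop_epoch <- length(val_losses)
  for (e in seq_along(val_losses)) {
    es <- es_update(es, e, val_losses[e])
    if (es$stop) { stop_epoch <- e; break }
  }
  list(best_epoch = es$best_epoch, stop_epoch = stop_epoch)
}

#' Train one model on one cross-validation fold
#'
#' Deep models are trained with Adam on the weighted binary cross-entropy,
#' with weight decay, dropout and early stopping on validation loss (patience
#' `config$early_stopping_patience`; the best-validation-epoch weights are
#' restored). Shallow models ignore the optimizer settings and fit once on the
#' fold's training split, with PCA fit inside the fold (training data only).
#'
#' @param spec A [model_spec()].
#' @param dataset The dataset the plan indexes into.
#' @param plan A [make_splits()] plan matching the model family.
#' @param fold Fold index.
#' @param config A [train_config()].
#' @param seed Optional override of the derived per-fold seed.
#' @return A `braingcn_fit` with the trained parameters and per-epoch loss
#'   curves (`$history`).
#' @export
train_model <- function(spec, dataset, plan, fold, config = train_config(),
                        seed = NULL) {
  stopifnot(inherits(spec, "braingcn_spec"), inherits(plan, "split_plan"))
  if (fold < 1 || fold > plan$n_folds) stop("invalid fold index", call. = FALSE)
  seed <- seed %||% derive_seed(config$seed, fold)
  tr <- train_indices(plan, fold)
  y_tr <- plan$assignments$label[tr]
  cw <- class_weights_for(y_tr)
  if (is_deep(spec)) {
    train_deep(spec, dataset, tr, val_indices(plan, fold), cw, config, seed,
               fold)
  } else {
    train_shallow(spec, dataset, tr, cw, seed, fold)
  }
}

train_deep <- function(spec, dataset, tr, va, cw, config, seed, fold) {
  set.seed(seed)
  spec_train <- spec
  spec_train$dropout <- config$dropout
  state <- adam_init(init_params(spec))
  params <- state$params  # mutated in place by adam_step
  is_gcn <- spec$name %in% c("gcn_simple", "gcn_residual")

  tr_graphs <- dataset[tr]
  va_graphs <- dataset[va]
  y <- vapply(tr_graphs, `[[`, integer(1), "label")
  y_va <- vapply(va_graphs, `[[`, integer(1), "label")
  if (is_gcn) {
    inp <- prepare_gcn_inputs(tr_graphs, spec)
    inp_va <- if (length(va)) prepare_gcn_inputs(va_graphs, spec) else NULL
    n <- inp$n
  } else {
    Xtr <- flatten_adjacency(tr_graphs, spec$n_regions)
    Xva <- if (length(va)) flatten_adjacency(va_graphs, spec$n_regions) else NULL
  }
  B <- length(tr)

  forward_set <- function(p, training, idx = seq_len(B)) {
    if (is_gcn) {
      rows <- as.vector(outer(seq_len(n), (idx - 1L) * n, "+"))
      gcn_forward(p, inp$A, idx, inp$X[rows, , drop = FALSE], n, spec_train,
                  training = training)
    } else {
      mlp_forward(p, Xtr[idx, , drop = FALSE], spec_train, training = training)
    }
  }
  val_loss_fn <- function(p) {
    if (length(va) == 0) return(NA_real_)
    s <- if (is_gcn) {
      gcn_forward(p, inp_va$A, seq_along(va), inp_va$X, n, spec,
                  training = FALSE)$score
    } else {
      mlp_forward(p, Xva, spec, training = FALSE)$score
    }
    weighted_bce(s, y_va, cw)
  }

  es <- es_init(config$early_stopping_patience)
  best_params <- tree_deep_copy(params)
  tr_loss_hist <- val_loss_hist <- numeric(0)
  monitor_val <- length(va) > 0
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(B)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      fw <- forward_set(params, training = TRUE, idx = bt)
      yb <- y[bt]
      loss <- weighted_bce(fw$score, yb, cw)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d (model %s, fold %d)",
                     epoch, spec$name, fold), call. = FALSE)
      }
      dlogit <- cw[yb + 1] * (fw$score - yb) / length(bt)
      bw <- if (is_gcn) {
        gcn_backward(params, inp$A, bt, spec_train, fw$cache, dlogit)
      } else {
        mlp_backward(params, spec_train, fw$cache, dlogit)
      }
      state <- adam_step(state, bw$grad, config$learning_rate,
                         config$weight_decay)
      ep_loss <- ep_loss + loss * length(bt)
    }
    vl <- val_loss_fn(params)
    monitored <- if (monitor_val) vl else ep_loss / B
    tr_loss_hist[epoch] <- ep_loss / B
    val_loss_hist[epoch] <- vl
    es <- es_update(es, epoch, monitored)
    if (es$improved) best_params <- tree_deep_copy(params)
    if (es$stop) break
  }
  structure(list(spec = spec, params = best_params, class_weights = cw,
                 seed = seed, fold = fold, best_epoch = es$best_epoch,
                 history = tibble::tibble(epoch = seq_along(tr_loss_hist),
                                          train_loss = tr_loss_hist,
                                          val_loss = val_loss_hist),
                 learner = NULL, pca = NULL),
            class = c("braingcn_fit", "braingcn_model"))
}

train_shallow <- function(spec, dataset, tr, cw, seed, fold) {
  set.seed(seed)
  X <- flatten_adjacency(dataset[tr], spec$n_regions)
  y <- factor(vapply(dataset[tr], `[[`, integer(1), "label"), levels = c(0, 1))
  k <- min(spec$pca_components, ncol(X), nrow(X) - 1L)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  pca <- list(center = pc$center, rotation = pc$rotation)
  Z <- pc$x
  platt <- NULL
  learner <- if (spec$name == "rf") {
    randomForest::randomForest(x = Z, y = y, ntree = spec$rf_estimators,
                               classwt = c("0" = cw[1], "1" = cw[2]))
  } else {
    sv <- e1071::svm(x = Z, y = y, kernel = spec$svm_kernel,
                     class.weights = c("0" = cw[1], "1" = cw[2]))
    # Platt-style score calibration fit on the training fold's decision values
    dv <- as.numeric(attr(stats::predict(sv, Z, decision.values = TRUE),
                          "decision.values"))
    platt <- suppressWarnings(
      stats::glm(I(y == "1") ~ dv, family = stats::binomial()))
    sv
  }
  structure(list(spec = spec, params = NULL, class_weights = cw, seed = seed,
                 fold = fold, best_epoch = NA_integer_, history = NULL,
                 learner = learner, pca = pca, platt = platt),
            class = c("braingcn_fit", "braingcn_model"))
}
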