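#' FGSM attack configuration
#'
#' Perturbation sizes default to a geometric grid spanning 1e-5 to 1e-3 (the
#' studied range) plus 0, which anchors the sweep at the clean evaluation.
#'
#' @param epsilons Ordered non-negative perturbation sizes.
#' @param target_stratum Cohort whose test subjects are attacked.
#' @param clip_nonnegative Clip perturbed features at 0 (off by default: the
#'   single-step attack contains no projection, and at these epsilons any
#'   violations are negligible).
#' @param resymmetrize Re-symmetrize perturbed feature matrices (off by
#'   default, for the same reason).
#' @param seed Integer seed (the attack itself is deterministic; the seed is
#'   recorded for provenance).
#' @return An object of class `attack_config`.
#' @export
attack_config <- function(epsilons = c(0, 1e-5, 10^-4.5, 1e-4, 10^-3.5, 1e-3),
                          target_stratum = c("pediatric", "adult"),
                          clip_nonnegative = FALSE, resymmetrize = FALSE,
                          seed = 1L) {
  target_stratum <- match.arg(target_stratum)
  if (any(epsilons < 0) || is.unsorted(epsilons)) {
    stop("epsilons must be non-negative and sorted ascending", call. = FALSE)
  }
  structure(list(epsilons = as.numeric(epsilons),
                 target_stratum = target_stratum,
                 clip_nonnegative = isTRUE(clip_nonnegative),
                 resymmetrize = isTRUE(resymmetrize),
                 seed = as.integer(seed)),
            class = "attack_config")
}

# Gradient of the training loss w.r.t. the input feature matrix, evaluated at
# the true label with the fit's own class weights (white-box access).
input_gradient <- function(fit, graph) {
  spec <- fit$spec
  if (!is_deep(spec)) {
    stop("FGSM requires end-to-end gradients; model '", spec$name,
         "' has none", call. = FALSE)
  }
  y <- graph$label
  w <- fit$class_weights[y + 1]
  if (spec$name == "mlp") {
    X <- matrix(as.numeric(graph$adjacency), nrow = 1)
    fw <- mlp_forward(fit$params, X, spec, training = FALSE)
    dlogit <- w * (fw$score - y)
    bw <- mlp_backward(fit$params, spec, fw$cache, dlogit, need_dX = TRUE)
    matrix(bw$dX, spec$n_regions, spec$n_regions)
  } else {
    inp <- prepare_gcn_inputs(list(graph), spec)
    fw <- gcn_forward(fit$params, inp$A, 1L, inp$X, inp$n, spec,
                      training = FALSE)
    dlogit <- w * (fw$score - y)
    bw <- gcn_backward(fit$params, inp$A, 1L, spec, fw$cache, dlogit,
                       need_dX = TRUE)
    bw$dX
  }
}

#' Fast gradient sign method perturbation of one subject
#'
#' The single-step white-box attack
#' \deqn{X^{adv} = X + \epsilon \cdot \mathrm{sign}(\nabla_X L(\theta, X, y)),}
#' where `L` is the same weighted binary cross-entropy used in training,
#' evaluated at the subject's true label (untargeted, loss-ascending form),
#' and `sign(0) = 0`. Only the node feature matrix is perturbed; the
#' adjacency used for graph propagation stays clean even when the features
#' were derived from it.
#'
#' @param fit A trained deep model (`braingcn_fit`); RF/SVM have no gradients
#'   and are rejected.
#' @param graph A `connectome_graph` with its true label.
#' @param epsilon Non-negative perturbation size.
#' @param config Optional [attack_config()] controlling clipping /
#'   re-symmetrization of the perturbed matrix.
#' @return The perturbed node feature matrix (for the MLP, the perturbed
#'   `n_regions x n_regions` input matrix).
#' @export
fgsm_perturb <- function(fit, graph, epsilon, config = NULL) {
  assert_scalar_number(epsilon, "epsilon", lower = 0)
  X <- if (fit$spec$name == "mlp") {
    graph$adjacency
  } else {
    graph$node_features %||% graph$adjacency
  }
  X_adv <- X + epsilon * sign(input_gradient(fit, graph))
  if (!is.null(config)) {
    if (config$clip_nonnegative) X_adv[X_adv < 0] <- 0
    if (config$resymmetrize) X_adv <- (X_adv + t(X_adv)) / 2
  }
  X_adv
}

#' Epsilon-sweep adversarial robustness protocol
#'
#' White-box FGSM sweep over the enriched-regime fold models: for every
#' epsilon and fold, each test subject of the target stratum is perturbed
#' with that fold's own model and re-evaluated on the same model. The
#' epsilon = 0 row reproduces the clean evaluation exactly.
#'
#' @param report A `braingcn_eval` from
#'   `run_regime("enriched", ..., return_fits = TRUE)`.
#' @param dataset The dataset the regime was run on.
#' @param config An [attack_config()].
#' @param models Which deep models in the report to attack (default: all).
#' @return A `braingcn_attack` tibble with one row per model, epsilon, fold
#'   (columns `n`, `accuracy`, `auc`).
#' @export
robustness_sweep <- function(report, dataset, config = attack_config(),
                             models = NULL) {
  fits <- attr(report, "fits")
  if (is.null(fits)) {
    stop("run the regime with return_fits = TRUE to keep fold models",
         call. = FALSE)
  }
  plans <- attr(report, "plans")
  cohorts <- vapply(dataset, `[[`, character(1), "cohort")
  rows <- list()
  for (name in names(fits)) {
    if (!is.null(models) && !name %in% models) next
    if (!fits[[name]][[1]]$spec$name %in% c("gcn_simple", "gcn_residual", "mlp")) next
    plan <- if (is_deep(fits[[name]][[1]]$spec)) plans$deep else plans$shallow
    for (fold in seq_along(fits[[name]])) {
      fit <- fits[[name]][[fold]]
      te <- test_indices(plan, fold)
      te <- te[cohorts[te] == config$target_stratum]
      if (length(te) == 0) {
        stop("target stratum '", config$target_stratum,
             "' is empty in fold ", fold, call. = FALSE)
      }
      graphs <- dataset[te]
      labels <- vapply(graphs, `[[`, integer(1), "label")
      for (eps in config$epsilons) {
        feats <- lapply(graphs, function(g) fgsm_perturb(fit, g, eps, config))
        sc <- predict_scores(fit, graphs, features = feats)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = name, epsilon = eps, fold = fold,
          stratum = config$target_stratum, n = length(te),
          accuracy = 100 * mean((sc >= 0.5) == (labels == 1)),
          auc = auc_score(sc, labels))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("braingcn_attack", class(out)),
            config = config, regime = attr(report, "regime"))
}

#' @export
glance.braingcn_attack <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$model, .data$epsilon) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = sd(.data$accuracy),
                     mean_auc = mean(.data$auc, na.rm = TRUE),
                     sd_auc = sd(.data$auc, na.rm = TRUE),
                     .groups = "drop")
}

#' Plot accuracy against perturbation size
#'
#' @param object A `braingcn_attack`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.braingcn_attack <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$epsilon, y = .data$mean_accuracy,
                                  colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy,
                   fill = .data$model), alpha = 0.15, colour = NA) +
    ggplot2::labs(x = "epsilon", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
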