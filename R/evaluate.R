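#' Area under the ROC curve (rank statistic)
#'
#' Probability that a uniformly random positive outscores a uniformly random
#' negative, with ties counted half — computed from the Wilcoxon rank sum.
#' Returns `NA` (undefined) when either class is absent.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`, or `NA` if undefined.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve as a step path
#'
#' @inheritParams auc_score
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, a monotone step path
#'   from (0, 0) to (1, 1); tied scores are grouped into one step.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, if (n0 > 0) fp / n0 else fp * 0),
    tpr = c(0, if (n1 > 0) tp / n1 else tp * 0)
  )
}

# Metrics for one set of graphs, overall and stratified by cohort.
evaluate_graphs <- function(fit, graphs, fold,
                            strata = c("overall", "adult", "pediatric")) {
  scores <- predict_scores(fit, graphs)
  labels <- vapply(graphs, `[[`, integer(1), "label")
  cohorts <- vapply(graphs, `[[`, character(1), "cohort")
  rows <- lapply(strata, function(st) {
    sel <- if (st == "overall") rep(TRUE, length(graphs)) else cohorts == st
    if (!any(sel)) return(NULL)
    sc <- scores[sel]; lb <- labels[sel]
    auc <- auc_score(sc, lb)
    tibble::tibble(
      model = fit$spec$name, fold = fold, stratum = st, n = sum(sel),
      accuracy = 100 * mean((sc >= 0.5) == (lb == 1)),
      auc = auc, auc_defined = !is.na(auc),
      roc = list(roc_curve(sc, lb))
    )
  })
  dplyr::bind_rows(rows)
}

#' Evaluate a trained fold model on its test set
#'
#' Accuracy (percent, threshold 0.5) and AUC (rank statistic, ties counted
#' half), overall and stratified by cohort, with the ROC path per stratum as a
#' list column. A stratum containing a single class gets `auc = NA` and
#' `auc_defined = FALSE` rather than a fabricated 0 or 1.
#'
#' @param fit A `braingcn_fit` trained on this fold's training data.
#' @param dataset The dataset the plan indexes into.
#' @param plan The [make_splits()] plan.
#' @param fold Fold index.
#' @param strata Strata to report.
#' @return Tibble with one row per stratum.
#' @export
evaluate <- function(fit, dataset, plan, fold,
                     strata = c("overall", "adult", "pediatric")) {
  evaluate_graphs(fit, dataset[test_indices(plan, fold)], fold, strata)
}

#' Run one training/evaluation regime
#'
#' The four regimes of the study:
#' * `adult_adult`, `pediatric_pediatric` — stratified 5-fold CV within one
#'   cohort.
#' * `adult_to_pediatric` — models trained per adult fold, each externally
#'   validated on the entire pediatric cohort (pediatric subjects never enter
#'   training or validation).
#' * `enriched` — 5-fold CV on the pooled dataset with cohort-stratified
#'   splits and cohort-stratified reporting (the adult-enrichment regime).
#'
#' Deep models use 70/10/20 splits; shallow models 80/20, over the same
#' stratified test folds.
#'
#' @param regime Regime name.
#' @param specs List of [model_spec()]s (or a single spec).
#' @param dataset A `connectome_dataset` containing the required cohorts.
#' @param config A [train_config()].
#' @param seed Seed for splits and training (defaults to `config$seed`).
#' @param return_fits Keep the per-fold fitted models (needed for
#'   [robustness_sweep()]) as an attribute.
#' @return A `braingcn_eval` tibble: one row per model, fold and stratum, with
#'   attributes `regime`, `seed`, `plans`, `histories` and (optionally)
#'   `fits`.
#' @export
run_regime <- function(regime = c("adult_adult", "adult_to_pediatric",
                                  "pediatric_pediatric", "enriched"),
                       specs, dataset, config = train_config(),
                       seed = config$seed, return_fits = FALSE) {
  regime <- match.arg(regime)
  if (inherits(specs, "braingcn_spec")) specs <- list(specs)
  cohorts <- vapply(dataset, `[[`, character(1), "cohort")
  cfg <- config
  cfg$seed <- as.integer(seed)

  train_data <- switch(regime,
    adult_adult = dataset[cohorts == "adult"],
    adult_to_pediatric = dataset[cohorts == "adult"],
    pediatric_pediatric = dataset[cohorts == "pediatric"],
    enriched = dataset)
  if (length(train_data) == 0) {
    stop("regime '", regime, "' requires a cohort absent from the dataset",
         call. = FALSE)
  }
  if (regime %in% c("adult_to_pediatric")) {
    ped <- dataset[cohorts == "pediatric"]
    if (length(ped) == 0) stop("no pediatric cohort to validate on", call. = FALSE)
  }
  mode <- if (regime == "enriched") "enriched" else "single_cohort"
  plans <- list(
    deep = make_splits(train_data, mode, "deep", seed = seed),
    shallow = make_splits(train_data, mode, "shallow", seed = seed)
  )

  rows <- list(); fits <- list(); histories <- list()
  for (m in seq_along(specs)) {
    spec <- specs[[m]]
    plan <- if (is_deep(spec)) plans$deep else plans$shallow
    model_fits <- vector("list", plan$n_folds)
    for (fold in seq_len(plan$n_folds)) {
      fit <- train_model(spec, train_data, plan, fold, cfg,
                         seed = derive_seed(seed, 1000 * m + fold))
      model_fits[[fold]] <- fit
      rows[[length(rows) + 1L]] <- if (regime == "adult_to_pediatric") {
        evaluate_graphs(fit, ped, fold, strata = c("overall", "pediatric"))
      } else {
        evaluate(fit, train_data, plan, fold)
      }
      if (!is.null(fit$history)) {
        histories[[length(histories) + 1L]] <-
          dplyr::mutate(fit$history, model = spec$name, fold = fold,
                        .before = 1)
      }
    }
    fits[[spec$name]] <- model_fits
  }
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("braingcn_eval", class(out)),
            regime = regime, seed = as.integer(seed), plans = plans,
            dataset_size = length(train_data),
            histories = dplyr::bind_rows(histories),
            fits = if (return_fits) fits else NULL)
}

#' @export
tidy.braingcn_eval <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$roc <- NULL
  dplyr::mutate(out, regime = attr(x, "regime"), .before = 1)
}

#' Fold-aggregated metrics
#'
#' Mean and sample standard deviation (n - 1 denominator) of accuracy and AUC
#' across folds, per model and stratum.
#'
#' @param x A `braingcn_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.braingcn_eval <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$model, .data$stratum) |>
    dplyr::summarise(
      n_folds = dplyr::n(),
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = sd(.data$accuracy),
      mean_auc = mean(.data$auc[.data$auc_defined]),
      sd_auc = sd(.data$auc[.data$auc_defined]),
      .groups = "drop") |>
    dplyr::mutate(regime = attr(x, "regime"), .before = 1)
}

#' @export
print.braingcn_eval <- function(x, ...) {
  cat(sprintf("<braingcn_eval> regime '%s', seed %d\n",
              attr(x, "regime"), attr(x, "seed")))
  print(glance(x))
  invisible(x)
}

#' Plot fold-aggregated accuracy per model and stratum
#'
#' @param object A `braingcn_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.braingcn_eval <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$model, y = .data$mean_accuracy,
                                  fill = .data$stratum)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "accuracy (%)",
                  title = sprintf("Regime: %s", attr(object, "regime"))) +
    ggplot2::theme_minimal()
}

#' Plot per-epoch training and validation loss curves
#'
#' @param report A `braingcn_eval` from [run_regime()].
#' @return A ggplot object, or `NULL` if no deep model was trained.
#' @export
plot_loss_curves <- function(report) {
  h <- attr(report, "histories")
  if (is.null(h) || nrow(h) == 0) return(NULL)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                              names_to = "curve", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$curve,
                                     group = interaction(.data$curve, .data$fold))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~model, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot ROC curves for one stratum
#'
#' @param report A `braingcn_eval`.
#' @param stratum Stratum to plot.
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(report, stratum = "overall") {
  df <- tibble::as_tibble(report) |>
    dplyr::filter(.data$stratum == !!stratum) |>
    dplyr::mutate(roc = .data$roc) |>
    tidyr::unnest("roc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = factor(.data$fold))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(colour = "fold") +
    ggplot2::theme_minimal()
}

#' Assert that no training or validation subject leaks into its test set
#'
#' @param plan A [make_splits()] plan.
#' @return `TRUE` invisibly; errors on leakage.
#' @export
check_no_leakage <- function(plan) {
  for (f in seq_len(plan$n_folds)) {
    te <- test_indices(plan, f)
    if (length(intersect(train_indices(plan, f), te)) ||
        length(intersect(val_indices(plan, f), te))) {
      stop("data leakage: train/val overlaps test in fold ", f, call. = FALSE)
    }
    if (length(intersect(train_indices(plan, f), val_indices(plan, f)))) {
      stop("train/validation overlap in fold ", f, call. = FALSE)
    }
  }
  all_test <- sort(unlist(lapply(seq_len(plan$n_folds), test_indices, plan = plan)))
  if (!identical(all_test, seq_len(nrow(plan$assignments)))) {
    stop("test folds do not partition the dataset", call. = FALSE)
  }
  invisible(TRUE)
}
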