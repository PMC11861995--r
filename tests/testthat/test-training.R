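test_that("weighted binary cross-entropy matches closed forms", {
  expect_equal(weighted_bce(0.5, 1), log(2))
  expect_lt(weighted_bce(c(1 - 1e-12, 1e-12), c(1, 0)), 1e-9)
  # with unit weights the weighted form is plain BCE
  s <- c(0.2, 0.9, 0.6, 0.4); y <- c(0, 1, 1, 0)
  plain <- -mean(y * log(s) + (1 - y) * log(1 - s))
  expect_equal(weighted_bce(s, y, c(1, 1)), plain)
  expect_error(weighted_bce(0.5, 2), "labels")
  expect_error(weighted_bce(0.5, 1, c(-1, 1)), "positive")
})

test_that("class weights are inverse frequencies normalized to mean 1", {
  y <- c(rep(1, 30), rep(0, 10))
  w <- class_weights_for(y)
  expect_equal(mean(w), 1)
  expect_equal(w[1] / w[2], (30 / 40) / (10 / 40))
  expect_warning(class_weights_for(rep(1, 5)), "single class")
})

test_that("deep splits are 70/10/20 and shallow splits 80/20", {
  ds <- tiny_dataset(n_regions = 6, n_adult = 100, n_pediatric = 0)
  deep <- make_splits(ds, "single_cohort", "deep", seed = 4)
  for (f in 1:5) {
    expect_equal(length(test_indices(deep, f)), 20)
    expect_equal(length(val_indices(deep, f)), 10)
    expect_equal(length(train_indices(deep, f)), 70)
  }
  shallow <- make_splits(ds, "single_cohort", "shallow", seed = 4)
  for (f in 1:5) {
    expect_equal(length(test_indices(shallow, f)), 20)
    expect_equal(length(train_indices(shallow, f)), 80)
  }
})

test_that("135 pediatric subjects give five test sets of 27", {
  ds <- tiny_dataset(n_regions = 6, n_adult = 0, n_pediatric = 135)
  plan <- make_splits(ds, "single_cohort", "deep", seed = 9)
  expect_equal(vapply(1:5, function(f) length(test_indices(plan, f)),
                      integer(1)), rep(27L, 5))
  check_no_leakage(plan)
})

test_that("enriched splits hold the cohort ratio constant within one subject", {
  ds <- tiny_dataset(n_regions = 6, n_adult = 309, n_pediatric = 135)
  plan <- make_splits(ds, "enriched", "deep", seed = 1)
  cohorts <- plan$assignments$cohort
  labels <- plan$assignments$label
  for (f in 1:5) {
    for (set in list(test_indices(plan, f), val_indices(plan, f),
                     train_indices(plan, f))) {
      for (lab in 0:1) {
        for (coh in c("adult", "pediatric")) {
          expected <- sum(labels == lab & cohorts == coh) *
            length(set) / length(ds)
          got <- sum(labels[set] == lab & cohorts[set] == coh)
          expect_lt(abs(got - expected), 2)
        }
      }
    }
    frac_adult <- mean(cohorts[test_indices(plan, f)] == "adult")
    expect_lt(abs(frac_adult - 309 / 444), 1 / length(test_indices(plan, f)))
  }
  check_no_leakage(plan)
})

test_that("split plans are deterministic given the seed", {
  ds <- tiny_dataset(n_regions = 6, n_adult = 40, n_pediatric = 20)
  p1 <- make_splits(ds, "enriched", "deep", seed = 31)
  p2 <- make_splits(ds, "enriched", "deep", seed = 31)
  expect_identical(p1$assignments, p2$assignments)
  expect_identical(p1$val_sets, p2$val_sets)
  p3 <- make_splits(ds, "enriched", "deep", seed = 32)
  expect_false(identical(p1$assignments$test_fold, p3$assignments$test_fold))
})

test_that("tiny strata trigger a warning but still assign everyone", {
  ds <- tiny_dataset(n_regions = 6, n_adult = 12, n_pediatric = 3)
  warnings <- testthat::capture_warnings(
    plan <- make_splits(ds, "enriched", "shallow", seed = 1))
  expect_true(any(grepl("best-effort", warnings)))
  expect_equal(sort(unlist(lapply(1:5, function(f) test_indices(plan, f)))),
               1:15)
})

test_that("the early-stopping monitor implements the patience arithmetic", {
  # constant validation loss from epoch 1: stop at epoch 36, keep epoch 1
  trace <- braingcn:::early_stop_trace(rep(1, 100), patience = 35)
  expect_equal(trace$stop_epoch, 36)
  expect_equal(trace$best_epoch, 1)
  # strictly decreasing loss: never stops, best is the last epoch
  trace <- braingcn:::early_stop_trace(seq(1, 0.01, length.out = 100), 35)
  expect_equal(trace$stop_epoch, 100)
  expect_equal(trace$best_epoch, 100)
  # improvement after a plateau resets the wait counter
  losses <- c(1, rep(0.9, 10), 0.5, rep(0.6, 12))
  trace <- braingcn:::early_stop_trace(losses, patience = 12)
  expect_equal(trace$best_epoch, 12)
  expect_equal(trace$stop_epoch, 24)
})

test_that("training reduces the loss on learnable synthetic data", {
  ds <- tiny_dataset(n_regions = 12, n_adult = 40, n_pediatric = 0,
                     sex_effect_size = 1.2)
  plan <- make_splits(ds, "single_cohort", "deep", seed = 2)
  fit <- train_model(model_spec("gcn_simple", 12, gcn_widths = c(8, 8)),
                     ds, plan, 1, tiny_train_config(epochs = 15))
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
  expect_true(all(is.finite(fit$history$val_loss)))
})

test_that("training is reproducible given identical seeds", {
  ds <- tiny_dataset(n_regions = 10, n_adult = 30, n_pediatric = 0)
  plan <- make_splits(ds, "single_cohort", "deep", seed = 6)
  cfg <- tiny_train_config(epochs = 6, seed = 11)
  f1 <- train_model(model_spec("gcn_residual", 10), ds, plan, 1, cfg)
  f2 <- train_model(model_spec("gcn_residual", 10), ds, plan, 1, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, ds[1:3]), predict(f2, ds[1:3]))
})

test_that("patience longer than the epoch budget is rejected", {
  expect_error(train_config(epochs = 10, early_stopping_patience = 35),
               "patience")
})
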