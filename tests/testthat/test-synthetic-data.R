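test_that("generated datasets have the configured shape and graph invariants", {
  ds <- generate_dataset(synthetic_config(n_regions = 40, n_adult = 100,
                                          n_pediatric = 40, seed = 7))
  expect_length(ds, 140)
  cohorts <- vapply(ds, `[[`, character(1), "cohort")
  expect_equal(sum(cohorts == "adult"), 100)
  expect_equal(sum(cohorts == "pediatric"), 40)
  for (g in ds[c(1, 50, 140)]) {
    expect_equal(dim(g$adjacency), c(40, 40))
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(g$adjacency >= 0))
    expect_identical(unname(diag(g$adjacency)), rep(0, 40))
    expect_equal(nrow(g$node_features), 40)
  }
})

test_that("female counts are the rounded cohort target fractions", {
  ds <- generate_dataset(synthetic_config(n_regions = 10, n_adult = 0,
                                          n_pediatric = 135,
                                          female_fraction_pediatric = 0.563,
                                          seed = 2))
  labels <- vapply(ds, `[[`, integer(1), "label")
  expect_equal(sum(labels), round(135 * 0.563))
  expect_equal(sum(labels), 76)

  ds2 <- generate_dataset(synthetic_config(n_regions = 10, n_adult = 309,
                                           n_pediatric = 0,
                                           female_fraction_adult = 0.534,
                                           seed = 2))
  expect_equal(sum(vapply(ds2, `[[`, integer(1), "label")), round(309 * 0.534))
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- synthetic_config(n_regions = 15, n_adult = 10, n_pediatric = 8,
                          seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(lapply(d1, `[[`, "adjacency"),
                   lapply(d2, `[[`, "adjacency"))
  expect_identical(vapply(d1, `[[`, integer(1), "label"),
                   vapply(d2, `[[`, integer(1), "label"))
})

test_that("zero sex effect with zero noise makes the sexes identical in law", {
  ds <- generate_dataset(synthetic_config(n_regions = 12, n_adult = 10,
                                          n_pediatric = 0, sex_effect_size = 0,
                                          noise_sd = 0, seed = 3))
  mats <- lapply(ds, `[[`, "adjacency")
  for (m in mats[-1]) expect_equal(m, mats[[1]])
})

test_that("cohort shift scales both sexes equally (female/male ratio invariant)", {
  mean_ratio <- function(shift) {
    ds <- generate_dataset(synthetic_config(n_regions = 15, n_adult = 0,
                                            n_pediatric = 30,
                                            cohort_shift = shift, seed = 11))
    labels <- vapply(ds, `[[`, integer(1), "label")
    w <- vapply(ds, function(g) mean(g$adjacency[upper.tri(g$adjacency)]),
                numeric(1))
    mean(w[labels == 1]) / mean(w[labels == 0])
  }
  expect_equal(mean_ratio(0), mean_ratio(0.8), tolerance = 1e-10)
})

test_that("a linear classifier separates a strongly planted effect", {
  skip_if_not_installed("glmnet")
  ds <- generate_dataset(synthetic_config(n_regions = 30, n_adult = 120,
                                          n_pediatric = 0,
                                          sex_effect_size = 1.2,
                                          sex_edge_fraction = 0.1,
                                          noise_sd = 0.2, seed = 13))
  X <- t(vapply(ds, function(g) as.numeric(g$adjacency), numeric(900)))
  y <- vapply(ds, `[[`, integer(1), "label")
  set.seed(1)
  test_idx <- sample(120, 30)
  fit <- glmnet::glmnet(X[-test_idx, ], y[-test_idx], family = "binomial",
                        lambda = 0.01)
  pred <- as.numeric(predict(fit, X[test_idx, ], type = "response") >= 0.5)
  expect_gt(mean(pred == y[test_idx]), 0.9)
})

test_that("node feature schemes match their definitions", {
  A <- matrix(c(0, 3, 3, 0), 2)
  g <- connectome_graph(A, 1, "adult", "s1")
  expect_identical(make_node_features(g, "connectivity_profile")$node_features, A)
  expect_identical(make_node_features(g, "degree")$node_features,
                   matrix(c(3, 3), ncol = 1))
  expect_identical(make_node_features(g, "one_hot")$node_features, diag(2))
  expect_error(make_node_features(g, "something_else"))
})

test_that("invalid configs and graphs are rejected", {
  expect_error(synthetic_config(n_regions = 1), "n_regions")
  expect_error(synthetic_config(female_fraction_adult = 1.4), "female_fraction")
  expect_error(synthetic_config(sex_effect_size = -1), "sex_effect_size")
  expect_error(synthetic_config(noise_sd = NaN), "noise_sd")
  expect_error(connectome_graph(matrix(c(0, 1, 2, 0), 2), 0, "adult", "x"),
               "symmetric")
  expect_error(connectome_graph(matrix(c(0, -1, -1, 0), 2), 0, "adult", "x"),
               "negative")
  expect_error(connectome_graph(diag(2), 0, "adult", "x"), "diagonal")
})

test_that("dataset tidier returns one row per subject", {
  ds <- tiny_dataset(n_regions = 8, n_adult = 5, n_pediatric = 3)
  td <- tidy(ds)
  expect_equal(nrow(td), 8)
  expect_named(td, c("subject_id", "cohort", "label", "mean_weight",
                     "max_weight"))
})
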