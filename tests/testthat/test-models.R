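test_that("analytic parameter counts match toy arithmetic", {
  # 4 -> 2 -> 1 with biases: 4*2+2 + 2*1+1 = 13
  toy <- model_spec("mlp", n_regions = 2, mlp_widths = 2)
  expect_equal(count_parameters(toy), 13)
  # the simple GCN at atlas scale under this package's conventions
  gcn <- model_spec("gcn_simple", n_regions = 379)
  expect_equal(count_parameters(gcn),
               (379 * 64 + 64) + (64 * 64 + 64) + (64 * 1 + 1))
  expect_equal(count_parameters(gcn), 28545)
})

test_that("analytic counts equal brute-force enumeration of built models", {
  specs <- list(
    model_spec("gcn_simple", 9, gcn_widths = c(5, 4)),
    model_spec("gcn_residual", 9),
    model_spec("gcn_residual", 9, use_skips = FALSE),
    model_spec("mlp", 5, mlp_widths = c(7, 3))
  )
  for (spec in specs) {
    m <- build_model(spec, seed = 1)
    expect_equal(count_parameters(m), count_parameters(spec))
    expect_equal(count_parameters(m), count_parameters_bruteforce(m))
  }
  expect_error(count_parameters(model_spec("rf", 5)), "trainable")
})

test_that("the MLP consumes the full flattened adjacency", {
  spec <- model_spec("mlp", n_regions = 379)
  expect_equal(spec$n_regions^2, 143641)
  small <- build_model(model_spec("mlp", 6), seed = 1)
  expect_equal(nrow(small$params$layers[[1]]$W), 36)
})

test_that("skip ablation narrows the residual readout to the final summary", {
  with_skips <- build_model(model_spec("gcn_residual", 10), seed = 1)
  without <- build_model(model_spec("gcn_residual", 10, use_skips = FALSE),
                         seed = 1)
  expect_equal(nrow(with_skips$params$head$W), 96)
  expect_equal(nrow(without$params$head$W), 32)
})

test_that("a zeroed final layer scores exactly 0.5", {
  for (name in c("gcn_simple", "gcn_residual", "mlp")) {
    m <- build_model(model_spec(name, 8), seed = 4)
    m$params$head$W[] <- 0
    m$params$head$b <- 0
    g <- random_graph(8, seed = 9)
    expect_identical(predict(m, g)$score, 0.5)
  }
})

test_that("inference is deterministic and dropout-free", {
  m <- build_model(model_spec("gcn_simple", 8), seed = 4)
  g <- random_graph(8, seed = 10)
  p1 <- predict(m, g)
  p2 <- predict(m, g)
  expect_identical(p1, p2)
  expect_identical(p1$label_hat, as.integer(p1$score >= 0.5))
})

test_that("GCN predictions are invariant under node permutation", {
  set.seed(77)
  for (name in c("gcn_simple", "gcn_residual")) {
    for (kind in c("mean", "max")) {
      m <- build_model(model_spec(name, 9, pooling = kind,
                                  aggregation = kind), seed = 5)
      for (i in 1:5) {
        g <- random_graph(9, seed = 100 + i)
        perm <- sample(9)
        gp <- permute_graph(g, perm)
        expect_lt(abs(predict(m, g)$score - predict(m, gp)$score), 1e-9)
      }
    }
  }
})

test_that("hand-derived gradients match finite differences", {
  perturb <- function(tree, leaf, j, d) {
    cnt <- 0L
    rec <- function(t) {
      for (k in seq_along(t)) {
        if (is.list(t[[k]])) t[[k]] <- rec(t[[k]])
        else { cnt <<- cnt + 1L; if (cnt == leaf) t[[k]][j] <- t[[k]][j] + d }
      }
      t
    }
    rec(tree)
  }
  set.seed(42)
  n <- 5
  cw <- c(1.3, 0.8)
  graphs <- lapply(1:3, function(i) random_graph(n, label = i %% 2,
                                                 id = paste0("s", i)))
  y <- vapply(graphs, `[[`, integer(1), "label")
  for (name in c("gcn_simple", "gcn_residual", "mlp")) {
    spec <- model_spec(name, n, gcn_widths = c(4, 3), mlp_widths = c(6, 4),
                       dropout = 0)
    m <- build_model(spec, seed = 9)
    # keep parameters away from ReLU kinks introduced by zero-initialized biases
    m$params <- rapply(m$params, function(x) x + rnorm(length(x), sd = 0.3),
                       how = "replace")
    inp <- if (name != "mlp") braingcn:::prepare_gcn_inputs(graphs, spec)
    loss_at <- function(params) {
      s <- if (name == "mlp") {
        braingcn:::mlp_forward(params,
                               braingcn:::flatten_adjacency(graphs, n),
                               spec)$score
      } else {
        braingcn:::gcn_forward(params, inp$A, 1:3, inp$X, n, spec)$score
      }
      weighted_bce(s, y, cw)
    }
    if (name == "mlp") {
      fw <- braingcn:::mlp_forward(m$params,
                                   braingcn:::flatten_adjacency(graphs, n),
                                   spec)
      dlogit <- cw[y + 1] * (fw$score - y) / 3
      bw <- braingcn:::mlp_backward(m$params, spec, fw$cache, dlogit)
    } else {
      fw <- braingcn:::gcn_forward(m$params, inp$A, 1:3, inp$X, n, spec)
      dlogit <- cw[y + 1] * (fw$score - y) / 3
      bw <- braingcn:::gcn_backward(m$params, inp$A, 1:3, spec, fw$cache,
                                    dlogit)
    }
    fg <- braingcn:::flatten_leaves(bw$grad)
    fp <- braingcn:::flatten_leaves(m$params)
    eps <- 1e-6
    for (i in seq_along(fp)) {
      for (j in seq_len(min(length(fp[[i]]), 3))) {
        num <- (loss_at(perturb(m$params, i, j, eps)) -
                loss_at(perturb(m$params, i, j, -eps))) / (2 * eps)
        expect_lt(abs(num - fg[[i]][j]) / max(1e-4, abs(num)), 1e-5)
      }
    }
  }
})

test_that("PCA components are fit on training folds only and stay frozen", {
  ds <- tiny_dataset(n_regions = 10, n_adult = 30, n_pediatric = 0)
  plan <- make_splits(ds, "single_cohort", "shallow", seed = 2)
  fit <- train_model(model_spec("rf", 10, pca_components = 5), ds, plan, 1)
  rotation_before <- fit$pca$rotation
  invisible(predict(fit, ds[test_indices(plan, 1)]))
  expect_identical(fit$pca$rotation, rotation_before)
  # the PCA center is the mean of the training rows, not of all rows
  Xtr <- t(vapply(ds[train_indices(plan, 1)],
                  function(g) as.numeric(g$adjacency), numeric(100)))
  expect_equal(unname(fit$pca$center), unname(colMeans(Xtr)))
})

test_that("checkpoints restore bit-identical predictions", {
  ds <- tiny_dataset(n_regions = 8, n_adult = 20, n_pediatric = 0)
  plan <- make_splits(ds, "single_cohort", "deep", seed = 1)
  fit <- train_model(model_spec("gcn_simple", 8, gcn_widths = c(6, 6)),
                     ds, plan, 1, tiny_train_config(epochs = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  restored <- load_model(path)
  expect_identical(predict(restored, ds[1:5]), predict(fit, ds[1:5]))
})

test_that("dimension mismatches are rejected at prediction time", {
  m <- build_model(model_spec("gcn_simple", 8), seed = 1)
  expect_error(predict(m, random_graph(9)), "expects 8")
})
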