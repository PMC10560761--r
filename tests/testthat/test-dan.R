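test_that("the hyperparameter grid enumerates 4 x 4 x 5 x 2 configurations", {
  g <- dan_grid()
  expect_equal(nrow(g), 160)
  expect_equal(length(unique(g$dropout)), 4)
  expect_equal(length(unique(g$hidden)), 4)
  expect_equal(length(unique(g$epochs)), 5)
  expect_equal(length(unique(g$learning_rate)), 2)
  expect_equal(anyDuplicated(g[, 1:4]), 0)
})

test_that("F1 is the harmonic mean with the documented edge case", {
  expect_equal(f1_score(0.62, 0.62), 0.62)
  expect_equal(f1_score(0.8, 0.8), 0.8)
  expect_equal(f1_score(1, 0.5), 2 / 3)
  expect_warning(z <- f1_score(0, 0), "zero")
  expect_equal(z, 0)
})

test_that("attention is a probability distribution and output symmetric at init", {
  pf <- planted_feature_matrix(n_per_group = 6, D = 120, seed = 2)
  fit <- dan_fit(pf$X, pf$y, dan_config(hidden = 16, epochs = 2), seed = 1)
  expect_true(all(fit$attention >= 0))
  expect_equal(sum(fit$attention), 1, tolerance = 1e-12)
  ## zeroed output layer: class probability exactly one half
  m <- fit$members[[1]]
  p <- .nn_forward_cpp(pf$X, m$gate, m$W1, m$b1, m$W2, m$b2,
                       matrix(0, nrow(m$W3), 2), rep(0, 2), TRUE)
  expect_equal(as.vector(p), rep(0.5, 2 * nrow(pf$X)))
})

test_that("evaluation is bit-reproducible under a fixed master seed", {
  pf <- planted_feature_matrix(n_per_group = 5, D = 80, seed = 3)
  cfg <- dan_config(hidden = 16, epochs = 4)
  e1 <- loocv_evaluate(cfg, pf$X, pf$y, repeats = 2, seed = 9)
  e2 <- loocv_evaluate(cfg, pf$X, pf$y, repeats = 2, seed = 9)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$per_repeat, e2$per_repeat)
  e3 <- loocv_evaluate(cfg, pf$X, pf$y, repeats = 2, seed = 10)
  expect_false(identical(e1$per_repeat, e3$per_repeat))
})

test_that("deterministic models report zero spread over repeats", {
  skip_if_not_installed("class")
  skip_if_not_installed("e1071")
  pf <- planted_feature_matrix(n_per_group = 6, D = 60, seed = 4)
  for (m in c("knn", "svm-linear")) {
    ev <- loocv_evaluate(m, pf$X, pf$y, repeats = 3, seed = 1)
    expect_equal(ev$summary$accuracy_sd, 0)
    expect_equal(ev$summary$f1_sd, 0)
  }
})

test_that("a strongly separable planted dataset is classified near-perfectly", {
  skip_if_not_installed("e1071")
  pf <- planted_feature_matrix(n_per_group = 10, D = 200, j = 100,
                               shift = 6, seed = 5)
  ev <- loocv_evaluate(dan_config(), pf$X, pf$y, repeats = 2, seed = 1)
  expect_gte(ev$summary$accuracy_mean, 0.9)
  sv <- loocv_evaluate("svm-linear", pf$X, pf$y, repeats = 1, seed = 1)
  expect_gte(sv$summary$accuracy_mean, 0.9)
})

test_that("label-shuffled data are classified at chance", {
  pf <- planted_feature_matrix(n_per_group = 6, D = 100, shift = 4, seed = 6)
  cfg <- dan_config(hidden = 16, epochs = 8)
  accs <- vapply(1:10, function(k) {
    set.seed(100 + k)
    ys <- sample(pf$y)
    loocv_evaluate(cfg, pf$X, ys, repeats = 1,
                   seed = k)$summary$accuracy_mean
  }, numeric(1))
  ## binomial noise around 0.5 over 10 x 12 pooled predictions
  se <- sqrt(0.25 / (10 * 12))
  expect_lt(abs(mean(accs) - 0.5), 4 * se + 0.02)
})

test_that("attention localizes a single informative feature", {
  hits <- vapply(1:10, function(k) {
    pf <- planted_feature_matrix(n_per_group = 8, D = 200, j = 77,
                                 shift = 5, seed = 100 + k)
    fit <- dan_fit(scale(pf$X), pf$y, dan_config(), seed = k)
    abs(which.max(fit$attention) - pf$j) <= 25
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("grid_search ranks deterministically and handles singleton grids", {
  pf <- planted_feature_matrix(n_per_group = 5, D = 60, shift = 4, seed = 7)
  g1 <- dan_grid()[c(3, 20, 60), ]
  r1 <- grid_search(pf$X, pf$y, g1, repeats = 1, seed = 2)
  r2 <- grid_search(pf$X, pf$y, g1[c(2, 3, 1), ], repeats = 1, seed = 2)
  expect_equal(r1$config_id, r2$config_id)
  expect_equal(r1$accuracy_mean, sort(r1$accuracy_mean, decreasing = TRUE))
  rs <- grid_search(pf$X, pf$y, dan_grid()[42, ], repeats = 1, seed = 2)
  expect_equal(nrow(rs), 1)
  expect_error(grid_search(pf$X, pf$y, dan_grid()[0, ]), "empty")
})

test_that("the model bank returns metrics in range for every member", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("glmnet")
  skip_if_not_installed("randomForest")
  skip_if_not_installed("class")
  pf <- planted_feature_matrix(n_per_group = 5, D = 60, shift = 4, seed = 8)
  bank <- suppressWarnings(run_baseline_bank(pf$X, pf$y, repeats = 2, seed = 1))
  expect_equal(nrow(bank), 9)
  metric_cols <- grep("_mean|_sd", names(bank))
  expect_true(all(bank[, metric_cols] >= 0 & bank[, metric_cols] <= 1))
})

test_that("single-class labels and length mismatches are rejected", {
  pf <- planted_feature_matrix(n_per_group = 4, D = 40, seed = 9)
  expect_error(loocv_evaluate(dan_config(), pf$X, rep(1L, 8)), "both classes")
  fit <- dan_fit(pf$X, pf$y, dan_config(hidden = 16, epochs = 2), seed = 1)
  expect_error(dan_forward(fit, pf$X[, 1:10]), "mismatch")
})
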