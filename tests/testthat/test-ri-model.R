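test_that("presets carry the reference training recipes", {
  d <- descriptor_preset()
  expect_equal(
    unlist(d[c("iterations", "learning_rate", "depth", "max_leaves",
               "min_data_in_leaf", "l2_leaf_reg", "early_stopping_rounds")]),
    c(iterations = 450, learning_rate = 0.03, depth = 8, max_leaves = 256,
      min_data_in_leaf = 1, l2_leaf_reg = 10, early_stopping_rounds = 5))
  cc <- cnl_preset()
  expect_equal(
    unlist(cc[c("iterations", "learning_rate", "depth", "max_leaves",
                "min_data_in_leaf", "l2_leaf_reg", "early_stopping_rounds")]),
    c(iterations = 5000, learning_rate = 0.077, depth = 6, max_leaves = 64,
      min_data_in_leaf = 1, l2_leaf_reg = 3, early_stopping_rounds = 5))
})

test_that("stratified splits honor class proportions within one sample", {
  set.seed(4)
  labels <- c(runif(30, 210, 430), runif(40, 450, 690), runif(30, 710, 1030))
  sp <- stratified_split(labels, train_fraction = 0.85, seed = 1)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  for (cls in list(1:30, 31:70, 71:100)) {
    n_tr <- length(intersect(sp$train, cls))
    expect_lte(abs(n_tr - 0.85 * length(cls)), 1)
  }
  # deterministic under a fixed seed
  expect_identical(sp, stratified_split(labels, 0.85, seed = 1))
  expect_false(identical(sp, stratified_split(labels, 0.85, seed = 2)))
})

test_that("degenerate stratification falls back to a plain split", {
  labels <- runif(40, 500, 600)   # single class: both end classes empty
  warns <- capture_warnings(sp <- stratified_split(labels, 0.5, seed = 3))
  expect_match(warns, "empty retention-index class", all = TRUE)
  expect_length(warns, 2)
  expect_equal(length(sp$train), 20)
})

test_that("grouped splits keep all entries of a group on one side", {
  labels <- runif(60, 210, 1030)
  groups <- rep(sprintf("g%02d", 1:20), each = 3)
  sp <- stratified_split(labels, 0.7, seed = 5, groups = groups)
  expect_length(intersect(unique(groups[sp$train]), unique(groups[sp$test])), 0)
})

test_that("evaluation metrics match their closed forms", {
  ev <- evaluate_ri(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ev[c("r_squared", "rmse", "max_error")]),
               c(r_squared = 1, rmse = 0, max_error = 0))
  ev2 <- evaluate_ri(c(11, 22, 33), c(1, 12, 23))
  expect_equal(ev2$rmse, 10)
  expect_equal(ev2$max_error, 10)
  ev3 <- evaluate_ri(c(0, 0), c(0, 10))
  expect_equal(ev3$r_squared, -1)               # 1 - 100/50
  expect_equal(ev3$rmse, sqrt(50), tolerance = 1e-12)
  expect_warning(evaluate_ri(c(1, 2), c(5, 5)), "zero-variance")
})

test_that("a step-function target is recovered nearly exactly", {
  set.seed(8)
  x <- matrix(rbinom(200, 1, 0.5), ncol = 1, dimnames = list(NULL, "f"))
  y <- 500 + 300 * x[, 1]
  tr <- 1:150; te <- 151:200
  m <- train_ri_model(x[tr, , drop = FALSE], y[tr],
                      descriptor_preset(random_seed = 1),
                      validation = list(features = x[te, , drop = FALSE],
                                        labels = y[te]))
  ev <- evaluate_ri(predict(m, x[te, , drop = FALSE]), y[te])
  expect_lt(ev$rmse, 5)
})

test_that("training is deterministic under a fixed seed and rejects degenerate labels", {
  set.seed(12)
  X <- matrix(rnorm(600), 100, 6)
  y <- 400 + 80 * X[, 1] + rnorm(100, 0, 5)
  m1 <- train_ri_model(X, y, descriptor_preset(random_seed = 9))
  m2 <- train_ri_model(X, y, descriptor_preset(random_seed = 9))
  expect_identical(predict(m1, X), predict(m2, X))
  expect_error(train_ri_model(X, rep(1, 100), descriptor_preset()), "constant")
  expect_error(train_ri_model(X, c(y[-1], NA), descriptor_preset()), "non-finite")
  expect_error(train_ri_model(X[1:5, ], y[1:5], descriptor_preset()), "at least 10")
})

test_that("early stopping never exceeds the iteration budget", {
  set.seed(13)
  X <- matrix(rnorm(400), 100, 4)
  y <- 500 + 100 * X[, 1] + rnorm(100, 0, 50)
  cfg <- gbt_config(iterations = 30, learning_rate = 0.1, depth = 3,
                    max_leaves = 8, l2_leaf_reg = 1, random_seed = 2)
  m <- train_ri_model(X[1:80, ], y[1:80], cfg,
                      validation = list(features = X[81:100, ], labels = y[81:100]))
  expect_lte(m$best_iteration, cfg$iterations)
})

test_that("prediction aligns feature columns by name", {
  set.seed(14)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 300 + 50 * X[, 1] - 30 * X[, 3] + rnorm(100, 0, 2)
  m <- train_ri_model(X, y, descriptor_preset(random_seed = 3))
  perm <- X[, c("c", "a", "b")]
  expect_identical(predict(m, perm), predict(m, X))
  expect_length(predict(m, X[1, , drop = FALSE]), 1L)
  bad <- X; colnames(bad) <- c("a", "b", "zz")
  expect_error(predict(m, bad), "do not match")
})

test_that("cross-validation partitions rows and recovers clean signal", {
  set.seed(15)
  X <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 400 + 200 * X[, 2]           # noise-free linear signal
  cv <- cross_validate(X, y, descriptor_preset(random_seed = 4), k = 5, seed = 6)
  folds <- attr(cv, "folds")
  expect_setequal(unique(folds), 1:5)
  expect_equal(length(folds), 100)   # every row in exactly one validation fold
  expect_gt(mean(cv$r_squared), 0.95)
  # permutation null: shuffled labels carry no signal
  cv_null <- cross_validate(X, sample(y), descriptor_preset(random_seed = 4),
                            k = 5, seed = 6)
  expect_lt(mean(cv_null$r_squared), 0.1)
})

test_that("refitting on the top features preserves concentrated signal", {
  set.seed(16)
  p <- 12
  X <- matrix(rnorm(250 * p), 250, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- 500 + 120 * X[, 1] - 90 * X[, 2] + 60 * X[, 3] + rnorm(250, 0, 5)
  tr <- 1:200; te <- 201:250
  full <- train_ri_model(X[tr, ], y[tr], descriptor_preset(random_seed = 5))
  top3 <- refit_top_features(full, X[tr, ], y[tr], top_k = 3)
  expect_length(top3$feature_names, 3)
  expect_setequal(top3$feature_names, c("f1", "f2", "f3"))
  ev_full <- evaluate_ri(predict(full, X[te, ]), y[te])
  ev_top <- evaluate_ri(predict(top3, X[te, ]), y[te])
  expect_lt(abs(ev_full$r_squared - ev_top$r_squared), 0.05)
  # top_k = everything is a no-op selection
  all_k <- refit_top_features(full, X[tr, ], y[tr], top_k = p)
  expect_setequal(all_k$feature_names, colnames(X))
})
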