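#' Gradient-boosted-tree configurations for retention-index regression
#'
#' Two named presets are provided, matching the reference training
#' recipes.  The descriptor (QSRR) preset: 450 iterations, learning
#' rate 0.03, depth 8, at most 256 leaves, minimum 1 observation per
#' leaf, L2 leaf regularization 10.  The CNL preset: 5000 iterations,
#' learning rate 0.077, depth 6, at most 64 leaves, minimum 1 per leaf,
#' L2 leaf regularization 3.  Both use an RMSE loss and stop early when
#' the validation error has not improved for 5 rounds.  Remaining
#' parameters take the backend's defaults, recorded in the trained
#' model's fingerprint.
#'
#' @param iterations Maximum boosting rounds.
#' @param learning_rate Shrinkage per round.
#' @param depth Maximum tree depth.
#' @param max_leaves Maximum leaves per tree.
#' @param min_data_in_leaf Minimum observations in a leaf.
#' @param l2_leaf_reg L2 regularization on leaf values.
#' @param early_stopping_rounds Rounds without validation improvement
#'   before stopping (active only when a validation set is supplied).
#' @param random_seed Seed passed to the backend.
#' @return A `gbt_config` list.
#' @export
gbt_config <- function(iterations, learning_rate, depth, max_leaves,
                       min_data_in_leaf = 1, l2_leaf_reg,
                       early_stopping_rounds = 5, random_seed = 0) {
  structure(
    list(iterations = as.integer(iterations), learning_rate = learning_rate,
         depth = as.integer(depth), max_leaves = as.integer(max_leaves),
         min_data_in_leaf = as.integer(min_data_in_leaf),
         l2_leaf_reg = l2_leaf_reg,
         early_stopping_rounds = as.integer(early_stopping_rounds),
         random_seed = as.integer(random_seed)),
    class = "gbt_config"
  )
}

#' @rdname gbt_config
#' @export
descriptor_preset <- function(random_seed = 0) {
  gbt_config(iterations = 450, learning_rate = 0.03, depth = 8,
             max_leaves = 256, min_data_in_leaf = 1, l2_leaf_reg = 10,
             random_seed = random_seed)
}

#' @rdname gbt_config
#' @export
cnl_preset <- function(random_seed = 0) {
  gbt_config(iterations = 5000, learning_rate = 0.077, depth = 6,
             max_leaves = 64, min_data_in_leaf = 1, l2_leaf_reg = 3,
             random_seed = random_seed)
}

#' Stratified splitting on retention-index classes
#'
#' Retention indices on the alkylamide scale are skewed, so train/test
#' splits are stratified over three classes with fixed unit
#' boundaries 200-440, 440-700 and 700-1041 (values outside the range
#' join the nearest end class).  Within each class the train fraction is
#' honored to within one sample; empty classes are skipped with a
#' warning.
#'
#' @param labels Numeric retention-index vector.
#' @param train_fraction Fraction assigned to training.
#' @param seed Integer seed; the split is deterministic given it.
#' @param class_edges Class boundaries, default `c(200, 440, 700, 1041)`.
#' @param groups Optional grouping vector (e.g. compound id), same
#'   length as `labels`: all members of a group land on the same side.
#'   Stratification then applies to groups via their median label.
#' @return List with integer vectors `train` and `test` partitioning
#'   `seq_along(labels)`.
#' @export
stratified_split <- function(labels, train_fraction = 0.85, seed = 1,
                             class_edges = c(200, 440, 700, 1041),
                             groups = NULL) {
  stopifnot(all(is.finite(labels)), train_fraction > 0, train_fraction < 1)
  if (is.null(groups)) groups <- seq_along(labels)
  gid <- unique(groups)
  glab <- vapply(gid, function(g) stats::median(labels[groups == g]), 0)
  cls <- ri_class(glab, class_edges)
  rng <- local_rng(seed)
  train_groups <- character(0)
  gid <- as.character(gid); names(glab) <- gid
  for (cl in levels(cls)) {
    members <- gid[cls == cl]
    if (!length(members)) {
      warning("empty retention-index class skipped: ", cl)
      next
    }
    n_tr <- round(length(members) * train_fraction)
    n_tr <- max(min(n_tr, length(members) - 1L), 1L)
    if (length(members) == 1L) n_tr <- 1L
    perm <- members[rng$sample_int(length(members))]
    train_groups <- c(train_groups, perm[seq_len(n_tr)])
  }
  train <- which(as.character(groups) %in% train_groups)
  list(train = train, test = setdiff(seq_along(labels), train))
}

ri_class <- function(labels, class_edges = c(200, 440, 700, 1041)) {
  breaks <- c(-Inf, class_edges[-c(1, length(class_edges))], Inf)
  cut(labels, breaks = breaks,
      labels = paste(utils::head(class_edges, -1), class_edges[-1], sep = "-"))
}

# Deterministic RNG scoped away from the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  call_with <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample_int = function(n, size = n) call_with(function() sample.int(n, size)),
    runif = function(n) call_with(function() stats::runif(n))
  )
}

as_feature_matrix <- function(features) {
  if (inherits(features, "cnl_matrix")) return(features$matrix)
  if (is.data.frame(features)) {
    if ("compound_id" %in% names(features)) {
      features <- features[setdiff(names(features), "compound_id")]
    }
    return(as.matrix(features))
  }
  features
}

#' Train a gradient-boosted retention-index regressor
#'
#' Fits an RMSE-loss gradient-boosted tree ensemble under a
#' [gbt_config()].  When a validation set is supplied, training stops
#' once the validation RMSE has not improved for
#' `config$early_stopping_rounds` rounds; without one, the full
#' iteration budget is used.  Features with nonzero split-gain
#' importance are recorded as `used_features`.
#'
#' @param features Numeric matrix, sparse `dgCMatrix`, `cnl_matrix`, or
#'   data frame (a `compound_id` column is dropped).
#' @param labels Numeric retention indices, finite, not constant.
#' @param config A [gbt_config()].
#' @param validation Optional list `list(features =, labels =)` used for
#'   early stopping.
#' @return An `ri_model`: the fitted booster plus `feature_names`,
#'   `used_features`, `importance` tibble, `config`, `best_iteration`
#'   and a `fingerprint` (seed, dimensions, backend parameters).
#' @export
train_ri_model <- function(features, labels, config, validation = NULL) {
  X <- as_feature_matrix(features)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%05d", seq_len(ncol(X)) - 1L)
  stopifnot(nrow(X) == length(labels))
  if (nrow(X) < 10) stop("need at least 10 training rows")
  if (!all(is.finite(labels))) stop("non-finite retention-index labels")
  if (stats::var(labels) == 0) stop("constant labels: degenerate regression")

  params <- list(
    objective = "reg:squarederror",
    eval_metric = "rmse",
    eta = config$learning_rate,
    max_depth = config$depth,
    max_leaves = config$max_leaves,
    grow_policy = "depthwise",
    tree_method = "hist",
    max_bin = 254,
    lambda = config$l2_leaf_reg,
    min_child_weight = config$min_data_in_leaf,
    nthread = 1,
    seed = config$random_seed
  )
  dtrain <- xgboost::xgb.DMatrix(X, label = labels, nthread = 1)
  evals <- list(train = dtrain)
  if (!is.null(validation)) {
    Xv <- as_feature_matrix(validation$features)
    if (is.null(colnames(Xv))) colnames(Xv) <- colnames(X)
    evals$validation <- xgboost::xgb.DMatrix(Xv, label = validation$labels, nthread = 1)
  }
  booster <- xgboost::xgb.train(
    params = params, data = dtrain, nrounds = config$iterations,
    evals = evals, verbose = 0,
    early_stopping_rounds = if (!is.null(validation)) config$early_stopping_rounds else NULL
  )
  imp <- tryCatch(
    tibble::as_tibble(xgboost::xgb.importance(model = booster)),
    error = function(e) tibble::tibble(Feature = character(0), Gain = numeric(0))
  )
  names(imp) <- tolower(names(imp))
  best_iter <- suppressWarnings(as.integer(xgboost::xgb.attr(booster, "best_iteration")))
  structure(
    list(
      booster = booster,
      feature_names = colnames(X),
      used_features = imp$feature,
      importance = imp,
      config = config,
      best_iteration = if (length(best_iter) && !is.na(best_iter)) best_iter else
        xgboost::xgb.get.num.boosted.rounds(booster),
      fingerprint = list(
        backend = paste0("xgboost-", as.character(utils::packageVersion("xgboost"))),
        seed = config$random_seed, n = nrow(X), p = ncol(X),
        params = params
      )
    ),
    class = "ri_model"
  )
}

#' @export
print.ri_model <- function(x, ...) {
  cat(sprintf("<ri_model> %d features (%d used), %d boosted rounds (lr %g, depth %d)\n",
              length(x$feature_names), length(x$used_features),
              x$best_iteration, x$config$learning_rate, x$config$depth))
  invisible(x)
}

#' Predict retention indices
#'
#' Columns are aligned to the model's training feature order by name;
#' a permuted but name-complete matrix predicts identically to the
#' canonical order, and genuinely mismatched columns raise an error
#' listing the differences.
#'
#' @param object An `ri_model`.
#' @param features New feature matrix / `cnl_matrix` / data frame.
#' @param ... Unused.
#' @return Numeric vector of predicted retention indices, one per row.
#' @export
predict.ri_model <- function(object, features, ...) {
  X <- as_feature_matrix(features)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, object$feature_names))
  if (!is.null(colnames(X)) && !identical(colnames(X), object$feature_names)) {
    missing <- setdiff(object$feature_names, colnames(X))
    if (length(missing)) {
      extra <- setdiff(colnames(X), object$feature_names)
      stop("feature columns do not match the model: missing [",
           paste(utils::head(missing, 5), collapse = ", "), "], unexpected [",
           paste(utils::head(extra, 5), collapse = ", "), "]")
    }
    X <- X[, object$feature_names, drop = FALSE]
  }
  stats::predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Regression evaluation report
#'
#' Computes the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`, the root-mean-squared error and the
#' maximum absolute error, the three statistics used to judge
#' retention-index models.
#'
#' @param predictions,truth Equal-length numeric vectors (n >= 2).
#' @return An `ri_eval` tibble row: `r_squared`, `rmse`, `max_error`,
#'   `n`; carries `predictions`/`truth` as attributes for plotting.
#' @export
evaluate_ri <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth), length(truth) >= 2)
  if (stats::var(truth) == 0) {
    warning("zero-variance truth: R^2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum((predictions - truth)^2) / sum((truth - mean(truth))^2)
  }
  out <- tibble::tibble(
    r_squared = r2,
    rmse = sqrt(mean((predictions - truth)^2)),
    max_error = max(abs(predictions - truth)),
    n = length(truth)
  )
  attr(out, "predictions") <- predictions
  attr(out, "truth") <- truth
  class(out) <- c("ri_eval", class(out))
  out
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified on the retention-index classes; each fold in
#' turn serves as the validation set (also driving early stopping, the
#' way hyperparameters are tuned on a training set).
#'
#' @inheritParams train_ri_model
#' @param k Number of folds, default 5.
#' @param seed Seed controlling fold assignment.
#' @param class_edges See [stratified_split()].
#' @return A `ri_cv` object: tibble of per-fold metrics with attribute
#'   `summary` (mean and sd per metric).
#' @export
cross_validate <- function(features, labels, config, k = 5, seed = 1,
                           class_edges = c(200, 440, 700, 1041)) {
  stopifnot(k >= 2)
  n <- length(labels)
  if (n < k) stop("fewer rows than folds")
  X <- as_feature_matrix(features)
  cls <- ri_class(labels, class_edges)
  rng <- local_rng(seed)
  fold <- integer(n)
  for (cl in levels(cls)) {
    idx <- which(cls == cl)
    if (!length(idx)) next
    fold[idx] <- ((rng$sample_int(length(idx)) - 1L) %% k) + 1L
  }
  reports <- purrr::map(seq_len(k), function(f) {
    va <- which(fold == f); tr <- which(fold != f)
    m <- train_ri_model(X[tr, , drop = FALSE], labels[tr], config,
                        validation = list(features = X[va, , drop = FALSE],
                                          labels = labels[va]))
    ev <- evaluate_ri(predict(m, X[va, , drop = FALSE]), labels[va])
    dplyr::mutate(tibble::as_tibble(ev), fold = f, .before = 1)
  })
  out <- dplyr::bind_rows(reports)
  attr(out, "summary") <- dplyr::summarise(
    tidyr::pivot_longer(out, c("r_squared", "rmse", "max_error"),
                        names_to = "metric"),
    mean = mean(.data$value), sd = stats::sd(.data$value), .by = "metric")
  attr(out, "folds") <- fold
  class(out) <- c("ri_cv", class(out))
  out
}

#' Refit on the top importance-ranked features
#'
#' Ranks the fitted model's features by split-gain importance (ties
#' broken by training feature order), keeps the top `top_k`, and
#' retrains the same configuration on that subset — the final-model
#' step of the descriptor workflow, where the 40 strongest descriptors
#' are refitted.
#'
#' @param model A fitted `ri_model`.
#' @inheritParams train_ri_model
#' @param top_k Number of features to keep, default 40.
#' @return A new `ri_model` on the reduced feature set.
#' @export
refit_top_features <- function(model, features, labels, config = model$config,
                               validation = NULL, top_k = 40) {
  X <- as_feature_matrix(features)
  if (is.null(colnames(X))) colnames(X) <- model$feature_names
  stopifnot(top_k <= ncol(X))
  imp <- model$importance
  ranked <- imp$feature[order(-imp$gain, match(imp$feature, model$feature_names))]
  ranked <- c(ranked, setdiff(model$feature_names, ranked))  # zero-importance tail
  keep <- ranked[seq_len(min(top_k, length(ranked)))]
  keep <- model$feature_names[model$feature_names %in% keep]  # canonical order
  val <- NULL
  if (!is.null(validation)) {
    Xv <- as_feature_matrix(validation$features)
    if (is.null(colnames(Xv))) colnames(Xv) <- model$feature_names
    val <- list(features = Xv[, keep, drop = FALSE], labels = validation$labels)
  }
  train_ri_model(X[, keep, drop = FALSE], labels, config, validation = val)
}

#' @describeIn train_ri_model Per-feature split-gain importance, one
#'   row per used feature.
#' @param x An `ri_model`.
#' @param ... Unused.
#' @export
tidy.ri_model <- function(x, ...) {
  x$importance
}

#' @describeIn train_ri_model One-row model summary.
#' @export
glance.ri_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_used_features = length(x$used_features),
    best_iteration = x$best_iteration,
    iterations = x$config$iterations,
    learning_rate = x$config$learning_rate,
    depth = x$config$depth,
    max_leaves = x$config$max_leaves,
    l2_leaf_reg = x$config$l2_leaf_reg,
    seed = x$config$random_seed
  )
}

#' Parity plot for an evaluation report
#'
#' Predicted versus true retention indices with the identity line and
#' the headline metrics in the subtitle.
#'
#' @param object An `ri_eval` from [evaluate_ri()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ri_eval <- function(object, ...) {
  d <- tibble::tibble(truth = attr(object, "truth"),
                      predicted = attr(object, "predictions"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$truth, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.6, color = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(experimental ~ r[i]), y = expression(predicted ~ r[i]),
      subtitle = sprintf("R² = %.2f, RMSE = %.0f, max error = %.0f (n = %d)",
                         object$r_squared, object$rmse, object$max_error, object$n)
    )
}

#' Feature-importance plot
#'
#' @param model An `ri_model`.
#' @param top_n Number of features to show, default 20.
#' @return A ggplot of split-gain importance.
#' @export
plot_importance <- function(model, top_n = 20) {
  d <- utils::head(dplyr::arrange(model$importance, dplyr::desc(.data$gain)), top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gain,
                                  y = stats::reorder(.data$feature, .data$gain))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "split-gain importance", y = NULL)
}
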