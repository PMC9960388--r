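#' Leverage of query points against a training design
#'
#' The leverage of a feature vector `x` against a training matrix `X`
#' is `h = x' (X'X)^{-1} x`, a Mahalanobis-like weighted distance of the
#' point from the bulk of the training design (for training rows it is
#' the diagonal of the hat matrix).  When `X'X` is rank-deficient —
#' routine for binary loss-bin features — the Moore-Penrose
#' pseudo-inverse is used, optionally stabilized by a small ridge.
#'
#' @param x Numeric vector (length p) or matrix (m x p) of query
#'   points, feature order matching `ad$feature_names`.
#' @param ad An `ad_model` from [fit_ad()].
#' @return Numeric vector of nonnegative leverages, one per query row.
#' @export
leverage <- function(x, ad) {
  stopifnot(inherits(ad, "ad_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(ad$gram_inverse)) {
    stop(sprintf("query has %d features; applicability domain expects %d",
                 ncol(x), ncol(ad$gram_inverse)))
  }
  if (!is.null(colnames(x)) && !is.null(ad$feature_names) &&
      !identical(colnames(x), ad$feature_names)) {
    if (!setequal(colnames(x), ad$feature_names)) {
      stop("query feature names do not match the applicability domain")
    }
    x <- x[, ad$feature_names, drop = FALSE]
  }
  rowSums((x %*% ad$gram_inverse) * x)
}

gram_inverse_of <- function(X, ridge = 0) {
  G <- crossprod(X)
  if (ridge > 0) G <- G + diag(ridge, ncol(G))
  qx <- qr(G)
  if (qx$rank < ncol(G)) {
    warning(sprintf("Gram matrix is rank-deficient (rank %d of %d); using pseudo-inverse",
                    qx$rank, ncol(G)))
    MASS::ginv(G)
  } else {
    tryCatch(chol2inv(chol(G)), error = function(e) MASS::ginv(G))
  }
}

#' Leave-one-out leverage threshold
#'
#' For each training row `i`, the leverage of `x_i` is computed against
#' the design with row `i` removed; the threshold `h*` is a percentile
#' (default the 95th) of that leave-one-out distribution, taken with
#' the linear-interpolation percentile definition ([stats::quantile()]
#' type 7).  For a full-column-rank design the Sherman-Morrison
#' identity gives the closed form `h_ii / (1 - h_ii)` from the ordinary
#' hat diagonal; rank-deficient designs fall back to explicit per-row
#' pseudo-inverses.
#'
#' @param X Training matrix, n x p, n >= 2.
#' @param percentile Percentile of the LOO distribution, default 95.
#' @param ridge Optional ridge added to the Gram diagonal (default 0).
#' @return List with `h_star` and `loo_leverages` (length n).
#' @export
loo_threshold <- function(X, percentile = 95, ridge = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2)
  G <- crossprod(X)
  if (ridge > 0) G <- G + diag(ridge, ncol(G))
  full_rank <- qr(G)$rank == ncol(G)
  if (full_rank) {
    Ginv <- tryCatch(chol2inv(chol(G)), error = function(e) MASS::ginv(G))
    h <- rowSums((X %*% Ginv) * X)
    loo <- ifelse(h < 1 - 1e-12, h / (1 - h), NA_real_)
    # h_ii = 1: the reduced design loses rank and the Sherman-Morrison form
    # diverges; score the row against the pseudo-inverse of the reduced Gram
    for (i in which(is.na(loo))) {
      Gi <- MASS::ginv(crossprod(X[-i, , drop = FALSE]))
      loo[i] <- drop(X[i, ] %*% Gi %*% X[i, ])
    }
  } else {
    warning("rank-deficient training Gram matrix; leave-one-out leverages via pseudo-inverse")
    loo <- vapply(seq_len(n), function(i) {
      Gi <- MASS::ginv(crossprod(X[-i, , drop = FALSE]) +
                         if (ridge > 0) diag(ridge, ncol(X)) else 0)
      drop(X[i, ] %*% Gi %*% X[i, ])
    }, 0)
  }
  fin <- loo[is.finite(loo)]
  if (!length(fin)) stop("all leave-one-out leverages are infinite")
  list(h_star = unname(stats::quantile(fin, percentile / 100, type = 7)),
       loo_leverages = unname(loo))
}

#' Fit a leverage-based applicability domain
#'
#' Stores the training design restricted to the features actually used
#' by the predictive model, its Gram inverse and the leave-one-out
#' percentile threshold `h*`.  A prediction for a new compound is
#' trusted only if its leverage does not exceed `h*` — i.e. the
#' compound is no further from the training bulk than the top tail of
#' the training compounds themselves under removal.
#'
#' @param X Training feature matrix (rows = training compounds/spectra,
#'   columns = the final model's features only).
#' @param percentile LOO percentile for `h*`; default 95.
#' @param ridge Optional ridge (default 0; pseudo-inverse handles rank
#'   deficiency without it).
#' @return An `ad_model`: list with `gram_inverse`, `h_star`,
#'   `loo_leverages`, `training_leverages`, `feature_names`, `n`, `p`,
#'   `rank`, `percentile`.
#' @export
fit_ad <- function(X, percentile = 95, ridge = 0) {
  X <- as.matrix(X)
  Ginv <- gram_inverse_of(X, ridge)
  ad <- structure(
    list(gram_inverse = Ginv, feature_names = colnames(X),
         n = nrow(X), p = ncol(X), rank = qr(crossprod(X))$rank,
         percentile = percentile),
    class = "ad_model"
  )
  ad$training_leverages <- leverage(X, ad)
  lt <- loo_threshold(X, percentile, ridge)
  ad$h_star <- lt$h_star
  ad$loo_leverages <- lt$loo_leverages
  ad
}

#' In-domain test for query points
#'
#' @param x Query vector or matrix (see [leverage()]).
#' @param ad An `ad_model`.
#' @return Tibble with `leverage` and `in_domain` (`TRUE` iff
#'   `leverage <= h_star`; the boundary is inclusive).
#' @export
in_domain <- function(x, ad) {
  h <- leverage(x, ad)
  tibble::tibble(leverage = h, in_domain = h <= ad$h_star)
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("<ad_model> n = %d, p = %d (rank %d), h* = %.4g (%gth LOO percentile)\n",
              x$n, x$p, x$rank, x$h_star, x$percentile))
  invisible(x)
}

#' @describeIn fit_ad One row per training observation with its hat
#'   leverage and leave-one-out leverage.
#' @param x An `ad_model`.
#' @param ... Unused.
#' @export
tidy.ad_model <- function(x, ...) {
  tibble::tibble(
    row = seq_len(x$n),
    leverage = unname(x$training_leverages),
    loo_leverage = x$loo_leverages
  )
}

#' @describeIn fit_ad One-row summary (`n`, `p`, `rank`, `h_star`,
#'   `percentile`).
#' @export
glance.ad_model <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, rank = x$rank,
                 h_star = x$h_star, percentile = x$percentile)
}

#' Leverage-distribution plot for an applicability domain
#'
#' Histogram of the training leave-one-out leverages with the `h*`
#' threshold marked; optionally overlays query leverages as a rug.
#'
#' @param object An `ad_model`.
#' @param query Optional numeric vector of query leverages.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ad_model <- function(object, query = NULL, ...) {
  d <- tidy.ad_model(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$loo_leverage)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$h_star, linetype = 2, color = "firebrick") +
    ggplot2::labs(x = "leave-one-out leverage", y = "training compounds",
                  title = sprintf("Applicability domain (h* = %.3g)", object$h_star))
  if (!is.null(query)) {
    p <- p + ggplot2::geom_rug(data = tibble::tibble(loo_leverage = query),
                               color = "steelblue", alpha = 0.6)
  }
  p
}
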