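#' Cumulative-neutral-loss mass grid
#'
#' The CNL feature space is a fixed grid of loss-mass bins from 0 to
#' 1000 Da with a step of 0.01 Da: 100,000 bins with centers at
#' `k * 0.01` Da for `k = 0 ... 99999`, each bin spanning +/- 5 mDa
#' around its center.  A loss is assigned to the bin whose center is
#' nearest (round-half-to-even on `mass / step`, the IEEE rounding rule
#' used by [round()]); losses of 1000 Da or more fall off-grid.
#'
#' @param min_mass,max_mass Grid limits in Da. Defaults 0 and 1000.
#' @param step Bin width in Da. Default 0.01.
#'
#' @return An object of class `cnl_grid`: a list with `min_mass`,
#'   `max_mass`, `step` and `n_bins`.
#' @examples
#' g <- cnl_grid()
#' g$n_bins
#' bin_index(18.004, g)  # same bin as 18.000
#' @export
cnl_grid <- function(min_mass = 0, max_mass = 1000, step = 0.01) {
  stopifnot(max_mass > min_mass, step > 0)
  n_bins <- (max_mass - min_mass) / step
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("grid span must be an exact multiple of `step`")
  }
  structure(
    list(min_mass = min_mass, max_mass = max_mass, step = step,
         n_bins = as.integer(round(n_bins))),
    class = "cnl_grid"
  )
}

#' @export
print.cnl_grid <- function(x, ...) {
  cat(sprintf("<cnl_grid> %g-%g Da, step %g Da, %d bins\n",
              x$min_mass, x$max_mass, x$step, x$n_bins))
  invisible(x)
}

#' Map a loss mass to its grid bin
#'
#' @param mass Numeric vector of loss masses in Da.
#' @param grid A [cnl_grid()].
#'
#' @return Integer vector of 0-based bin indices; `NA` for masses that
#'   fall off-grid (index < 0 or >= `n_bins`).
#' @export
bin_index <- function(mass, grid = cnl_grid()) {
  idx <- as.integer(round((mass - grid$min_mass) / grid$step))
  idx[idx < 0L | idx >= grid$n_bins] <- NA_integer_
  idx
}

#' Center mass of a grid bin
#'
#' @param index Integer vector of 0-based bin indices.
#' @inheritParams bin_index
#' @return Numeric vector of bin-center masses in Da.
#' @export
bin_center <- function(index, grid = cnl_grid()) {
  grid$min_mass + index * grid$step
}
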