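#' Read a molecular-descriptor table
#'
#' Expects a CSV whose first column is the compound identifier and whose
#' remaining columns are numeric descriptors (the layout descriptor
#' generators such as PaDEL export).  Computation of descriptors is out
#' of scope; this package consumes the tables.
#'
#' @param path CSV path.
#' @param compound_col Name of the identifier column; defaults to the
#'   first column.
#' @return A tibble with `compound_id` first, then numeric descriptor
#'   columns.
#' @export
read_descriptors <- function(path, compound_col = NULL) {
  t <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  compound_col <- compound_col %||% names(t)[1]
  t <- dplyr::rename(t, compound_id = dplyr::all_of(compound_col))
  t <- dplyr::relocate(t, "compound_id")
  if (anyDuplicated(t$compound_id)) {
    stop("duplicate compound ids in ", path)
  }
  dplyr::mutate(t, dplyr::across(-"compound_id", as.numeric))
}

#' Min-max scale descriptor columns
#'
#' Each descriptor column is mapped to `[0, 1]` by
#' `(x - min) / (max - min)` over the finite values of the fitting data.
#' Constant columns (max = min) map to 0 and are flagged.  The fitted
#' `(min, max)` pairs are recorded so exactly the same affine map can be
#' replayed on new compounds, whose values may legitimately land outside
#' `[0, 1]`.
#'
#' @param tbl A descriptor tibble (`compound_id` + numeric columns).
#'
#' @return A list with `table` (scaled tibble) and `params` (tibble
#'   `descriptor`, `min`, `max`, `constant`).
#' @export
minmax_scale <- function(tbl) {
  stopifnot(is.data.frame(tbl), "compound_id" %in% names(tbl))
  desc <- setdiff(names(tbl), "compound_id")
  rng <- purrr::map(tbl[desc], function(x) {
    if (!any(is.finite(x))) NULL else range(x[is.finite(x)])
  })
  bad <- desc[vapply(rng, is.null, TRUE)]
  if (length(bad)) {
    stop("descriptor column(s) with no finite values: ", paste(bad, collapse = ", "))
  }
  params <- tibble::tibble(
    descriptor = desc,
    min = unname(purrr::map_dbl(rng, 1)),
    max = unname(purrr::map_dbl(rng, 2))
  )
  params$constant <- params$max == params$min
  list(table = scale_with_params(tbl, params), params = params)
}

scale_with_params <- function(tbl, params) {
  scaled <- tbl
  for (k in seq_len(nrow(params))) {
    d <- params$descriptor[k]
    span <- params$max[k] - params$min[k]
    scaled[[d]] <- if (span == 0) {
      ifelse(is.finite(tbl[[d]]), 0, tbl[[d]])
    } else {
      (tbl[[d]] - params$min[k]) / span
    }
  }
  scaled
}

#' Replicate-stability descriptor curation
#'
#' Descriptor calculations (3D optimizations in particular) are not
#' perfectly reproducible, so the same compound set is computed in
#' replicate (typically triplicate) and only descriptors that are stable
#' across replicates are kept.  All replicates are first min-max scaled
#' jointly per descriptor so variances are comparable across
#' descriptors; then, for each descriptor, the across-replicate sample
#' variance is computed per compound and aggregated over compounds
#' (maximum by default, mean optionally); the descriptor is kept iff the
#' aggregate is strictly below `threshold` (default 0.01 on the scaled
#' scale).
#'
#' Compounds with any non-finite descriptor value in any replicate
#' (failed/non-converged calculations) are dropped row-wise before
#' curation and listed in the report, never imputed.
#'
#' @param replicates List of >= 2 descriptor tibbles sharing compound
#'   ids and descriptor columns.
#' @param threshold Strict upper variance bound for keeping a
#'   descriptor. Default 0.01.
#' @param aggregate How per-compound replicate variances are pooled per
#'   descriptor: `"max"` (default, strictest) or `"mean"`.
#'
#' @return A `curation_report`: list with `kept` (character),
#'   `dropped_unstable` (tibble `descriptor`, `variance`),
#'   `dropped_nonfinite` (character), `dropped_compounds` (character),
#'   `scaling_params` (as [minmax_scale()]), `threshold`, `aggregate`.
#' @export
stability_filter <- function(replicates, threshold = 0.01,
                             aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(replicates), length(replicates) >= 2)
  desc <- setdiff(names(replicates[[1]]), "compound_id")
  ids <- sort(replicates[[1]]$compound_id)
  for (r in replicates[-1]) {
    if (!setequal(setdiff(names(r), "compound_id"), desc)) {
      stop("replicates disagree on descriptor columns")
    }
    if (!setequal(r$compound_id, ids)) {
      diff <- c(setdiff(ids, r$compound_id), setdiff(r$compound_id, ids))
      stop("replicates disagree on compounds: ", paste(diff, collapse = ", "))
    }
  }
  replicates <- purrr::map(replicates, ~ .x[match(ids, .x$compound_id), c("compound_id", desc)])

  # drop non-converged compounds (any non-finite value in any replicate)
  finite_ok <- Reduce(`&`, purrr::map(replicates, function(r) {
    rowSums(!is.finite(as.matrix(r[desc]))) == 0
  }))
  dropped_compounds <- ids[!finite_ok]
  replicates <- purrr::map(replicates, ~ .x[finite_ok, , drop = FALSE])
  if (nrow(replicates[[1]]) < 2) stop("fewer than 2 converged compounds")

  # all-missing-after-drop columns cannot be scaled
  stacked <- dplyr::bind_rows(replicates)
  sc <- minmax_scale(stacked)
  n_rep <- length(replicates)
  n_cmp <- nrow(replicates[[1]])
  scaled_reps <- split(sc$table, rep(seq_len(n_rep), each = n_cmp))

  agg_var <- vapply(desc, function(d) {
    vals <- vapply(scaled_reps, function(r) r[[d]], numeric(n_cmp))  # cmp x rep
    per_cmp <- apply(vals, 1, stats::var)                            # sample (n-1) variance
    if (aggregate == "max") max(per_cmp) else mean(per_cmp)
  }, 0)

  kept <- desc[agg_var < threshold]
  dropped <- desc[agg_var >= threshold]
  structure(
    list(
      kept = kept,
      dropped_unstable = tibble::tibble(descriptor = dropped,
                                        variance = unname(agg_var[dropped])),
      dropped_nonfinite = character(0),
      dropped_compounds = dropped_compounds,
      scaling_params = sc$params[sc$params$descriptor %in% desc, ],
      variances = tibble::tibble(descriptor = desc, variance = unname(agg_var)),
      threshold = threshold,
      aggregate = aggregate
    ),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> kept %d / %d descriptors (threshold %g, %s aggregation)\n",
              length(x$kept), length(x$kept) + nrow(x$dropped_unstable) +
                length(x$dropped_nonfinite), x$threshold, x$aggregate))
  if (length(x$dropped_compounds)) {
    cat(sprintf("  %d non-converged compound(s) dropped\n", length(x$dropped_compounds)))
  }
  invisible(x)
}

#' Apply a curation report to a descriptor table
#'
#' Restricts `tbl` to the report's kept descriptors (in report order)
#' and replays the stored min-max scaling.  New compounds may fall
#' outside the fitted range; values are not clipped.  Rows with any
#' non-finite value among kept descriptors are dropped and reported via
#' the `dropped_compounds` attribute.
#'
#' @param tbl A raw (unscaled) descriptor tibble containing every kept
#'   column.
#' @param report A `curation_report` from [stability_filter()].
#' @return Scaled tibble `compound_id` + kept descriptors; attribute
#'   `dropped_compounds`.
#' @export
apply_curation <- function(tbl, report) {
  stopifnot(inherits(report, "curation_report"))
  missing <- setdiff(report$kept, names(tbl))
  if (length(missing)) {
    stop("table is missing kept descriptor column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- tbl[, c("compound_id", report$kept)]
  ok <- rowSums(!is.finite(as.matrix(out[report$kept]))) == 0
  dropped <- out$compound_id[!ok]
  out <- out[ok, , drop = FALSE]
  params <- report$scaling_params[match(report$kept, report$scaling_params$descriptor), ]
  out <- scale_with_params(out, params)
  attr(out, "dropped_compounds") <- dropped
  out
}

#' @describeIn stability_filter Tidy per-descriptor curation outcome:
#'   one row per descriptor with its aggregate replicate variance and
#'   status (`kept` / `dropped_unstable`).
#' @param x A `curation_report`.
#' @param ... Unused.
#' @export
tidy.curation_report <- function(x, ...) {
  dplyr::mutate(
    x$variances,
    status = ifelse(.data$descriptor %in% x$kept, "kept", "dropped_unstable")
  )
}
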