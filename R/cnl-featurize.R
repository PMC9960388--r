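#' Compute cumulative neutral losses for each spectrum
#'
#' A cumulative neutral loss (CNL) is the mass difference between the
#' precursor ion and one fragment ion, `precursor_mz - fragment_mz`,
#' each fragment treated independently.  Fragments heavier than the
#' precursor are physically impossible losses; they are excluded and
#' counted per spectrum.  A loss of exactly 0 Da (surviving precursor)
#' is valid.
#'
#' @param spectra A spectra tibble from [read_msp()]/[read_mgf()].
#'
#' @return The input tibble with `fragments`/`meta` replaced by a
#'   `losses` list-column (numeric Da, in fragment order) and an
#'   `n_excluded` column counting above-precursor fragments.  Spectra
#'   with an empty fragment list raise an error — an unusable spectrum
#'   must be dropped by the reader, not silently featurized.
#' @examples
#' sp <- tibble::tibble(
#'   spectrum_id = "s1", compound_id = NA_character_, precursor_mz = 200,
#'   adduct = NA_character_,
#'   fragments = list(tibble::tibble(mz = c(182, 100), intensity = c(100, 50))),
#'   meta = list(list())
#' )
#' compute_cnls(sp)$losses[[1]]  # 18, 100
#' @export
compute_cnls <- function(spectra) {
  stopifnot(is.data.frame(spectra))
  n_frag <- vapply(spectra$fragments, nrow, 0L)
  if (any(n_frag == 0L)) {
    stop("spectra without fragments cannot be featurized: ",
         paste(spectra$spectrum_id[n_frag == 0L], collapse = ", "))
  }
  res <- purrr::map2(spectra$fragments, spectra$precursor_mz, function(fr, pmz) {
    loss <- pmz - fr$mz
    keep <- loss >= 0
    list(losses = loss[keep], n_excluded = sum(!keep))
  })
  dplyr::mutate(
    dplyr::select(spectra, -dplyr::any_of(c("fragments", "meta"))),
    losses = purrr::map(res, "losses"),
    n_excluded = purrr::map_int(res, ~ as.integer(.x$n_excluded))
  )
}

#' Encode one loss set as a ternary grid vector
#'
#' Produces the length-`n_bins` ternary encoding of a single spectrum's
#' losses: 1 where at least one loss falls in the bin (+/- 5 mDa around
#' the bin center at the default grid), -1 for every bin beyond the
#' precursor's own bin (a loss there would require a fragment heavier
#' than the precursor — encoding impossibility separately from absence),
#' 0 elsewhere.  Losses at or above the grid maximum are off-grid and
#' dropped with a warning.
#'
#' Mostly a reference/diagnostic tool: [build_cnl_matrix()] produces the
#' same encoding in sparse form for whole spectra sets.
#'
#' @param losses Numeric vector of loss masses (Da), all `>= 0`.
#' @param precursor_mz Precursor ion m/z (Da).
#' @param grid A [cnl_grid()].
#'
#' @return Integer vector of length `grid$n_bins` with values in
#'   `{-1, 0, 1}`, plus attribute `n_off_grid`.
#' @export
encode_row <- function(losses, precursor_mz, grid = cnl_grid()) {
  stopifnot(is.numeric(losses), all(losses >= 0), precursor_mz > 0)
  v <- integer(grid$n_bins)
  p_bin <- as.integer(round((precursor_mz - grid$min_mass) / grid$step))
  if (p_bin + 1L < grid$n_bins) v[(p_bin + 2L):grid$n_bins] <- -1L  # 1-based
  idx <- bin_index(losses, grid)
  off <- sum(is.na(idx))
  if (off > 0) {
    warning(sprintf("%d loss(es) at/above %g Da fall off-grid and were dropped",
                    off, grid$max_mass))
  }
  v[idx[!is.na(idx)] + 1L] <- 1L
  attr(v, "n_off_grid") <- off
  v
}

#' Build the sparse ternary CNL feature matrix
#'
#' One row per spectrum (duplicates preserved, input order kept), and
#' `n_bins + 1` columns: the ternary loss bins `cnl_00000 ...`, then the
#' continuous precursor-ion-mass feature `precursor_mz`.  Only the 1
#' entries, the -1 impossibility region and the precursor mass are
#' stored (a `Matrix::dgCMatrix`); per row the -1 region is the single
#' run of bins strictly beyond the precursor's bin, so it is
#' reconstructed from one breakpoint.
#'
#' @param spectra A spectra tibble ([read_msp()] shape).
#' @param grid A [cnl_grid()].
#' @param quiet Suppress the off-grid-loss warning count.
#'
#' @return An object of class `cnl_matrix`: list with
#'   \describe{
#'     \item{matrix}{sparse `dgCMatrix`, spectra x (bins + precursor).}
#'     \item{rows}{tibble `spectrum_id`, `compound_id`, `precursor_mz`,
#'       `n_losses`, `n_excluded`, `n_off_grid` aligned with matrix rows.}
#'     \item{grid}{the grid used.}
#'   }
#' @export
build_cnl_matrix <- function(spectra, grid = cnl_grid(), quiet = FALSE) {
  cn <- compute_cnls(spectra)
  n <- nrow(cn)
  nb <- grid$n_bins

  p_bin <- as.integer(round((cn$precursor_mz - grid$min_mass) / grid$step))
  per_row <- purrr::map2(cn$losses, p_bin, function(l, pb) {
    idx <- as.integer(round((l - grid$min_mass) / grid$step))
    off <- sum(idx >= nb)
    ones <- unique(idx[idx >= 0L & idx < nb])
    neg_from <- pb + 1L
    neg <- if (neg_from < nb) neg_from:(nb - 1L) else integer(0)
    list(ones = ones, neg = neg, off = off)
  })
  ones <- purrr::map(per_row, "ones")
  negs <- purrr::map(per_row, "neg")
  n_off <- purrr::map_int(per_row, ~ as.integer(.x$off))
  if (!quiet && sum(n_off) > 0) {
    warning(sprintf("%d loss(es) across %d spectra fell off-grid (>= %g Da)",
                    sum(n_off), sum(n_off > 0), grid$max_mass))
  }

  len1 <- lengths(ones); len2 <- lengths(negs)
  i <- rep.int(seq_len(n), len1 + len2 + 1L)
  j <- unlist(purrr::pmap(list(ones, negs), function(o, g) c(o, g, nb)), use.names = FALSE) + 1L
  x <- unlist(purrr::pmap(list(len1, len2, cn$precursor_mz),
                          function(a, b, p) c(rep.int(1, a), rep.int(-1, b), p)),
              use.names = FALSE)
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, nb + 1L))
  colnames(m) <- c(sprintf("cnl_%05d", 0:(nb - 1L)), "precursor_mz")
  rownames(m) <- cn$spectrum_id

  structure(
    list(
      matrix = m,
      rows = tibble::tibble(
        spectrum_id = cn$spectrum_id,
        compound_id = cn$compound_id,
        precursor_mz = cn$precursor_mz,
        n_losses = lengths(cn$losses),
        n_excluded = cn$n_excluded,
        n_off_grid = n_off
      ),
      grid = grid
    ),
    class = "cnl_matrix"
  )
}

#' @export
print.cnl_matrix <- function(x, ...) {
  cat(sprintf("<cnl_matrix> %d spectra x %d features (%d loss bins + precursor mass)\n",
              nrow(x$matrix), ncol(x$matrix), x$grid$n_bins))
  cat(sprintf("  stored entries: %d (1s: %d)\n", length(x$matrix@x),
              sum(x$matrix@x == 1)))
  invisible(x)
}

#' Export a CNL matrix to MatrixMarket + column metadata
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format), `rows.csv`
#' (per-spectrum metadata) and `columns.csv` (bin center masses and a
#' flag for the precursor-mass column) under `dir`.
#'
#' @param x A `cnl_matrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cnl_matrix <- function(x, dir) {
  stopifnot(inherits(x, "cnl_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$matrix, file.path(dir, "matrix.mtx"))
  readr::write_csv(x$rows, file.path(dir, "rows.csv"))
  cols <- tibble::tibble(
    column = seq_len(ncol(x$matrix)),
    name = colnames(x$matrix),
    bin_center_da = c(bin_center(0:(x$grid$n_bins - 1L), x$grid), NA_real_),
    is_precursor_mass = c(rep(FALSE, x$grid$n_bins), TRUE)
  )
  readr::write_csv(cols, file.path(dir, "columns.csv"))
  invisible(dir)
}
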