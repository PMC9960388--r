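test_that("the loss grid is 100,000 bins of 0.01 Da", {
  g <- cnl_grid()
  expect_identical(g$n_bins, 100000L)
  expect_equal((g$max_mass - g$min_mass) / g$step, g$n_bins)
  expect_equal(bin_center(1800, g), 18.00)
})

test_that("losses within 5 mDa of a common center share a bin", {
  g <- cnl_grid()
  expect_identical(bin_index(18.000, g), 1800L)
  expect_identical(bin_index(18.004, g), 1800L)
  expect_identical(bin_index(17.9961, g), 1800L)
  # property: center +/- (<5 mDa) never changes the bin
  set.seed(11)
  centers <- sample(0:99999, 200) * 0.01
  eps <- runif(200, -0.0049, 0.0049)
  expect_identical(bin_index(centers + eps, g), bin_index(centers, g))
})

test_that("cumulative neutral losses are precursor minus fragment, impossible losses excluded", {
  sp <- make_spectra(
    c(200.0, 300.0, 200.0),
    list(c(182.0, 100.0), c(282.0), c(210.0, 150.0))
  )
  cn <- compute_cnls(sp)
  expect_equal(cn$losses[[1]], c(18.0, 100.0))
  expect_equal(cn$losses[[2]], 18.0)           # water loss collapses to one variable
  expect_equal(cn$losses[[3]], 50.0)           # 210 > precursor: excluded
  expect_equal(cn$n_excluded, c(0L, 0L, 1L))
  empty <- make_spectra(100, list(numeric(0)))
  expect_error(compute_cnls(empty), "without fragments")
})

test_that("ternary encoding: 1 at loss bins, -1 beyond the precursor, 0 elsewhere", {
  g <- cnl_grid()
  v <- encode_row(c(18.000, 18.004, 100.0), precursor_mz = 250.00, grid = g)
  expect_setequal(unique(v), c(-1L, 0L, 1L))
  expect_identical(which(v == 1L) - 1L, c(1800L, 10000L))
  # brute-force oracle over all bin centers
  centers <- (0:99999) * 0.01
  expect_identical(sum(v == -1L), sum(centers > 250.00))
  expect_identical(sum(v == -1L), 100000L - 25001L)
  # no bin is both 1 and -1; losses can never land in the -1 region
  expect_true(all(which(v == 1L) < min(which(v == -1L))))
  # empty loss set: no 1s, bins at/below precursor all 0
  v0 <- encode_row(numeric(0), precursor_mz = 500.0, grid = g)
  expect_identical(sum(v0 == 1L), 0L)
  expect_true(all(v0[centers <= 500.0] == 0L))
})

test_that("the -1 region depends only on the precursor, never on fragments", {
  g <- cnl_grid()
  a <- encode_row(c(18.011), 320.55, g)
  b <- encode_row(c(120.0, 56.063, 0), 320.55, g)
  expect_identical(which(a == -1L), which(b == -1L))
})

test_that("off-grid losses are dropped with a counted warning", {
  sp <- make_spectra(1200, list(c(100, 1190)))   # losses 1100 and 10
  expect_warning(cm <- build_cnl_matrix(sp), "off-grid")
  expect_equal(cm$rows$n_off_grid, 1L)
  expect_warning(v <- encode_row(c(1100, 10), 1200), "off-grid")
  expect_identical(attr(v, "n_off_grid"), 1L)
})

test_that("encoding is a pure function of the spectrum", {
  sp <- cached_small_world()$spectra[1:5, ]
  m1 <- build_cnl_matrix(sp)$matrix
  m2 <- build_cnl_matrix(sp)$matrix
  expect_identical(m1, m2)
})

test_that("feature matrix has one row per spectrum, bins then precursor mass", {
  sp <- make_spectra(
    c(200.0, 200.0, 410.5),
    list(c(182.0, 100.0), c(182.0, 100.0),
         c(392.489, 354.53, 310.45, 255.5, 110.07)),
    ids = c("a", "b", "c")
  )
  cm <- build_cnl_matrix(sp)
  expect_equal(dim(cm$matrix), c(3L, 100001L))
  expect_equal(colnames(cm$matrix)[c(1, 100001)], c("cnl_00000", "precursor_mz"))
  expect_equal(unname(cm$matrix[, "precursor_mz"]), sp$precursor_mz)
  # byte-identical spectra give identical rows (duplicates preserved)
  expect_identical(cm$matrix[1, ], cm$matrix[2, ])
  # 5 fragments in distinct bins -> five 1s, checked against an independent oracle
  oracle_bins <- unique(round((410.5 - sp$fragments[[3]]$mz) / 0.01))
  expect_equal(sum(cm$matrix[3, ] == 1), length(oracle_bins))
  expect_setequal(which(cm$matrix[3, seq_len(100000)] == 1) - 1L, oracle_bins)
  # dense reference encoder agrees with the sparse assembly
  v <- encode_row(410.5 - sp$fragments[[3]]$mz, 410.5)
  expect_equal(unname(cm$matrix[3, seq_len(100000)]), as.numeric(v))
})

test_that("matrix export round-trips through MatrixMarket", {
  sp <- make_spectra(c(200, 350.2), list(c(182, 100), c(332.19, 195.2)))
  cm <- build_cnl_matrix(sp)
  d <- tempfile()
  export_cnl_matrix(cm, d)
  back <- Matrix::readMM(file.path(d, "matrix.mtx"))
  expect_equal(as.matrix(back), as.matrix(cm$matrix), ignore_attr = TRUE)
  cols <- readr::read_csv(file.path(d, "columns.csv"), show_col_types = FALSE)
  expect_equal(nrow(cols), 100001L)
  expect_equal(cols$bin_center_da[1801], 18.00)
  expect_true(cols$is_precursor_mass[100001])
})
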