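desc_tbl <- function(...) {
  tibble::tibble(compound_id = sprintf("c%02d", seq_along(..1)), ...)
}

test_that("min-max scaling maps fitted extremes to 0 and 1", {
  t <- desc_tbl(a = c(0, 5, 10), b = c(3, 3, 3), c = c(-2, 0, 2))
  sc <- minmax_scale(t)
  expect_equal(sc$table$a, c(0, 0.5, 1), tolerance = 1e-12)
  expect_equal(sc$table$b, c(0, 0, 0))   # degenerate range
  expect_equal(sc$table$c, c(0, 0.5, 1), tolerance = 1e-12)
  expect_true(sc$params$constant[sc$params$descriptor == "b"])
  expect_error(minmax_scale(desc_tbl(a = c(1, 2, 3), bad = rep(NA_real_, 3))),
               "no finite values")
})

test_that("replicate variance filter keeps stable, drops unstable, strictly below threshold", {
  # descriptor 'stable' identical across replicates; 'wild' takes scaled values
  # 0/1/0 for compound c01 -> sample variance 1/3
  reps <- list(
    desc_tbl(stable = c(1, 2, 4), wild = c(0, 5, 5)),
    desc_tbl(stable = c(1, 2, 4), wild = c(10, 5, 5)),
    desc_tbl(stable = c(1, 2, 4), wild = c(0, 5, 5))
  )
  rep_out <- stability_filter(reps, threshold = 0.01)
  expect_identical(rep_out$kept, "stable")
  expect_equal(rep_out$dropped_unstable$descriptor, "wild")
  expect_equal(rep_out$dropped_unstable$variance, 1 / 3, tolerance = 1e-12)
  # partition property
  expect_setequal(c(rep_out$kept, rep_out$dropped_unstable$descriptor),
                  c("stable", "wild"))

  # a variance exactly at the threshold is dropped: the bound is strict
  at <- stability_filter(reps, threshold = 1 / 3)
  expect_true("wild" %in% at$dropped_unstable$descriptor)
  above <- stability_filter(reps, threshold = 1 / 3 + 1e-9)
  expect_true("wild" %in% above$kept)
})

test_that("raising the threshold never shrinks the kept set", {
  w <- cached_small_world()
  lo <- stability_filter(w$descriptor_replicates, threshold = 0.005)
  hi <- stability_filter(w$descriptor_replicates, threshold = 0.05)
  expect_true(all(lo$kept %in% hi$kept))
})

test_that("replicates must agree on compounds and descriptors", {
  r1 <- desc_tbl(a = c(1, 2, 3))
  r2 <- r1; r2$compound_id[3] <- "zz"
  expect_error(stability_filter(list(r1, r2)), "zz")
  r3 <- desc_tbl(b = c(1, 2, 3))
  expect_error(stability_filter(list(r1, r3)), "descriptor columns")
})

test_that("non-converged compounds are dropped row-wise and reported", {
  r <- desc_tbl(a = c(1, 2, 3, 4), b = c(0, 1, 2, 3))
  r_bad <- r; r_bad$a[2] <- NaN
  rep_out <- stability_filter(list(r_bad, r, r), threshold = 0.5)
  expect_identical(rep_out$dropped_compounds, "c02")
})

test_that("apply_curation replays the stored scaling without clipping", {
  reps <- list(desc_tbl(a = c(0, 5, 10), b = c(1, 2, 3)),
               desc_tbl(a = c(0, 5, 10), b = c(1, 2, 3)))
  rep_out <- stability_filter(reps)
  new <- tibble::tibble(compound_id = "x", a = 20, b = 2)
  out <- apply_curation(new, rep_out)
  expect_equal(out$a, 2.0)            # beyond the fitted range, not clipped
  # idempotence: the fitting replicate scales to the same values again
  again <- apply_curation(reps[[1]], rep_out)
  expect_equal(again$a, c(0, 0.5, 1), tolerance = 1e-12)
  expect_error(apply_curation(new[, c("compound_id", "a")], rep_out), "missing kept")
})

test_that("tidy() on a curation report partitions every descriptor", {
  w <- cached_small_world()
  rep_out <- stability_filter(w$descriptor_replicates)
  td <- tidy(rep_out)
  expect_setequal(td$descriptor,
                  setdiff(names(w$descriptor_replicates[[1]]), "compound_id"))
  expect_setequal(unique(td$status), c("kept", "dropped_unstable"))
})
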