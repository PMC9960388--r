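# Hand-built spectra tibble with known losses.
make_spectra <- function(precursors, frag_lists, ids = NULL, compound_ids = NULL) {
  n <- length(precursors)
  ids <- ids %||% sprintf("spec%02d", seq_len(n))
  compound_ids <- compound_ids %||% rep(NA_character_, n)
  tibble::tibble(
    spectrum_id = ids,
    compound_id = compound_ids,
    precursor_mz = precursors,
    adduct = NA_character_,
    fragments = lapply(frag_lists, function(mz) {
      tibble::tibble(mz = mz, intensity = rep(100, length(mz)))
    }),
    meta = replicate(n, list(), simplify = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_text_fixture <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# Session-level cache: the 300-compound worlds and their two-stage runs are
# shared between the end-to-end tests so they are computed once.
.cache <- new.env(parent = emptyenv())

cached_world <- function(seed = 7, ...) {
  key <- paste0("world_", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- generate_world(seed = seed, ...)
  .cache[[key]]
}

cached_small_world <- function() {
  if (is.null(.cache$small_world)) {
    .cache$small_world <- generate_world(
      n_compounds = 60, n_experimental = 30, n_experimental_spectra = 14,
      n_ood = 5, seed = 42)
  }
  .cache$small_world
}

# Keep only the light-weight pieces of each end-to-end run: a full result
# retains the ~100k-column sparse matrix and five of those do not fit in
# memory at once.
cached_run <- function(seed) {
  key <- paste0("run_", seed)
  if (is.null(.cache[[key]])) {
    w <- cached_world(seed)
    res <- suppressWarnings(suppressMessages(
      run_two_stage(w$descriptor_replicates, w$ri_labels,
                    w$corpus_descriptors, w$spectra, seed = seed,
                    quiet = TRUE)))
    .cache[[key]] <- list(
      glance = glance(res),
      evaluations = tidy(res),
      used_features = res$cnl_model$used_features,
      outside_domain = attr(res$pseudo_labels, "outside_domain"),
      manifest = res$manifest
    )
    rm(res); gc(verbose = FALSE)
  }
  .cache[[key]]
}
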