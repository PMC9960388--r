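#' AD-gated pseudo-labeling of a descriptor corpus
#'
#' Predicts retention indices for a curated descriptor table with the
#' descriptor model, but only emits a record for compounds inside the
#' model's applicability domain; out-of-domain compounds are listed
#' with their leverage in the `outside_domain` attribute and counted in
#' a message.  Experimental labels are never produced here — every
#' record carries `provenance = "predicted"`.
#'
#' @param model The descriptor `ri_model` (typically the top-40 refit).
#' @param ad The matching `ad_model`, fitted on the model's features.
#' @param descriptors Curated descriptor tibble ([apply_curation()]
#'   with the model's curation report).
#' @param quiet Suppress the gate-count message.
#' @return Tibble of retention-index records: `compound_id`, `r_i`,
#'   `provenance`, `leverage`; attribute `outside_domain` is a tibble of
#'   the rejected compounds.
#' @export
pseudo_label <- function(model, ad, descriptors, quiet = FALSE) {
  stopifnot(inherits(model, "ri_model"), inherits(ad, "ad_model"))
  missing <- setdiff(model$feature_names, names(descriptors))
  if (length(missing)) {
    stop("descriptor table lacks model feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  X <- as.matrix(descriptors[, model$feature_names, drop = FALSE])
  dom <- in_domain(X, ad)
  keep <- dom$in_domain
  out <- tibble::tibble(
    compound_id = descriptors$compound_id[keep],
    r_i = if (any(keep)) predict(model, X[keep, , drop = FALSE]) else numeric(0),
    provenance = "predicted",
    leverage = dom$leverage[keep]
  )
  attr(out, "outside_domain") <- tibble::tibble(
    compound_id = descriptors$compound_id[!keep],
    leverage = dom$leverage[!keep]
  )
  if (!quiet) {
    message(sprintf("pseudo-labeled %d / %d compounds (%d outside the applicability domain)",
                    sum(keep), length(keep), sum(!keep)))
  }
  out
}

#' Assemble the CNL training and test sets
#'
#' Combines pseudo-labeled corpus records with experimentally labeled
#' records, expands each record to one entry per spectrum (redundant
#' spectra stay separate entries), and splits into three disjoint sets:
#' the training set (`corpus_train_fraction` of the corpus, default
#' 85%, plus `experimental_train_fraction` of the experimental
#' compounds, default 30%), a held-out corpus test set and a withheld
#' experimental test set whose compounds are wholly absent from
#' training.  Splits are stratified on retention-index classes and
#' grouped by compound, so no compound's spectra leak across the
#' boundary.  Experimental records keep their measured label; they are
#' never overwritten by predictions.
#'
#' @param corpus_records Tibble (`compound_id`, `r_i`,
#'   `provenance = "predicted"`), e.g. from [pseudo_label()].
#' @param experimental_records Tibble (`compound_id`, `r_i`) of
#'   measured labels; `provenance` filled as `"experimental"`.
#' @param spectra Spectra tibble ([read_msp()] shape) covering both
#'   record sets; records without any spectrum are dropped and listed.
#' @param corpus_train_fraction,experimental_train_fraction Split
#'   fractions, defaults 0.85 and 0.30.
#' @param seed Split seed.
#' @param group_by_compound Keep all spectra of a compound on one side
#'   (default `TRUE`); `FALSE` gives a spectrum-level split of the
#'   corpus for comparison.
#' @return List of tibbles `train`, `corpus_test`, `experimental_test`
#'   (columns `spectrum_id`, `compound_id`, `r_i`, `provenance`), plus
#'   `unmatched` (records with no spectrum).
#' @export
assemble_cnl_training <- function(corpus_records, experimental_records, spectra,
                                  corpus_train_fraction = 0.85,
                                  experimental_train_fraction = 0.30,
                                  seed = 1, group_by_compound = TRUE) {
  stopifnot(corpus_train_fraction > 0, corpus_train_fraction < 1,
            experimental_train_fraction > 0, experimental_train_fraction < 1)
  corpus_records <- dplyr::mutate(
    corpus_records, provenance = dplyr::coalesce(.data$provenance, "predicted"))
  experimental_records <- dplyr::mutate(
    dplyr::select(experimental_records, "compound_id", "r_i"),
    provenance = "experimental")
  overlap <- intersect(corpus_records$compound_id, experimental_records$compound_id)
  if (length(overlap)) {
    # experimental labels win; the corpus copy of the compound is discarded
    corpus_records <- dplyr::filter(corpus_records, !.data$compound_id %in% overlap)
  }

  spec_map <- dplyr::select(spectra, "spectrum_id", "compound_id")
  expand <- function(records) {
    dplyr::inner_join(dplyr::select(records, "compound_id", "r_i", "provenance"),
                      spec_map, by = "compound_id")
  }
  corpus_entries <- expand(corpus_records)
  exp_entries <- expand(experimental_records)
  unmatched <- dplyr::bind_rows(
    dplyr::anti_join(corpus_records, spec_map, by = "compound_id"),
    dplyr::anti_join(experimental_records, spec_map, by = "compound_id")
  )
  if (nrow(unmatched)) {
    message(sprintf("%d record(s) had no matching spectrum and were dropped", nrow(unmatched)))
  }

  split_entries <- function(entries, fraction, seed) {
    grp <- if (group_by_compound) entries$compound_id else seq_len(nrow(entries))
    stratified_split(entries$r_i, train_fraction = fraction, seed = seed, groups = grp)
  }
  sc <- split_entries(corpus_entries, corpus_train_fraction, seed)
  se <- split_entries(exp_entries, experimental_train_fraction, seed + 1L)

  if (1 - corpus_train_fraction < 0.02 || 1 - experimental_train_fraction < 0.02) {
    warning("train fractions leave a near-empty test set")
  }
  list(
    train = dplyr::bind_rows(corpus_entries[sc$train, ], exp_entries[se$train, ]),
    corpus_test = corpus_entries[sc$test, ],
    experimental_test = exp_entries[se$test, ],
    unmatched = unmatched
  )
}

#' Run the two-stage retention-index workflow
#'
#' End-to-end orchestration: (1) curate the replicate descriptor tables
#' and train the descriptor QSRR model on the experimentally labeled
#' compounds (stratified 85/15 split, early stopping on an inner
#' validation slice, refit on the top `top_k` descriptors); (2) fit the
#' leverage applicability domain on the refit's features and
#' pseudo-label the corpus descriptors inside it; (3) featurize all
#' spectra on the CNL grid, assemble the combined training set
#' (85% of the corpus entries + 30% of the experimental entries) and
#' train the CNL model, then evaluate on the held-out corpus entries
#' (against their pseudo-labels) and on the withheld experimental
#' entries (against measured values).
#'
#' Every stage derives its seed deterministically from `seed`; rerunning
#' with the same inputs and seed reproduces every split, model and
#' report.
#'
#' @param descriptor_replicates List of >= 2 raw descriptor tibbles for
#'   the experimentally labeled compounds (replicate calculations).
#' @param ri_labels Tibble `compound_id`, `r_i` of measured retention
#'   indices for (a superset of) those compounds.
#' @param corpus_descriptors Raw descriptor tibble for the unlabeled
#'   corpus compounds (single calculation).
#' @param spectra Spectra tibble covering corpus compounds and the
#'   experimentally labeled compounds that have spectra.
#' @param seed Pipeline seed (integer).
#' @param top_k Descriptors kept in the final descriptor model,
#'   default 40.
#' @param descriptor_train_fraction Descriptor-model train fraction,
#'   default 0.85.
#' @param corpus_train_fraction,experimental_train_fraction CNL
#'   assembly fractions, defaults 0.85 / 0.30.
#' @param variance_threshold Replicate-stability threshold, default 0.01.
#' @param ad_percentile LOO percentile for the applicability domains,
#'   default 95.
#' @param grid CNL grid, default [cnl_grid()].
#' @param group_by_compound See [assemble_cnl_training()].
#' @param quiet Suppress stage messages.
#' @return A `ri_two_stage` list: `curation`, `descriptor_model`,
#'   `descriptor_ad`, `cnl_model`, `cnl_ad`, `pseudo_labels`,
#'   `assembly`, `evaluations` (tibble of the five reports:
#'   descriptor train/test, CNL train/corpus-test/experimental-test),
#'   `manifest` (counts at every gate), `seed`.
#' @export
run_two_stage <- function(descriptor_replicates, ri_labels, corpus_descriptors,
                          spectra, seed = 1, top_k = 40,
                          descriptor_train_fraction = 0.85,
                          corpus_train_fraction = 0.85,
                          experimental_train_fraction = 0.30,
                          variance_threshold = 0.01, ad_percentile = 95,
                          grid = cnl_grid(), group_by_compound = TRUE,
                          quiet = FALSE) {
  seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("two-stage pipeline failed at stage '%s': %s",
                   name, conditionMessage(e)), call. = FALSE)
    })
  }

  # -- stage 1: descriptor curation -----------------------------------------
  curation <- stage("curation",
                    stability_filter(descriptor_replicates, threshold = variance_threshold))
  desc <- stage("curation", apply_curation(descriptor_replicates[[1]], curation))
  labeled <- dplyr::inner_join(ri_labels, desc, by = "compound_id")
  say("stage 1: %d curated descriptors, %d labeled compounds",
      length(curation$kept), nrow(labeled))

  # -- stage 2: descriptor model --------------------------------------------
  desc_eval <- stage("descriptor_model", {
    sp <- stratified_split(labeled$r_i, descriptor_train_fraction, seed = seed + 11L)
    tr <- labeled[sp$train, ]; te <- labeled[sp$test, ]
    inner <- stratified_split(tr$r_i, 0.85, seed = seed + 12L)
    cfg <- descriptor_preset(random_seed = seed + 13L)
    Xcols <- curation$kept
    fit0 <- train_ri_model(
      tr[inner$train, Xcols], tr$r_i[inner$train], cfg,
      validation = list(features = tr[inner$test, Xcols],
                        labels = tr$r_i[inner$test]))
    fit <- refit_top_features(
      fit0, tr[inner$train, Xcols], tr$r_i[inner$train],
      validation = list(features = tr[inner$test, Xcols],
                        labels = tr$r_i[inner$test]),
      top_k = min(top_k, length(Xcols)))
    list(fit = fit, train = tr, test = te,
         eval_train = evaluate_ri(predict(fit, tr[, Xcols]), tr$r_i),
         eval_test = evaluate_ri(predict(fit, te[, Xcols]), te$r_i))
  })
  desc_model <- desc_eval$fit
  say("stage 2: descriptor model test R^2 = %.3f (RMSE %.1f, n = %d)",
      desc_eval$eval_test$r_squared, desc_eval$eval_test$rmse, desc_eval$eval_test$n)

  # -- stage 3: applicability domain + pseudo-labeling ----------------------
  desc_ad <- stage("applicability_domain", {
    fit_ad(as.matrix(desc_eval$train[, desc_model$feature_names]),
           percentile = ad_percentile)
  })
  corpus_curated <- stage("pseudo_label", apply_curation(corpus_descriptors, curation))
  labels_pred <- stage("pseudo_label",
                       pseudo_label(desc_model, desc_ad, corpus_curated, quiet = quiet))
  say("stage 3: h* = %.3g; %d corpus compounds pseudo-labeled, %d outside the domain",
      desc_ad$h_star, nrow(labels_pred), nrow(attr(labels_pred, "outside_domain")))

  # -- stage 4: CNL featurization + assembly --------------------------------
  cnl <- stage("featurize", build_cnl_matrix(spectra, grid, quiet = quiet))
  assembly <- stage("assembly", assemble_cnl_training(
    labels_pred, ri_labels, spectra,
    corpus_train_fraction = corpus_train_fraction,
    experimental_train_fraction = experimental_train_fraction,
    seed = seed + 21L, group_by_compound = group_by_compound))
  if (nrow(assembly$train) < 30) {
    warning("undersized CNL training set (", nrow(assembly$train), " entries)")
  }
  say("stage 4: CNL sets — train %d, corpus test %d, experimental test %d entries",
      nrow(assembly$train), nrow(assembly$corpus_test), nrow(assembly$experimental_test))

  # -- stage 5: CNL model ---------------------------------------------------
  cnl_res <- stage("cnl_model", {
    rowix <- function(entries) match(entries$spectrum_id, cnl$rows$spectrum_id)
    tr_ix <- rowix(assembly$train)
    inner <- stratified_split(assembly$train$r_i, 0.85, seed = seed + 22L,
                              groups = if (group_by_compound) assembly$train$compound_id)
    cfg <- cnl_preset(random_seed = seed + 23L)
    fit <- train_ri_model(
      cnl$matrix[tr_ix[inner$train], , drop = FALSE],
      assembly$train$r_i[inner$train], cfg,
      validation = list(
        features = cnl$matrix[tr_ix[inner$test], , drop = FALSE],
        labels = assembly$train$r_i[inner$test]))
    evals <- list(
      train = evaluate_ri(predict(fit, cnl$matrix[tr_ix, , drop = FALSE]),
                          assembly$train$r_i),
      corpus_test = evaluate_ri(
        predict(fit, cnl$matrix[rowix(assembly$corpus_test), , drop = FALSE]),
        assembly$corpus_test$r_i),
      experimental_test = evaluate_ri(
        predict(fit, cnl$matrix[rowix(assembly$experimental_test), , drop = FALSE]),
        assembly$experimental_test$r_i))
    list(fit = fit, evals = evals, train_rows = tr_ix)
  })
  cnl_model <- cnl_res$fit
  say("stage 5: CNL model R^2 — train %.3f, corpus test %.3f, experimental test %.3f",
      cnl_res$evals$train$r_squared, cnl_res$evals$corpus_test$r_squared,
      cnl_res$evals$experimental_test$r_squared)

  # -- stage 6: CNL applicability domain on used features -------------------
  cnl_ad <- stage("cnl_ad", {
    used <- cnl_model$used_features
    if (length(used) < 2) NULL else
      suppressWarnings(fit_ad(
        as.matrix(cnl$matrix[cnl_res$train_rows, used, drop = FALSE]),
        percentile = ad_percentile))
  })

  evaluations <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(desc_eval$eval_train), model = "descriptor", split = "train"),
    dplyr::mutate(tibble::as_tibble(desc_eval$eval_test), model = "descriptor", split = "test"),
    dplyr::mutate(tibble::as_tibble(cnl_res$evals$train), model = "cnl", split = "train"),
    dplyr::mutate(tibble::as_tibble(cnl_res$evals$corpus_test), model = "cnl", split = "corpus_test"),
    dplyr::mutate(tibble::as_tibble(cnl_res$evals$experimental_test), model = "cnl", split = "experimental_test")
  )
  evaluations <- dplyr::relocate(evaluations, "model", "split")

  manifest <- list(
    n_descriptors_in = length(curation$kept) + nrow(curation$dropped_unstable),
    n_descriptors_kept = length(curation$kept),
    n_nonconverged_compounds = length(curation$dropped_compounds),
    n_labeled_compounds = nrow(labeled),
    n_corpus_compounds = nrow(corpus_curated),
    n_pseudo_labeled = nrow(labels_pred),
    n_outside_domain = nrow(attr(labels_pred, "outside_domain")),
    h_star_descriptor = desc_ad$h_star,
    n_spectra = nrow(spectra),
    n_excluded_fragments = sum(cnl$rows$n_excluded),
    n_off_grid_losses = sum(cnl$rows$n_off_grid),
    n_train_entries = nrow(assembly$train),
    n_corpus_test_entries = nrow(assembly$corpus_test),
    n_experimental_test_entries = nrow(assembly$experimental_test),
    n_unmatched_records = nrow(assembly$unmatched),
    n_cnl_used_features = length(cnl_model$used_features),
    seed = seed
  )

  structure(
    list(curation = curation, descriptor_model = desc_model,
         descriptor_ad = desc_ad, cnl_model = cnl_model, cnl_ad = cnl_ad,
         pseudo_labels = labels_pred, assembly = assembly, cnl_features = cnl,
         evaluations = evaluations, manifest = manifest, seed = seed),
    class = "ri_two_stage"
  )
}

#' @export
print.ri_two_stage <- function(x, ...) {
  cat("<ri_two_stage> two-stage retention-index workflow\n")
  print(as.data.frame(x$evaluations), row.names = FALSE)
  invisible(x)
}

#' @describeIn run_two_stage Evaluation table: one row per model/split
#'   with `r_squared`, `rmse`, `max_error`, `n`.
#' @param x A `ri_two_stage` result.
#' @param ... Unused.
#' @export
tidy.ri_two_stage <- function(x, ...) x$evaluations

#' @describeIn run_two_stage One-row summary of the run.
#' @export
glance.ri_two_stage <- function(x, ...) {
  ev <- function(m, s, col) {
    x$evaluations[[col]][x$evaluations$model == m & x$evaluations$split == s]
  }
  tibble::tibble(
    descriptor_train_r2 = ev("descriptor", "train", "r_squared"),
    descriptor_test_r2 = ev("descriptor", "test", "r_squared"),
    descriptor_test_rmse = ev("descriptor", "test", "rmse"),
    cnl_train_r2 = ev("cnl", "train", "r_squared"),
    cnl_corpus_test_r2 = ev("cnl", "corpus_test", "r_squared"),
    cnl_experimental_test_r2 = ev("cnl", "experimental_test", "r_squared"),
    cnl_corpus_test_rmse = ev("cnl", "corpus_test", "rmse"),
    cnl_experimental_test_rmse = ev("cnl", "experimental_test", "rmse"),
    h_star_descriptor = x$manifest$h_star_descriptor,
    n_pseudo_labeled = x$manifest$n_pseudo_labeled,
    n_cnl_used_features = x$manifest$n_cnl_used_features,
    seed = x$seed
  )
}

#' Persist the artifacts of a two-stage run
#'
#' Writes the evaluation table, run manifest, curation report,
#' pseudo-labels and split membership as JSON/CSV under `dir`, and the
#' two boosters in the backend's binary format.
#'
#' @param x A `ri_two_stage` result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_two_stage <- function(x, dir) {
  stopifnot(inherits(x, "ri_two_stage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$evaluations, file.path(dir, "evaluations.csv"))
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(tidy.curation_report(x$curation), file.path(dir, "curation.csv"))
  readr::write_csv(x$pseudo_labels, file.path(dir, "pseudo_labels.csv"))
  splits <- dplyr::bind_rows(
    dplyr::mutate(x$assembly$train, set = "train"),
    dplyr::mutate(x$assembly$corpus_test, set = "corpus_test"),
    dplyr::mutate(x$assembly$experimental_test, set = "experimental_test")
  )
  readr::write_csv(splits, file.path(dir, "cnl_splits.csv"))
  xgboost::xgb.save(x$descriptor_model$booster, file.path(dir, "descriptor_model.ubj"))
  xgboost::xgb.save(x$cnl_model$booster, file.path(dir, "cnl_model.ubj"))
  jsonlite::write_json(
    list(descriptor = x$descriptor_model$fingerprint, cnl = x$cnl_model$fingerprint,
         descriptor_features = x$descriptor_model$feature_names,
         cnl_used_features = x$cnl_model$used_features),
    file.path(dir, "models.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
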