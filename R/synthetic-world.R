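#' Characteristic neutral-loss vocabulary of the synthetic world
#'
#' Fourteen loss masses (Da) used by [generate_world()], chosen around
#' real functional-group losses: water (18.011), formic acid (46.005),
#' butene (56.063), sulfur dioxide (65.97), a sulfanilamide-type
#' fragment (155.00), ammonia (17.027), carbon monoxide (28.003),
#' carbon dioxide/acetaldehyde (44.026), sulfur trioxide (79.957),
#' phosphoric acid (97.977), and four further moieties.  Each mass has
#' a fixed slope linking its occurrence probability to the latent
#' retention-driving variable.
#'
#' @return Tibble with `loss_mass`, `alpha` (intercept), `beta` (slope
#'   on the latent variable).
#' @export
loss_vocabulary <- function() {
  tibble::tibble(
    loss_mass = c(18.011, 46.005, 56.063, 65.97, 155.00, 17.027, 28.003,
                  44.026, 79.957, 97.977, 121.05, 35.977, 60.021, 87.032),
    alpha = c(0.5, 0, 0, 0, 0, 0.3, -0.3, 0, 0, -0.2, 0, 0.2, -0.4, 0),
    beta = c(2.2, -1.9, 2.4, -2.6, 2.8, 1.2, -1.4, 1.6, -2.1, 1.8,
             -1.2, 1.4, -1.6, 1.3)
  )
}

#' Generate a self-contained synthetic retention-index world
#'
#' Emulates the data a two-stage retention-index study consumes, with
#' known ground truth.  Each compound carries a latent hydrophobicity
#' surrogate `z ~ N(0, 1)` that drives everything observable:
#'
#' * retention index: `r_i = 200 + 841 * sigmoid(z) + N(0, ri_noise_sd)`,
#'   spanning roughly 200-1041;
#' * descriptors: `n_informative` columns affine in `z` plus
#'   independent noise, `n_decoy` columns of pure noise, and
#'   `n_unstable` columns whose replicate-to-replicate noise is large
#'   (so replicate-stability curation must drop exactly those);
#'   replicate tables differ only by replicate noise;
#' * spectra: the precursor ion mass is affine in `z` (molecular weight
#'   genuinely carries retention information); each spectrum draws
#'   characteristic neutral losses from [loss_vocabulary()] with
#'   inclusion probability `plogis(alpha + beta * z)`, plus uniform
#'   decoy losses; fragments are `precursor - loss`, always positive.
#'
#' Compounds split into an experimental arm (measured `r_i`, descriptor
#' triplicates; a subset also carries spectra — most experimentally
#' indexed chemicals have no public spectrum) and a corpus arm
#' (descriptors computed once, spectra only, no labels).  A designated
#' number of corpus compounds are generated out-of-distribution: their
#' informative descriptors are shifted far outside the fitted range so
#' an applicability domain must flag them.
#'
#' @param n_compounds Total compounds (>= 20), default 300.
#' @param n_experimental Compounds with measured labels, default half.
#' @param n_experimental_spectra Experimental compounds that also have
#'   spectra, default 40% of the experimental arm.
#' @param n_ood Out-of-distribution corpus compounds, default 15.
#' @param n_informative,n_decoy,n_unstable Descriptor counts, defaults
#'   30/20/10.
#' @param n_replicates Descriptor replicate tables, default 3.
#' @param descriptor_noise_sd Noise sd on informative descriptors
#'   (latent units), default 0.15.
#' @param replicate_noise_sd Replicate noise sd for stable columns (on
#'   the raw descriptor scale whose span is ~6), default 0.02.
#' @param unstable_noise_sd Replicate noise sd for unstable columns,
#'   default 1.5.
#' @param ri_noise_sd Measurement noise on `r_i`, default 50 (index
#'   units; noise-ceiling R^2 about 0.92).
#' @param mean_spectra_corpus,mean_spectra_experimental Mean spectra
#'   per compound (redundant spectra are the rule in public libraries),
#'   defaults 2.5 and 2.
#' @param decoy_losses_per_spectrum Mean uniform decoy losses per
#'   spectrum, default 3.
#' @param ood_shift Shift (raw descriptor units) applied to informative
#'   descriptors of out-of-distribution compounds, default 8.
#' @param seed Integer seed; same seed, same world, byte for byte.
#'
#' @return A `synthetic_world` list: `compounds` (tibble with
#'   `compound_id`, `latent`, `r_i_true` (noise-free), `r_i`,
#'   `precursor_mz`, `arm`, `has_spectra`, `is_ood`),
#'   `descriptor_replicates` (list of tibbles, experimental arm),
#'   `corpus_descriptors` (tibble), `spectra` (spectra tibble),
#'   `ri_labels` (tibble `compound_id`, `r_i`), `unstable_descriptors`
#'   (character), `params`.
#' @seealso [write_world()] to materialize it as CSV/MSP files,
#'   [oracle_ri()] for the noise-free targets.
#' @export
generate_world <- function(n_compounds = 300,
                           n_experimental = floor(n_compounds / 2),
                           n_experimental_spectra = floor(n_experimental * 0.4),
                           n_ood = 15,
                           n_informative = 30, n_decoy = 20, n_unstable = 10,
                           n_replicates = 3,
                           descriptor_noise_sd = 0.15,
                           replicate_noise_sd = 0.02,
                           unstable_noise_sd = 1.5,
                           ri_noise_sd = 50,
                           mean_spectra_corpus = 2.5,
                           mean_spectra_experimental = 2,
                           decoy_losses_per_spectrum = 3,
                           ood_shift = 8,
                           seed = 7) {
  if (n_compounds < 20) stop("need at least 20 compounds")
  n_corpus <- n_compounds - n_experimental
  if (n_experimental < 10 || n_corpus < 10) stop("both arms need >= 10 compounds")
  if (n_ood >= n_corpus) stop("n_ood must be smaller than the corpus arm")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv())) else
    assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ids <- sprintf("CMP%04d", seq_len(n_compounds))
  latent <- stats::rnorm(n_compounds)
  r_i_true <- 200 + 841 * stats::plogis(latent)
  r_i <- r_i_true + stats::rnorm(n_compounds, 0, ri_noise_sd)
  precursor <- pmin(pmax(300 + 80 * latent + stats::rnorm(n_compounds, 0, 25), 170), 900)

  arm <- c(rep("experimental", n_experimental), rep("corpus", n_corpus))
  is_ood <- logical(n_compounds)
  is_ood[sample(which(arm == "corpus"), n_ood)] <- TRUE
  has_spectra <- arm == "corpus"
  has_spectra[sample(which(arm == "experimental"), n_experimental_spectra)] <- TRUE

  compounds <- tibble::tibble(
    compound_id = ids, latent = latent, r_i_true = r_i_true, r_i = r_i,
    precursor_mz = precursor, arm = arm, has_spectra = has_spectra,
    is_ood = is_ood
  )

  # ---- descriptors ---------------------------------------------------------
  d_names <- c(sprintf("d_inf%02d", seq_len(n_informative)),
               sprintf("d_dec%02d", seq_len(n_decoy)),
               sprintf("d_uns%02d", seq_len(n_unstable)))
  n_desc <- length(d_names)
  slope <- stats::runif(n_informative, 0.6, 1.4) * sample(c(-1, 1), n_informative, TRUE)
  icept <- stats::runif(n_informative, -1, 1)
  base_value <- function(idx) {
    z <- latent[idx]
    inf <- vapply(seq_len(n_informative), function(k) {
      icept[k] + slope[k] * z
    }, numeric(length(idx)))
    dec <- matrix(stats::rnorm(length(idx) * n_decoy), ncol = n_decoy)
    uns <- matrix(stats::rnorm(length(idx) * n_unstable), ncol = n_unstable)
    m <- cbind(inf, dec, uns)
    colnames(m) <- d_names
    m
  }
  exp_ix <- which(arm == "experimental")
  cor_ix <- which(arm == "corpus")
  base_exp <- base_value(exp_ix)
  base_cor <- base_value(cor_ix)
  base_cor[is_ood[cor_ix], seq_len(n_informative)] <-
    base_cor[is_ood[cor_ix], seq_len(n_informative)] +
    ood_shift * matrix(sample(c(-1, 1), sum(is_ood) * n_informative, TRUE),
                       ncol = n_informative)
  # per-compound descriptor noise shared across replicates (the "true" computed value)
  noise_exp <- matrix(stats::rnorm(length(exp_ix) * n_desc, 0, descriptor_noise_sd),
                      ncol = n_desc)
  noise_cor <- matrix(stats::rnorm(length(cor_ix) * n_desc, 0, descriptor_noise_sd),
                      ncol = n_desc)
  rep_sd <- c(rep(replicate_noise_sd, n_informative + n_decoy),
              rep(unstable_noise_sd, n_unstable))
  descriptor_replicates <- purrr::map(seq_len(n_replicates), function(r) {
    noise <- matrix(stats::rnorm(length(exp_ix) * n_desc), ncol = n_desc) %*% diag(rep_sd)
    out <- tibble::as_tibble(base_exp + noise_exp + noise)
    dplyr::bind_cols(tibble::tibble(compound_id = ids[exp_ix]), out)
  })
  corpus_noise <- matrix(stats::rnorm(length(cor_ix) * n_desc), ncol = n_desc) %*% diag(rep_sd)
  corpus_descriptors <- dplyr::bind_cols(
    tibble::tibble(compound_id = ids[cor_ix]),
    tibble::as_tibble(base_cor + noise_cor + corpus_noise))

  # ---- spectra -------------------------------------------------------------
  vocab <- loss_vocabulary()
  spec_rows <- list()
  for (i in which(has_spectra)) {
    n_spec <- 1L + stats::rpois(1, (if (arm[i] == "corpus") mean_spectra_corpus
                                    else mean_spectra_experimental) - 1)
    for (s in seq_len(n_spec)) {
      pmz <- precursor[i] + stats::rnorm(1, 0, 0.002)  # instrument mass error
      p_inc <- stats::plogis(vocab$alpha + vocab$beta * latent[i])
      keep <- stats::runif(nrow(vocab)) < p_inc & vocab$loss_mass < pmz - 1
      losses <- vocab$loss_mass[keep] + stats::rnorm(sum(keep), 0, 0.002)
      n_dec <- stats::rpois(1, decoy_losses_per_spectrum)
      losses <- c(0, losses, stats::runif(n_dec, 1, pmz - 0.5))
      frag_mz <- pmz - losses
      spec_rows[[length(spec_rows) + 1L]] <- tibble::tibble(
        spectrum_id = sprintf("%s_S%02d", ids[i], s),
        compound_id = ids[i],
        precursor_mz = pmz,
        adduct = "[M+H]+",
        fragments = list(tibble::tibble(
          mz = frag_mz,
          intensity = round(stats::runif(length(frag_mz), 5, 100), 1))),
        meta = list(list(instrument = sample(c("orbitrap", "qtof"), 1),
                         collision_energy = sample(c("10", "20", "30"), 1)))
      )
    }
  }
  spectra <- dplyr::bind_rows(spec_rows)

  structure(
    list(
      compounds = compounds,
      descriptor_replicates = descriptor_replicates,
      corpus_descriptors = corpus_descriptors,
      spectra = spectra,
      ri_labels = dplyr::select(
        dplyr::filter(compounds, .data$arm == "experimental"),
        "compound_id", "r_i"),
      unstable_descriptors = sprintf("d_uns%02d", seq_len(n_unstable)),
      params = list(
        n_compounds = n_compounds, n_experimental = n_experimental,
        n_experimental_spectra = n_experimental_spectra, n_ood = n_ood,
        n_informative = n_informative, n_decoy = n_decoy,
        n_unstable = n_unstable, n_replicates = n_replicates,
        descriptor_noise_sd = descriptor_noise_sd,
        replicate_noise_sd = replicate_noise_sd,
        unstable_noise_sd = unstable_noise_sd, ri_noise_sd = ri_noise_sd,
        ri_intercept = 200, ri_span = 841, seed = seed)
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d compounds (%d experimental / %d corpus, %d OOD), %d spectra, seed %d\n",
              x$params$n_compounds, x$params$n_experimental,
              x$params$n_compounds - x$params$n_experimental, x$params$n_ood,
              nrow(x$spectra), x$params$seed))
  invisible(x)
}

#' Noise-free retention index of a synthetic compound
#'
#' Returns `200 + 841 * sigmoid(latent)`, the generator's target before
#' measurement noise — the oracle for recovery tests.
#'
#' @param world A `synthetic_world`.
#' @param compound_id Character vector of compound ids.
#' @return Numeric vector of noise-free retention indices.
#' @export
oracle_ri <- function(world, compound_id) {
  ix <- match(compound_id, world$compounds$compound_id)
  if (anyNA(ix)) {
    stop("unknown compound id(s): ",
         paste(compound_id[is.na(ix)], collapse = ", "))
  }
  world$params$ri_intercept +
    world$params$ri_span * stats::plogis(world$compounds$latent[ix])
}

#' Materialize a synthetic world as files
#'
#' Writes the replicate descriptor CSVs
#' (`descriptors_rep<k>.csv`), the corpus descriptor CSV
#' (`descriptors_corpus.csv`), the spectra (`spectra.msp`), the label
#' table (`ri_labels.csv`) and the ground truth
#' (`truth.csv`: latent variable, noise-free r_i, arm/OOD flags) under
#' `dir` — every file in the format the corresponding reader consumes.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(world$descriptor_replicates)) {
    readr::write_csv(world$descriptor_replicates[[r]],
                     file.path(dir, sprintf("descriptors_rep%d.csv", r)))
  }
  readr::write_csv(world$corpus_descriptors, file.path(dir, "descriptors_corpus.csv"))
  readr::write_csv(world$ri_labels, file.path(dir, "ri_labels.csv"))
  write_msp(world$spectra, file.path(dir, "spectra.msp"))
  readr::write_csv(world$compounds, file.path(dir, "truth.csv"))
  invisible(dir)
}
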