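# cnlri

Retention-index prediction for structurally unknown chemicals, directly from
tandem mass spectra.

## The problem

Non-target LC-HRMS screening yields thousands of fragmentation spectra of
chemicals nobody can yet name. Retention behavior would be a powerful filter
on candidate structures, but conventional QSRR models need the molecular
structure, and measured retention indices (r<sub>i</sub>, on the alkylamide
scale for C18 reversed-phase chromatography) need co-injected calibrants that
historical data usually lack.

`cnlri` implements a two-stage, semi-supervised workaround:

1. **Descriptor stage.** A gradient-boosted QSRR model is trained on compounds
   with measured r<sub>i</sub> and curated molecular descriptors (min-max
   scaling; replicate-stability filtering that keeps only descriptors whose
   across-replicate variance is below 0.01). Its applicability domain is the
   leverage statistic h = **x**ᵀ(**X**ᵀ**X**)⁻¹**x** with a threshold h\* set
   at the 95th percentile of the training set's leave-one-out leverages.
2. **CNL stage.** The descriptor model pseudo-labels a large spectral corpus —
   only inside its domain. Each spectrum is converted to cumulative neutral
   losses (precursor mass − fragment mass) encoded as a ternary vector over
   100,000 bins of 0.01 Da spanning 0–1000 Da (1 = loss present, 0 = absent,
   −1 = heavier than the precursor, i.e. impossible), plus the precursor mass
   as a continuous feature. A second gradient-boosted model trained on the
   combined pseudo-labeled + experimental entries then predicts r<sub>i</sub>
   from nothing but a spectrum.

The package provides MSP/MGF readers, the CNL featurizer (sparse,
Matrix-backed), descriptor curation, the leverage applicability domain,
stratified splitting / cross-validation / evaluation, the two-stage
orchestrator, a fully synthetic test world with known ground truth, and
ggplot2 diagnostics (`autoplot()` on evaluations and domains). Everything is
tibble-in/tibble-out and pipe-friendly, with `tidy()`/`glance()` methods on
fitted objects.

## Worked example

```r
library(cnlri)

# a synthetic study: 300 compounds, half with measured r_i (triplicate
# descriptors), half an unlabeled spectral corpus, 15 compounds designed
# out-of-distribution
world <- generate_world(seed = 7)

res <- run_two_stage(world$descriptor_replicates, world$ri_labels,
                     world$corpus_descriptors, world$spectra, seed = 7)
#> stage 1: 50 curated descriptors, 150 labeled compounds
#> stage 2: descriptor model test R^2 = 0.856 (RMSE 58.8, n = 22)
#> stage 3: h* = 0.699; 130 corpus compounds pseudo-labeled, 20 outside the domain
#> stage 4: CNL sets — train 305, corpus test 42, experimental test 86 entries
#> stage 5: CNL model R^2 — train 0.985, corpus test 0.856, experimental test 0.850

tidy(res)
#> # A tibble: 5 × 6
#>   model      split             r_squared  rmse max_error     n
#>   <chr>      <chr>                 <dbl> <dbl>     <dbl> <int>
#> 1 descriptor train                 0.987  21.5      117.   128
#> 2 descriptor test                  0.856  58.8      129.    22
#> 3 cnl        train                 0.985  23.0      105.   305
#> 4 cnl        corpus_test           0.856  74.7      148.    42
#> 5 cnl        experimental_test     0.850  70.6      165.    86
```

Reading the output: the descriptor QSRR model explains 86% of the held-out
variance; its predictions seed the corpus (20 compounds — including all 15
designed outliers — are refused by the applicability domain); the CNL model
then reaches R² = 0.85 / RMSE ≈ 71 r<sub>i</sub> units on spectra of compounds
it has never seen, judged against measured values. The corpus test is scored
against its own pseudo-labels, so the experimental test is the honest number.

Individual stages work standalone:

```r
spectra <- read_msp("spectra.msp")            # or read_mgf()
cnl     <- build_cnl_matrix(spectra)          # 100,001 sparse columns
report  <- stability_filter(list(rep1, rep2, rep3), threshold = 0.01)
curated <- apply_curation(new_table, report)
ad      <- fit_ad(train_features)             # h* via leave-one-out
in_domain(query_features, ad)
autoplot(evaluate_ri(predict(model, X), truth))
```

A thin CLI mirroring these steps ships in `inst/cli/cnlri`
(`simulate`, `featurize`, `curate`, `ad-filter`, `run-two-stage`).

## Scope notes

Descriptor computation (e.g. PaDEL) and spectral-library retrieval are out of
scope: the package consumes descriptor CSVs and MSP/MGF files. Losses are
computed in m/z space assuming singly charged precursors; fragment intensities
are parsed but unused by design. See the vignette
(`vignettes/cnl-retention-index.Rmd`) for the model's assumptions, numerical
conventions, and the limits of what the synthetic world demonstrates.
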