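---
title: "Predicting retention indices from cumulative neutral losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting retention indices from cumulative neutral losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-target screening by LC-HRMS produces thousands of fragmentation spectra of
chemicals whose structures are unknown. Retention behavior is a powerful
orthogonal filter for candidate structures, but classical
quantitative structure-retention relationship (QSRR) models need the structure
— exactly what is missing — and measured retention indices (r~i~, here on the
alkylamide homologous-series scale used for C18 reversed-phase separations)
need co-injected calibrants that most historical datasets lack.

`cnlri` implements a two-stage workaround. A descriptor-based QSRR model,
trained on compounds with measured r~i~, pseudo-labels a large spectral corpus
with predicted r~i~ values — but only inside its applicability domain. A second
regressor then learns to predict r~i~ directly from the fragmentation spectrum,
represented as **cumulative neutral losses** (CNLs): the differences between
the precursor ion mass and each fragment mass, treated as independent features.
Once trained, that second model needs nothing but a measured MS/MS spectrum.

## The CNL representation

For a spectrum with precursor m/z $p$ and fragments $f_1, \dots, f_k$, the CNL
set is $\{p - f_j : f_j \le p\}$. Losses collapse enormous fragment diversity
into recurring, functional-group-specific variables: a loss of 18.011 Da is a
water loss whether the precursor was at 180 or at 580 Da.

Each spectrum becomes a ternary vector over a fixed grid of 100,000 bins
covering 0–1000 Da in 0.01 Da steps (±5 mDa tolerance around each bin center):

* `1` — at least one loss falls in the bin,
* `0` — no loss observed there, but a loss would have been possible,
* `-1` — the bin's mass exceeds the precursor mass, so a loss there is
  physically impossible (a fragment heavier than its precursor); encoding
  impossibility separately from absence is deliberate,

plus the precursor ion mass as one continuous feature (molecular weight itself
carries retention information). Precursor masses are taken as given in the
record, assuming singly charged ions, with no adduct arithmetic; fragment
intensities are parsed but unused — the encoding is presence/absence.

Numerical conventions worth stating exactly:

* bin assignment is `round(mass / 0.01)` with IEEE round-half-to-even; a loss
  at an exact half-boundary (e.g. 18.005) goes to the even bin index;
* the `-1` region starts at the bin *after the precursor's own bin*. For an
  on-grid precursor this is identical to "center mass greater than the
  precursor", but for an off-grid precursor (say 249.996 Da) a loss equal to
  the precursor rounds into bin 25000 (center 250.00); starting the region one
  bin later guarantees no bin can ever be `1` and `-1` at once;
* losses at or above 1000 Da fall off-grid and are dropped with a counted
  warning; a loss of exactly 0 Da (surviving precursor) is a valid bin-0 entry;
* redundant spectra of one compound are kept as separate rows, never merged —
  instrument-to-instrument variability is part of what the model must absorb.

Rows are stored sparsely: the `1` entries plus the `-1` run, which is fully
described by the precursor's bin index.

## Descriptor curation

Molecular descriptor calculations (3D geometry optimization in particular) are
not perfectly reproducible, so the same compounds are computed in replicate
(triplicate by default). All replicates are min-max scaled jointly per
descriptor; the across-replicate sample variance (the unbiased $n-1$ form —
three observations per compound) is computed per compound and aggregated over
compounds; a descriptor is kept iff the aggregate is **strictly below 0.01**.
Two aggregation modes exist because "the variance of each descriptor" can be
read per-compound-then-pooled or globally: the default takes the maximum over
compounds (strictest — one unstable compound disqualifies the descriptor),
`aggregate = "mean"` the mean. Compounds with non-finite descriptor values
(failed optimizations) are dropped row-wise and reported, never imputed.
The stored `(min, max)` pairs are replayed verbatim on new tables; new
compounds may scale outside $[0, 1]$ and are not clipped.

## Applicability domain

Predictions are gated by the leverage statistic
$h = \mathbf{x}^\top (\mathbf{X}^\top \mathbf{X})^{-1} \mathbf{x}$,
computed against the training design restricted to the features the final
model actually uses. The threshold $h^*$ is the 95th percentile (linear
interpolation between order statistics) of the leave-one-out leverage
distribution: each training row scored against the design with itself removed.
For a full-column-rank design the Sherman–Morrison identity gives the LOO
value in closed form as $h_{ii} / (1 - h_{ii})$; rank-deficient Gram matrices
(routine when binary loss bins are the features) fall back to the
Moore–Penrose pseudo-inverse, with an optional ridge behind a flag. The
in-domain comparison is inclusive ($h \le h^*$). The threshold is recomputed
per model and per feature set, never reused across feature spaces.

## Models

Both stages use RMSE-loss gradient-boosted tree ensembles with two fixed
recipes: the descriptor model runs up to 450 rounds at learning rate 0.03,
depth 8 (≤256 leaves), minimum 1 observation per leaf, L2 leaf penalty 10; the
CNL model up to 5000 rounds at learning rate 0.077, depth 6 (≤64 leaves), L2
penalty 3. Training stops once the validation RMSE has not improved for 5
rounds. The backend is xgboost with histogram trees grown depthwise: the leaf
budgets 256 and 64 equal $2^8$ and $2^6$, i.e. the bound a depth-limited
symmetric tree implies, so depthwise growth is the faithful mapping (lossguide
growth with a hard leaf cap measurably over-interpolates noise at the sample
sizes used here). The histogram uses 254 borders, the convention of the
gradient-boosting implementation the recipes come from; for ternary columns
the sketch degenerates to three cut points, so this costs nothing on the CNL
side. All training is single-threaded, which makes every run bit-reproducible
under a fixed seed; one pipeline seed deterministically derives every split
and training seed.

Splits are stratified over the three r~i~ classes 200–440, 440–700 and
700–1041 (values outside joining the end classes), honoring the train fraction
within one sample per class. The descriptor workflow refits the final model on
the 40 features with the highest split-gain importance (ties broken by feature
order); "variance explained" rankings are approximated by the backend's native
gain. The reference protocol stops on "the validation set" without defining
one, so `run_two_stage()` carves a stratified 15% inner slice out of each
training set for early stopping; test sets are never touched during training.
The early-stopped model itself is kept as the final model — refitting on the
full training split with the frozen round count was also evaluated and was
slightly worse at these sample sizes.

The two-stage assembly combines 85% of the pseudo-labeled corpus entries with
30% of the experimentally labeled entries into the CNL training set; the other
15% of the corpus is the corpus test set (judged against its pseudo-labels)
and the withheld 70% of experimental compounds form the stringent test —
compounds wholly unknown to the model, judged against measured values. Splits
are compound-grouped by default (every spectrum of a compound on one side), a
stricter rule than a spectrum-level split: redundant spectra would otherwise
leak near-duplicates across the boundary. A spectrum-level mode exists for
comparison. Experimental records always keep their measured r~i~; predictions
never overwrite them.

## The synthetic world

Real inputs (descriptor tables, spectral libraries, measured index tables) are
large external artifacts, so the package carries a generator that emulates
their statistical shape with known ground truth. Each compound has a latent
hydrophobicity surrogate $z \sim N(0,1)$ driving everything observable:

* $r_i = 200 + 841 \cdot \mathrm{sigmoid}(z) + \varepsilon$,
  $\varepsilon \sim N(0, 50)$ — spanning the 200–1041 class range with a
  noise-ceiling $R^2 \approx 0.9$, leaving measurable headroom above the
  pipeline's recovery floors;
* 30 informative descriptors affine in $z$ (noise sd 0.15), 20 pure-noise
  decoys, and 10 designed-unstable columns whose replicate noise (sd 1.5
  against stable columns' 0.02) guarantees the variance filter must remove
  exactly them;
* precursor mass $= 300 + 80 z$ (sd-25 noise, clamped to 170–900 Da):
  molecular weight genuinely correlates with retention, and the continuous
  mass feature was found highly informative in practice;
* spectra draw characteristic losses from a 14-mass vocabulary (water 18.011,
  formic acid 46.005, butene 56.063, SO~2~ 65.97, a sulfonamide-type fragment
  155.00, ammonia 17.027, CO 28.003, and seven more) with inclusion
  probability $\mathrm{logit}^{-1}(\alpha_k + \beta_k z)$, slopes
  $|\beta_k| \in [1.2, 2.8]$, plus Poisson(3) uniform decoy losses, ±2 mDa
  mass error and a surviving-precursor peak.

The default study conditions are 300 compounds: 150 experimental (measured
r~i~, descriptor triplicates; 60 of them also carry spectra — most compounds
with measured indices have no public spectrum, so spectral coverage of the
labeled set is deliberately partial) and 150 corpus compounds (descriptors
computed once, 1–4 spectra each, no labels), of which 15 are generated
out-of-distribution by shifting their informative descriptors far outside the
fitted range — the applicability domain must catch them. Arm sizes balance two
needs at a desk-scale total: enough labeled compounds for a stable QSRR fit
and enough corpus entries for the CNL stage.

What the generator does **not** emulate: real fragmentation chemistry
(losses are conditionally independent given $z$; real spectra share
correlated substructure losses), isotope patterns, collision-energy
dependence, co-elution artifacts, or a descriptor space with thousands of
partially redundant columns. Passing recovery tests on this world therefore
demonstrates that the machinery — featurization, curation, gating, two-stage
training — extracts the signal that is present by construction; it does not
certify accuracy on real libraries, whose headline numbers require the
original corpora.

## Degenerate inputs and tie rules

Empty fragment lists are rejected at read time (counted, never silent);
fragments above the precursor are excluded at loss computation and counted;
constant descriptor columns scale to 0 and are flagged; zero-variance truth
makes $R^2$ undefined and is flagged rather than returned as a number;
identical importance ties in the top-$k$ refit resolve by training feature
order; the in-domain boundary is inclusive; `h* ` percentiles use
interpolation (type 7), documented because "95% confidence interval" admits
several readings.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
300-compound world (≈490 spectra, ≈23 million stored matrix entries) in well
under a minute per seeded run on one core; five seeded replicates back the
error-propagation and feature-recovery checks. Smaller worlds (30–60
compounds) exercise mechanics where full scale adds nothing.

## Known limitations

* The GBT recipes are fixed; no hyperparameter search is
  performed (`cross_validate()` exposes the machinery).
* The CNL applicability domain on thousands of near-binary features is
  rank-deficient almost by construction; the pseudo-inverse leverage is
  well-defined but geometrically looser than in the descriptor space.
* Adduct handling is deliberately absent: losses are computed in m/z space
  assuming singly charged precursors.
* MSP/MGF parsing targets the common NIST/Mascot text dialects, not every
  vendor variant; mzML is out of scope.
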