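---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models the package implements, the
assumptions behind them, the tunable parameters, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Differential interactome models

### Filtering and imputation

Protein-groups tables are filtered by the standard quality flags (reverse
matches, potential contaminants, only-identified-by-site), a minimum
distinct-peptide count (default 2), and a replicate-quantification rule:
a protein must be quantified in at least *k* replicates of some single
condition, with `k3` (k = 3, capped at the condition's replicate count)
and `all` both available — datasets differ in which is appropriate, so
the rule is a parameter rather than a constant. Zero intensities are
missingness, and all analysis is on log2 LFQ.

Missing values are imputed per **sample column** from
`N(mean_obs − downshift·sd_obs, (width·sd_obs)²)` with `downshift = 1.8`
and `width = 0.3`. The per-column scope is the Perseus convention for
intensity-dependent (MNAR) dropout: each run has its own detection floor.
Observed values are never touched, and a fixed seed reproduces the draws
bit-exactly.

### t-test route

Enrichment of a target bait over a union of control baits uses the
pooled-variance Student's t-test (two-sided) on imputed data,
Benjamini–Hochberg FDR across proteins, and the two-threshold call
`log2FC > 1` and `FDR < 0.05`. A methods-text p < 0.05 reading and a
figure-style `-log10(p) > 1` reading of the significance cut coincide
here; both remain expressible through the `fdr_cut` argument.

### LASSO route with fixed-lambda selective inference

Per protein, `log2(LFQ) ~ labtime + labtime:bait` with labelling time
categorical (1-min reference) and bait interactions against the reference
bait. Two encoding details matter:

- conditions never sampled produce structurally absent columns, which are
  dropped;
- a labelling time sampled for exactly one bait makes that bait's
  interaction an exact duplicate of the labtime main effect. The
  duplicate is dropped (the main-effect copy is kept); otherwise
  `X_A'X_A` is exactly singular and the selective-inference constraints
  are undefined.

The fit is glmnet coordinate descent on
`(1/2n)‖y − Xβ‖² + λ‖β‖₁` with column standardization and an unpenalized
intercept (`thresh = 1e-28`, `maxit = 1e7`), λ chosen at the minimum of
11-fold cross-validated MSE over a 100-value path spanning four decades
below `λ_max`; folds are plain seeded random assignments. σ is the
residual SD of the `lambda.min` fit with an `n − df − 1` correction
(df = active-set size).

Selective p-values condition on the selection event at the fixed
`lambda.min`: with active set A and signs s, the constraints
`{y : sign/KKT conditions hold}` form a polyhedron; for each active
coefficient the statistic `η'y` (η the corresponding row of the
pseudo-inverse of the standardized active design) is Gaussian with
SD `σ‖η‖`, truncated to the interval `[V⁻, V⁺]` the polyhedron implies.
The reported p-value is the two-sided truncated-Gaussian tail
probability; the truncated CDF is evaluated through upper-tail logs so
far-tail intervals do not underflow, and a numerically empty interval
yields p = 1 with a warning. Inference is done in the standardized
coordinates glmnet actually penalizes, so the conditioning event matches
the fitted model. No multiple-testing correction is applied to these
p-values, mirroring the per-protein model-selection logic. Calibration is
verified in the test suite: pooled active-set p-values from 500
global-null replicates at a fixed λ pass a Kolmogorov–Smirnov uniformity
test, and a one-predictor design matches a quadrature oracle to 1e-4.

Note the caveat: p-values at a *cross-validated* λ inherit extra
randomness the polyhedral lemma does not condition on; under strong
planted effects the pipeline's error rates remain controlled in the
seeded recovery test, but the fixed-λ guarantee is exact only for fixed
λ.

**Calls.** A protein joins a non-reference bait's set when that bait has
a significant positive interaction effect, and the reference bait's set
when a significant effect is negative. When several interactions for one
bait are significant the summarizing effect is configurable; the default
is the largest-magnitude significant interaction, a deliberate package
choice (the aggregation is not canonical).

## Sequence features

Residue fractions exclude `X` from numerator and denominator; FCR and
NCPR use D, E, K, R only (histidine counts as uncharged there but
carries a pKa of 6.5 in the pI bisection — the usual feature-toolkit
convention). The pI solver bisects the Henderson–Hasselbalch net charge
(EMBOSS pKa table, free termini) on (0, 14) to |charge| < 1e-4; the
charge is monotone in pH so the root is unique. Molecular weight uses
average isotopic residue masses plus one water; `X` contributes the mean
residue mass. All scales live in `aa_scales()` as configuration data.

### Blockiness z-scores

Eight residue classes: polar {S,T,N,Q,C,H}, hydrophobic {I,L,M,V},
positive {R,K}, negative {D,E}, aromatic {F,W,Y}, and singleton classes
A, P, G. The placement of H and C in "polar" is the least-standardized
choice; it is fixed here and documented rather than configurable. For an
unordered pair (X,Y) the patterning statistic maps residues to ±1/0 and
averages `(σ_win − σ_seq)²` over sliding windows of sizes 5 and 6
(averaged), with `σ = (f₊ − f₋)²/(f₊ + f₋)` and σ = 0 for windows
holding neither class; the diagonal uses the binary class fraction. The
z-score is against `n_scrambles` uniform permutations of the sequence
(default 100,000; the tests use 1,000 with fixed seeds for speed).
Degenerate nulls (e.g. homopolymers, where every scramble is identical)
map to z = 0. The null is approximately standard normal but visibly
right-skewed — δ is a mean of squared deviations over heavily
overlapping windows — so |z| < 3 holds for about 99% of null values
rather than the Gaussian 99.7%; the calibration test asserts the pooled
99% level. The scramble loop is implemented in C++ and driven by R's
RNG, so results are seed-reproducible.

## Classifiers

All three models share the training protocol: Adam at learning rate
1e-4, categorical cross-entropy with class weights
`n/(n_classes·n_c)`, early stopping on validation loss (patience 25,
max 1000 epochs), stratified 3-fold cross-validation, several replicate
trainings per fold (default 10) with the best kept by validation AUROC,
and macro one-vs-rest AUROC as the headline metric. Open choices
resolved here:

- the early-stopping/selection validation set is a stratified 10% split
  carved from each training fold; the held-out fold is never touched
  until final evaluation;
- univariate screening (logistic fit per feature, retain macro AUROC
  strictly above 0.5) is computed in-sample on the full data — a known
  mild leakage, accepted because the screen is a complexity reduction,
  not a performance claim; MinMax normalization is likewise fitted
  globally;
- unstated hyperparameters: dropout 0.3 (CNN head), batch size 32 —
  both configurable;
- replicate trainings are not decoration: with a patience-based stop and
  a small validation split, an unlucky initialization can stall before
  learning starts, and replicate selection is the protocol's own remedy.

The networks are implemented in base R matrix algebra (dense, batch
normalization, ReLU, dropout, same-padding 1-D convolution, pool-2 max
pooling with floor semantics, global average pooling), sized for this
package's problem scales rather than as a general framework. The CNN
requires pad length ≥ 2⁵ so five poolings survive; 320 → 10 positions,
as the architecture expects.

## Integrated-gradients attribution

Attributions toward a class are
`x_i · mean_{k=1..steps} ∂F/∂x_i((k/steps)·x)` with a zero baseline and
50 steps; `F` is the softmax probability by default (logit available),
and the target is the sample's true class (predicted-class available).
Class summaries weight each sample by 1/(class size) so classes
contribute equally, and report top-k features (k = 8).

A quadrature caveat, measured rather than assumed: for ReLU networks the
output along the straight path is piecewise linear, so the path
derivative is piecewise constant and any fixed 50-point rule (Riemann,
trapezoid, Gauss–Legendre were all measured) carries kink-limited error
on the order of (Σ|derivative jumps|)/(2·steps). Mean completeness error
at 50 steps is ~1–3% of `F(x) − F(0)` with worst samples above that, and
the error halves (on average) per step doubling; the input gradient
itself is exact to 1e-10 against finite differences. Completeness should
therefore be monitored per analysis and `steps` raised where tighter
closure is needed; rankings are far less sensitive than the completeness
residual.

## Descriptive compartment statistics

Two-group scalar comparisons (pI, MW) use Mann–Whitney U; when both
groups have ≤ 8 values the p-value is an exact enumeration over all
group assignments (which also handles ties, counting tied cross-pairs as
one half), otherwise the normal approximation with tie correction. The
exact/approximate switch at 8 is a cost choice: enumeration is ≤ 12,870
assignments there. Amino-acid usage compares per-protein fractions
(not pooled residues) with two-sided Welch t-tests per residue, ranking
residues by |mean difference| and flagging the top five. Domain content
reports per-group prevalence (fraction of proteins with any coverage)
and mean coverage of one annotation category.

## Spatial colocalization

`G(Δ) = ⟨δA(r)·δB(r+Δ)⟩/(⟨A⟩⟨B⟩)` is computed for all lattice
displacements by zero-padded FFT with per-displacement overlap counts
(verified against a nested-loop oracle to 1e-9), then radially averaged.
The randomized null applies the 7 non-identity symmetries of the square
to one channel and averages the 7 profiles. The ratio is taken in the
offset form `C = (1 + G)/(1 + G_RAND)` — the image-correlation-
spectroscopy convention — so C is stable when raw correlations cross
zero and converges to 1 for random signals; C is invariant to positive
rescaling of either channel. Against-constant hypotheses (median
C(0) > 1) use the one-sided Wilcoxon signed-rank test, two-condition
comparisons the one-sided Mann–Whitney; 80% bands are 10th–90th
percentiles across images, suppressed below 3 images. The saturation
rescale before Pearson colocalization clips 0.35% of pixels, split
equally between tails (the split is a documented choice). The
biotinylation "radius delta" is reported in both defensible readings —
the literal `(area_biotin − area_RNA)/2` (area units) and the
circle-equivalent radius difference `√(area_b/π) − √(area_r/π)` — since
the verbal formula mixes units; neither is asserted as canonical.

## Synthetic-data generator

The generator exists so every stage can be tested with the statistical
structure it assumes; each generator derives its own RNG stream from
`(seed, generator-name)`, so adding one never perturbs another.

- **Protein sets**: three classes. FC-like sequences are longer
  (lengths ~ N(600, 150²) aa) and carry three 20-residue D/E tracts;
  DFC-like are shorter (N(350, 100²)), carry three 15-residue K blocks
  and one RRM annotation interval (70–90 aa); nuclear proteins are
  background composition only (Swiss-Prot-like average frequencies).
  Tract placement is uniform with non-overlap by rejection; a tract
  longer than its sequence is a sizing error. Lengths are floored at 50
  aa so the blockiness windows always fit.
- **LFQ**: per-protein baseline N(26, 2²) log2 units, bait-specific
  shifts of +2 (4× the 0.5 noise SD) for a seeded 5% of proteins per
  bait, Gaussian noise, and logistic MNAR censoring
  `P(missing) = plogis((24 − x)/1)`. The design is 3 baits × labelling
  times {1,5,15} min (plus 3 min for one bait only) × 4 replicates.
  Effect magnitudes in real data are experiment-specific; these defaults
  are free parameters chosen once as plausible strong effects, not
  estimates of any dataset.
- **Images**: a Gaussian spot (σ = 0.25 µm at 30 nm pixels, 128 px
  field) with Poisson + Gaussian read noise at peak SNR 10, plus a
  uniform background at 10% of peak. Two deliberate deviations from the
  most literal "centred spot" reading: the spot centre is jittered by up
  to 1/8 of the field, because a pixel-centred spot is invariant under
  all 7 square symmetries, which forces `G_RAND = G` and `C ≡ 1` — the
  randomized null is only informative for non-symmetric images, as real
  acquisitions are; and the background is nonzero because on an empty
  field the mean-normalized G leaves the regime where `1 + G` stays
  positive, and the ratio convention presumes the background real
  micrographs have. With halo on, channel B becomes an annulus at
  0.5 µm radius, emulating reduced labelling in the spot core.

What the generator does **not** emulate: peptide-level quantification
and roll-up, between-run normalization artefacts, correlated missingness
across samples, realistic PSF optics, autofluorescence texture, or any
evolutionary sequence structure beyond composition and planted blocks.
Passing tests therefore demonstrate correctness and calibration of the
statistics under their stated assumptions — not performance on real
data.

## Problem sizes in the test suite

The suite runs the full protocol at reduced sizes chosen for a
single-CPU workstation: 300-protein LFQ recovery, 150-protein
classifier recovery with 2 replicates per fold, a 30-sequence CNN
overfit check at pad 48, 500-replicate selective-inference and
blockiness calibrations at 1,000 scrambles, and 20 noise image pairs at
256². Defaults in the package remain the full-scale settings
(100,000 scrambles, 10 replicates per fold, 1000 epochs).

## Known limitations

- Selective inference is exact for a fixed λ; CV-selected λ breaks the
  conditioning slightly (see above).
- The blockiness null is right-skewed; z-scores are calibrated in
  spread but not Gaussian in the upper tail.
- Integrated-gradients completeness at 50 steps carries the quadrature
  error analysed above.
- The MLP/CNN engine is single-threaded base R: adequate at the tested
  scales, not intended for thousands of long sequences.
- Screening and normalization are fitted globally by default (per-fold
  variants are the obvious extension where leakage matters).
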