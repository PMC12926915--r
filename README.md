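# proxitome

Analysis toolkit for RNA-targeted proximity-labelling proteomics of nested
condensates such as the nucleolus. Proximity labelling deposits biotin on
molecules near a probe-defined RNA "bait"; streptavidin enrichment and
label-free quantitative mass spectrometry (LFQ) then yield a per-bait
interactome. `proxitome` implements the downstream computational pipeline
for such experiments: differential-interactome inference, protein
sequence-feature engineering, compartment-identity classification with
attribution, descriptive compartment statistics, and the
randomization-normalized spatial colocalization statistic for two-channel
micrographs — all exercisable end-to-end on a seeded synthetic-data
generator, with no external data.

It is written for computational proteomics / RNA-biology groups analysing
bait-resolved interactomes (e.g. distinct pre-rRNA regions marking the
fibrillar centre, dense fibrillar component and granular component of the
nucleolus) and for methodologists who want a tested reference
implementation of the statistics involved.

## What it computes

**Differential interactomes.** From a MaxQuant-style protein-groups table
(filters: reverse / contaminant / only-identified-by-site flags, peptide
count, replicate-quantification rule; zeros are missing; log2 scale) with
Perseus-style imputation — missing values drawn per sample column from
`N(mean_obs − 1.8·sd_obs, (0.3·sd_obs)²)`:

- *t-test route*: per protein, pooled-variance Student's t of one bait
  against a union of control baits; Benjamini–Hochberg FDR; calls at
  log2FC > 1 and FDR < 0.05.
- *LASSO route*: per protein, `log2(LFQ) ~ labtime + labtime:bait`
  (treatment-coded; 1-min and reference-bait baselines) fitted by glmnet
  (`thresh = 1e-28`, `maxit = 1e7`, 11-fold CV); at the cross-validated
  `lambda.min`, fixed-lambda selective inference gives each active
  coefficient a polyhedral-lemma p-value — the least-squares statistic
  `η'y` conditional on the selected active set and signs is Gaussian
  truncated to the KKT-implied interval `[V⁻, V⁺]` — with σ estimated from
  the residuals (`n − df − 1` correction). Sign rules turn significant
  interaction effects into per-bait protein sets.

**Sequence features and classifiers.** Per protein: residue and
residue-class fractions, FCR, NCPR, Kyte–Doolittle hydropathy, molecular
weight, isoelectric point (bisection on the Henderson–Hasselbalch charge
curve, EMBOSS pKa table), annotation-coverage fractions, and 8×8
blockiness z-scores against composition-matched scramble nulls
(`z = (δ_obs − mean δ_null)/sd δ_null`, default 100,000 scrambles, windows
5 and 6). Three classifiers under stratified 3-fold CV with class
weighting and macro one-vs-rest AUROC: a feature MLP (128/64 units, batch
norm, ReLU) after univariate-AUROC screening, a sequence CNN (five
128-filter kernel-10 blocks with pool-2, global average pooling, 64-unit
dense head), and an embedding MLP for precomputed fixed-length vectors.
Integrated gradients (50 interpolation steps from a zero baseline,
class-balanced averaging) rank features per class.

**Spatial statistics.** Pearson colocalization after saturation rescale
(0.35% clipped); biotinylation radius delta from mask areas; and the
colocalization measure `C(d) = G*(d) / G*_RAND(d)`, where
`G*(d) = 1 + ⟨δA δB⟩/(⟨A⟩⟨B⟩)` is the radially averaged fluctuation
cross-correlation (FFT, non-periodic overlaps) and the null averages the 7
non-identity symmetries of the square applied to one channel. `C(d) > 1`
indicates above-random colocalization; one-sided Mann–Whitney/Wilcoxon
tests and 80% bands summarize conditions.

## Worked example

```r
library(proxitome)

cfg  <- sim_config(seed = 42, n_per_class = 40)
recs <- simulate_protein_sets(cfg)          # FC-like / DFC-like / nuclear
labs <- vapply(recs, function(r) r$label, "")

# planted acidity: FC-like proteins have much lower pI than DFC-like
fc  <- vapply(recs[labs == "FC_like"],  isoelectric_point, numeric(1))
dfc <- vapply(recs[labs == "DFC_like"], isoelectric_point, numeric(1))
scalar_group_test(fc, dfc, alternative = "less")
#> <stat_result> mann-whitney (normal-approx, less): statistic 0, p = 7.175e-15
#>  group  n    median      mean
#>      a 40  4.135015  4.152033
#>      b 40 10.774980 10.776469

fm  <- assemble_feature_matrix(recs)        # MinMax-normalized features
scr <- screen_features(fm, labs)            # univariate AUROC > 0.5
rep1 <- train_feature_mlp(unclass(fm)[, attr(scr, "retained")], labs,
                          train_config(folds = 3, replicates_per_fold = 2,
                                       max_epochs = 300, seed = 42))
rep1
#> <classifier_report> feature_mlp: macro one-vs-rest AUROC 1.000 over 3 folds

# colocalized spot image pair: C(0) > 1, C -> 1 at large displacement
pr <- simulate_image_pair(sim_config(seed = 42), halo = FALSE)
cp <- coloc_profile(pr, max_d = 1.2, bin_width = 0.06)
c(C0 = cp$C[1], C_far = tail(cp$C, 1), PCC = pearson_colocalization(pr))
#>        C0     C_far       PCC
#> 1.1983...  0.987...  0.886...
```

The Mann–Whitney U of 0 says every FC-like pI is below every DFC-like pI —
the planted D/E tracts acidify the class; the AUROC of 1.0 shows the
feature classifier recovers the planted three-class structure from
held-out folds; `C(0) ≈ 1.2 > 1` flags above-random colocalization of the
two co-registered channels, decaying to ≈ 1 beyond the spot size.

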