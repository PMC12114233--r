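# dockclass

Binary activity classification from molecular docking scores.

Docking-based virtual screening produces a continuous score per molecule
(Glide-style convention: negative, lower = stronger predicted binding).
`dockclass` turns such scores into active/inactive classifiers and
quantifies how much two refinements — ensemble docking and
structural-similarity score calibration — improve on a single-structure
model. The motivating system is SGLT2 inhibition by gliflozin-like
compounds, but nothing in the package is specific to that target.

## Methods at a glance

**KDE-intersection threshold.** Fit a Gaussian kernel density estimate
(Scott's bandwidth) to the scores of the active and the inactive class and
take the crossing point of the two curves as the classification cutoff —
the score at which false-positive and false-negative density mass are
penalized evenly. The active side of the cutoff is inferred from the class
means, so the same procedure handles raw docking scores (actives low) and
calibrated scores (actives high).

**Ensemble docking (rank-by-number).** For every subset of target
structures of sizes 2–K, each compound's ensemble score is the arithmetic
mean of its per-structure scores (compounds missing any member score are
excluded); one threshold model is fitted per subset, and the 26 subsets of
five structures are ranked by MCC.

**Similarity-weighted calibration.** Query scores are corrected by
reference ligands with known activity,

    DS_j = DS_j0 * (1/w) * sum_i S_ij^p * (dG_i / DS_i),   w = sum_i S_ij^p

with `S` a Tanimoto similarity matrix over molecular fingerprints
(MACCS keys, radius-2 circular, or path-based) and `dG` on the pChEMBL
scale, so calibrated scores approximate pChEMBL values. The exponent `p`
is chosen from the grid 4–60 (step 8) by stratified 5-fold
cross-validation on mean MCC; the final threshold is the mean of the fold
thresholds.

Support modules: activity labeling at pChEMBL > 8 with conflicting-label
filtering, stratified fold assignment, MCC / balanced accuracy / ROC AUC /
enrichment factor, a paired R/S-stereoisomer score comparison with
interaction-fingerprint loss tallies, and a synthetic-data generator
(score tables, gliflozin-like SMILES libraries with a
structure–activity neighborhood signal, paired stereo libraries, binary
interaction matrices) so the whole pipeline runs with no docking engine.

## Worked example

```r
library(dockclass)

# KDE-intersection threshold on two known Gaussian score classes
set.seed(2024)
actives   <- rnorm(5000, -10, 1)
inactives <- rnorm(5000,  -8, 1)
find_threshold(actives, inactives)
#> threshold_model: threshold = -9.0234 (lower_is_active)
#>   class means: active -9.9972, inactive -8.0155
```

The fitted cutoff sits at the crossing of the two class densities, within
0.03 of the analytic midpoint −9 of the two means; compounds scoring below
it are called active.

```r
# full three-methodology comparison on a synthetic docking study
res <- run_full_comparison(list(seed = 1))
res
#> Three-methodology comparison (seed 1 )
#>                  method                                       detail   mcc    ba
#>  similarity_calibration                      morgan_circular, p = 20 0.453 0.720
#>        ensemble_docking struct_1+struct_2+struct_3+struct_4+struct_5 0.418 0.709
#>           docking_score                                     struct_1 0.380 0.691

res$calibration
#> calibration_result (morgan_circular): best p = 20, mean CV MCC = 0.453
#>   final threshold (mean over 5 folds) = 7.997
```

On the default synthetic study (260 gliflozin-like compounds, five
pseudo-structures, single-structure screening AUC ≈ 0.7) the calibrated
model beats the best ensemble, which beats the single-structure model —
and because calibrated scores approximate pChEMBL values, the
cross-validated classification threshold lands next to the activity cutoff
of 8 used for labeling.

```r
# paired stereoisomer comparison (R- vs S-configuration libraries)
pair <- simulate_paired_libraries(stereo_sim_config(seed = 42))
paired_score_test(pair$scores_R, pair$scores_S)
#> paired_comparison over 291 pairs
#>   mean R = -9.519, mean S = -9.268 (medians -9.518 / -9.253)
#>   mean diff (S - R) = 0.252, t = 6.682 (df 290), p = 1.21e-10
#>   95% CI [0.177, 0.326]
```

The S-configured library scores significantly weaker (less negative) than
its R-configured counterpart, the signature of a configuration-sensitive
binding site.

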