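---
title: "Docking-score classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking-score classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockclass)
```

## The problem

Structure-based virtual screening ranks candidate molecules by a docking
score — a physics-motivated estimate of binding affinity, conventionally
negative with lower values meaning stronger predicted binding. Turning that
continuous score into a binary *active / inactive* call requires a cutoff,
and a principled one should account for where the two classes actually sit
on the score axis. `dockclass` implements three ways of building such a
classifier from a table of per-compound, per-structure docking scores, with
SGLT2 (the renal sodium/glucose co-transporter targeted by the gliflozin
drug class) as the motivating system:

1. **KDE-intersection threshold** on the scores of a single target
   structure;
2. **ensemble docking**: the same threshold procedure applied to the
   rank-by-number mean score over a subset of target conformations, scanned
   over all subsets;
3. **similarity-weighted score calibration**: each compound's score is
   corrected by the similarity-weighted activity/score ratio of reference
   ligands, with the similarity exponent chosen by stratified
   cross-validation, and the threshold procedure applied to the calibrated
   scores.

A paired stereoisomer comparison (R- vs S-configuration at the sugar C5
position of gliflozin-like inhibitors) with interaction-fingerprint loss
tallies completes the toolkit.

## The threshold method

For each class we fit a Gaussian-kernel density estimate with Scott's
bandwidth `sd(x) * n^(-1/5)`. The classification threshold is the crossing
point of the two class densities: at that score the estimated density of
actives equals that of inactives, so moving the cutoff in either direction
trades false negatives against false positives unevenly. Numerically the
two densities are evaluated on a common 2048-point grid spanning the pooled
scores plus three bandwidths of padding on each side; sign changes of their
difference are located and refined by linear interpolation. KDE tails can
produce spurious extra crossings, so among multiple candidates we keep the
one lying between the two class means and nearest their midpoint. If the
densities never cross inside the grid, fitting fails loudly with the grid
bounds.

The *orientation* of the rule (which side of the threshold is active) is
inferred from the class means rather than hard-coded, because the two score
spaces used in this package have opposite polarity: raw docking scores put
actives low, calibrated scores (which approximate pChEMBL activity values)
put actives high. A score exactly at the threshold is classified inactive;
the convention is arbitrary, affects a measure-zero event, and is
documented in `classify()`.

Per-class bandwidths are fitted independently; pooling them is a defensible
alternative, but the class samples can have quite different sizes and
spreads, and independent fits follow the usual one-sample KDE default.

## Activity labeling

Activities arrive as pChEMBL values (−log10 molar). A compound is *active*
when **every** recorded value exceeds 8.0 strictly, *inactive* when every
value is at or below 8.0; compounds whose values straddle the cutoff get
conflicting labels and are dropped. After labeling, compounds with more
than one activity value are removed entirely (`drop_multi_activity()`) so
every modeled compound has an unambiguous activity. The strict `> 8`
reading of "above the threshold" puts a compound at exactly 8.0 in the
inactive class; boundary records are rare and the choice is visible in the
function contract.

## Ensemble docking

`enumerate_ensembles()` lists all structure subsets of sizes 2–K (26
subsets for K = 5). For each subset the *rank-by-number* score of a
compound is the arithmetic mean of its scores in the member structures. A
compound missing a score in any member (a failed dock) is excluded from
that ensemble rather than averaged over the available members: partial
means would mix ensembles of different effective sizes and bias the
ranking. Each ensemble gets its own threshold model fitted and evaluated on
its own retained compounds, matching how per-structure dock counts differ
in practice; ensembles are then ranked by MCC.

## Similarity-weighted calibration

The calibration corrects a query score by reference ligands with known
activity:

$$DS_j = DS_j^0 \cdot \frac{1}{\omega} \sum_i S_{ij}^p \,
\frac{\Delta G_i}{DS_i}, \qquad \omega = \sum_i S_{ij}^p$$

`S` holds Tanimoto similarities between query and reference fingerprints
and the integer exponent `p` sets how sharply the correction concentrates
on the nearest references: at `p = 4` the correction is a broad consensus,
at `p = 60` it is dominated by the single most similar reference. We take
`ΔG` to be the reference pChEMBL value rather than a kcal/mol binding
energy: the ratio `ΔG/DS` is then (pChEMBL per score unit), so calibrated
scores land on the pChEMBL scale — which is exactly why the fitted
thresholds on calibrated data come out near the labeling cutoff of 8, a
useful internal consistency check that the package's cross-validation
reproduces on synthetic data. References with a zero docking score must be
excluded upstream (the ratio is undefined); a query with zero total weight
is passed through uncalibrated and flagged.

`cross_validate_calibration()` runs the exponent grid `4, 12, …, 60` (8
points) under a stratified 5-fold split: each fold once becomes the query
set, calibrated against the union of the other folds, with a threshold
model fitted and scored on that fold. The best `p` maximizes the mean fold
MCC; ties go to the smaller `p` (the least similarity dependence). The
final threshold is the mean of the five fold thresholds at the best `p`,
and `apply_final_model()` carries it to an external set that must be
disjoint from the references.

Three fingerprint families are supported through the OpenBabel backend:
`maccs_keys` (166 structural keys), `morgan_circular` (radius-2 circular,
reported at 4096 bits by the backend and folded by OR to 2048), and
`path_based` (linear paths up to 7 bonds, 1024 bits). SMILES are
canonicalized before hashing so alternative spellings of one molecule map
to one fingerprint. Fingerprints are computed in one batch process per
call; per-molecule round trips through the toolkit are two orders of
magnitude slower and would dominate the cross-validation runtime.

## Stereoisomer comparison

`invert_stereocenter()` flips the tetrahedral parity marker of a chosen
atom directly in the SMILES string (with OpenBabel canonicalization
available for comparisons), which is all that inverting a configuration
requires; docking the inverted library is out of scope.
`paired_score_test()` is the classical paired t-test on index-aligned
score vectors (S − R differences, two-sided, 95% CI), refusing
zero-variance differences rather than reporting an infinite t statistic.
`interaction_loss_tally()` compares two binary ligand × (residue,
interaction-type) matrices by column sums; losses above a reporting cutoff
(default 5, i.e. strictly more than five lost interactions) are listed in
descending order, gains are kept in a separate log, and the full per-column
difference vector is returned so totals can be audited: total losses minus
total gains always equals the difference of the matrix totals. The
denominator of the reported loss fractions is configurable (default: the
R-library ligand count) because the natural choice — docked R library,
docked S library, or the full designed library — depends on the question
being asked.

## The synthetic-data generator

All pipeline stages are testable without a docking engine:

* `simulate_scores()` draws class-conditional Gaussian scores for
  `n_structures` pseudo-structures. Each compound has a shared latent
  affinity deviation plus independent per-structure noise; the parameter
  `rho` is exactly the inter-structure score correlation. This mirrors the
  mechanism that makes ensemble averaging work — only the independent
  component averages away.
* `simulate_library_smiles()` builds gliflozin-like molecules
  combinatorially: a glucose nucleus C-linked to a substituted aromatic
  ring, a methylene bridge, and a second substituted ring, with 18
  substituents per position. Each substituent carries a latent activity
  effect (SD 0.8 pChEMBL units) and compounds add base activity 7.8, their
  two fragment effects, and measurement noise (SD 0.25). Molecules sharing
  fragments therefore look alike to a fingerprint *and* act alike — the
  neighborhood signal the calibration exploits.
* `simulate_study()` couples the two: per-structure scores are
  `-5 − 0.5 · pChEMBL` plus correlated noise (total SD 1.2, shared
  fraction `rho = 0.5`, 2% dropout). These defaults were chosen to put the
  single-structure screening performance in the realistic mid-range of
  docking campaigns (ROC AUC ≈ 0.7) rather than in an optimistic regime
  where no score correction could help; they produce the qualitative
  method ordering (calibrated > ensemble > single-structure MCC in the
  median) that motivates the three-method comparison.
* `simulate_paired_libraries()` defaults to 291 pairs with a mean
  disadvantaged-configuration shift of 0.26 score units and a per-pair SD
  of 0.65, the latter implied by a 95% CI of half-width 0.075 at that
  sample size.

What the generator does *not* emulate: multimodal or skewed score
distributions, activity cliffs (structurally near-identical compounds with
opposite activity), systematic docking failures concentrated in one
chemotype, and assay noise heterogeneity. Green property tests on this
generator therefore demonstrate internal correctness and the direction of
the methodological effects, not field performance on real screening data.

## Numerical and design choices

* **Stratified folds**: per-class shuffle under one seed, then round-robin
  assignment; per-fold class counts differ by at most one, and the split
  is a pure function of (labels, k, seed).
* **MCC degenerate denominator** (a zero row or column sum) returns 0 with
  a warning — the common convention for an uninformative table.
* **Enrichment factor** uses `ceiling(fraction · N)` for the top-set size;
  ties at the cutoff rank are resolved by stable sort order. Published EF
  variants differ in tie handling; ours is documented and
  self-consistent.
* **ROC AUC** is the rank statistic (ties count one half), implemented
  directly and cross-checked in the tests against an independent ROC
  package and against all-pairs enumeration.
* **Determinism**: every stochastic stage takes an explicit seed;
  `run_full_comparison()` derives stage seeds from one master seed by
  hashing the stage name, so stages can be re-run independently yet
  reproducibly, and a rerun of the same config is byte-identical.
* **Problem sizes in the test-suite**: distributional checks run at
  n = 5000 per class where a closed form is being recovered (threshold
  midpoint ± 0.1), and at 120–300 compounds for pipeline-level properties
  over 25–50 seeds, sizes at which the Monte-Carlo variability of each
  property is comfortably below the asserted margins.

## Known limitations

* Fingerprint bit layouts follow the OpenBabel backend; other toolkits'
  MACCS/circular/path implementations will produce different similarity
  values, so thresholds and best exponents are not transferable across
  backends.
* The path-based family is 1024 bits wide (the backend's native width),
  not 2048 as circular fingerprints are.
* The KDE intersection assumes unimodal, overlapping class distributions;
  heavily multimodal score distributions can put the chosen crossing far
  from any useful operating point.
* Calibrated scores inherit the multiplicative noise of the query's own
  docking score; calibration sharpens classification when the activity
  neighborhood is informative, it cannot remove score noise entirely.
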