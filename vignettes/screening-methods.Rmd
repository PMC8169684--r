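---
title: "Methods: herbicide-likeness screening and mode-of-action modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: herbicide-likeness screening and mode-of-action modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Weed resistance is managed in two ways: rotating herbicides with different
modes of action (MoA), and finding new phytotoxic chemotypes — natural
products being the richest source. Both call for the same computational
machinery: a way to say whether a candidate molecule *looks like* a herbicide
(physicochemical likeness), which weed-selectivity class it would fall into
(broadleaf-selective BL, grass-selective G, non-selective NS), and which MoA
class its structure points to — together with an honest statement of when
those predictions should not be trusted.

`herbiscreen` composes these into a stepwise cascade:

1. **Herbicide-likeness filter** — six descriptor-range criteria; compounds
   satisfying at least four proceed.
2. **Weed-selectivity prediction** — a multi-class classifier over nine
   whole-molecule descriptors, gated by a *physicochemical applicability
   domain* (AD).
3. **MoA prediction** — a multi-class classifier over MACCS structural keys,
   gated by a *structural AD*.

Every stage is also runnable in audit mode, which computes all quantities for
all compounds regardless of the gates, so domain membership can be tabulated
for a whole library.

## Structural representation

Structures enter as SMILES and are standardized once: the largest organic
fragment is kept (counter-ions stripped, ties broken lexicographically on the
canonical string), formal charges are neutralized where a neutral form exists,
and the canonical form is returned. Permanently charged species (quaternary
ammonium; internally balanced groups such as nitro) are kept as they are —
some important herbicide classes are permanent cations, so rejecting or
force-neutralizing them would be wrong. Cleaning is idempotent, and the
synthetic generator emits structures that are already fixed points of it.

The structural descriptor is the 166-key MACCS substructure fingerprint.
Following the key-frequency protocol, keys present in strictly more than
`min_count` training compounds (default 5) are retained; the retained-key
list travels with the trained model so external compounds are always
fingerprinted consistently. Structural similarity is the Tanimoto coefficient
TC on retained keys; dissimilarity is the Jaccard distance 1 − TC.

## Physicochemical descriptors

The selectivity models and the likeness filter use whole-molecule
descriptors: HBD and HBA counts (OH/NH donors; O/N acceptors), clogP, TPSA,
relative polar surface area (RelPSA), net charge, molecular weight, carbon
and sp³-atom counts, a shape index, log aqueous solubility (logSw) and log
aqueous diffusivity (logDiff).

Several of these are classically computed with closed commercial tools. This
package computes open equivalents and accepts externally supplied values as
overrides (used verbatim and flagged):

* **clogP** — the toolkit's additive atom-contribution estimate.
* **logSw** — the ESOL regression (Delaney 2004):
  `0.16 − 0.63·clogP − 0.0062·MW + 0.066·RB − 0.74·AP` with RB rotatable
  bonds and AP the aromatic-atom proportion.
* **ShapeIndex** — topological graph diameter divided by heavy-atom count,
  oriented so spherical < 0.5 < linear. A crude but monotone stand-in for
  3-D shape scores.
* **RelPSA** — TPSA divided by an additive total-surface estimate
  (free-sphere van der Waals areas scaled by 1/3; the scale reproduces
  benzene's ≈110 Å² surface).
* **logDiff** — Hayduk–Laudie,
  `D = 13.26×10⁻⁵ / (η^1.14 · V^0.589)` cm²/s with η the water viscosity in
  cP (0.8904 at 25 °C) and V a LeBas additive molar volume (per-element
  increments, −15 cm³/mol per ring; benzene = 96 cm³/mol). Reported as
  log₁₀ of D in 10⁻⁵ cm²/s units, so V = 100 cm³/mol gives ≈ 0.
* **Net charge** — a SMARTS rule list rather than a pKa engine: basic
  nitrogens (aliphatic amines, amidines/guanidines, quaternary N) minus
  acidic oxygens (carboxylic, sulfonic, phosphonic, N-hydroxy). Acetic acid
  scores −1, ethylamine +1, any neutral hydrocarbon 0. The rule lists are
  arguments, so they can be extended without touching the code.

Before modelling, descriptor matrices are scaled column-wise to zero mean and
unit sample standard deviation. Scaling statistics are learned on the
training set only and stored with the model; external compounds are always
placed into the *training* frame. (Fitting the scaler on all data at once
would leak test information into training; the package deliberately avoids
that, accepting that this may differ from workflows that scaled the full
set.) Fingerprint bits are never scaled. A constant column is an error, not a
silent NaN.

## Clustering and its validation

Chemical-space structure is explored with agglomerative clustering on the
Jaccard distance matrix using Ward's minimum-variance criterion in its
squared-distance ("ward.D2") form, since the dissimilarity fed in is not an
squared Euclidean distance. Internal validation uses the Dunn index (minimum
between-cluster separation over maximum cluster diameter), Dunn2 (minimum
average between-cluster dissimilarity over maximum average within-cluster
dissimilarity), and the average silhouette width; agreement with external
labels uses the adjusted Rand index (ARI). Dunn and Dunn2 are implemented
directly from their definitions; the silhouette comes from the `cluster`
package (singleton clusters contribute 0); ARI is pair-counting with the
expected-index correction and is cross-checked against an independent
implementation in the test suite.

## Classifiers and tuning

The primary classifier is a random forest: its class probability for a
compound is the fraction of trees voting for the class, which doubles as a
confidence score for the applicability domain. XGBoost, an RBF-kernel SVM and
naive Bayes are available behind the same interface for comparison; the
forest remains the only one wired into AD gating, because SVM scores would
need calibration before they could be read as probabilities.

Hyperparameters are selected by grid search under repeated stratified
cross-validation (default 10 × 10-fold; the test suite and examples use
5-fold with 1–2 repeats to keep runtimes in minutes). Fold assignment is
stratified by dealing each class's members round-robin over a shuffled fold
order, so no fold ever holds out an entire class — with very small classes
this smoothly degrades toward leave-pair-out behaviour without a special
case. Ties in mean resampled accuracy go to the least complex grid point
(smallest `mtry`, lowest cost, shallowest trees). The final model is refit on
the whole training set with the winning parameters, and every fold-level
accuracy is retained for resampling comparisons. All stochastic steps take
explicit seeds and restore the caller's RNG state.

The default forest grid tunes `mtry` over `{√p/2, √p, 2√p, p/3}` with 500
trees — the single influential forest parameter.

### Splitting protocol

Class-labelled sets are split by stratified random sampling: classes with
fewer than 3 members are excluded from modelling and relabelled to the
catch-all "Z" class; classes of 3–5 members are split 50:50; larger classes
80:20 with the train count rounded half-up and at least one member left in
each part. The split is a partition — train, test and excluded ids are
disjoint and jointly exhaustive — and deterministic given its seed.

### Performance metrics

Per class, one-vs-rest counts give sensitivity, specificity, precision, F1,
balanced accuracy and Cohen's kappa `(Po − Pe)/(1 − Pe)`; multi-class
summaries add unweighted macro averages, overall accuracy and multi-class
kappa from the confusion-matrix marginals. A zero denominator defines the
affected rate as 0 and raises a degenerate-denominator flag rather than
producing NaN. The worked example TP=40/FN=10/FP=5/TN=45 → kappa 0.7,
F1 0.8421 is kept as an executable check, and the formulas are cross-checked
against `caret::confusionMatrix` in the test suite.

## Applicability domains

A prediction is reported as reliable only inside the model's domain:

* **Structural AD** (MoA model): minimum Jaccard distance to the training
  fingerprints < 0.4 — i.e. TC > 0.6 to at least one training compound — AND
  predicted class probability > 0.6.
* **Physicochemical AD** (selectivity model): minimum Euclidean distance to
  the training compounds in the scaled nine-descriptor space < 2.0 AND
  predicted class probability > 0.6.

All four thresholds are strict inequalities (a probability of exactly 0.6
fails) and configurable for sensitivity analysis. Verdicts are pure functions
of (distance, probability) and monotone: moving closer to training or gaining
confidence can never push a compound out of the domain. Out-of-domain
predictions keep their label in the report but are flagged unclassified.
The Euclidean domain uses all nine scaled descriptors; no subset is dropped
for the distance.

## Herbicide-likeness rules

Six descriptor families, one vote each, evaluated on raw (unscaled) values:

| family     | strict            | lenient           |
|------------|-------------------|-------------------|
| HBD        | ≤ 2               | ≤ 2               |
| HBA        | ≤ 6               | ≤ 7               |
| clogP      | 0.5 < x ≤ 3.5     | 0.5 < x ≤ 4.5     |
| TPSA       | 20 < x ≤ 120 Å²   | same              |
| RelPSA     | 0.1 < x ≤ 0.5     | same              |
| net charge | ≤ 0               | ≤ 0               |

Ranges are half-open `(lo, hi]`: clogP = 0.5 fails, TPSA = 120 passes. A
compound passes the filter with ≥ 4 satisfied families. Both variants are
first-class because published screens report both bound sets without fixing
which one fed their pass counts; the lenient variant is the default, and a
screen can simply be run twice to report both. Tightening any bound can only
lower a compound's criterion count — this monotonicity is enforced by test.

## The synthetic compound generator

Real labelled herbicide tables are not redistributable here, so the generator
creates the two regimes the models assume, and the whole pipeline is
validated on them:

* **Scaffold classes** (MoA analogue): each class grows from one scaffold
  template (sulfonylurea-like diphenylurea, phenoxyacetic, cyclohexanedione,
  azines, …) with a Poisson number of substituents (default rate 2) drawn
  uniformly from a common pool and placed at random open ring positions.
  Classes are therefore structurally separable — high within-class, lower
  between-class Tanimoto similarity — which is the regime in which
  fingerprint classifiers are expected to reach high accuracy.
* **Selectivity classes** (BL/G/NS): all classes share the same small
  aromatic scaffolds; the classes differ only through their substituents.
  Per-class targets (defaults: NS clogP 1.0 / TPSA 110 / HBD 2;
  G 3.5 / 40 / 0; BL 2.5 / 60 / 1) are translated into expected counts of
  lipophilic, polar, H-bond-donor and acidic substituent groups. Counts are
  drawn under-dispersed (integer base + Bernoulli fraction + sparse jitter)
  because a curated selectivity class sits tightly around its characteristic
  polarity; the donor count is held at the class target (the distinguishing
  signature — "mostly one donor" for BL, two for NS, none for G), an acidic
  OH counts toward the donor budget, and donors are kept preferentially when
  a draw exceeds the scaffold's open slots. Shifts are realized entirely by
  substituent choice — descriptor values are never edited after computation,
  so the full descriptor pipeline is exercised honestly. An empty shift list
  produces a null set on which classifiers perform at chance.
* **Unseen families**: three natural-product-like cores (pyranose sugar,
  decalin terpenoid, polyketide fragment) are structurally remote from the
  synthetic-herbicide templates and serve as probes of the structural AD.
  Decorated sugar and polyketide families are rejected by the structural
  domain at ≥ 90%; compact aliphatic rings (decalin, cyclohexanedione) land
  closer to the training space in MACCS representation (~75% rejection) —
  a known coarseness of fragment-key similarity, and one reason the domain
  also requires a confident class probability.

What the generator does *not* emulate: real herbicide chemistry and
synthesizability, the size and 19-class imbalance of curated MoA sets, tail
physicochemistry (zwitterions, organometallics), or assay noise in labels.
Passing the synthetic recovery tests therefore shows the pipeline is
correctly wired and statistically sound under its assumptions — not that the
same accuracies will be reached on any particular real compound table.

## Numerical and design choices

* Strict inequalities at every gate boundary, matching the stated threshold
  wording; boundary behaviour is pinned by tests.
* Probability rows are renormalized to sum exactly to 1; argmax ties break in
  label-vocabulary order, deterministically.
* 80:20 rounding is `floor(0.8·n + 0.5)` with ≥ 1 test member per modelled
  class; the convention is stated because published protocols rarely are.
* The Jaccard distance on non-empty fingerprints is a proper metric (the
  triangle inequality is verified exhaustively over all 6-bit vectors in the
  tests); two all-zero fingerprints have undefined similarity and raise an
  error rather than returning a silent 0 or 1.
* Open Babel accepts some malformed SMILES by silent truncation; a
  pre-validation step (balanced parentheses, brackets, ring-bond digits)
  turns those into explicit structure errors.
* Problem sizes in the tests and the acceptance script (tens of compounds
  per class, 5–10-fold CV with 1–10 repeats) were chosen so the full
  validation runs in minutes on one core while keeping every statistical
  check well-powered.

## Known limitations

* Open-source descriptor stand-ins (clogP, logSw, ShapeIndex, RelPSA) differ
  numerically from the commercial calculators used in published tables;
  rule-boundary counts near a bound can differ accordingly. Overrides exist
  precisely so externally computed values can be dropped in.
* The net-charge heuristic is a substructure rule list, not a pKa model; it
  will miss unusual ionizable groups unless the rule lists are extended.
* MACCS keys are coarse for very small or very decorated molecules; the
  structural AD inherits that coarseness (see the decalin note above).
* The exact identity of a retained-key subset depends on the training set;
  only the selection rule is reproducible, so retained keys are always
  persisted with the model rather than re-derived.
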