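---
title: "Dose-specific combination sensitivity: models, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-specific combination sensitivity: models, measures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combosens)
```

## The prediction task

`combosens` models the relative growth inhibition of a cancer cell line
treated with one or two drugs at explicit micromolar concentrations.
Inhibition is percent-like: 0 for an untreated control, 100 for complete
growth suppression, negative when treatment accelerates growth; values are
bounded to [−200, 200] and anything outside is treated as a measurement
artifact and discarded. Predicting at the dose level — rather than
predicting a synergy score aggregated over a dose grid — is the central
design commitment: it keeps the model output interpretable, lets any
downstream sensitivity (or synergy) measure be recomputed from predictions,
and avoids the known fragilities of synergy scores as a primary target.

Evaluation is *cell-blind* by default: the train/test split operates on
cell lines, never on individual measurements, so test cells are entirely
unseen. This mimics the clinically relevant question — what will work for a
*new* patient — and is substantially harder than a random entry-level
split, which leaks cell-line identity through other entries of the same
cell.

## Preprocessing

`preprocess_screen()` applies, in a fixed order: the [−200, 200] quality
filter; removal of entries with no dosed drug; removal of cell lines
without expression profiles; merging of same-drug "combinations" into
monotherapies at the summed concentration; rewriting of two-drug entries
with exactly one positive dose as monotherapies; replicate averaging;
log1p transformation of concentrations; and a per-drug minimum entry count
filter. The order matters and is observable: the quality filter acts on
inhibition before same-drug merging, so a merged monotherapy can never
carry an out-of-bounds inhibition.

Replicate detection canonicalizes drug pairs lexicographically, with each
concentration following its drug — the orientation of a pair in the raw
table carries no information. The drug-count filter is applied once, after
all other steps, and is not iterated to a fixed point; on realistic data
the second pass would remove at most a handful of borderline drugs, and a
single application keeps the operation idempotent and predictable. The
threshold itself is a parameter (`drug_min_entries`): large public screens
conventionally use 10,000, while desk-scale synthetic screens use 1.

The log1p scale is recorded on the table and enforced downstream: encoders
refuse raw-scale tables and the preprocessor refuses to normalize twice.
Dose-response reconstruction, by contrast, needs raw micromolar
concentrations, so `preprocess_screen(..., log1p_concs = FALSE)` produces
the replicate-averaged table on the original scale.

## Features

**Cell lines.** A PCA on training-cell expression profiles (centering
only, no per-gene scaling — public expression matrices arrive normalized,
and rescaling would up-weight low-variance genes). The number of
components is a parameter; 300 is a sensible default on a ~1000-cell
corpus, and desk-scale runs use 8–20, bounded by the training cell count.
The model stores training-cell gene means, so projecting a held-out cell
can never leak test information into the feature space; during
cross-validation the PCA is refit per fold on that fold's training cells
for the same reason.

**Drugs and concentrations.** Four encodings:

1. *onehot* — one feature per drug carrying its log1p concentration.
2. *onehottar* — onehot plus one count feature per target molecule
   (targets kept when hit by ≥ `min_target_degree` drugs, default 5);
   a feature counts the entry drugs hitting that target, so 0–2.
3. *maccs* — two binary fingerprint blocks, each followed by its drug's
   concentration.
4. *physchem* — as maccs with numeric descriptor blocks.

Feature-block layout is `[cell PCs | drug1 block | conc1 | drug2 block |
conc2]`; the layout is a frozen convention (any fixed one works), with
concentrations adjacent to their drug blocks. Constant fingerprint or
descriptor columns are dropped when the encoding config is built, computed
over the configured drugs — block lengths are therefore data-dependent,
not hard-coded. Settings 1–2 cannot encode drugs outside their index
(attempting to raises an error naming the drug); settings 3–4 can encode
any drug with known features.

The feature-block settings are order-dependent: drug order AB and BA
describe the same treatment with different vectors. `build_dataset(...,
duplicate = TRUE)` therefore includes every combination entry twice, once
per order, with identical targets; monotherapies once. The package's
validation suite demonstrates the consequence: a forest trained on
duplicated data predicts AB and BA nearly identically, while one trained
without duplication shows visibly larger AB/BA discrepancies on the same
world and seed.

## Models

Random forest (`ranger`), elastic net (`glmnet`) and a single-hidden-layer
neural network (`nnet`) sit behind one fit/predict contract, so the
algorithm × encoding benchmark is a loop rather than bespoke code. Two
baselines calibrate all results: the global training mean, and the
per-treatment mean (per drug for monotherapies, per pair for combinations,
global mean for unseen treatments).

Hyperparameter selection uses 5-fold cross-validation on training cell
lines (folds partition cells, entries follow their cell), choosing the
candidate with the smallest mean MAE across folds; ties break by grid
order. Default grids are deliberately small desk-scale choices: forest —
500 trees, sqrt features per split, min node size {1, 5}; elastic net —
mixing {0.1, 0.5, 0.9} × a log-spaced penalty grid; network — one hidden
layer of {8, 32} units with decay 0.1 and inputs standardized internally.
The network defaults are honest placeholders sized for a single CPU, not a
claim about optimal architecture. All stochastic components (split, folds,
tree seeds, weight initialization) derive from one pipeline seed.

## From predictions back to pharmacology

Inhibition converts to relative viability as `(100 − inhibition)/100`,
clamped to [0, 1].

**Curves.** The three-parameter logistic
`f(x) = c + (1 − c)/(1 + exp(b(log x − log e)))` is fit by
bound-constrained Levenberg–Marquardt least squares (`minpack.lm`),
optimizing `e` on the log scale for conditioning, with three starts
(`c₀ ∈ {min v, min v / 2, 0}`, `b₀ ∈ {1, 2}`, `e₀` at the geometric
mean/median concentration) and the best converged solution kept. Fits
require ≥ 5 points; fits with RMSE > 0.3 viability units (the conventional
satisfactory-quality bound) are rejected but retain their RMSE for
reporting. Near-constant viabilities (an inert drug) short-circuit to a
flat curve flagged `degenerate` — the slope is unidentifiable there and a
nonlinear fit would return noise.

**IC levels.** Inverted in closed form,
`x = e · ((1 − c)/(v* − c) − 1)^{1/b}`, undefined when the asymptote sits
above the target viability; a bisection root-finder exists only as an
independent oracle in the test suite, which checks agreement to 1e−9.

**CMax viability** evaluates the fitted curve at the drug's CMax. A CMax
beyond the screened range is an extrapolation of the fitted function and
is flagged, not refused: the logistic form is the model's explicit
assumption about behavior beyond the screened window.

**Dose-response matrices** are assembled per cell line and drug pair over
the screened concentrations augmented with a zero margin per axis:
viability 1 at (0, 0), monotherapy values along the margins, combination
values in the interior. The margins make bilinear interpolation
well-defined near the axes. Cells without measurements are flagged
missing.

**Combination CMax viability** is the minimum bilinearly interpolated
viability over an inclusive 100-point-per-axis lattice spanning
`[0, CMax_A] × [0, CMax_B]` (10,000 points). Including 0 in the lattice is
harmless — the untreated corner has viability 1 and cannot be the minimum
of a nontrivial surface. Matrix-based measures never extrapolate: a CMax
beyond the screened range is clamped to the screened maximum and flagged
(in contrast to the curve-based measure, where the fitted function is
trusted beyond the data). Interpolation operates on the viability scale
after clamping; interpolating inhibitions first and converting afterwards
would differ only through the clamp, and the viability convention is
frozen here. The grid minimum is validated against a dense 1000 × 1000
oracle (an independent hand-written bilinear interpolator) within the
grid-resolution bound — the largest viability difference between adjacent
matrix cells.

## Evaluation conventions

Overall Pearson correlations on multi-drug data are inflated by
between-treatment mean differences: constant per-treatment predictions
already correlate with the actuals. The package therefore reports
per-drug (monotherapies) and per-combination correlations alongside
overall values. Groups with fewer than two distinct actual values have an
*undefined* PCC — reported as `NA`, never as 0 — and macro-averages state
both the mean over defined groups and the count of exclusions, since
either convention (excluding or zero-filling) is defensible and the
choice changes the number.

Approach comparisons use paired Wilcoxon signed-rank tests on per-sample
absolute errors from identically keyed test samples, Bonferroni-adjusted
by the number of unordered pairs (12 approaches → 66 tests). Zero
differences are dropped before ranking (the classic signed-rank
convention). The effect size `r` is the standardized signed-rank statistic
divided by √(non-zero pairs); its sign encodes direction (positive when
the first approach errs more), its magnitude the strength.

Interval-stratified errors use half-open bins `(lo, hi]` with default
edges {−25, 0, 25, 50, 75, 100}.

Rankings are ascending in viability with lexicographic tie-breaks
(deterministic), Spearman correlations use 1-based average ranks for ties,
and top-k overlap uses the strict positional cutoff after tie-breaking.
Treatments lacking a CMax value are excluded from both rankings
symmetrically. The expected top-k overlap of a random permutation is
k²/n (hypergeometric mean), which the test suite verifies by simulation.

## The synthetic world

`generate_world()` produces screens whose ground truth is known exactly,
so every stage of the pipeline has a recovery target:

- each (cell, drug) monotherapy follows a 3PL whose inflection
  concentration is `exp(μ_drug + ⟨cell latent, drug effect⟩)` — the drug
  effect is a linear readout of the drug's fingerprint bits, so
  fingerprint-encoded models can learn potency, and the cell latent drives
  the expression matrix, so cell-blind generalization is learnable;
- combinations follow Bliss-style independence (product of monotherapy
  viabilities), with a localized Gaussian dip on the log-concentration
  plane for a configurable fraction of pairs — the "synergy window" that
  motivates defining the combination measure as a box minimum rather than
  a corner value;
- inhibition is `100·(1 − viability)` plus Gaussian noise with sd 7
  (the scale of replicate disagreement reported for large public
  combination screens), clipped to [−200, 200] *after* noise so extreme
  noise settings exercise the quality filter;
- dose grids are half-log-spaced around each drug's prior median potency —
  typical screening design — and the CMax sits at a configurable quantile
  of the screened log range (default 0.75).

Note one statistical subtlety the suite accounts for: the sample standard
deviation of k replicates is biased low by the factor c₄(k) (≈ 0.80 at
k = 2, ≈ 0.89 at k = 3), so the mean replicate sd of a world generated at
noise sd 7 converges to 7·c₄(k), not 7.

What the generator does *not* emulate: multi-source batch effects,
heteroscedastic or inhibition-dependent noise, missing-at-random dose
grids, drug-specific dose designs, and the marginal inhibition
distribution of any real database. Passing tests on this world
demonstrate that the machinery is correct and that the pipeline recovers
known signal; they do not certify performance numbers on real screens.

## Problem sizes

The test suite runs worlds of 5–16 cell lines, 4–7 drugs and 3–10
combination pairs with 5 doses per drug — large enough that every code
path (duplication, folds, margins, synergy windows) is exercised, small
enough to iterate quickly. `scripts/acceptance.R` uses 30 cell lines, 10
drugs, 20 combination pairs and 2 replicates (16,500 averaged entries),
with a 300-tree forest on 20 cell components; these sizes were chosen once
as a representative desk-scale screen.

## Known limitations

- The neural-network backend is a single-hidden-layer perceptron; it
  stands in for the algorithm class, not for tuned deep models.
- The combination CMax viability inherits the resolution of its 100 × 100
  lattice; pathologically narrow synergy pockets (narrower than one cell
  of the screened dose grid) are invisible to bilinear interpolation no
  matter the lattice density.
- Curve-based and matrix-based measures treat extrapolation differently
  by design (extrapolate-and-flag vs clamp-and-flag); mixing them in one
  ranking is legitimate but the flags should be inspected.
- Per-treatment rankings include whatever treatments have defined measures
  for that cell line; no availability filtering beyond that is applied.
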