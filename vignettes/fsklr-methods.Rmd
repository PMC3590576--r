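---
title: "Predicting beta-turns with fixed-size kernel logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting beta-turns with fixed-size kernel logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A beta-turn is a four-residue motif that reverses the direction of a
polypeptide chain: the C-alpha atoms of residues i and i+3 approach within
about 7 angstroms without the intervening residues forming a helix or a
strand.  Roughly a quarter of the residues of globular proteins sit in
turns, so a per-residue turn/non-turn classifier faces a 1:3 class
imbalance, strong spatial autocorrelation (turns come in runs of four or
more), and evidence that is spread over a local sequence window rather
than concentrated at the residue itself.

`fsklr` implements a sparse kernel logistic regression pipeline for this
problem: evolutionary profiles and predicted secondary structure are
encoded per residue over a sliding window, a fixed-size (prototype-based)
kernel logistic regression produces calibrated-in-the-large turn
probabilities, and ordered state-changing rules repair label patterns
that are inconsistent with the minimum turn run length.

## Feature encoding

Each residue is described by 216 features:

* **PSSM window (140).**  The position-specific scoring matrix (an
  L x 20 log-odds profile from an iterative homology search) is squashed
  elementwise through the logistic function `1/(1 + exp(-x))` and a
  seven-residue window centred on the residue is concatenated
  (20 x 7 = 140).  Window positions beyond either terminus contribute
  zeros.  The logistic squashing is position-independent, so no
  dataset-level statistics leak across cross-validation splits (min-max
  scaling would).
* **Secondary-structure blocks (76)** from four three-state (H/E/C)
  predictor sources in a fixed, enforced order: a per-source one-hot of
  the central state (12); the central confidence digit divided by 10 (4);
  per-source, per-state indicators of the four patterns SSS, SSX, XSS,
  XSX over the residue and its two neighbours, where X means "not S" and
  boundary residues fire no pattern (48); and per-source, per-state
  occupancy ratios over the window (12).

Features are then ranked by the average of their information-gain rank
and chi-squared rank (10 equal-width bins on [0,1]; ties broken toward
the lower feature index) and the top 90 are retained.  The discretisation
granularity and the average-rank fusion are package choices; both
criteria are standard filter scores and agree closely on this encoding,
and the fusion makes the selection robust to either score's tie
structure.  The selector is always fitted on training rows only; a
per-fold refit is the default in cross-validation.

## The classifier

Kernel logistic regression models the turn posterior through a logit,
`P(turn | x) = 1/(1 + exp(-f(x)))` with `f(x) = w'phi(x) + b`, fitted by
minimising the penalized negative log-likelihood

    (1/2) w'w + (lambda/2) sum_i log(1 + exp(-y_i f(x_i))),

with `y_i` in {+1, -1}.  Note the convention: `lambda` weights the loss,
not the penalty, so larger `lambda` means a better data fit (it plays
the role of 2C in the common C-parameterisation).  The kernel is the RBF
`K(x, x') = exp(-gamma ||x - x'||^2)`.  In the printed form of the logit
model the two class probabilities are sometimes stated with the opposite
sign attached to `f`; the package follows the loss above, under which
`f` is unambiguously the log-odds of the positive (turn) class.

Two fitting routes are provided:

* **Exact dual form** (`klr_fit_dual`): the representer expansion
  `f(x) = sum_i alpha_i K(x, x_i) + b` fitted by iteratively reweighted
  least squares on the dense kernel matrix.  Cost is cubic in n, so this
  is the small-data estimator and the correctness reference.
* **Fixed-size form** (`fs_klr_train`): m prototype vectors are selected
  by seeded k-means (k-means++ initialisation, Lloyd iterations to a
  1e-4 relative inertia change) with each centroid snapped to its
  nearest data row, so prototypes are actual residues.  Clusters smaller
  than `outlier_min_frac * n` are treated as outlier clusters and their
  prototypes are replaced once from the largest remaining clusters,
  since landmark sets polluted by outliers waste approximation capacity.
  The m x m prototype kernel is eigendecomposed and components above a
  1e-12 relative eigenvalue cutoff define the explicit Nystrom map
  `Phi = K_{n,m} U_p Lambda_p^{-1/2}`, whose Gram matrix is exactly the
  Nystrom approximation `K_{n,m} K_{m,m}^+ K_{m,n}`; the classical
  out-of-sample eigen-extension (eigenvalues scaled by n/m) is available
  as `nystrom_extension`.  The model is then fitted in this explicit
  p-dimensional space by a trust-region Newton method: conjugate-gradient
  inner solves truncated at the trust boundary, radius quartered when the
  actual-to-predicted reduction ratio falls below 0.25 and doubled when
  it exceeds 0.75 at the boundary, with a relative gradient-norm stop at
  1e-6.  Early iterations therefore take cheap approximate steps and the
  final iterations are full Newton steps.  The intercept rides along as
  an appended unpenalized coordinate.

At m = n the fixed-size route reproduces the exact dual probabilities to
better than 1e-3 (the suite checks 1e-8-level agreement on 50-point
problems), and the Nystrom reconstruction error in Frobenius norm
decreases monotonically in m on nested prototype sets, reaching zero at
full rank.

## Thresholding and state-changing rules

A residue is labelled a turn when its probability reaches the decision
threshold, 0.45 by default — slightly below 1/2 to favour sensitivity
under the 1:3 imbalance; ties count as turns.  Four ordered rules then
smooth each chain's label string:

1. `tnt -> ttt`  (isolated non-turn removed)
2. `ntn -> nnn`  (isolated turn removed)
3. `nttn -> tttt` (isolated pair completed to a run of four)
4. `ntttn -> ttttn` or `ntttt` (isolated triplet completed on the flank
   with the higher turn probability; ties go to the left flank)

Within a pass all matches are located on the pass-input string and
flipped together, which removes any scan-direction ambiguity; patterns
never extend past the chain termini.  After the full sequence, every
maximal turn run flanked by non-turns on both sides has length at least
four (runs touching a chain end may be shorter) — the suite verifies
this, and equality with an independent brute-force rule engine, on every
{t,n} string up to length 8.  Note that rules 3 and 4 can recreate a
`tnt` motif out of material rule 1 already passed over (for example
`tnnttn -> tntttt`), so the pass sequence is not idempotent; the rules
are applied exactly once, in order, as specified.

## Evaluation protocol

Quality is measured per residue with the Matthews correlation
coefficient, `Q_total` (accuracy), `Q_predicted` (precision),
`Q_observed` (sensitivity) and specificity, all derived from the
confusion counts with 't' positive.  Any measure with a zero denominator
is reported as `NA`, never as zero — with ~25% prevalence a degenerate
all-negative predictor already reaches `Q_total` = 75%, so the
undefined-precision case is common enough to deserve an explicit
sentinel.  ROC curves sweep the unique raw probabilities and AUC is the
trapezoidal area, computed before smoothing because the rules are
threshold-dependent; the AUC equals the normalized Mann-Whitney rank
statistic, which the tests exploit as an oracle.

Cross-validation is sevenfold at the chain level: chains are shuffled
under a seed (after sorting, so the plan depends only on the chain-ID
set) and dealt round-robin; every residue of a chain shares its fold and
folds keep their natural class proportions.  Per fold, the feature
selector and the model are fitted on the six training folds and the
held-out chains are scored residue-pooled; the summary is the arithmetic
mean over folds.  A held-out fold that contains a single class by chance
gets an `NA` AUC.  Hyperparameters (`lambda`, `gamma`) are tuned by an
exhaustive grid search on mean CV MCC (ties: higher `Q_total`, then
smaller `gamma`, then larger `lambda`); the defaults
`lambda in 2^{-6..6}`, `gamma in 2^{-8..2}` are log-2 grids.  The
prototype count is chosen by an incremental search that grows m until
the mean CV MCC stops improving by more than 0.005 for two consecutive
steps, reporting the full (m, Q_total, MCC) trace.  The full-jackknife
variant is available by setting k to the number of chains.

## The synthetic data generator

Real benchmark inputs (PSSMs from a homology search, four external
secondary-structure predictors, crystallographically assigned turn
labels) cannot be redistributed or regenerated offline, so the package
ships a seeded generator that emulates their statistical structure:

* **Labels**: a two-state renewal process — turn segments of length
  `min_run + Geometric(1/2)` and gaps of length `1 + Geometric(q)` with
  q calibrated so the expected prevalence is `turn_fraction` (default
  0.25, matching the ~25% of residues observed in turns).  Turns start
  only where at least `min_run` (default 4) residues remain, so every
  turn run is full length.
* **PSSMs**: integer-rounded Normal(mu, 1) log-odds with a class shift
  of `pssm_effect` (default 1.0) on the first `n_signal_cols` (default
  5) columns, applied on the logit scale before the logistic scaling —
  the same place real profiles carry their signal.  Rounding keeps the
  PSI-BLAST-style writer/reader round trip exact.
* **Secondary structure**: a latent true state per residue — coil for
  turn residues, H/E/C at 0.45/0.35/0.20 otherwise — emitted correctly
  by each of the four sources with probability `ss_accuracy` (default
  0.8), else one of the other two states; confidence digits are high
  (5-9) when the emission matches the latent state and low (0-4)
  otherwise, degraded by `confidence_fidelity`.  At `ss_accuracy = 1/3`
  the emissions and confidences are exactly uninformative, which the
  no-signal null test uses: the end-to-end CV AUC then sits at 0.5.

The generator's sources are conditionally independent given the latent
state, its residue composition is uniform, and its profile columns are
independent Gaussians — all simplifications relative to real data, where
predictors are correlated and profiles have strong compositional
structure.  Passing tests on this generator therefore demonstrate that
the machinery recovers signal of the assumed form, not that it attains
any particular accuracy on crystallographic benchmarks.

## Numerical choices and degenerate inputs

* IRLS step-halves whenever a Newton step would raise the objective and
  adds a 1e-10 diagonal jitter to its linear systems.
* The trust-region solver errors (with the last gradient norm) rather
  than returning silently on non-convergence; its CG forcing sequence
  `min(0.1, sqrt(||g|| / ||g_0||))` yields the superlinear tail the
  tests check.
* Duplicated prototypes only shrink the retained eigenspace (p < m);
  an all-below-cutoff spectrum is an error.
* Probability evaluation is overflow-safe via `log1p(exp(-|x|))`
  factorisations; decision values of +-800 produce exact 0/1
  probabilities without NaN.
* Single-class training splits abort cross-validation naming the fold;
  single-class held-out folds yield `NA` AUC.
* Model files round-trip predictions to full double precision
  (~1e-15 relative), not bit-for-bit, because numbers pass through
  decimal JSON.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
100 chains of 40-80 residues (~6,000 residues) for the end-to-end
sevenfold cross-validation, 40 chains for the prototype-count search,
350 chains (~21,000 residues) for the prevalence and reliability checks,
and 20-50-point problems for the solver-versus-oracle comparisons.
These sizes were chosen so that every check exercises the same code
paths as a full benchmark run while remaining quick on one CPU.

## Known limitations

* Per-decile reliability of the predicted probabilities is approximate:
  observed turn frequencies track the decile centres monotonically and
  the mean probability matches the prevalence to within 0.02, but
  individual deciles can deviate by up to ~0.15.  Logistic likelihoods
  guarantee calibration on average, not per probability bin, under model
  misspecification.
* Only the binary turn/non-turn problem is covered; turn-type
  classification (type I, II, VIII, ...) would require a multiclass
  extension of the same machinery.
* The four-source secondary-structure input format is a single
  documented columnar layout; converters from specific external
  predictors' native outputs are out of scope, as is running those
  predictors or a homology search.
* Turn labels are consumed, never derived: assignment from 3D
  coordinates belongs to structure-analysis tooling.
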