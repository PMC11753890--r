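---
title: "Multi-view clathrin prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view clathrin prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetclp)
```

## The problem

Clathrin is the principal coat protein of clathrin-mediated endocytosis;
recognizing clathrin proteins from sequence alone is a binary
classification task over protein sequences. `targetclp` implements a
multi-view pipeline for this task: four complementary per-protein
feature representations are extracted, fused with learned scalar
weights, pruned by a wrapper feature selector, and classified by a
recurrent neural network with a fixed decision threshold.

This vignette is the package's own account of each stage: the model, the
parameters that matter, the numerical conventions, and what the shipped
synthetic data can and cannot demonstrate.

## CLBP texture descriptors of profile matrices

The two transformed views treat an $L \times 20$ profile matrix as a
grayscale image and summarize its local texture with the completed local
binary pattern (CLBP).

**Scaling.** A profile matrix $P$ (a PSSM, or an energy-contact
expansion, below) is min-max scaled to 8-bit intensities:
$P_I = \mathrm{round}\!\left(255\,(P - \min P)/(\max P - \min P)\right)$.
A constant matrix maps to the all-zero image. Rounding is
round-half-to-even (R's `round()`), which is platform stable. Min-max
scaling makes every downstream descriptor invariant under positive
affine maps of the profile — a property the test suite checks
numerically.

**Code maps.** With a $3 \times 3$ window (radius $R = 1$, $N = 8$
neighbors), every interior pixel serves as a window center. Note that
"interior" means all rows $2..L-1$ crossed with columns $2..19$ — a
diagonal-only reading of the center index would give at most
$\min(L, 20)$ samples and could not fill a texture histogram. Three
codes are computed per center $c$:

* **C** (center): $1$ iff $P_I(c) \ge T$, where $T$ is the mean
  intensity of the whole image;
* **S** (sign): $\sum_{n=0}^{7} s_n 2^n$ with $s_n = 1$ iff
  $P_I(n) - P_I(c) \ge 0$. The sign bit is coded $\{0,1\}$, the standard
  CLBP convention: a $\{+1,-1\}$-valued sum cannot index a histogram
  space, so the package deliberately reads the signed variant sometimes
  printed in the literature as a typo for the standard coding;
* **M** (magnitude): $\sum_{n=0}^{7} m_n 2^n$ with $m_n = 1$ iff
  $|P_I(n) - P_I(c)| \ge T_m$, where $T_m$ is the mean absolute
  center–neighbor difference over the whole image, computed once per
  image.

Neighbors are indexed $n = 0$ at the east pixel, proceeding
counter-clockwise. Borders are not padded: only interior centers are
used, so each map has exactly $(L-2) \times 18$ entries. Padding schemes
would change histogram mass unpredictably; dropping the border is the
simplest deterministic choice.

**Histogram.** For $N = 8$ there are 58 *uniform* circular codes (at
most two 0/1 transitions); each gets its own bin, all non-uniform codes
share one catch-all bin (59 bins). The descriptor concatenates the
uniform-pattern histogram of S (59), the uniform-pattern histogram of M
(59) and the joint M-by-C histogram (59 bins for each value of the C
bit, 118), giving $59 + 59 + 118 = 236$ values. The decomposition is
recorded in the descriptor's `scheme` attribute
(`S_u2(59)+M_u2(59)+M_u2xC(2x59)`); among the decompositions that total
236 this one uses each operator exactly once and is the one the package
commits to. Bins hold raw counts by default (a normalization flag
divides by the center count), so the S and M parts each sum to
$(L-2) \cdot 18$ — a conservation law the tests assert.

**RECM-T.** The second texture view expands a sequence into an
$L \times 20$ matrix whose row $j$ is the energy-contact vector of
residue $j$ against the 20 standard amino acids, read from a symmetric
$20 \times 20$ residue-wise energy contact matrix (self-contact on the
diagonal, pairwise contact energies off it). Published energy tables
are not redistributed here — inventing published constants would be
worse than requiring them — so the matrix is a required runtime input;
for testing, `gen_energy_matrix()`
produces a clearly-synthetic symmetric stand-in with contact-energy-like
values in $[-8, 2]$.

Both views then share one code path: `pssm_clbp()` and `recm_clbp()`
each yield a 236-dimensional descriptor for any $L \ge 3$; shorter
sequences cannot host a $3 \times 3$ window and are rejected.

## QLC: composition/transition/distribution descriptors

For each of seven physicochemical properties (hydrophobicity,
normalized van der Waals volume, polarity, polarizability, charge,
secondary-structure propensity, solvent accessibility) the 20 amino
acids are partitioned into three groups. The shipped grouping table is
the canonical three-group CTD scheme from the descriptor literature
(`inst/extdata/ctd_groups.tsv`); because published variants of the table
exist, it is overridable via `ctd_groupings(path)`.

Per property the package computes, over the group-encoded sequence of
effective length $L'$ (unknown residues mapped to `X` are excluded):

* **C** (3): percentage of each group, summing to 100;
* **T** (3): for the unordered group pairs, the percentage of adjacent
  positions where the two groups meet in either order, out of $L'-1$;
* **D** (15): per group, the 1-based positions of the first occurrence
  and of occurrence number $\lceil q\,n_g\rceil$ for
  $q \in \{0.25, 0.5, 0.75\}$ plus the last occurrence, each as a
  percentage of $L'$. The ceiling rule is the common CTD convention; a
  group absent from the sequence contributes five zeros. Within a group
  the five slots are non-decreasing.

Concatenation over the seven properties gives
$7 \times (3+3+15) = 147$ features, of which the distribution block
contributes $7 \times 15 = 105$.

**Normalization.** The QLC block is z-scored per feature column,
$z = (x - \bar x)/\mathrm{sd}(x)$, with statistics fitted on training
rows only and persisted in the model bundle, so prediction-time inputs
are transformed identically (no train/test leakage). The sample
standard deviation ($n-1$ denominator) is used; zero-variance columns
get a unit divisor and a flag. A min-max variant is available behind
`fit_normalization(method = "minmax")` for users who prefer a $[0,1]$
range, but the z-score is the default because a formula beats a prose
description when the two disagree.

## Pooled language-model embeddings

The fourth view is a per-residue embedding matrix ($D \times L$,
$D = 1280$ for the ESM-1b transformer) collapsed to a fixed-length
vector by global average pooling over positions. Pretrained weights are
an external download and are never bundled; the package therefore
provides three sources behind one contract: `esm_embed()` (an adapter
that fails with an actionable error when no weights are present),
precomputed matrices loaded from disk, and `mock_embed()` — a
deterministic, bounded function of residue identity, position and seed
that exercises every pipeline stage without any model. The mock carries
no biological signal and is documented as such; pooling excludes any
special tokens by construction since the mock and the file format are
per-residue only.

## Weighted multi-view integration by differential evolution

The four views (ESM 1280, PSSM-CLBP 236, QLC 147, RECM-CLBP 236;
integrated width 1899) are fused by scaling each block with a scalar
weight and concatenating. Weights $w \in [-2, 2]^4$ are learned by
classic DE/rand/1/bin: population initialized uniformly in the box;
mutant $v = w_{r_1} + F\,(w_{r_2} - w_{r_3})$ with three distinct
non-target members; binomial crossover with a guaranteed coordinate
$k_{rand}$; strictly-greater greedy selection (ties keep the target).
Defaults follow the published optimizer settings: population $N = 100$,
$G_{max} = 50$ generations, $CR = 0.5$, $F = 0.5$. Out-of-bounds mutant
coordinates are clipped to the box — the simplest rule that preserves
the bound invariant — and the choice is recorded in the result object.

The objective is the mean MCC of a stratified 5-fold cross-validation on
the weighted features. The classifier inside this fitness is
configurable: the default is a closed-form dual ridge regression,
chosen because it is deterministic, costs milliseconds, and — unlike an
unregularized linear fit, whose decision rule is invariant to invertible
block scaling — is genuinely sensitive to the view weights, which is
what makes them identifiable. The full recurrent classifier can be
swapped in (`classifier = "snbilstm"`) when its
$\sim\!N \cdot G_{max} \cdot k$ trainings are affordable.

## Feature selection by binary tree growth

The integrated vector is pruned by a binary tree-growth (BTG)
metaheuristic. Continuous "tree" positions are binarized each iteration
by an S-shaped logistic transfer (bit set iff $\sigma(x) >$ a uniform
draw; a V-shaped option exists), and candidate masks are scored by
$\alpha\,(1 - \mathrm{metric}) + (1-\alpha)\,|m|/D$, minimized, with the
metric a stratified 5-fold 1-nearest-neighbor accuracy. The population
is partitioned by fitness rank into best (local refinement
$x \leftarrow x/\theta + r\,x$), competition (moves toward a
$\lambda$-mix of its two nearest neighbors among the better trees),
removal (worst trees re-initialized) and reproduction (noisy copies of
best trees). Defaults — population 30, 100 iterations, groups
6/12/6/6, $\theta = 0.8$, $\lambda = 0.5$, $\alpha = 0.99$ — are the
canonical tree-growth literature values; the exact variant used by any
run is persisted in its result. The best mask ever seen is returned, so
the fitness trace is non-increasing and the returned subset can never be
empty (all-zero candidates are repaired by forcing one random bit).
Published feature-subset sizes from specific datasets are
documentation, not reproducible targets: a wrapper selector's output
depends on the data and seeds.

## The SnBiLSTM classifier

The classifier consumes the (selected) feature vector as a short
sequence: chunks of `width` values (default 64) form
$\lceil D/\mathrm{width} \rceil$ timesteps, zero-padded at the tail. A
bidirectional LSTM (128 units per direction by default) encodes the
sequence; the final states of both directions are concatenated and
passed through a dense head. "Self-normalizing" is realized the
established way: SELU activations with LeCun-normal initialization and
the matching alpha-dropout (rate 0.05) on the dense layers, while the
recurrent cells stay standard. The sigmoid output is trained with
binary cross-entropy and Adam (learning rate $10^{-3}$, batch 32, up to
100 epochs, early stopping with patience 10 on training loss, keeping
the best parameters seen).

The forward and backward passes are implemented directly in R with
batched matrix operations and full backpropagation through time;
analytic gradients are verified against central finite differences in
the test suite. All randomness (initialization, shuffling, dropout)
derives from the configured seed, so training is bit-reproducible;
prediction is deterministic. Baseline variants (`bilstm` with a
ReLU/plain-dropout head, unidirectional `lstm`) share the train/predict
contract for structural comparisons.

The decision rule is exactly $p > Th$ with $Th = 0.5$ by default: a
probability equal to the threshold is classified negative. Class
weighting is off by default (the motivating datasets are near-balanced)
and available by flag.

## Evaluation machinery

Accuracy, sensitivity, specificity and MCC come from the confusion
table; a zero factor in the MCC denominator yields 0, flagged. AUC uses
the rank (Mann–Whitney) formulation with midrank ties, cross-checked in
the tests against an independent ROC library. AUPR is step-wise average
precision over score thresholds rather than trapezoidal interpolation,
which is optimistic on PR curves; the choice is recorded in the report.
Stratified k-fold (default $k = 5$) spreads each class across folds
with per-class counts differing by at most one, under a seeded shuffle.

## Synthetic data: what it shows and what it does not

Every input has a seeded generator: random sequences (uniform residue
composition), plausible profile matrices (+4 log-odds on the observed
residue, −1 elsewhere, integer Gaussian noise of sd 2, clamped to
$[-15, 15]$ — the integer range ASCII profiles actually use), symmetric
energy matrices, and two-class multi-view Gaussian feature sets with
planted informative dimensions. These emulate the *formats and scales*
of real data, not its biology: profiles have no phylogenetic
correlation structure, sequences no domain architecture, and the mock
embeddings no learned semantics. Passing tests therefore demonstrate
correctness of the transforms, optimizers and classifier on data whose
ground truth is known by construction — not predictive performance on
real clathrin datasets, which additionally requires real profiles from
an iterative database search, the published energy table and pretrained
embedding weights.

Test and verification problem sizes are chosen at desk scale as the
package's own convention: descriptor oracles run on $\ge 100$ random
matrices with $L \in [3, 60]$; weight-learning checks use planted-signal
designs with tens of rows; selector recovery uses $n = 100$, $D = 20$
with 5 informative columns shifted by 2 at unit noise over 10 seeds;
classifier sanity uses $n = 400$, $d = 50$ with a 4-sigma shift on 5
planted columns, where near-perfect stratified CV accuracy is expected
and permuted labels must fall back to chance.

## Known limitations

* The CLBP histogram decomposition is one of several that reach 236
  bins; descriptors are comparable only within one `scheme`.
* The BTG inner evaluator (1-NN accuracy) is fast but high-variance on
  tiny samples; selected subsets vary across seeds even when recall of
  planted features is stable.
* Training the recurrent classifier in base R is practical for
  desk-scale feature tables (thousands of rows); it is not a GPU
  framework replacement.
* The energy-contact placeholder and mock embeddings are synthetic;
  scientific use requires the real energy table and real embeddings.
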