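---
title: "Predicting ion-ligand binding residues from sequence windows"
author: "ionseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ion-ligand binding residues from sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionseg)
```

## The problem

Small ion ligands — acid-radical ions such as sulfate or phosphate, and
metal ions such as Zn²⁺ or Ca²⁺ — bind proteins through a handful of
residues. Identifying those residues from sequence alone is useful when no
structure is available. `ionseg` treats the task as residue-level binary
classification: every residue is represented by an odd-length sequence
window centred on it, and a kernel SVM decides whether the centre residue
binds the ion.

## The model

### Windows

For window length $L$ (odd), $(L-1)/2$ dummy residues `X` are appended at
both termini so that every residue, including terminal ones, appears once
as a window centre. A window is a positive example iff its centre is an
annotated binding residue. Residue-level annotations use 1-based
coordinates throughout; the padded string is purely internal.

### Five property alphabets

Each window position is encoded under five alphabets (pad class always
last; symbol order is fixed because features are order-sensitive):

| property | classes | size |
|---|---|---|
| AA  | 20 amino acids + pseudo residue `X` | 21 |
| HYD | strongly hydrophilic (R,D,E,N,Q,K,H); strongly hydrophobic (L,I,V,A,M,F); weakly hydrophilic (S,T,Y,W); P; G; C; pad | 7 |
| CHG | positive (K,R,P); negative (D,E); uncharged; pad | 4 |
| SS  | helix; sheet; coil; pad | 4 |
| SA  | exposed (relative accessibility strictly > 0.25); buried; pad | 3 |

The charge grouping lists proline among the positively charged residues;
chemically debatable, but it is the established grouping for this encoding
and we keep it. SS and SA come from per-residue tracks produced by an
upstream structure predictor and consumed as input files; `ionseg` does not
predict them. Composition vectors include the pad class frequency, so every
block stays normalized no matter how much padding a window carries.

### Composition features (39 dims)

Per-window symbol frequencies under the five alphabets, concatenated in the
order AA, HYD, CHG, SS, SA: $21+7+4+4+3 = 39$ dimensions, each block
summing to 1.

### Position-matrix scoring

For one class's training windows, the position frequency matrix is

$$p_{i,j} = \frac{n_{i,j} + \sqrt{N_i}/A}{N_i + \sqrt{N_i}},$$

where $n_{i,j}$ counts symbol $j$ at position $i$, $N_i$ is the column
total and $A$ the alphabet size (21 for amino acids; the pseudocount mass
$\sqrt{N_i}$ is spread uniformly over the alphabet, which generalizes the
amino-acid constant 21 to the other alphabets and keeps every column summing
to exactly 1 while forbidding zero probabilities). The weight matrix is the
log-ratio to a background distribution, $m_{i,j} = \log(p_{i,j}/p_{0,j})$,
and each position gets a conservation index

$$C_i = \frac{100}{\log A}\Big(\sum_j p_{i,j}\log p_{i,j} + \log A\Big)
\in [0, 100],$$

zero at a uniform column and 100 at a fully conserved one. A window with
observed symbols $j(i)$ scores

$$S = \frac{\sum_i C_i\,(m_{i,j(i)} - m_{i,\min})}
           {\sum_i C_i\,(m_{i,\max} - m_{i,\min})} \in [0,1].$$

Both $C$ and $S$ are invariant to the logarithm base (we use natural logs
and test the invariance). Positive-class and negative-class matrices are
fitted per property, giving two kinds of features: the per-position weight
lookups (2L values per property — "position conservation" features) and the
pair of $S$ scores per property (10 values over the five properties).

### Increment of diversity

A count vector $X = (n_1,\dots,n_s)$ with total $N$ has diversity
$D(X) = N\log N - \sum_i n_i\log n_i$ (with $0\log 0 = 0$), and two sources
compare through the increment of diversity
$ID(X,Y) = D(X+Y) - D(X) - D(Y) \ge 0$, which vanishes exactly on
proportional count vectors. Per property, the symbol counts of all training
windows of one class pool into a "standard source"; a test window's own
length-$L$ counts yield $ID$ against the positive and negative source — 10
values over the five properties. We use raw counts (not frequencies) on the
test side, the literal reading of the count-based formulas.

The 10 ID values followed by the 10 S scores form the 20-dimensional
*refinement* features.

### Classifier

A soft-margin SVM with the Pearson VII universal kernel
$$K(x,y) = \Big[1 + \big(2\sqrt{2^{1/\omega}-1}\,\lVert x-y\rVert/\sigma\big)^2\Big]^{-\omega},$$
trained by a from-scratch sequential-minimal-optimization solver
(maximal-violating-pair working-set selection, analytic two-variable
updates, explicit KKT gap as stopping rule). The solver is deterministic
and, in the tests, its dual objective is checked against an independent
interior-point QP solution of the same dual to $10^{-4}$ relative.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| window length $L$ | 9 (scan 5–17) | residues per window; odd |
| $\omega$ | 1 | PUK tailing exponent (1 = Lorentzian, large = Gaussian-like) |
| $\sigma$ | 1 | PUK half-width on the standardized feature scale |
| $C$ | 1 | SVM box constraint |
| tolerance | $10^{-3}$ | SMO KKT gap at convergence |
| background | pooled | $p_0$: add-one smoothed pooled frequencies, or uniform |
| folds / resamples | 5 / 10 | cross-validation protocol |

The original description of this model family does not report its SVM
toolkit settings; $\omega = \sigma = C = 1$ are the common toolkit defaults
and all three are exposed. Features are standardized to zero mean and unit
variance (statistics from training folds only): the blocks live on very
different scales (frequencies in $[0,1]$, ID values growing with $\log N$),
and a distance-based kernel would otherwise be dominated by the
largest-scale block.

## Evaluation protocol

Negative windows outnumber positives by tens of times, so evaluation draws
a negative subset equal in size to the positive set, uniformly without
replacement, then runs stratified 5-fold cross-validation on the balanced
set; this is repeated 10 times and the reported Sn/Sp/Acc/MCC are means
over the 10 resamples (within a resample, fold confusion counts are pooled
before computing metrics; per-fold macro-averaging is available behind a
flag). Everything fitted — matrices, sources, standardization, SVM — sees
training folds only; the suite asserts that permuting held-out labels
leaves every fitted artifact bit-identical. With a fixed seed the whole
report is bit-identical across runs.

The window-size scan runs this protocol at each odd $L$ (default 5–17) and
selects the $L$ maximizing mean MCC, breaking ties toward the smaller
window (less estimation variance at equal signal).

## The synthetic benchmark

No binding database ships with the package; a seeded generator produces
datasets with known ground truth:

- proteins of 90–110 residues (250 by default), background residues uniform
  over the 20 amino acids;
- 2% of residues per protein planted as binding sites — mirroring the
  strong class imbalance of real residue-level binding annotations, and
  sparse enough that most negative windows lie outside any motif
  neighbourhood (an earlier draft with a 10% rate let motif neighbourhoods
  cover most of each chain, which blurred the very contrast the benchmark
  exists to measure);
- residues within an odd influence window (default 7) of a binding site are
  drawn from the mixture $s \cdot \text{motif} + (1-s) \cdot \text{background}$,
  with the default motif uniform over R, G, K, S, H, T — the residues
  preferentially observed around ion-binding sites — and $s$ the signal
  strength;
- SS letters i.i.d. with a coil bias near binding sites; SA values from two
  beta modes (exposed $\sim$ Beta(6,2), buried $\sim$ Beta(2,6)), binding
  residues exposed more often, so the strict 0.25 exposure threshold is
  exercised from both sides;
- every binding-dependent bias scales with $s$, so $s = 0$ is a genuine
  null with exchangeable classes.

What passing on this benchmark shows: the full pipeline — windowing,
encodings, matrix and diversity fitting, SMO — recovers a planted
compositional/exposure signal and stays silent on null data. What it does
not show: performance on real proteins, whose binding sites are governed by
three-dimensional geometry, correlated residue usage, and family structure
none of which the generator emulates. The shipped worked example
(`inst/extdata/worked_example/`, regenerated by `make_worked_example()`) is
a miniature of the same generator for documentation and smoke tests.

## Numerical choices and degenerate inputs

- Square-root pseudocounts make zero probabilities impossible, so weight
  matrices are always finite; the background is strictly positive by
  add-one smoothing.
- A zero denominator in $S$ (every position uninformative) returns
  $S = 0$ with a warning instead of an error, so a degenerate training fold
  cannot abort a cross-validation run.
- MCC with a zero denominator factor is defined as 0 (warning); Sn/Sp with
  a zero denominator are reported as `NA`.
- Confusion products are computed in double precision (the four-factor MCC
  denominator overflows 32-bit integers already at a few hundred test
  windows).
- Prediction ties (decision value exactly 0) count as positive.
- Windows whose padding overhangs both termini ($L$ > protein length) are
  kept; padding guarantees their validity.
- Nonstandard residue letters (B, Z, U, O, J) map to the unknown residue
  `X` with a warning.
- SA values outside $[0,1]$ by at most $10^{-9}$ are clamped (warning);
  larger excursions are errors.

## Design choices that were genuinely open

- **Background $p_0$**: unspecified in the model family's description; we
  default to add-one smoothed pooled training frequencies (both classes),
  with `background = "uniform"` as the alternative.
- **"Position conservation" features**: realized as the 2L weight-matrix
  lookups per property; a model-independent one-hot site encoding is
  available behind `position_mode = "onehot"` since the flat encoding is
  the other defensible reading.
- **Test-side ID source**: the window's raw symbol counts, matching the
  count-based formulas; frequencies would differ only by the scale of $N$.
- **Resample-then-split ordering** for balanced CV, with stratified folds.
- **Problem sizes in the test-suite**: the planted-signal check uses the
  generator defaults (~500 positives, 10×5 CV, about 20 s); unit tests use
  miniatures of tens of proteins. These sizes are the package's own choice
  of a desk-scale benchmark.

## Known limitations

- Sequence-only: no structural neighbourhood, no per-ion chemistry.
- The SMO solver is quadratic in the training-set size per iteration
  scan; it is comfortable at the thousands-of-windows scale the balanced
  protocol produces, not for training on full unbalanced genomes.
- No probability calibration; decision values are margins, not
  probabilities.
- Redundancy reduction (sequence-identity filtering) is out of scope; if
  the input contains near-duplicate chains, cross-validation folds are not
  independent.
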