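---
title: "siStack: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{siStack: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
open design decisions were settled the way they were. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` compute at run
time.

## The prediction problem

An siRNA is a 19-bp RNA duplex whose antisense (guide) strand directs
cleavage of a complementary mRNA site. Measured silencing efficacy — the
percent inhibition of the target transcript, in [0, 100] — varies widely
between siRNAs, and the variation is partly encoded in the sense-strand
sequence: positional nucleotide preferences, composition, and the duplex's
stacking thermodynamics all carry signal. siStack predicts efficacy from the
sense 19-mer with a two-layer stacked ensemble and flags, for scanned
candidates, the thermodynamic regime in which its predictions are most
trustworthy.

Everything internal works on the sense strand, 5′→3′, positions 1–19; the
antisense strand is derived by reverse complementation where thermodynamics
need it. `T` is accepted as a synonym of `U` on input and normalized away.
Efficacy stays on the [0, 100] % scale throughout — Pearson correlation, the
selection criterion used everywhere, is scale-invariant, so no label
normalization is applied before training.

## Layer 1: characteristic methods

Each layer-1 method is an epsilon-SVR over one input representation.

**Sequence encodings.** Numeric maps A,U,C,G to 1,2,3,4 per position (width
19) — deliberately kept although an ordinal code is a poor fit for a kernel
machine, as a baseline. Binary is the one-hot code A = `0 0 0 1`,
U = `0 0 1 0`, C = `0 1 0 0`, G = `1 0 0 0`, position-major (width 76).
Hybrid appends to each quartet the fitted position weight
`p(b, n) = cor(indicator[s_n = b], efficacy)` (width 95). Zero-variance
indicator cells get weight 0 (with a warning) rather than NaN so the encoder
stays a total function.

**Feature sets.** Three candidate families are enumerated on the training
data: the 76 positional indicators; overlapping n-gram frequencies for
n = 2..5 (counting is *overlapping* — in `AAAA` the frequency of `AA` is 3 —
because overlap preserves strictly more information and is consistent with
the worked `AGGAG`/`AG` = 2 example); and 21 thermodynamic quantities (18
stacks, their sum, whole-duplex ΔH and ΔS; whether ΔH/ΔS should also enter
per-step is ambiguous, so the package exposes them as whole-duplex sums,
which keeps the thermo family at 21 elements). n-grams are enumerated from
subwords actually observed in the training set: an absent subword has zero
variance and no defined correlation. Selection keeps single/n-gram elements
with p < 0.001 (exact t-test of the Pearson correlation) and, when a
threshold is set, |r| strictly above it (matching the ">" convention of the
method family): F162 has no |r| cut, F85 uses 0.10/0.09 (single/n-gram), F65
0.12/0.10, F47 0.13/0.12. Thermodynamic elements are always retained.
Raising a threshold can only shrink the set, so the family is nested in
size. Element order is deterministic (single, n-gram, thermo; each sorted by
key), making fitted specs reproducible artifacts (`writeFeatureSpec()`).

**Thermodynamics.** The shipped parameter table is the Xia et al. (1998) RNA
Watson–Crick nearest-neighbor set (ΔG37/ΔH/ΔS), keyed by the 5′→3′
dinucleotide of the strand under evaluation; reverse-complementary steps
share one value because they name the same duplex stack. `whole_dG` is
strictly the sum of the 18 stacks spanning antisense positions 1–2 … 18–19 —
no duplex-initiation or terminal corrections — because it is used as a
*relative* stability feature and as a stratification variable, not as an
absolute folding energy. The orientation convention (stacks evaluated on the
derived antisense strand) is covered by an involution property test: the
stack vector of the reverse complement is the reversal of the original.

**Rule encoding.** Twelve published design-rule sets are shipped as an
editable config table mapping (set, position, nucleotide) to ±1; silent
cells are 0, so each position contributes 12 slots (width 228). Conflicts
*within* one set at one cell are rejected at load time; conflicts across
sets are real disagreements between publications and are preserved. The
shipped table is a best-effort curated transcription of the cited
guidelines, versioned in the file header; tests therefore exercise the rule
*encoder* with toy tables rather than asserting the curation itself.

**SVR settings.** The kernel and hyperparameters are genuinely open choices.
The default is an RBF-kernel epsilon-SVR (e1071/LIBSVM) with cost 10,
gamma = 1/width and epsilon 0.1 on standardized columns — cost 10 because
the planted-signal regression surfaces are smooth and the tighter fit
measurably helps at the few-hundred-sample sizes the package targets.
`svrConfig(tune = TRUE)` enables an inner 5-fold grid search (cost 2⁻³..2⁷,
gamma 2⁻⁹..2¹, epsilon {0.01, 0.1, 1}); it is off by default because the
full grid inside 10-fold cross-validation costs ~10⁴ SVR fits per method
for gains that the fixed defaults already capture on smooth synthetic
signal.

**Cross-validation.** `trainLayer1()` records the 10-fold cross-validated
Pearson r *before* any layer-2 use, refitting the entire encoder (position
weights, feature selection) inside every fold — selection on the full data
would leak. Folds are a deterministic function of the seed, so cv_r is
bit-reproducible.

## Layer 2: fusion

Methods with cv_r ≥ 0.6 (inclusive) are admitted and paired one
sequence-type × one feature-type. Whether the original two-layer scheme
trained layer 2 on in-fold or out-of-fold layer-1 predictions is not
determinable; siStack trains on **out-of-fold** predictions
(`buildStackingFrame()`), the standard stacked-generalization discipline,
because in-fold predictions provably inflate layer-2 training correlation —
exactly the overfitting mode that large feature sets exhibit.

Three mechanisms fuse the two component predictions:

- **SVR**: epsilon-SVR from 2 standardized inputs.
- **NN**: a 2-6-1 feed-forward network, sigmoidal hidden and output units,
  efficacy scaled to [0,1] internally and rescaled on output (so predictions
  are bounded in [0,100]). Fitting uses `nnet` (BFGS); the optimizer is an
  implementation detail of this architecture and the initial weights are
  seeded, so training is reproducible.
- **GA-evolved linear weights**: minimizes the MSE of `W1·R1 + W2·R2` over
  W ∈ [0,1]² with a generational GA — 16 bits per weight mapped linearly to
  [0,1], fitness-proportional (roulette) selection on inverse MSE, one-point
  crossover at 0.7, per-bit mutation at 0.001, population 100, elitism 1.
  Elitism makes the best MSE monotone non-increasing, and with two weights
  the box-constrained least-squares optimum is computable in closed form, so
  the GA is testable against an analytic bound (the suite requires it within
  5% relative MSE at 2000 generations). Weights are not constrained to sum
  to 1 — the least-squares optimum generally does not. The chromosome
  encoding, selection scheme and elitism level are documented choices, not
  claims about the original implementation.

`trainPipeline()` holds out a seeded 20% of the training data, trains
layer 1 and every admitted pair's fusion on the remaining 80%, and selects
the pair with the best held-out r. The final model stays fitted on the 80%
split — refitting on 100% after selection would make the admission values,
the stacking frame and the selection score describe a different model than
the one shipped. Tie-breaking is "first best" in deterministic pair order.

## Evaluation

`stratifiedEvaluate()` reports Pearson r plus Acc, Sn, Sp and MCC after
thresholding *both* observed and predicted efficacy at ≥ 70% inhibition
(inclusive; the two cuts are independently configurable for sensitivity
analysis). Sn/Sp are reported as absent — not 0 — when the truth has no
positives/negatives; a zero factor in the MCC denominator yields MCC = 0
with a warning (the conventional total extension). Percentages print to two
decimals.

Records are additionally split at whole ΔG = −34.6 kcal/mol, the boundary
falling in the "≥" (weak-stacking) stratum, and per-stratum r is reported;
a stratum with n < 3 reports r as absent. In experimental screens the
weak-stacking stratum is where efficacy prediction is more reliable, which
is why `scanTarget()` labels it `high_confidence` and the scan report
recommends it.

## The synthetic generator: what it does and does not show

`syntheticDataset()` emulates the *structure* of an siRNA screen: uniform
19-mers, efficacy in [0,100], a planted signal plus Gaussian noise,
`efficacy = clip(50 + effect·z(signal) + N(0, sd), 0, 100)`. Three signal
models: `gc_linear` (GC count), `thermo_linear` (negated whole ΔG, so
stabler duplexes score higher), `motif_rules` (count of planted
position-specific nucleotides, default G1/U10/A19). Defaults are
effect_size 15 and noise_sd 10 — roughly the signal-to-noise at which a
few hundred records support r ≈ 0.6–0.8 layer-1 models, the regime the
admission rule was designed for; the end-to-end checks use 1000 training /
300 test records at noise_sd 10.

What passing on synthetic data does **not** show: real screens have
correlated positional effects, batch structure, saturation at both ends of
the efficacy scale and label noise far from Gaussian; none of these are
emulated. One visible artifact: under `gc_linear` the planted signal is
collinear with duplex stability, so the ΔG ≥ −34.6 stratum (GC-poor, hence
low-signal-range) shows a *lower* r than the ΔG < −34.6 stratum — the
opposite of the experimental motivation for the split. The stratified
machinery is therefore validated separately with planted heteroscedastic
noise, where the expected ordering is constructed to hold.

## Numerical and degenerate-input choices

- Zero-variance feature candidates are dropped with a warning (correlation
  undefined); zero-variance position-weight cells become weight 0.
- `pearsonR()` errors on zero variance rather than returning 0 or NA — model
  selection must not mistake a constant predictor for an uncorrelated one.
- Standardization of encoder columns is fitted on the training portion only
  and stored in the model; constant columns get scale 1.
- A CV fold whose removal leaves constant labels is merged with a neighbor
  (warning).
- Candidate ids are `<parent>:<start>-<end>`, 1-based inclusive; scan
  ordering is predicted efficacy descending, start position as tie-break.
- All training entry points take an integer seed; fold assignment, the
  validation split, NN initialization and the GA stream derive from it, and
  generators restore the caller's RNG state.

## Problem sizes

The test suite trains layer-1 models on 200–500-record synthetic sets
(seconds each); the deep end-to-end check uses 1000 training / 300 test
records with all four default methods, and the GA-vs-least-squares suite
runs 20 frames at population 100 × 2000 generations. These sizes were chosen
as the smallest at which the planted signals are decodable with comfortable
margin.

## Known limitations

- The shipped rule table is a curated approximation of the cited design
  guidelines, not a mechanical transcription of their sources.
- The 162/85/65/47 element *identities* of the original feature-set family
  depend on the proprietary training screen and are not reproduced; only the
  selection procedure and thresholds are.
- No mRNA secondary-structure / target-accessibility features, and no
  off-target screening — out of scope by design.
- Fusion is strictly two-input (one sequence-type + one feature-type
  method).
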