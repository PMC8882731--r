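---
title: "Predicting plant 6mA sites by majority-voting ensembles: methods and design"
author: "i6maVote authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plant 6mA sites by majority-voting ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

N6-methyladenine (6mA) is an epigenetic DNA modification in which the
adenine base carries a methyl group at its N6 position. In plants it is
associated with growth and developmental regulation, and wet-lab detection
(single-molecule real-time sequencing, restriction-enzyme-based protocols)
is slow and costly at genome scale. The computational task this package
addresses is therefore a binary classification problem: given a 41-nt DNA
window centered on an adenine, decide whether that central adenine is
methylated. The 41-nt width is the conventional window used by the plant
6mA benchmark datasets this family of predictors is trained on; the window
alphabet is A, C, G, T plus N for an unidentified nucleotide.

```{r}
library(i6maVote)
```

## Sequence handling and cleaning

`readFastaWindows()` parses FASTA, uppercases, and maps every character
outside {A,C,G,T} to N. Mapping rather than erroring keeps arbitrary user
FASTA usable, and N is a first-class symbol in all encoders. The cleaning
step (`cleanWindows()`) applies three rules in a fixed order: windows whose
length is not exactly 41 nt are dropped (benchmark curation drops
longer-than-41 sequences; we also drop shorter ones, because every encoder
assumes one fixed length); exact duplicate sequences within a label are
reduced to their first occurrence (deterministic, independent of any hash
order); and any sequence occurring in both the positive and the negative
set is removed from both. Duplication is plain string equality — reverse
complements are deliberately not treated as duplicates, since the
methylation mark is strand-specific. A window whose central base is not A
only warns at cleaning time but is a hard error at prediction time: curated
datasets guarantee the central A, arbitrary user input does not.

`splitWindows()` performs the 80/20 train/test split. The split is
stratified by label under a recorded seed; plain uniform sampling would be
equally defensible for the near-balanced benchmark datasets, but
stratification removes a needless source of variance in small synthetic
experiments.

## The six feature encoders

All encoders operate over the 5-symbol alphabet with the fixed order
A < C < G < T < N; the k-mer codebook (`kmerCodebook()`) enumerates k-mers
lexicographically in that order, which pins every one-hot index and
property-table row order.

* **One-hot1** — each nucleotide becomes a 5-bit indicator; an L-nt window
  gives 5L bits with exactly L ones.
* **One-hot2** (the default) — each of the L−1 overlapping dinucleotides
  becomes a 25-bit indicator; a 41-nt window gives the method's standard
  1000-dimensional vector with exactly 40 ones. This is the encoder the
  final model uses: it captures *which* dinucleotide occurs at *which*
  position, and positional information is exactly what distinguishes 6mA
  neighborhoods.
* **AMNF / ADNF** — accumulated mono-/di-nucleotide frequencies: element t
  is the frequency of the (di)nucleotide at position t within the prefix
  ending there. `encodeAMNF("ACGTNA")` is (1, 1/2, 1/3, 1/4, 1/5, 2/6);
  values are stored at full precision (the conventional two-decimal display
  0.33 is a rounding of 1/3, not the stored value). The worked example
  confirms N counts like any other symbol.
* **DPCP / TPCP** — for every k-mer token i and property j the feature is
  N_i × PC_ij, the raw token count times the tabulated physicochemical
  value, flattened token-major. Reading the descriptor as one value per
  (token, property) *pair* — rather than a per-token sum over properties —
  keeps the property dimension intact; the per-token-sum alternative can be
  obtained by supplying a single-column table. Counts are raw by
  definition; `normalizeCounts = TRUE` switches to relative frequencies
  for length-heterogeneous exploratory use.

Fusion (`encodeFused()`) is plain concatenation in the listed order with no
rescaling — the comparison machinery treats fused encoders exactly like
atomic ones.

### The bundled property tables are synthetic

The dinucleotide/trinucleotide physicochemical literature tables that
real-data DPCP/TPCP analyses use are not redistributable inside this
package, so the bundled defaults
(`inst/extdata/*_properties_synthetic.tsv`) contain *synthetic*
standardized values: reproducible standard-normal draws rounded to three
decimals, with every N-containing token set to 0, shaped as 15 dinucleotide
and 11 trinucleotide properties to match the published descriptor
dimensions (25×15 → 375-dim DPCP, 125×11 → 1375-dim TPCP). They exercise
the machinery fully — every algebraic property of the encoder
(linearity in the table, count correctness, dimension) is independent of
the actual values — but carry no biophysical meaning. For real-data work,
supply a literature table via `readPropertyTable()`; the TSV schema is
`token<TAB>prop1<TAB>...` with one row per k-mer.

## The ensemble classifier

Five heterogeneous base learners are trained on the same encoded matrix:
random forest (via `ranger`), linear discriminant analysis (via
`MASS::lda`), a single-hidden-layer perceptron (via `nnet`; input, hidden
and output layer — the hidden width is a tunable hyperparameter, default
4), an L2-regularized logistic regression fit by per-sample stochastic
gradient descent (implemented in the package; learning rate decays by an
inverse-scaling schedule), and extreme gradient boosting (via `xgboost`).
Each learner emits a hard 0/1 vote — never a probability — and the
ensemble calls a window 6mA-positive when at least `voteThreshold` (default
3 of 5) votes are positive. With five voters and threshold 3 this is the
strict majority and no tie can arise; for user-configured even ensembles a
tie maps to 0 with a warning, the conservative choice for a rare-mark
detection problem.

Two numerical details are worth recording. First, `MASS::lda` refuses
variables with zero pooled within-group variance. Columns that are constant
overall carry no information and are dropped (the surviving column indices
are stored on the fit); columns constant *within* each class but different
*between* classes are maximally discriminative, and are retained by adding
a tiny seeded jitter (sd 10⁻³, below any meaningful scale of the 0/1 and
frequency features) so the within-class scatter is invertible. Second, the
xgboost booster is reduced to its raw-byte serialization inside saved model
archives so that `saveEnsemble()`/`loadEnsemble()` round-trip to
bit-identical predictions across sessions.

Hyperparameters are tuned, when requested, by exhaustive grid search
(`gridSearch()`): every combination in the Cartesian product is scored by
stratified k-fold cross-validated accuracy, ties break deterministically to
the first combination in enumeration order, and failing combinations are
recorded and skipped. The default grids live in
`inst/extdata/default_config.json`; they are inputs, not constants. Grid
search runs *inside* the training data (the validation split never touches
it), avoiding the optimistic bias of tuning on the evaluation set.

## Evaluation

`computeMetrics()` implements the four standard indicators — accuracy,
Matthews correlation coefficient, sensitivity and specificity — from the
TP/TN/FP/FN counts. When the MCC denominator is zero (a degenerate
predictor or single-class sample) the uninformative value 0 is returned,
the standard convention; SN/SP are NA when their class is absent. MCC
equals the Pearson correlation of the two binary label vectors, which the
test suite uses as an independent oracle. Cross-validation (`kfoldCv()`)
uses stratified folds under a recorded seed — a single seeded run, with the
seed exposed, rather than an average over repetitions — and
`sweepEncoders()` crosses every encoder with every classifier at identical
folds and seed to produce the encoder-comparison table.

## The synthetic-data generator

Real plant 6mA benchmarks cannot be bundled, so `simulateWindows()`
generates datasets whose positives carry the position-specific nucleotide
enrichment that two-sample logos show around plant 6mA sites: A enriched at
center-relative positions −6, −4, −3, 4, 7, 8, 10, 11, 12; C at −7, −2, 2,
6, 9; G at −8, −1, 2, 3, 5, 8; T at 3 — 21 (position, base) pairs, all
encoded in `defaultEnrichmentProfile()`. Logos convey position and identity
but not a usable numeric magnitude, so a single configurable strength s
applies to every pair: at an enriched position a positive window carries
the enriched base with probability s and otherwise draws from the
background (uniform A/C/G/T by default), giving an expected enriched-base
frequency of s + (1−s)/4. Negatives are i.i.d. background with a forced
central A. This is a deliberate simplification: real negatives come from
chromosomes without detected 6mA and share genome composition, CG skew and
local context with positives. Consequently, passing synthetic recovery
tests demonstrates that the pipeline *learns planted positional signal*,
not that it attains any particular accuracy on real genomes; cross-species
generalization questions cannot be asked of this generator at all.

Flank positions can be masked to N with probability `nRate` (default 0) to
exercise the N-handling paths. Generated windows pass cleaning untouched
except for chance duplicates, which the standard cleaning step removes,
mirroring the real data flow.

## Problem sizes used by the checks

The test suite exercises the full cycle at sizes chosen to make the
statistical assertions stable: the headline recovery experiment uses 1000
positives and 1000 negatives at strength 1.0 with an 80/20 split (held-out
accuracy > 0.95, MCC > 0.9); the chance-level control uses 500/500 at
strength 0 against a 99% binomial interval around 0.5; the voting-gain
check compares the median ensemble accuracy to the median base-learner
accuracy over five seeds at 250/250, strength 0.5, where base learners
differ enough for voting to matter; and the encoder-comparison sweep runs
all six encoders × five classifiers with 5-fold CV on 150/150 windows at
strength 0.5, enough for the positional/non-positional gap to dominate
fold noise.

## Known limitations

* The ensemble is as good as its features: only exact-position signal is
  modeled, and the package deliberately omits feature selection,
  probability calibration, soft/weighted voting and stacked meta-learners.
* The bundled property tables are synthetic (above); DPCP/TPCP results with
  them characterize the machinery, not dinucleotide biophysics.
* The generator does not emulate genome-scale composition; accuracy figures
  on synthetic data are not comparable to published real-data figures.
* Single-label windows only; genome scanning (sliding a window over a
  chromosome) is out of scope.

## A minimal end-to-end run

```{r, eval = FALSE}
ws <- simulateWindows(1000, 1000, defaultEnrichmentProfile(strength = 1),
                      seed = 1)
sp <- splitWindows(ws, trainFraction = 0.8, seed = 1)
model <- trainEnsemble(sp$train, encoder = "ONEHOT2", seed = 1)
pred <- predict(model, sp$test)
computeMetrics(confusionCounts(windowLabels(sp$test), pred$ensemble_label))
```
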