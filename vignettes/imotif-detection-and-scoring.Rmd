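---
title: "Detecting and scoring DNA i-motifs with imotifr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring DNA i-motifs with imotifr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imotifr)
```

## The biological problem

i-Motifs are four-stranded DNA structures formed by cytosine-rich sequences:
four runs of consecutive cytosines (C-tracts) pair through intercalated,
hemiprotonated C·C(H+) base pairs, with the intervening nucleotides extruded
as loops. Their stability is usually summarised by the *transition pH* — the
pH at which half of the molecular population is folded — measured by UV
absorption spectroscopy. `imotifr` addresses three connected tasks:

1. **Detection** — enumerate putative i-motif forming sequences in DNA under
   explicit structural constraints;
2. **Scoring** — predict a quantitative stability label (transition pH by
   default) for each candidate from sequence-derived features, and summarise
   it as a 0–1 stability score;
3. **Model training** — learn the scoring model from user data with a
   bi-level AutoML search, and ship it as a portable bundle.

## The detection grammar

A candidate motif is parsed as `tract loop tract ... loop tract`, governed by
`detection_params()`:

| knob | default | meaning |
|---|---|---|
| `n_tracts_min/max` | 4 / 4 | number of C-tracts |
| `tract_len_min/max` | 3 / 5 | consecutive C per tract |
| `loop_min/max` | 1 / 12 | loop length bounds (nt) |
| `side_loop_*`, `middle_loop_*` | unset | per-role overrides |
| `greedy` | `FALSE` | maximal vs minimal motif per anchor |
| `allow_overlap` | `FALSE` | keep or resolve overlapping calls |
| `loop_mode` | `equal_loops` | placement objective inside long C-runs |

The defaults encode the canonical intramolecular i-motif: exactly four
tracts of 3–5 cytosines and loops of 1–12 nt. The widely quoted "3 to 5"
range is ambiguous between tract *count* and tract *length*; because an
intramolecular i-motif structurally requires four strands, and because side
and middle loops are only well defined with four tracts, we expose both
knobs and map "3 to 5" to tract length, with tract count defaulting to
exactly four.

Two clarifications the verbal description leaves open, fixed here as
package policy:

* **Loops may contain cytosines, but never a run of `tract_len_min` or more
  consecutive C.** Any tract-capable run inside a motif must host a tract.
  Without this rule the grammar is wildly ambiguous (a run of 15 C could be
  parsed as tracts separated by all-C "loops"); with it, every loop contains
  at least one non-C base and tracts always sit in distinct maximal C-runs.
* **Ambiguous bases (N) terminate tracts always, and invalidate loops unless
  `allow_n_in_loops = TRUE`.** The conservative default avoids motif calls
  spanning assembly gaps.

**Anchoring and greediness.** Every offset inside a tract-capable C-run is a
potential anchor (first-tract start). Non-greedy detection (the default)
reports the *minimal-length* valid motif at each anchor; greedy detection
reports the *maximal-length* one (larger tract counts and longer tracts
absorbed first, ties broken toward more tracts). With
`allow_overlap = FALSE`, candidates are then resolved strictly
left-to-right: keep the leftmost, drop everything intersecting a kept call.
This is deterministic and independent of discovery order.

**Loop localisation.** When a C-run is longer than the tract it hosts, the
tract's offset within the run is a free choice. `equal_loops` minimises the
population variance of the loop lengths; `short_side_loops` minimises the
summed length of the two side loops first, then the variance. Remaining ties
go to the leftmost placement (and, at equal starts, the longest tracts),
making every call reproducible. `assign_loops()` exposes this placement step
on its own.

The whole grammar is also implemented a second time in the test suite as a
character-level brute-force parser applied to every substring; the engine
and the oracle agree exactly on hundreds of random and motif-spiked
sequences, for both greedy settings and both loop modes.

Coordinates are 0-based half-open internally and in BED output, 1-based
inclusive in the TSV report. Detection always operates on the C-rich strand;
a `-` call means the motif lies on the reverse complement, with coordinates
mapped back to the forward strand. Genome scans default to both strands,
and overlap resolution is applied per strand.

## The 33 canonical features

All scoring models consume the same ordered 33-feature vector
(`imotif_feature_names`): 13 structural descriptors (motif length, tract
count, tract-length mean/min/max/variance, loop count, loop-length
mean/min/max/variance, total loop length, fraction of the motif inside
tracts), the four mono-nucleotide fractions, and the 16 dinucleotide
frequencies in row-major A,C,G,T order. Variances use the population
(divide-by-*n*) convention; dinucleotide counts are divided by motif length
minus one. The exact feature set behind published i-motif scoring services
is not enumerated publicly, so this list is an interpretation frozen as a
package-level constant — bundles store the feature-name list explicitly, so
a future replacement set remains self-describing.

Normalization is fit on training data only (`fit_normalizer()`), z-score by
default because the portfolio contains scale-sensitive models (SVR, MLP);
zero-variance columns (e.g. `n_tracts` under the default four-tract grammar)
are flagged and passed through with unit scale.

## The bi-level AutoML engine

Model selection is formulated as nested optimisation: the upper level picks
a (feature-selection method, regressor family) pair from a 7 × 12 portfolio
(84 combinations — six selector families plus a pass-through `NONE`, which
is the only factorisation consistent with twelve regressor families); the
lower level tunes that pair's hyperparameters. Both levels maximise the
coefficient of determination R². We deliberately define both objectives as
the mean *out-of-fold* R² of a k-fold cross-validation on the training split
(k = 5 by default) rather than resubstitution R², which would trivially
favour overfitting ensembles; the held-out test split (20%, seeded shuffle)
is scored exactly once, after the search ends.

**Lower level (TPE).** Hyperparameters are tuned with a Tree-structured
Parzen Estimator: after a seeded random start-up phase, past trials are
split into good (top 25%) and bad sets, Parzen densities `l(x)` and `g(x)`
are built per parameter (log-scaled domains on the log scale, integers
rounded, categoricals as smoothed count ratios), and the candidate
maximising `l/g` is evaluated next. When a configuration space is finite and
no larger than the trial budget it is enumerated exhaustively — the density
model adds nothing there, and small discrete domains are then solved
optimally.

**Upper level (Tabu search).** The 84-pair space is walked with a
full-memory tabu list: each round evaluates one previously unvisited
neighbour (pairs differing in exactly one coordinate) with the full TPE
budget, moves there if it improves on the current pair, and restarts from
the best visited pair with unvisited neighbours when stuck. One evaluation
per round is what makes the preset budgets meaningful — the largest preset
(84 rounds) visits the entire space, at which point the result provably
equals exhaustive search. The per-pair TPE seed is derived from the global
seed and the pair label only, so the search history is reproducible and
independent of visit order; a failed fit scores `-Inf` and the search
continues.

Budget presets (`automl_budget()`): `swift_basic` 8 × 10, `balanced`
20 × 25, `thorough` 40 × 60, `best_performance` 84 × 150 (upper rounds ×
TPE trials). These spans are declared package defaults, chosen to range
from minutes to days of single-CPU work.

**Portfolio backends.** Standard fits go through established packages:
ridge (`MASS`), decision trees (`rpart`), random/extra/bagged forests
(`ranger`), gradient boosting in classic, histogram and fully-tuned
variants (`xgboost`), support vector regression (`e1071`), neural networks
(`nnet`, one hidden layer — R has no installed multi-layer MLP regressor,
so the hidden-layer domain collapses to one layer). AdaBoost.R2 and
out-of-fold stacking have no installed R implementation and are provided
in-package. Selector families: univariate selection, select-from-model,
forward sequential selection, recursive feature elimination with and
without cross-validated subset size, and variance thresholding. Note that
under the default z-score normalizer the variance threshold can only remove
flagged constant columns — an honest consequence of normalising before
selecting, documented rather than hidden. Hyperparameter domains are frozen in a
single internal table; published overviews of comparable services name the
parameters but not their ranges, so the ranges here are standard
practitioner choices.

Training sequences are re-validated before use: a row enters the design
matrix only if the full sequence parses as a single motif under the
detection grammar (a greedy parse anchored at the first base must span the
last). Invalid rows are dropped with a warning.

## Bundles and the stability score

`write_bundle()` packages detection parameters, the feature-name list, the
normalizer, the fitted pipeline and the training-label range into one tar
archive (`manifest.json` + `model.bin` + MD5 `checksum`). The manifest is
plain JSON readable without R; the model blob is implementation-specific
and tagged with its serialization format. Loading verifies the checksums
and refuses manifests newer than the reader. Round-tripping a model through
a bundle reproduces its predictions bit-for-bit.

The stability score of a motif is the min–max calibration of its predicted
label against the training-label range, clamped to [0, 1] — the same
convention used to place average scores of different species on a common
0–1 scale. Whether a public scoring service derives score and transition pH
from one model or two is not documented; here a single regression plus
calibration produces both outputs, which keeps the score monotone in the
predicted label by construction.

## Genome statistics

`c_density()` is the fraction of unambiguous bases that are cytosine
(N excluded from numerator and denominator). `genome_summary()` reports
i-motifs per million nucleotides, `iPM = n_motifs / genome_length * 1e6`,
counting motifs from both strands (non-overlapping per strand) against the
single-strand assembly length including ambiguous bases — "per million
nucleotides" most naturally references assembly size, but published
per-species tables do not state their strand/denominator convention, so
conclusions sensitive to a factor of two should compare both. Default
detection parameters are assumed for cross-species tables.
`summarize_genomes()` adds the 0–1 min–max `relative_score` across a set of
genomes (defined as 0.5, with a warning, if all means are equal).

## The synthetic-data generator

Tests and examples never download data; the generator produces every input
with known ground truth:

* `random_background()` draws i.i.d. bases at a target GC content (default
  0.4, a typical intergenic composition) and then destroys any accidental
  motif by C→T substitution in a tract base, re-scanning both strands until
  the detection engine certifies the sequence clean.
* `spike_motifs()` samples motifs uniformly from the constraint grammar
  (loop bases from {A, G, T}, so tract boundaries are exact), inserts them
  at seeded positions at least 50 nt apart on random strands, and clears a
  C/G-free buffer of `loop_max + tract_len_max` nt around each insert so no
  tract can reach across a motif boundary. The truth table is verified
  against a greedy both-strand scan before it is returned. Because sampled
  tracts may exceed `tract_len_min`, the *non-greedy* scan legitimately
  reports a minimal sub-span: exact-coordinate recovery is a greedy-scan
  property, count/anchor/strand recovery a non-greedy one.
* `labelled_dataset()` labels sampled motif sequences with a linear law
  over named raw features plus Gaussian noise (default: loop length down,
  tract length and C fraction up, intercept 5.8 — signs and magnitudes
  chosen to mimic how transition pH responds to architecture, on the
  5.5–7.5 pH scale typical of i-motif experiments; plausibility only, no
  measured values are claimed). `target_r2` back-solves the noise SD for a
  requested signal-to-total variance ratio, and the planted coefficients
  are returned for recovery tests.

What passing synthetic tests does **not** show: real transition-pH data has
correlated, heteroscedastic noise, a non-linear dependence on architecture,
and sequence families absent from the uniform grammar sampler. The AutoML
recovery results certify the machinery (search, validation discipline,
calibration), not biological accuracy of any shipped default model — no
experimentally trained model is included.

## Numerical choices and scale

Problem sizes used by the test suite and the acceptance script were chosen
as the package's own reference conditions: oracle equivalence on 300-nt
sequences (100 random + 50 spiked, all four greedy × loop-mode
combinations), AutoML recovery on n = 500 labelled motifs at signal
R² ≈ 0.9 with the `balanced` preset, density statistics on a 1 Mb spiked
genome. Ties in loop placement are broken deterministically (leftmost, then
longest tracts); floating-point objective comparisons use a 1e-12 margin;
fold assignment, TPE proposals and every stochastic fit derive from one
integer seed.

## Known limitations

* The grammar scores no thermodynamics: a sterically plausible parse is not
  evidence of folding at physiological pH.
* `n_tracts` ranges other than exactly four are supported by the engine but
  the side/middle loop roles are only biologically meaningful at four.
* The stacking and AdaBoost.R2 implementations are intentionally compact
  (fixed base-learner menu, linear-loss AdaBoost); they are portfolio
  members, not reference implementations of those algorithms.
* iPM comparisons across publications are sensitive to strand and
  denominator conventions; see above.

## A complete example

```{r example, eval = FALSE}
ds <- labelled_dataset(200, seed = 1, target_r2 = 0.9)
model <- automl_train(ds, budget = automl_budget("swift_basic"), seed = 1)
glance(model)

spec <- synthetic_spec(genome_length = 1e5, n_motifs = 10, seed = 1)
g <- synthetic_genome(spec)
scored <- score_sequences(model, g$genome)
genome_summary(g$genome, model = model, label = "demo")

write_bundle(model, "demo.imotif")
```
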