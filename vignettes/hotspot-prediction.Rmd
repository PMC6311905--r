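---
title: "Predicting interaction hot spots from sequence: model and design notes"
author: "hotspotter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting interaction hot spots from sequence: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotter)
```

## The problem

A small minority of the residues in a protein–protein interface contribute
most of the binding free energy. These *hot spots* are identified
experimentally by alanine scanning: a residue is a hot spot when mutating it
to alanine raises the binding free energy (ΔΔG) by roughly 2 kcal/mol or
more. Because scanning is slow and expensive, sequence-based predictors are
useful both for prioritising mutagenesis and for interface-targeted ligand
design. This package implements a purely sequence-based predictor: its only
inputs are the chain sequence, a table of amino-acid physicochemical
descriptors, and (optionally) a per-residue relative accessible surface
area (relASA) predicted from sequence by an external tool such as NetSurfP.

## Labeling rules

Residue-level mutation records are labeled by two rules:

* **ΔΔG rule** — ΔΔG ≥ 2.0 kcal/mol → hot; ΔΔG ≤ 0.4 kcal/mol → non-hot;
  anything in between is ambiguous and excluded from datasets. The
  thresholds follow the consensus alanine-scanning convention and give
  near-balanced classes on typical scanning compilations. Values exactly at
  a cutoff are assigned to the nearer class by default; a `strict` mode
  drops them instead, for a literal strictly-greater/strictly-less reading.
  The default keeps boundary records because silently discarding measured
  residues is the worse failure mode for a screen.
* **Interaction-strength rule** — qualitative records (as in the BID
  database) labeled `strong` are hot; `intermediate`, `weak` and
  `insignificant` are non-hot. Treating `intermediate` as negative rather
  than dropping it is a deliberate choice: the category vocabulary is
  closed, and a predictor deployed on such data must make a call on every
  residue. This is worth revisiting in sensitivity analyses, since
  intermediate residues are the most likely label noise.

## The descriptor table

Amino-acid descriptors come from the AAindex1 catalogue (544 indices, one
value per canonical residue type), taken at run time from the copy bundled
with the `seqinr` package or parsed from a user-supplied flat file. Highly
correlated descriptors carry redundant information and would let one
physicochemical theme dominate a voting ensemble, so the table is pruned by
greedy correlation-threshold elimination (`remove_redundant()`): repeatedly
count, for each descriptor, the number of others with absolute Pearson
correlation above the threshold (default 0.5), remove the worst offender
(ties broken toward the later table position, so earlier entries are
preferred), and stop when no pair exceeds the threshold. Absolute
correlation is used because an anti-correlated descriptor pair is exactly as
redundant for the downstream learners as a correlated one. The greedy
remove-worst-first order makes the procedure deterministic; on the full
usable catalogue (531 descriptors after dropping incomplete and
zero-variance entries) it retains 50 descriptors at threshold 0.5.

The package's default table (`hotspot_properties()`) is a fixed
46-descriptor set: 40 curated accessions spanning alpha/turn propensity,
hydrophobicity and physicochemical classes, completed by 6 accessions chosen
deterministically as the first catalogue entries whose absolute correlation
with every already-selected descriptor is at most 0.5
(`BEGF750103`, `BROC820101`, `CHAM830103`, `CHAM830105`, `CHOP780207`,
`ISOY800102`). The fixed list, rather than a fresh run of the elimination
algorithm, is the default because the elimination result depends on the
catalogue version and on the (otherwise arbitrary) removal order; a frozen
set keeps encodings reproducible across environments.

Descriptors are min-max normalized to [0, 1] per descriptor before
encoding. This matters for the window pad value below: a pad of 1.0 is only
meaningful on a known scale. `normalization = "none"` is available for raw
values.

## Residue encoding

For one descriptor, a chain sequence becomes a numeric profile
\(h_1, \dots, h_n\) (one value per residue; letters outside the 20 canonical
codes take the descriptor's mean). Each residue is encoded by the
auto-correlation of the profile inside a sliding window of length
\(W = 2M + 1\) centred on it:

\[ r_j \;=\; \frac{1}{W-1} \sum_{l=1}^{W-j} h_l \, h_{l+j},
   \qquad j = 1, \dots, M, \]

where the window entries hanging over either chain end are set to the pad
value (default 1.0, the top of the normalized range). The lag features
capture local sequence-order structure — how a physicochemical theme
repeats or decays around the residue — rather than just composition.

Numerical conventions worth stating:

* The prefactor divides by \(W - 1\) (window length minus one) for every
  lag, so a constant window of ones gives the closed form
  \(r_j = (W-j)/(W-1)\), which the tests assert exactly.
* The window is always full length: padding makes every center position
  valid, including chains shorter than the window.
* `M = 11` (a 23-residue window, 11 features per descriptor) is the
  default; `select_m()` scans a grid (default 3, 7, 11, 15, 19) and returns
  the F1-optimal value with the full trace, since the best depth is
  dataset-dependent.
* When relASA is enabled (the default), the residue's scalar relASA is
  appended to *every* descriptor's feature vector (dimension \(M + 1\)), so
  each base classifier sees it. The alternative — treating relASA as a 47th
  descriptor with its own auto-correlation profile — would require
  chain-complete relASA rather than per-site values and is not implemented.

## The voting ensemble

Every descriptor trains two base classifiers on its own feature matrix: a
k-nearest-neighbour voter (k = 5, Euclidean metric) and an RBF-kernel
support vector machine (cost 1, kernel width 1/feature-dimension — the
libsvm defaults). With the default 46 descriptors that is a pool of 92
bases. Hyperparameters are deliberately the library defaults: the bases are
meant to be many, cheap and diverse, with the ensemble — not per-base
tuning — carrying the performance. All of them are configurable.

Training protocol:

1. **Stratified ten-fold cross-validation.** Folds are as equal as possible
   (sizes differ by at most one) with per-fold class counts within one of
   proportional; classes are interleaved across folds so both constraints
   hold simultaneously. Feature standardization is computed from the
   training folds only, so no held-out information leaks into the scaler.
2. **Out-of-fold concatenation.** Each base predicts every residue exactly
   once from the fold that held it out; the concatenated predictions give
   the base's F1. Ranking uses this single concatenated F1, not a per-fold
   average, because a per-fold average is noisier at these dataset sizes.
3. **F1 ranking and top-n voting.** Bases are sorted by F1 (ties: KNN
   before SVM, then descriptor order — a fixed, documented rule so ranking
   is deterministic). For each n in a grid (default odd 3–91) the majority
   vote of the top n bases' out-of-fold predictions is scored; the
   F1-maximizing n is selected, smallest n on ties. The grid is restricted
   to odd n so votes cannot tie; where a tie is still possible (even vote
   counts from user grids) it resolves to non-hot, the conservative call
   for a screen. The vote fraction (share of bases voting hot) serves as a
   graded score for ROC analysis; it exceeds 1/2 exactly when the hard vote
   is hot.
4. **Refit.** The selected bases are refitted on the full training set;
   those refits are the deployed model. Using fold models instead would
   discard a tenth of the data per base for no benefit at deployment time.

The trained model is persisted as a directory of plain-text files: a
versioned key-value manifest (configuration, hyperparameters, seed, the
full ranked base list with F1s) plus the training feature rows per selected
descriptor. Loading refits the bases from the stored rows — both learners
are deterministic given data and hyperparameters, so a reloaded model
reproduces the saved one's predictions exactly, without binary
serialization.

Determinism throughout is a design goal: fold assignment is a pure function
of the seed, libsvm's optimizer is deterministic, and the one genuinely
random component — `class::knn`'s random tie-break among equidistant
neighbours — is pinned to a fixed RNG substream. Two runs with the same
inputs and seed agree bit for bit.

## Evaluation

`compute_metrics()` reports accuracy, specificity, recall (sensitivity),
precision TP/(TP+FP), F1 and the Matthews correlation coefficient from a
confusion matrix with hot as the positive class. Metrics with a zero
denominator are reported as 0 and flagged in an `undefined` field rather
than erroring, so ranking never crashes on a degenerate base that predicts
one class. AUC uses the tie-corrected Mann–Whitney rank form (mid-ranks),
which the tests verify against exhaustive pair enumeration and against an
established independent implementation.

## The synthetic benchmark generator

Real alanine-scanning compilations cannot be bundled, so the test surface
is synthetic data with *planted, recoverable* signal. The generator draws
chains i.i.d. over the 20 residue types, samples labeled sites, and gives
each site a latent score

\[ s \;=\; \text{strength} \times
   \overline{r_1^{(d)}(\text{site})}_{d \in \text{signal set}}
   \;+\; \mathcal{N}(0, \sigma), \]

the mean lag-1 windowed auto-correlation of the designated signal
descriptors at the site — exactly the statistic the encoder computes. The
top `hot_fraction` quantile of sites becomes hot with ΔΔG drawn uniformly
from [2, 5] kcal/mol; the rest draw from [0, 0.4]. No generated ΔΔG falls
in the ambiguous band, so read-back counts are exact by construction.
relASA is uniform on [0, 1] with a +0.2 shift (clipped) for hot sites,
giving the appended feature path a weak genuine association to exercise.

Two properties of this design deserve emphasis:

* **Recovery is a test of the encoding chain.** Because the signal lives in
  the same auto-correlation statistic the encoder computes, a pipeline that
  mangles windows, padding or descriptor mapping fails recovery outright —
  it is not a generic "can a classifier learn something" check.
* **A split signal is structurally hard for per-descriptor voting.** Each
  base sees one descriptor's features only. If the latent signal is the
  mean over several descriptors, no single voter observes it in full, and
  piloting showed out-of-fold F1 saturating around 0.75–0.83 for a
  three-descriptor signal versus 0.88–0.97 for a one-descriptor signal at
  the same signal-to-noise ratio. The frozen recovery conditions
  (`recovery_study_config()`) therefore plant the signal in a single
  descriptor: 12-descriptor table, strength 8, noise SD 0.05 (realized
  SNR ≈ 10), 6 chains × 100 residues, 30 sites per chain, 40% hot, M = 5,
  ten folds, odd n in 3–23. Under these conditions the acceptance suite
  requires out-of-fold F1 ≥ 0.85 on at least 18 of 20 seeds and a signal
  descriptor's base inside the ranking's top 10 as often. The
  split-signal ceiling is a real limitation of the architecture worth
  knowing about, not an artifact of the generator.
* **The zero-signal null excludes relASA.** Setting the signal strength to
  zero removes the auto-correlation signal but *not* the generator's
  deliberate relASA–label association, so the null comparison (zero-signal
  F1 inside the permuted-label band, both re-running the full selection to
  carry its optimism bias) encodes without the relASA column. With relASA
  on, zero-signal data is legitimately predictable and the comparison
  would conflate the two signal paths.

What the generator does **not** emulate: real interface composition (no
amino-acid bias at hot sites beyond the planted statistic), realistic ΔΔG
shapes (uniform bands only), sequence redundancy and homology structure
(every chain is independent), or real relASA (uniform noise plus a shift).
Passing the synthetic suite therefore demonstrates that the machinery is
correct and sensitive, not that any particular accuracy will be achieved on
experimental compilations — performance there depends on data the package
cannot ship, an external relASA predictor, and hyperparameters tuned to
that data.

The five *corpus twins* (`synthetic_corpus_twins()`) reproduce the exact
hot/non-hot margins of the standard benchmark corpora (ASEdb 58/91 train;
BID 70/115, SKEMPI 120/234, dbMPIKT 106/384, Mix 292/697 test) in the same
file dialects the real readers consume, with 15% extra ambiguous-band rows
added to the ΔΔG corpora so read-back also exercises the exclusion rule,
and category labels on the BID twin to exercise the strength-category rule.
They make the full benchmark-scale protocol runnable end to end — the
acceptance script trains the 92-base ensemble on the ASEdb twin and tests
on the other four. The Mix twin is generated directly at its margins
(`mix_datasets()` implements concatenate-and-deduplicate for real data,
where the published margins of the mixed corpus are not consistent with the
union of its two parts).

## Problem sizes in the shipped tests

The test suite runs the encoder and metric oracles at 1,000 random cases
each, ensemble selection against a brute-force oracle on 10-base pools, 20
recovery seeds plus 12 null-pipeline runs at the frozen study conditions,
and one benchmark-scale training (92 bases, 149 residues, ten folds, 45
grid values). These sizes were chosen so the whole suite exercises every
claim at full fidelity while completing in well under a minute per
property; the pipeline itself scales linearly in residues × descriptors ×
folds.

## Known limitations

* The per-descriptor base design caps performance when informative signal
  is spread thinly across many descriptors (see above); a feature-fusion
  variant is the natural extension but is out of scope here.
* Positions must already be expressed in chain-sequence coordinates;
  mapping from author/PDB numbering is the data supplier's responsibility.
* relASA is consumed, never computed: the package does not run or replace
  an accessibility predictor.
* The ambiguous ΔΔG band (0.4, 2.0) is discarded, as is conventional;
  models never see those residues and cannot be evaluated on them.
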