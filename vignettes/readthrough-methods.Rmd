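---
title: "Predicting basal translational readthrough and hidden PTS1 signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting basal translational readthrough and hidden PTS1 signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readthrough)
library(dplyr)
```

## The problem

When a ribosome reaches a stop codon it usually terminates, but with low
frequency a near-cognate tRNA decodes the stop as sense and translation
continues to the next in-frame stop. This *basal translational readthrough*
(BTR) appends a C-terminal extension to the protein. If that extension
carries a functional element — the case this package is built around is a
hidden peroxisomal targeting signal type 1 (PTS1) — a fraction of the
protein population acquires a new localization. The rate of basal
readthrough is largely determined by the *stop-codon context* (SCC): the
stop triplet itself plus a handful of flanking nucleotides.

This package implements the full prediction stack:

1. a ridge-regression model of readthrough propensity (RTP) over
   indicator-encoded stop-codon contexts;
2. stepwise feature elimination deriving reduced models and the
   high-readthrough consensus motif;
3. a regularized least-squares classifier (RLSC) for PTS1 signals in
   C-terminal peptides, with calibrated posterior probabilities;
4. a transcriptome scan that detects readthrough extensions and ranks them
   by the product of scaled RTP and PTS1 posterior;
5. dual-reporter readthrough statistics with first-order error propagation;
6. synthetic-data generators with planted structure so that every stage is
   testable without external downloads.

## The readthrough-propensity model

The SCC is the 15-nt window from position −6 to +9, with the stop at
+1..+3. Each of the 12 flanking positions is one-hot encoded over
A/C/G/T, and the stop is a single 3-way categorical position (TAA, TAG,
TGA), giving a 51-dimensional binary vector (12 × 4 + 3). Feature vectors
are normalized to Euclidean unit length, which for a k-position encoding
means dividing by √k (√13 ≈ 3.6 for the full context).

With $X$ the $n \times d$ matrix of normalized feature vectors and $y$ the
experimental basal readthrough values, the weights solve the ridge normal
equations without an intercept:

$$\mathbf{w} = (X^\top X + k\,I)^{-1} X^\top y .$$

The closed form has no intercept term, and we adopt that as-is; the
indicator encoding absorbs a constant through the block structure (every
row activates exactly one entry per block), so an explicit intercept is
redundant for prediction. We solve the symmetric system directly rather
than inverting $X^\top X + kI$.

Two fitted models are bundled verbatim from the published weight tables:
**LINiter** (all 12 context positions + stop) and **LINfs3** (stop and
positions +4..+6). Their raw-weight stacks have Euclidean norms 0.0088 and
0.0063. The normalized, dimensionless **RTP score** of a context is

$$\mathrm{RTP} = \frac{\text{sum of matched raw weights}}
{\lVert \mathbf{w} \rVert \cdot \sqrt{k_\text{pos}}},$$

equivalently the raw sum divided by the combined shortcut divisors 0.0317
(LINiter) and 0.0126 (LINfs3). RTP may be negative; the genome scan
rescales it to [0, 1] (RTP⁺) before forming product scores.

```{r}
fs3 <- published_model("LINfs3")
rtp_score(fs3, "AAAAGACCTG TGA CTAGTGAGCT") # the LDHB context
```

### Regularization

The regularization strength is selected by leave-one-out cross-validation
over the grid $k = 10^i, i = -3, -2.7, \dots, 3$ (21 values); ties go to
the strongest regularization (smallest loo-SSE at the smallest $k$ is
preferred — a conservative choice). The bundled models use the published
optimum $k = 10^{0.3} \approx 1.995$. Leave-one-out predictions are
computed with the exact leave-one-out identity for penalized linear
smoothers ($e_i = (y_i - \hat y_i)/(1 - h_{ii})$), and the test suite
verifies the identity against a literal refit-n-times oracle.

Training targets may be in percent or fractional units; the model records
which was used. The normalized RTP score is invariant to uniform scaling
of the weights, so rankings are unaffected by the unit choice — only the
unnormalized BTR prediction carries units.

## Feature selection and the consensus motif

Starting from the full model, the context position with the smallest sum
of squared regression coefficients is removed; $k$ is re-selected by
leave-one-out CV at every step and the loo-SSE recorded; the stop is never
a removal candidate; the procedure ends when only the stop remains.
Whether $k$ should be re-optimized at each step was an open design point;
we re-optimize and record `k_used` per step, because each reduced design
is a new estimation problem. Exact importance ties are broken by removing
the position farthest from the stop, upstream before downstream — an
explicit, testable rule chosen so that stop-proximal downstream positions
(the biologically informative ones) survive longest.

The "regression error" tracked along the trace is the leave-one-out CV
SSE — the only error the selection procedure defines — not the training
SSE. The global minimum of the trace defines the reduced model; interior
local minima are reported as well. On the published weights, the reduced
three-position model's per-position argmax yields the high-readthrough
consensus **UGA CUA** (stop underlined in the original notation):

```{r}
attr(consensus_motif(fs3, rna = TRUE), "consensus")
```

## PTS1 classification

C-terminal peptides are encoded as binary indicators over the last 15
residues (positions −15..−1 from the terminus) × 20 amino acids. Shorter
peptides leave leading blocks empty; the undefined residue `X` — used for
the recoded stop codon, whose inserted amino acid is unknowable — leaves
its block zero and contributes nothing. Peptide vectors are *not*
unit-normalized: window occupancy varies between peptides and the
published procedure normalizes only the nucleotide vectors.

The RLSC is ridge regression against ±1 labels, sharing the solver with
the RTP models (the equivalence is a test). Three details were genuinely
open and resolved as follows:

* **Posterior calibration.** The mapping from raw margin score to a
  posterior probability is a two-parameter monotone sigmoid
  $p = \operatorname{logit}^{-1}(\text{slope} \cdot (s - \text{midpoint}))$
  fitted Platt-style to *held-out* cross-validation scores (with the
  standard regularized targets), then the weights are refitted on the full
  data. The slope is constrained positive, so posteriors are strictly
  increasing in the raw score.
* **Regularization.** $k$ is selected by stratified cross-validated
  squared error over the same $10^{-3..3}$ grid and recorded in the model
  file.
* **Class imbalance.** No reweighting — plain least squares — matching the
  classifier's definition; heavily imbalanced training sets are flagged
  when the model prints.

Evaluation is by stratified 5-fold cross-validation; pooled held-out
scores give the trapezoidal auROC and the step-integrated auPRC, both
verified in tests against exhaustive naive oracles.

## The transcriptome scan

Input records are coding sequences (including the annotated stop) plus up
to 300 nt of downstream sequence. Filtering removes records with
undetermined nucleotides, frame or stop violations, proteins shorter than
15 aa, or fewer than 6 downstream nucleotides (no +4..+9 context);
removals are logged, never errors. Records with identical 3′ termini (last
45 CDS nt + downstream) collapse to one representative — the
lexicographically smallest id, fixed for determinism — with all member ids
retained.

A readthrough extension runs from the first nucleotide after the stop to
the next in-frame stop within the downstream window; transcripts without
such a stop have no extension. The extension peptide is prefixed with `X`
for the recoded stop. The PTS1 scoring window is the last 15 residues of
protein + extension, so short extensions let the window dip into the
annotated protein, as the 15-residue window definition implies.

Candidates are ranked by $\mathrm{RTP}^{+} \times \mathrm{PTS1}$, where
RTP⁺ is the ranking model's RTP min-max scaled to [0, 1] *across the
scanned set* — ranks therefore depend on the input universe, which is
recorded in the scan attributes. Transcripts without an extension receive
posterior 0 and hence product 0 (they still occupy ranks, mirroring the
zero-product tail of a genome-wide scan). The half-max rank — the first
rank scoring below 50% of the maximum — summarizes how sharply candidate
support decays.

## Reporter statistics

Dual-reporter readthrough is the luminescence/fluorescence ratio
$y = x_2/x_1$ per replicate with first-order propagation
$\sigma_y = [\sigma_{x_1}^2 (\partial y/\partial x_1)^2 +
\sigma_{x_2}^2 (\partial y/\partial x_2)^2]^{1/2}$, combined across
replicates by inverse-variance weighting ($w_i = 1/\sigma_i^2$,
$x_m = \sum x_i w_i / \sum w_i$, $\sigma_{x_m} = (\sum w_i)^{-1/2}$) and
normalized to the no-stop control, set to 100%. Replicates with zero SD
are rejected rather than given infinite weight, since the weighting
formula is undefined there. Blank subtraction, when blank columns are
present, is the only pre-transformation. First-order propagation is
accurate to a few per mill against Monte-Carlo at coefficients of
variation up to ~10%; the tests pin this at 5% relative.

## Synthetic data: what it emulates, and what it does not

The generators produce data with the statistical structure each stage
assumes, with fixed seeds making them pure functions of their arguments.

* `gen_scc_dataset()` draws contexts uniformly per position and responses
  from a planted linear model plus Gaussian noise — Gaussian because that
  is the noise model least squares optimizes. Planted weights
  (`planted_scc_weights()`) are constructed with equal block sums: the
  indicator design has one exact linear dependency per position block, so
  raw weights are only identifiable up to block-constant shifts, and
  equal-block-sum weights are precisely the representative ridge converges
  to as $k \to 0$. The default gauge constant (block sum 0.2) keeps
  responses positive, like readthrough percentages; the default noise SD
  (0.004, ~40% of the planted signal SD) defines the moderate-noise
  regime.
* `gen_pts1_dataset()` plants terminal PTS1 tripeptides
  ({SKL, SRL, ARL, AKL}) on random peptide bodies; negatives avoid the
  motifs. With bodies of realistic length the classes are separable *at
  the terminus* but body positions add score noise — cross-validated
  auROC lands around 0.99, much like a real corpus. Restricting peptides
  to bare tripeptides (`length_range = c(3, 3)`) removes body noise and
  gives the perfectly separable case with held-out auROC exactly 1.
* `gen_transcriptome()` builds well-formed decoys (uniform codon usage —
  no attempt to mimic human codon bias) and plants candidates carrying the
  TGA-CTAG context motif and an 18-nt extension ending in SRL, the
  structure of the top-ranked human transcript. Decoys are
  rejection-sampled away from both the context motif and PTS1-like
  termini.

What passing on synthetic data does **not** show: real stop-codon contexts
are not uniform (the bundled frequency table shows the actual position
biases), real readthrough responses are heteroskedastic and bounded below
by assay background, real PTS1 corpora are heavily imbalanced orthology
sets, and a real transcriptome's candidate density is far from the planted
1-in-500. Published data-dependent figures — leave-one-out SSE minima of
order $10^{-7}$–$10^{-6}$, held-out Pearson correlations of 0.34/0.41,
auROC 0.996 / auPRC 0.863, genome-wide motif and transcript counts, and
specific posterior values — depend on external corpora that are not
bundled, and are documented rather than reproduced.

## Numerical choices and problem sizes

* Ridge systems are solved with a symmetric direct solve; the test suite
  requires agreement with an independent dense QR solve to $10^{-10}$.
* Leave-one-out uses the exact hat-matrix identity (no approximation).
* Degenerate inputs: all-equal scores min-max scale to all zeros; all-zero
  indicator vectors refuse normalization; zero-norm models refuse RTP
  scoring; tie rules (smallest $k$, lexicographically first base, id
  order, distance-from-stop removal) are explicit and tested.
* The test and acceptance runs use desk-scale problem sizes chosen so each
  property is statistically comfortable at any seed: 120 contexts for
  noiseless weight recovery, 400 for moderate-noise held-out correlation,
  60 low-noise contexts for elimination recovery, 2000 peptides for the
  null auROC, and 500 decoys for the end-to-end scan.

## Known limitations

* Linear models only; the underlying relationship between context and
  readthrough is partly non-linear, which the modest real-data
  correlations reflect. Non-linear extensions are out of scope.
* The first-pass (LIN) and five-position (LINfs5) weight values were never
  published; the procedures that produce them are fully supported, but
  those specific models cannot be reconstructed.
* Standard genetic code only; no 4-base stops, no reverse-strand logic
  (inputs are sense-strand CDS exports), no handling of ambiguity codes
  beyond filtering.
* The reporter module consumes tidied plate tables, not instrument
  exports.
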