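---
title: "Ternary classification of readiness potentials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ternary classification of readiness potentials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpbci)
```

## The problem

The readiness potential (RP, Bereitschaftspotential) is a slow negative EEG
deflection that builds up over motor cortex for up to ~1.5 s before a
voluntary movement. Its late phase lateralizes: amplitude is larger over the
hemisphere contralateral to the moving hand. Because the RP precedes the
movement and is specific to *voluntary* action, it is an attractive control
signal for asynchronous brain-computer interfaces: a user could signal intent
by merely preparing a small movement, and a three-state decoder (idle /
left-hand / right-hand) turns that into a practical control alphabet.

The catch is that the single-trial RP is a few microvolts buried in ongoing
EEG. `rpbci` implements a complete decoding chain for this problem:

1. **Trial screening and epoching** — trials in which the key press follows
   the auditory cue within 2 s (a reactive rather than self-initiated
   response) or contains multiple presses are discarded. From each valid
   trial two 500 ms epochs are cut: the interval just before the cue (idle)
   and the interval ending 130 ms before the press (pre-movement).
2. **PSTF feature extraction** — a pipeline of spatio-temporal filtering:
   zero-phase Butterworth band filtering, EOG artifact regression, a
   regularized Fisher-criterion spatial beamformer, and non-overlapping
   window averaging, with the cut-offs, regularization and window size
   optimized per subject (and per binary subproblem) by inner
   cross-validation.
3. **Ternary classification** — either one direct multiclass model (MCS) or
   a binary decomposition: one-against-one with pairwise coupling,
   one-against-all, a directed binary tree, or a decision directed acyclic
   graph (DDAG).
4. **ODCS** — an ordered diversified classifier system: at every binary
   node, five candidate algorithms (LPGM, SVM, FLDA, LR, RLS) are ranked by
   validation accuracy; the top one is selected or the top *m* are fused by
   a reliability-weighted average of their posteriors.
5. **Evaluation** — Cohen's kappa under a trial-level 10-chunk
   cross-validation protocol.

## The feature model

Let $X_{i,k} \in \mathbb{R}^{N \times T}$ be the $k$-th epoch of class $C_i$
($N$ channels, $T$ samples). With class means $M_i$, grand mean $M$ and
empirical priors $p_i = K_i / K$, the spatial scatter matrices are

$$S_b = \sum_i p_i (M_i - M)(M_i - M)', \qquad
  S_w = \sum_i \sum_k (X_{i,k} - M_i)(X_{i,k} - M_i)'.$$

$S_w$ is the raw pooled scatter, deliberately unnormalized. The beamformer
$W$ maximizes the Fisher quotient $W'S_bW / W'(S_w + \gamma I)W$, i.e. it is
the leading eigenvector of $(S_w + \gamma I)^{-1} S_b$; the filter output
$y_k = W'X_k$ is a single virtual channel whose class contrast is maximal.
$\gamma$ shrinks the solution toward the leading eigenvector of $S_b$ and
guarantees invertibility; it is one of the searched hyperparameters.
Averaging $y_k$ over consecutive non-overlapping windows of $w$ samples
keeps the slow temporal evolution that characterizes the RP while reducing
the dimension to $T' = \lfloor T/w \rfloor$ features.

Numerically, the eigenproblem is solved on the symmetrized form via a
Cholesky whitening of $S_w + \gamma I$; the filter is normalized to unit
Euclidean norm with its largest-magnitude entry positive, so results are
deterministic. A $\gamma = 0$ candidate that meets a singular $S_w$ scores
zero in the grid search instead of aborting it.

## Hyperparameters and their defaults

| parameter | candidates (default grid) | role |
|---|---|---|
| low-pass cut-off | 1–7 Hz | upper edge of the RP band |
| high-pass cut-off | none, 0.1, 0.3, 0.5 Hz | drift removal |
| $\gamma$ | 0, 1, 10, $10^3$, $10^4$, $10^5$, $10^6$ | beamformer shrinkage |
| window $w$ | 5, 10, 25 samples | temporal feature resolution |
| RLS $\lambda$ | 0, 0.5, 1, 10, $10^2 \ldots 10^5$ | ridge weight (inner CV) |

The full product (588 combinations) is searched exhaustively by stratified
5-fold inner cross-validation on training data only; ties resolve toward the
lower low-pass, absent high-pass, lower $\gamma$ and larger window —
i.e. toward the smoother, simpler model. Butterworth order is 4 per pass
(a common EEG default that remains numerically stable at a 0.1 Hz cut-off);
each pass is applied forward and backward, which zeroes the phase response
and squares the magnitude response. Epochs are short (50 samples at the
100 Hz working rate), so signals are reflect-padded by one epoch length
before filtering. The working rate itself comes from an anti-aliased
integer-factor downsampling of the acquisition rate (1 kHz by default).

EOG regression coefficients $b = \mathrm{Cov}(EOG)^{-1}\mathrm{Cov}(EOG, EEG)$
are estimated on training epochs only and applied frozen to test epochs —
the regression is part of the model, not of the data. Because both the
regression subtraction and the band filters are linear, the grid search
filters each problem's signals once per cut-off pair and applies the
fold-specific coefficients to the filtered EOG; this is observationally
equivalent to re-running the chain per fold and dominates the speedup that
makes the exhaustive search practical.

## Decompositions, coupling and the ODCS

All binary training sets are balanced by subsampling the larger side without
replacement (seeded); superclass pools ("all others", "movement") are
subsampled class-proportionally first, so the pool's internal mix is
preserved. Test data are never subsampled.

One-against-one posteriors are combined by pairwise coupling: the
probability vector $p$ on the simplex minimizing
$\sum_{i<j}(r_{ji}p_i - r_{ij}p_j)^2$, computed by the standard fixed-point
iteration of the second Wu–Lin–Weng formulation. The DDAG evaluates the
first-vs-last classifier of its ordered class list and eliminates the loser
until one class survives; the default order is `RIL` (root compares right
vs left). The directed binary tree first separates idle from movement, then
left from right. Each scheme maps every input to exactly one label; ties at
any comparison resolve toward the earlier class in the canonical (R, I, L)
order, making every prediction deterministic.

The ODCS orders the five candidate algorithms per binary subproblem by
seeded stratified 5-fold validation accuracy on the subproblem's training
features (one estimate, used both for ranking and as the fusion weight —
the alternative of a single held-out split would be noisier at these sample
sizes). Fusion weights are the softmax of the validation accuracies,
$\omega_i = e^{VA_i} / \sum_j e^{VA_j}$: a convex combination that never
leaves the range of its inputs, reduces to plain averaging under equal
accuracies and to pure selection at $m = 1$. During the hyperparameter grid
search for ODCS runs the scoring classifier is FLDA — closed-form, fast,
and the strongest single candidate on this kind of feature — while
single-algorithm runs score the grid with the same algorithm they deploy.

Two details are deliberate interpretations where the design was open. The
node layout of the three DDAG orders follows the standard construction
(root = first vs last of the ordered list). And each binary subproblem fits
its own PSTF (binary-form scatter matrices) rather than sharing one chain
per subject; the direct multiclass model uses the ternary-form scatter.

## Evaluation protocol

Trials are split into 10 equal, disjoint, contiguous chunks *at the trial
level*, so a trial's idle and movement epochs always share a chunk; each
fold trains on nine chunks and tests on the untouched tenth. Contiguous
(chronological) chunking is the conservative default under slow signal
drifts; a seeded shuffled assignment is available in the configuration. A
leakage guard aborts any run in which a test trial appears on the training
side. Because test sets keep their natural ~2:1:1 idle:left:right imbalance,
Cohen's kappa
$$k = \frac{N\sum_i h_{ii} - \sum_i T_{r_i}T_{c_i}}
           {N^2 - \sum_i T_{r_i}T_{c_i}}$$
is the headline score rather than raw accuracy; both the mean of fold kappas
and the pooled-confusion kappa are reported (they differ in general — the
mean is the headline).

```{r kappa-example}
cm <- reference_confusion_odcs3_ddag()
cm
cohen_kappa(cm)
round(100 * per_class_accuracy(cm), 2)
```

The bundled reference matrix shows the characteristic error structure of
this problem: idle is recognized almost perfectly, and most movement errors
are lateral confusions (right predicted as left and vice versa), consistent
with the bilateral — if asymmetric — cortical origin of the RP.

## The synthetic data generator

No public recording accompanies this problem, so the package ships a
generator (`simulate_dataset()`) that emulates the protocol's structure
with known ground truth: per trial, an idle baseline, a cue at a random
time, a press latency drawn from a normal distribution (mean 4.76 s,
SD 1.98 s) truncated at the 2 s screening bound, and EEG composed of

* a pre-movement negativity: a linear ramp from zero at 1.5 s before the
  press to its peak at the press, loaded on a unit-norm spatial pattern over
  the hand-area channels (C1/C3/CP1/CP3 and mirrors) with contralateral
  dominance set by `lateralization_ratio` (default 2; a ratio of 1 makes
  left and right indistinguishable by construction);
* 1/f-power background noise, independent per channel plus a shared
  common-mode term, and an 8–12 Hz oscillation with random phase and
  frequency per channel;
* blink artifacts: raised-cosine deflections on four EOG channels, mixed
  into the EEG through a known frontal-weighted matrix, so the EOG
  regression step has an exactly recoverable target.

Configured fractions of trials violate the screening rules on purpose
(reactive presses, double presses) to exercise the screening stage. The
whole dataset is a pure function of the config seed.

The defaults (34 + 4 channels at 1 kHz, 200 trials per side, RP amplitude
12 µV against 2.5 µV pink and 1.5 µV alpha noise) put the single-trial RP
clearly above the background: a deliberately favourable regime in which the
full ODCS3-DDAG protocol reaches a mean fold kappa around 0.95. That choice
makes the end-to-end tests sharp — failures indicate defects, not noise —
but it must not be read as an empirical claim: real single-trial RP data are
far noisier, carry non-stationarities, volume-conducted source mixtures and
oscillatory (ERD) components that the generator deliberately omits, and
desk-scale synthetic kappas say nothing about the scores attainable on real
recordings. What passing tests *do* establish is internal correctness:
screening, windows, the beamformer's recovery of a planted pattern (exact
at zero noise), balance of every subproblem, absence of train/test leakage,
and chance-level collapse under label shuffling.

## Problem sizes used in the shipped checks

Unit tests run on small fixtures (tens of trials, 200 Hz, reduced grids) so
the whole suite stays fast; the end-to-end acceptance check runs one
default-scale simulated participant (400 trials, 34 channels, 1 kHz) through
ODCS3-DDAG with a reduced but range-spanning grid
(low-pass {1, 3, 5} Hz, high-pass {none, 0.3} Hz, γ {0, 10, 10⁴},
windows {5, 10, 25}) — the package's standing configuration for
desk-scale reproduction, chosen once to span each hyperparameter's range at
a fraction of the full 588-point product.

## Known limitations

* The generator plants a single rank-one RP source per hand; it does not
  model volume conduction from a realistic head geometry, ERD, or
  non-stationary noise.
* Only the first Fisher eigenvector is used as a spatial filter;
  multi-filter extensions (CSP-style banks) are out of scope.
* SVM probabilities come from Platt-style calibration inside `e1071`, and
  the RLS posterior is a softmax over one-vs-rest ridge scores — both are
  calibration conventions, adequate here because downstream decisions use
  posterior order, not calibrated magnitudes.
* Group-level inference across participants (ANOVA and post-hoc tests on
  kappa tables) is out of scope; `write_results()` exports per-fold CSVs
  for external statistics.
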