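# rpbci

Ternary classification of single-trial readiness potentials (RPs) for
self-paced brain-computer interfaces, in R.

The readiness potential is a slow negative EEG deflection that builds up
over motor cortex for up to ~1.5 s before a voluntary movement, with larger
amplitude over the hemisphere contralateral to the moving hand. Decoding it
on single trials allows a three-state asynchronous BCI — idle vs an upcoming
left-hand vs right-hand fine movement — paced by the user, not the system.
`rpbci` implements the full decoding chain for researchers working on
movement-related cortical potentials:

* **Trial screening and epoching** — reactive responses (press within 2 s of
  the cue) and multi-press trials are discarded; each valid trial yields a
  500 ms idle epoch (pre-cue) and a 500 ms pre-movement epoch ending 130 ms
  before the key press.
* **PSTF feature extraction** — zero-phase Butterworth band filtering, EOG
  artifact regression, a regularized Fisher-criterion spatial beamformer,
  and non-overlapping window averaging, with all hyperparameters (cut-offs,
  regularization γ, window size) optimized per subject and per subproblem by
  inner 5-fold cross-validation over the candidate grid
  {1..7 Hz} × {none, 0.1, 0.3, 0.5 Hz} × {0, 1, 10, 10³..10⁶} × {5, 10, 25}.
* **Multiclass strategies** — a direct ternary classifier (MCS) or binary
  decompositions: one-against-one with Wu–Lin–Weng pairwise coupling,
  one-against-all, a directed binary tree (idle vs movement, then left vs
  right), and decision directed acyclic graphs in all three node orders.
* **ODCS** — the ordered diversified classifier system: per class pair, five
  candidate algorithms (pooled-covariance Gaussian model, RBF-SVM, Fisher
  LDA, logistic regression, regularized least squares) are ranked by
  validation accuracy; the best is selected (`m = 1`) or the top *m* are
  fused by a reliability-weighted average with softmax-of-accuracy weights
  `ω_i = exp(VA_i) / Σ_j exp(VA_j)`.
* **Evaluation** — Cohen's kappa
  `k = (N Σ h_ii − Σ T_ri T_ci) / (N² − Σ T_ri T_ci)` under a trial-level
  10-chunk cross-validation protocol with a leakage guard; kappa is used
  because test sets keep their natural ~2:1:1 idle:left:right imbalance.
* **Synthetic data** — a seeded generator of RP-like EEG (lateralized
  pre-movement ramp, 1/f and alpha background, blink artifacts mixed through
  a known EOG matrix) with ground truth, so every stage is testable without
  any recording.

## Worked example

The bundled reference confusion matrix — the pooled 10-fold test counts of
an ODCS3-DDAG classifier over fourteen participants — reproduces the
headline statistics of this method family:

```r
library(rpbci)
cm <- reference_confusion_odcs3_ddag()
cm
#>        predicted
#> correct    R    I    L
#>       R 1896  116  608
#>       I   51 5043  146
#>       L  454  128 2038
round(cohen_kappa(cm), 4)
#> [1] 0.7701
round(100 * per_class_accuracy(cm), 2)
#>     R     I     L
#> 72.37 96.24 77.79
```

Idle epochs are recognized almost perfectly (96.24%); most movement errors
are lateral confusions between right (72.37% correct) and left (77.79%
correct), as expected from the bilateral origin of the RP.

End to end on synthetic data — simulate one small participant, run the
ODCS3-DDAG protocol, and read the per-fold kappas:

```r
cfg <- sim_config(n_trials_per_side = 25, fs_acquire = 200, seed = 42)
sim <- simulate_epochs(cfg)
sim$epochs
#> <epoch_set> 100 epochs, 34 channels x 100 samples @ 200 Hz
#>
#>  I  L  R
#> 50 25 25

rt <- run_protocol(sim$epochs, method = "ddag", odcs_m_best = 3,
                   grid = pstf_grid(low_pass = c(1, 3), high_pass = NA,
                                    gamma = c(0, 10), window = c(10, 25)),
                   n_chunks = 10, seed = 42)
rt
#> <result_table> method=ddag: mean fold kappa = 0.9042 (SD 0.1342), pooled kappa = 0.9040
#>        predicted
#> correct  R  I  L
#>       R 23  1  1
#>       I  1 49  0
#>       L  3  0 22
```

Each of the 10 folds trains the full chain (PSTF grid search, per-pair
classifier ordering, fusion of the best three) on 9 chunks of trials and
predicts the held-out chunk; the mean fold kappa of 0.90 on this favourable
synthetic regime indicates a near-clean separation, with the residual errors
again lateral (R↔L). `write_results(rt, "out/")` exports the per-fold CSV.

A thin command-line wrapper is installed under `inst/cli/rpbci`:

```sh
Rscript inst/cli/rpbci simulate --config cfg.yaml --out data/
Rscript inst/cli/rpbci run --config cfg.yaml --data data/ --out results/
Rscript inst/cli/rpbci compare --config cfg.yaml --data data/ --out results/
```

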