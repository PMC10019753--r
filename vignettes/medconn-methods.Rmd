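---
title: "Methods: inter-hemispheric EEG connectivity and group classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-hemispheric EEG connectivity and group classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis model

`medconn` quantifies functional connectivity between the left and right
prefrontal hemispheres in multichannel EEG recorded over a sequence of
experimental states (baseline, meditation, transmission, post), and asks
whether connectivity features separate meditator groups (long-term LTM,
short-term STM, non-meditator NM). The chain is:

1. restrict to 20 prefrontal channels (10 left, 10 right);
2. cut the recording into its states and decompose each state into the four
   canonical bands — delta 0.3–4, theta 4–8, alpha 8–12, beta 12–30 Hz;
3. slice each band-filtered state into non-overlapping 10 s epochs;
4. per epoch, compute the full 20×20 Pearson correlation and phase-locking
   value (PLV) matrices; summarise each by the mean of its 10×10
   inter-hemispheric block;
5. per epoch, convert the PLV matrix to a weighted graph and compute the
   mean Onnela clustering coefficient (CC) and the characteristic path
   length (SP) from all-pairs Dijkstra distances;
6. classify group pairs from state-wise or band-wise feature tables under
   10-fold cross-validation, and test group differences per
   (measure, band, state) cell.

The statistical assumptions are those of its parts: PLV assumes narrowband
input (the Hilbert analytic signal only yields a meaningful instantaneous
phase for band-limited signals — hence band-pass first, always); Pearson
correlation assumes second moments exist (trivially true here); the Welch
group test assumes approximate normality of *subject-level* feature means,
reasonable since each is an average over many epochs.

## Synthetic cohorts: what they emulate, and what not

Real recordings of this design (128-channel nets, 250 Hz, four states of
5/10/10/5 minutes, 34 participants: 13 LTM / 11 STM / 10 NM) are not
publicly available, so the generator reproduces the *statistical structure*
the analysis consumes. For each state and band, all channels of both
hemispheres share a common unit-variance narrowband process, mixed per
channel as

```
x_ch = kappa * common + (1 - kappa) * private_ch   (+ sensor noise)
```

with `common` and `private_ch` independent white-noise processes band-passed
to the band edges, and `kappa` in [0, 1] the coupling strength for that
(group, state, band). Bands are summed per channel. Narrowband *noise*
rather than sinusoids is essential: sinusoids have degenerate (perfectly
predictable) phases, which would make PLV trivially 1 at any coupling. The
mapping `kappa -> empirical PLV` is monotone but not analytic in any simple
form; the test suite documents it empirically (Spearman rho > 0.95 across a
kappa grid, PLV > 0.99 at kappa = 1 with zero noise).

Generator defaults encode the targeted study design: 250 Hz; state
durations 300/600/600/300 s; 10 channels per hemisphere labelled
`PF_L1..PF_L10` / `PF_R1..PF_R10`; group sizes 13/11/10; coupling higher
for LTM than STM than NM and higher during meditation and transmission
than at baseline/post (LTM 0.35/0.60/0.65/0.40 across the four states,
STM 0.30/0.45/0.50/0.35, NM 0.25/0.30/0.30/0.25, equal across bands);
sensor noise SD 0.5 relative to the unit-variance band mixture — a
moderate, realistic signal-to-noise choice. Subject `i` of a cohort uses
RNG seed `master + i`, so cohorts are deterministic and individual subjects
reproducible in isolation.

Deliberately **not** modelled: ocular/muscular artifacts (the corresponding
manual cleaning step of real pipelines is irreproducible and out of scope),
volume conduction, full-scalp geometry, 1/f background spectra, and
non-stationarity within a state. Passing tests therefore demonstrate that
the pipeline recovers coupling structure it is pointed at — not that real
EEG carries such structure.

## Numerical choices

- **Filtering.** Zero-phase Butterworth band-pass, order 4 per pass, run
  forward–backward twice. Zero phase is mandatory because PLV is
  phase-sensitive; a causal filter's group delay would bias phase
  differences. The doubled pass steepens the stop-band so that a tone 2 Hz
  outside a band edge is suppressed below 1% amplitude while the passband
  stays within ±5%. Signals are reflect-padded by three periods of the low
  band edge before filtering (then trimmed) to absorb the IIR start-up
  transient; the recursion itself runs through C-level `stats::filter`.
  The filter is applied to whole state segments *before* epoching, so epochs
  carry no per-epoch edge artifacts. An optional 50 Hz notch exists for real
  recordings with mains interference; it is off by default.
- **Instantaneous phase.** FFT construction of the analytic signal. The
  first and last 5% of each epoch's phase series are trimmed before the PLV
  average because the transform's circular boundary distorts them; the
  trimmed sample count is the `L` of the PLV definition and is recorded in
  the matrix metadata.
- **PLV form.** The modulus of the mean unit phasor,
  `|1/L sum exp(j (phi_i - phi_j))|`. Without the modulus the quantity would
  be complex and could not span the documented range 0..1.
- **Null level of PLV.** For genuinely independent *white*-phase signals the
  expected PLV is of order `1/sqrt(L)`. Band-limited signals decorrelate
  much more slowly — phases are autocorrelated over roughly the reciprocal
  bandwidth — so the effective number of independent phase samples is far
  smaller than L and the null PLV correspondingly larger (about 0.05 for
  60 s of alpha at 250 Hz). Tests assert each regime where it applies.
- **Edge weights.** Correlation-derived graphs use `|r|` — a strong negative
  association is still coupling, and signed weights would break the [0, 1]
  weight domain of the clustering formula. PLV is used as-is. Graph metrics
  default to the PLV graph (weights natively in [0, 1]); a
  `graph_from = "correlation"` switch exists.
- **Clustering coefficient.** The Onnela triangle-intensity form
  `(w_jk w_jl w_kl)^(1/3)` with binary degree over nonzero edges; nodes with
  degree < 2 score 0, and the mean is over nodes with degree >= 2. Weights
  are already bounded by 1, so no max-weight normalisation is applied. On
  0/1 weights this reduces exactly to the binary clustering coefficient.
- **Distances.** Edge length `d = 1/w` (strong coupling = short path),
  consistent with reading the average shortest path as inverse global
  efficiency; `d = 1 - w` is available behind `dist_transform`. Unreachable
  pairs are excluded from the characteristic-path mean and reported via
  `finite_pair_fraction` rather than imputed. Dijkstra runs from every
  source with a dense O(n²) scan — optimal at n = 20.
- **Thresholding.** None by default (`q = 1`): with 20 nodes and full
  matrices every node has 19 nonzero neighbours. A proportional threshold
  (keep the strongest fraction `q` of edges) is available, since sparser
  graphs make degree- and path-based metrics more discriminating.
- **Epochs.** 10 s non-overlapping. This gives >= 30 samples per state per
  subject at the default durations and at least 3 cycles of the slowest
  delta component per epoch; shorter epochs destabilise delta-band phase
  estimates, longer ones starve the classifier of samples.

## Classification design

The sampling unit is the (subject, epoch) pair. With 10–13 subjects per
group, subject-level samples cannot support stable 10-fold cross-validation,
so epochs are the samples — which makes leakage the central danger. Folds
are therefore assigned at the *subject* level by default: all epochs of a
subject share a fold, and the stratified round-robin assignment keeps
per-class fold sizes within one subject of each other. Feature
standardisation is fit on training folds only (a deliberate-leak regression
test guards this). With fewer than 10 subjects the code falls back to
epoch-level folds and warns that training and test epochs may then share
subjects — the leaky protocol many small-sample EEG studies implicitly use,
kept available precisely for that comparison.

Hyperparameters are fixed and documented rather than tuned: decision tree =
`rpart` defaults; LDA and binary logistic regression in textbook form; SVM
with RBF kernel, cost 1, gamma 1/p; k-NN with k = 5; ensemble = 100-tree
bagging (random forest with mtry = p). Accuracy is the headline metric;
sensitivity/specificity derive from the pooled confusion matrix. The
state-wise design defaults to baseline/meditation/transmission (post is
available via the `states` argument); the band-wise design uses all four
bands, pairing epochs across states by index truncated to each subject's
shortest state.

## Group statistics

Group contrasts are Welch two-sample t-tests on subject-level means (epochs
averaged within subject first — epoch-level testing would pseudo-replicate
by treating correlated epochs as independent). The test choice is this
package's own: bar-panel comparisons of this kind rarely name their test,
and Welch is the robust default for small unequal groups. Stars follow the
conventional thresholds (* p < 0.05, ** p < 0.01, *** p < 0.001), applied
per cell without multiple-testing correction by default to mirror the usual
per-panel presentation; Benjamini–Hochberg adjustment is available via
`adjust = "BH"`. A pooled-variance Student variant sits behind `method`.
Under the null the test's type-I error is calibrated at the nominal 5%
(simulation in the test suite).

## Interchange formats

Recordings serialise to a channels × samples CSV plus a versioned JSON
sidecar (montage, sampling rate, group, schedule); montage maps load from
two-column CSVs; connectivity matrices export to labelled CSV with JSON
metadata; graphs export as edge lists. These plain-text formats are the
package's interchange dialect — self-describing, diffable and
dependency-free; EDF import can be layered on top by converting to this
dialect with any EDF reader.

## Problem sizes used in tests

The shipped tests and `scripts/acceptance.R` run the pipeline at reduced
scale — 60 s states, one to four bands, 5–16 subjects per group — which
preserves every structural property under test (coupling recovery,
directionality, calibration) while keeping the suite quick to run. The
generator's defaults remain the full design; nothing in the code depends on
the reduced sizes.

## Known limitations

- PLV on amplitude-mixed signals measures phase alignment induced by the
  shared component; it is not a model of neural phase coupling mechanisms.
- The synthetic montage is positionless; no spatial leakage/volume
  conduction means connectivity estimates are optimistic relative to real
  scalp EEG, where zero-lag leakage inflates both r and PLV.
- Characteristic path length on dense 20-node graphs varies smoothly with
  mean weight; its discriminative value grows if proportional thresholding
  is enabled.
- With epoch-level folds (the fallback), reported accuracies are
  optimistic; the warning is deliberate and should be heeded in any real
  analysis.
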