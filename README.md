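# medconn

Band-limited inter-hemispheric EEG connectivity analysis of meditation
states, with cross-validated classification of meditator groups.

Meditation studies repeatedly report stronger functional coupling between
the left and right prefrontal cortex in experienced meditators, especially
during practice. `medconn` implements that analysis as a tested, reusable R
pipeline for researchers working with multichannel EEG recorded across a
sequence of conditions (here called *states*: baseline, meditation,
transmission, post). Because raw human recordings of this kind are rarely
shareable, the package ships a first-class synthetic-cohort generator whose
inter-hemispheric coupling is controlled per group, state and frequency
band, so every downstream stage can be validated without any data download.

## What it computes

For every 10 s epoch of each band-filtered state segment (delta 0.3–4 Hz,
theta 4–8 Hz, alpha 8–12 Hz, beta 12–30 Hz; 20 prefrontal channels, 10 per
hemisphere), four connectivity features:

- **Pearson correlation** between channels *i*, *j*:
  `Cor(i,j) = Cov(i,j) / sqrt(Var(i) Var(j))`, averaged over the 10×10
  inter-hemispheric channel pairs.
- **Phase-locking value** from Hilbert-transform instantaneous phases:
  `PLV(i,j) = |1/L Σ exp(jΘ(i,j))|` where `Θ` is the per-sample phase
  difference; 1 means perfect phase synchrony, independent phases decay
  toward 0.
- **Weighted clustering coefficient** (Onnela form) of the connectivity
  graph: `C_j = 1/(k_j(k_j−1)) Σ_(k,l) 2 (w_jk w_jl w_kl)^(1/3)` — local
  segregation.
- **Characteristic path length**: mean Dijkstra shortest-path distance over
  node pairs with edge length `d = 1/w` — the inverse proxy for global
  efficiency (shorter = better integrated).

Features feed two designs: *state-wise* tables (4 measures × 4 bands per
state) and *band-wise* tables (4 measures × 4 states per band), classified
with six families — decision tree, LDA, logistic regression, SVM (RBF),
k-NN and a 100-tree bagged ensemble — under 10-fold cross-validation with
subject-level folds (all epochs of a subject stay in one fold, so no subject
leaks between training and test). Between-group contrasts use Welch tests
on subject-averaged features with conventional significance stars.

## Worked example

```r
library(medconn)

cfg <- synth_config(n_per_group = c(LTM = 5, STM = 0, NM = 5),
                    state_durations = c(baseline = 60, meditation = 60),
                    seed = 42)
cohort <- generate_cohort(cfg)
cohort[[1]]
#> <eeg_recording LTM_01 group=LTM: 20 ch x 30000 samples @ 250 Hz, states: baseline, meditation>

feats <- cohort_features(cohort)     # one row per subject/state/band/epoch
head(feats, 3)
#>   subject_id group    state  band epoch_index          r       plv        cc       sp
#> 1     LTM_01   LTM baseline delta           1 0.04017522 0.2098207 0.1876428 5.023101
#> 2     LTM_01   LTM baseline delta           2 0.28024876 0.2473196 0.2424636 4.076851
#> 3     LTM_01   LTM baseline delta           3 0.22490558 0.2221827 0.1959484 4.720830

compare_groups(feats, "plv", "alpha", "meditation", c("LTM", "NM"))
#> <plv | alpha band | meditation: LTM 0.5875 (sd 0.0198, n=5) vs NM 0.1809 (sd 0.0056, n=5), p=2.969e-07 ***>

tab <- build_feature_table(feats, "statewise", "meditation")
cv <- crossvalidate(tab, "LTM vs NM", "SVM", seed = 1)
cv
#> <cv_result LTM vs NM | statewise/meditation | SVM (subject-level folds): mean accuracy 1.000>
cv$confusion_matrix
#>      predicted
#> truth LTM NM
#>   LTM  30  0
#>   NM    0 30
```

The long-term meditator (LTM) group was simulated with alpha coupling 0.60
during meditation against 0.30 for non-meditators (NM), so the group gap in
mean inter-hemispheric alpha PLV (0.59 vs 0.18) is the generator's design
showing through the full pipeline, and an SVM separates the groups
perfectly. `run_full_comparison(feats, seed = 1)` produces the whole
2 comparisons × (3 states + 4 bands) × 6 classifiers accuracy grid, and
`comparison_grid(feats)` the 192-cell grid of Welch tests with stars.

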