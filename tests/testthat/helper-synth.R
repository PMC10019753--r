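# small cohort settings used across test files: four 40 s states, 2 subjects
# per group, moderate noise
small_cfg <- function(seed = 7, ...) {
  synth_config(
    n_per_group = c(LTM = 2, STM = 2, NM = 2),
    state_durations = c(baseline = 60, meditation = 60,
                        transmission = 60, post = 60),
    noise_sd = 0.3, seed = seed, ...)
}

# lazily computed shared fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

cached_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(small_cfg())
  .fixtures$cohort
}

cached_feats <- function() {
  if (is.null(.fixtures$feats))
    .fixtures$feats <- cohort_features(cached_cohort())
  .fixtures$feats
}

# a single-band, single-state recording: cheap input for connectivity tests
quick_recording <- function(kappa, noise_sd = 0, seconds = 40, seed = 11,
                            band = eeg_bands()["alpha"]) {
  cfg <- synth_config(n_per_group = c(LTM = 1, STM = 0, NM = 0),
                      state_durations = c(meditation = seconds),
                      band_coupling = kappa, noise_sd = noise_sd,
                      bands = band, seed = seed)
  generate_recording(cfg, "LTM", "S01", seed = seed)
}

# mean inter-hemispheric connectivity of one whole-state epoch
state_interhem <- function(rec, method, band = eeg_bands()$alpha,
                           epoch_seconds = NULL) {
  segs <- segment_states(rec)
  st <- names(segs)[1L]
  n_sec <- ncol(segs[[st]]) / rec$sampling_rate
  ctx <- list(subject_id = rec$subject_id, group = rec$group, state = st,
              left = which(rec$montage$hemisphere == "left"),
              right = which(rec$montage$hemisphere == "right"))
  ep <- band_epochs(segs[[st]], rec$sampling_rate,
                    epoch_seconds %||% n_sec, band, ctx)[[1L]]
  mean(interhemispheric_block(connectivity_matrix(ep, method)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# construct a band_epoch directly from a channels x samples matrix
fake_epoch <- function(data, fs = 250, band = eeg_bands()$alpha,
                       subject_id = "S01", group = "LTM",
                       state = "meditation", epoch_index = 1L) {
  n <- nrow(data)
  if (is.null(rownames(data)))
    rownames(data) <- c(sprintf("PF_L%d", seq_len(n %/% 2)),
                        sprintf("PF_R%d", seq_len(n - n %/% 2)))
  structure(list(subject_id = subject_id, group = group, state = state,
                 band = band, epoch_index = epoch_index, data = data,
                 sampling_rate = fs, left = seq_len(n %/% 2),
                 right = (n %/% 2) + seq_len(n - n %/% 2)),
            class = "band_epoch")
}

# construct a weighted graph directly from a symmetric matrix
fake_graph <- function(w) {
  diag(w) <- 0
  structure(list(nodes = sprintf("n%d", seq_len(nrow(w))), weights = w),
            class = "weighted_graph")
}

# random symmetric weight matrix in [0,1] with a given edge density
random_graph <- function(n, density = 0.7) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- stats::runif(sum(ut))
  vals[stats::runif(sum(ut)) > density] <- 0
  w[ut] <- vals
  w <- w + t(w)
  fake_graph(w)
}

# fabricated long feature table: one state, four bands, gaussian features with
# a group shift of `effect` (in SDs) applied to every measure for group1
fake_feats <- function(n_subj = c(LTM = 12, NM = 12), n_epochs = 4,
                       effect = 0, state = "meditation", seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in names(n_subj)) for (s in seq_len(n_subj[[g]])) {
    sid <- sprintf("%s_%02d", g, s)
    subj_shift <- stats::rnorm(1, mean = if (g == names(n_subj)[1L]) effect else 0,
                               sd = 0.5)
    for (b in names(eeg_bands())) for (e in seq_len(n_epochs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = g, state = state, band = b,
        epoch_index = e,
        r = stats::rnorm(1, subj_shift), plv = stats::rnorm(1, subj_shift),
        cc = stats::rnorm(1, subj_shift), sp = stats::rnorm(1, -subj_shift),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
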