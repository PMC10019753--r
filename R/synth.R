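#' Default group x state coupling map
#'
#' Inter-hemispheric coupling strength kappa per (group, state, band). The
#' defaults encode the study design the pipeline targets: long-term meditators
#' (LTM) couple more strongly than short-term meditators (STM), who couple
#' more strongly than non-meditators (NM), and coupling rises during
#' meditation and transmission relative to baseline and post. The same map is
#' used in all four bands.
#'
#' @param groups,states,bands Dimension labels.
#' @return 3-d numeric array `[group, state, band]` with values in `[0, 1]`.
#' @export
default_band_coupling <- function(groups = c("LTM", "STM", "NM"),
                                  states = c("baseline", "meditation",
                                             "transmission", "post"),
                                  bands = names(eeg_bands())) {
  base <- rbind(
    LTM = c(baseline = 0.35, meditation = 0.60, transmission = 0.65, post = 0.40),
    STM = c(baseline = 0.30, meditation = 0.45, transmission = 0.50, post = 0.35),
    NM  = c(baseline = 0.25, meditation = 0.30, transmission = 0.30, post = 0.25)
  )
  k <- array(NA_real_, dim = c(length(groups), length(states), length(bands)),
             dimnames = list(group = groups, state = states, band = bands))
  for (g in groups) for (s in states)
    k[g, s, ] <- if (g %in% rownames(base) && s %in% colnames(base)) base[g, s] else 0.3
  k
}

#' Configure a synthetic EEG cohort
#'
#' Describes a cohort of synthetic multichannel recordings whose
#' inter-hemispheric coupling per band is controlled by a kappa map. Defaults
#' mirror the targeted study design: 250 Hz sampling, four states of
#' 5/10/10/5 minutes, 10 channels per prefrontal hemisphere, groups of
#' 13 LTM / 11 STM / 10 NM.
#'
#' @param n_per_group Named counts for `LTM`, `STM`, `NM`.
#' @param sampling_rate Hz.
#' @param state_durations Named seconds per state; order defines the schedule.
#' @param band_coupling Either a single kappa in `[0, 1]` applied everywhere,
#'   or a `[group, state, band]` array as from [default_band_coupling()].
#' @param noise_sd SD of additive white sensor noise, in units of the
#'   (unit-variance) band-limited signal mixture.
#' @param n_channels_per_hemisphere Channels per hemisphere (default 10).
#' @param bands List of bands to simulate (default the four canonical bands).
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A `synth_config` object.
#' @export
#' @examples
#' cfg <- synth_config(n_per_group = c(LTM = 2, STM = 2, NM = 2),
#'                     state_durations = c(baseline = 30, meditation = 30),
#'                     seed = 1)
synth_config <- function(n_per_group = c(LTM = 13, STM = 11, NM = 10),
                         sampling_rate = 250,
                         state_durations = c(baseline = 300, meditation = 600,
                                             transmission = 600, post = 300),
                         band_coupling = default_band_coupling(),
                         noise_sd = 0.5,
                         n_channels_per_hemisphere = 10,
                         bands = eeg_bands(),
                         seed = 1L) {
  groups <- c("LTM", "STM", "NM")
  stopifnot(all(names(n_per_group) %in% groups), all(n_per_group >= 0))
  if (any(state_durations <= 0)) stop("state durations must be positive")
  if (is.null(names(state_durations))) stop("state_durations must be named")
  highest <- max(vapply(bands, `[[`, 0, "high"))
  if (sampling_rate <= 2 * highest)
    stop("sampling_rate must exceed twice the highest band edge (",
         2 * highest, " Hz)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.numeric(band_coupling) && length(band_coupling) == 1L) {
    k <- band_coupling
    band_coupling <- array(k, dim = c(3, length(state_durations), length(bands)),
                           dimnames = list(group = groups,
                                           state = names(state_durations),
                                           band = band_names(bands)))
  }
  if (any(band_coupling < 0 | band_coupling > 1))
    stop("all coupling strengths must lie in [0, 1]")
  structure(list(
    n_per_group = n_per_group,
    sampling_rate = sampling_rate,
    state_durations = state_durations,
    band_coupling = band_coupling,
    noise_sd = noise_sd,
    n_channels_per_hemisphere = as.integer(n_channels_per_hemisphere),
    bands = bands,
    seed = as.integer(seed)
  ), class = "synth_config")
}

coupling_for <- function(config, group, state, band_name) {
  k <- config$band_coupling
  dn <- dimnames(k)
  if (!group %in% dn$group) stop("unknown group label: ", group)
  if (!state %in% dn$state) stop("state ", state, " absent from coupling map")
  if (!band_name %in% dn$band) stop("band ", band_name, " absent from coupling map")
  k[group, state, band_name]
}

# unit-variance narrowband noise: white noise band-passed to the band edges
narrowband <- function(n, sampling_rate, band) {
  x <- bandpass(stats::rnorm(n), sampling_rate, band)
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Generate one synthetic EEG recording
#'
#' For every state and band, the left- and right-hemisphere channels share a
#' common band-limited component mixed per channel as
#' `x_ch = kappa * common + (1 - kappa) * private_ch`, where `common` and
#' `private_ch` are independent unit-variance narrowband processes (white
#' noise band-passed to the band edges) and `kappa` is the configured
#' coupling for (group, state, band). Bands are summed per channel and white
#' sensor noise of SD `noise_sd` is added. Larger kappa yields larger
#' inter-hemispheric correlation and phase-locking in that band.
#'
#' @param config A [synth_config()].
#' @param group One of `LTM`, `STM`, `NM`.
#' @param subject_id Subject label.
#' @param seed Seed for this subject's RNG substream; defaults to the
#'   config master seed.
#' @return An `eeg_recording`.
#' @export
generate_recording <- function(config, group, subject_id,
                               seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (!group %in% dimnames(config$band_coupling)$group)
    stop("unknown group label: ", group)
  set.seed(as.integer(seed %% .Machine$integer.max))
  fs <- config$sampling_rate
  nch_h <- config$n_channels_per_hemisphere
  nch <- 2L * nch_h
  labels <- c(sprintf("PF_L%d", seq_len(nch_h)), sprintf("PF_R%d", seq_len(nch_h)))
  hemis <- rep(c("left", "right"), each = nch_h)

  states <- names(config$state_durations)
  ns <- as.integer(round(config$state_durations * fs))
  total <- sum(ns)
  data <- matrix(0, nrow = nch, ncol = total, dimnames = list(labels, NULL))
  start <- 0L
  schedule <- data.frame(state = states, start = NA_integer_, end = NA_integer_,
                         stringsAsFactors = FALSE)
  for (si in seq_along(states)) {
    st <- states[si]
    n <- ns[si]
    seg <- matrix(0, nrow = nch, ncol = n)
    for (b in config$bands) {
      kappa <- coupling_for(config, group, st, b$name)
      common <- narrowband(n, fs, b)
      for (ch in seq_len(nch)) {
        private <- narrowband(n, fs, b)
        seg[ch, ] <- seg[ch, ] + kappa * common + (1 - kappa) * private
      }
    }
    if (config$noise_sd > 0)
      seg <- seg + matrix(stats::rnorm(nch * n, sd = config$noise_sd), nch, n)
    data[, (start + 1L):(start + n)] <- seg
    schedule$start[si] <- start
    schedule$end[si] <- start + n
    start <- start + n
  }
  structure(list(
    subject_id = subject_id,
    group = group,
    montage = data.frame(label = labels, hemisphere = hemis,
                         stringsAsFactors = FALSE),
    sampling_rate = fs,
    data = data,
    schedule = schedule
  ), class = "eeg_recording")
}

#' Generate a full synthetic cohort
#'
#' Subjects are generated in fixed group order (LTM, STM, NM); subject `i`
#' (1-based counter over the whole cohort) uses seed `config$seed + i`, so the
#' cohort is deterministic given the config and individual subjects are
#' reproducible regardless of how many others are generated.
#'
#' @param config A [synth_config()].
#' @return List of [generate_recording()] outputs,
#'   `sum(config$n_per_group)` long.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  out <- list()
  counter <- 0L
  for (g in c("LTM", "STM", "NM")) {
    n <- config$n_per_group[[g]] %||% 0L
    for (i in seq_len(n)) {
      counter <- counter + 1L
      out[[counter]] <- generate_recording(
        config, g, sprintf("%s_%02d", g, i), seed = config$seed + counter)
    }
  }
  out
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s group=%s: %d ch x %d samples @ %g Hz, states: %s>\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$sampling_rate, paste(x$schedule$state, collapse = ", ")))
  invisible(x)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config: %s; fs=%g Hz; states %s; %d+%d channels; noise_sd=%g; seed=%d>\n",
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group), collapse = " "),
              x$sampling_rate,
              paste(sprintf("%s(%gs)", names(x$state_durations), x$state_durations), collapse = " "),
              x$n_channels_per_hemisphere, x$n_channels_per_hemisphere,
              x$noise_sd, x$seed))
  invisible(x)
}
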