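# apply an IIR filter (b, a) along a vector at C speed
iir_apply <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution", sides = 1L)
  v <- v[-seq_len(nb - 1L)]
  as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
}

# zero-phase forward-backward pass of one filter, on a plain vector
filtfilt_vec <- function(b, a, x) {
  y <- iir_apply(b, a, x)
  rev(iir_apply(b, a, rev(y)))
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass (order 4 per pass) forward and backward,
#' twice, so the net filter has zero phase shift -- mandatory upstream of
#' phase-locking estimates, which a causal filter's group delay would corrupt
#' -- and a stop-band steep enough to suppress a tone 2 Hz outside the band to
#' below 1% amplitude. The signal is reflect-padded at both ends by roughly
#' three periods of the lower band edge before filtering and trimmed
#' afterwards, which suppresses the start-up transient of the IIR recursion.
#'
#' @param data Numeric vector, or channels x samples matrix (filtered row-wise).
#' @param sampling_rate Sampling rate in Hz.
#' @param band Band object from [band()] or a canonical band name.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered data, same shape as the input.
#' @export
#' @examples
#' fs <- 250
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1 / fs))
#' y <- bandpass(x, fs, "alpha")   # 10 Hz is in-band: passes through
bandpass <- function(data, sampling_rate, band, order = 4L) {
  band <- as_band(band)
  nyq <- sampling_rate / 2
  if (band$high >= nyq)
    stop("band edge ", band$high, " Hz at or above Nyquist (", nyq, " Hz)")
  flt <- signal::butter(order, c(band$low, band$high) / nyq, type = "pass")
  one <- function(x) {
    n <- length(x)
    pad <- min(n - 1L, ceiling(3 * sampling_rate / band$low))
    xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    y <- filtfilt_vec(flt$b, flt$a, filtfilt_vec(flt$b, flt$a, xp))
    y[(pad + 1L):(pad + n)]
  }
  if (is.matrix(data)) {
    out <- t(apply(data, 1L, one))
    dimnames(out) <- dimnames(data)
    out
  } else one(data)
}

#' Optional 50 Hz notch filter
#'
#' Second-order IIR notch, zero-phase. Off by default in the synthetic
#' pipeline; real recordings may carry mains interference.
#'
#' @inheritParams bandpass
#' @param freq Notch centre frequency in Hz (default 50).
#' @param bw Notch bandwidth in Hz.
#' @return Filtered data, same shape as input.
#' @export
notch <- function(data, sampling_rate, freq = 50, bw = 2) {
  nyq <- sampling_rate / 2
  if (freq >= nyq) stop("notch frequency at or above Nyquist")
  w0 <- freq / nyq
  q <- freq / bw
  # standard biquad notch (RBJ cookbook form)
  w <- pi * w0
  alpha <- sin(w) / (2 * q)
  b <- c(1, -2 * cos(w), 1)
  a <- c(1 + alpha, -2 * cos(w), 1 - alpha)
  b <- b / a[1L]; a <- a / a[1L]
  one <- function(x) filtfilt_vec(b, a, x)
  if (is.matrix(data)) {
    out <- t(apply(data, 1L, one))
    dimnames(out) <- dimnames(data)
    out
  } else one(data)
}

#' Restrict a recording to the prefrontal channel set
#'
#' Maps each channel label to `left`, `right` or `drop` and returns the
#' recording restricted to the retained channels, reordered left block first,
#' right block second, preserving the original relative order within each
#' block. Hemisphere counts must be equal.
#'
#' @param recording An [eeg_recording].
#' @param montage_map Data frame with columns `label` and `hemisphere`
#'   (values `left`, `right` or `drop`). Defaults to the recording's own
#'   montage (identity selection).
#' @return An [eeg_recording] with the retained channels.
#' @export
select_prefrontal <- function(recording, montage_map = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(montage_map))
    montage_map <- recording$montage
  if (!all(c("label", "hemisphere") %in% names(montage_map)))
    stop("montage_map needs columns 'label' and 'hemisphere'")
  keep <- montage_map[montage_map$hemisphere %in% c("left", "right"), , drop = FALSE]
  missing <- setdiff(keep$label, recording$montage$label)
  if (length(missing))
    stop("retained labels missing from recording: ", paste(missing, collapse = ", "))
  left <- keep$label[keep$hemisphere == "left"]
  right <- keep$label[keep$hemisphere == "right"]
  if (length(left) != length(right) || length(left) == 0L)
    stop("unequal hemisphere counts: ", length(left), " left vs ",
         length(right), " right")
  # preserve original channel order within each hemisphere block
  ord_left <- recording$montage$label[recording$montage$label %in% left]
  ord_right <- recording$montage$label[recording$montage$label %in% right]
  sel <- c(ord_left, ord_right)
  idx <- match(sel, recording$montage$label)
  recording$data <- recording$data[idx, , drop = FALSE]
  recording$montage <- data.frame(
    label = sel,
    hemisphere = rep(c("left", "right"), c(length(ord_left), length(ord_right))),
    stringsAsFactors = FALSE
  )
  recording
}

#' Split a recording into per-state signal segments
#'
#' @param recording An [eeg_recording] whose schedule lists each state at most
#'   once, with non-overlapping half-open sample intervals.
#' @return Named list, one channels x samples matrix per scheduled state.
#' @export
segment_states <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  sch <- recording$schedule
  if (nrow(sch) == 0L) return(structure(list(), names = character(0)))
  if (anyDuplicated(sch$state))
    stop("schedule lists a state more than once")
  sch <- sch[order(sch$start), , drop = FALSE]
  if (any(sch$end[-nrow(sch)] > sch$start[-1L]))
    stop("overlapping schedule entries")
  if (any(sch$start < 0) || any(sch$end > ncol(recording$data)))
    stop("schedule interval outside recorded data")
  out <- lapply(seq_len(nrow(sch)), function(i)
    recording$data[, (sch$start[i] + 1L):sch$end[i], drop = FALSE])
  names(out) <- sch$state
  out
}

#' Cut a band-filtered state segment into fixed-length epochs
#'
#' The band filter is applied to the whole state segment first, then the
#' result is sliced into consecutive non-overlapping windows; a trailing
#' partial window is discarded. Filtering before slicing avoids per-epoch
#' filter edge artifacts.
#'
#' @param state_data Channels x samples matrix for one state.
#' @param sampling_rate Hz.
#' @param epoch_seconds Window length in seconds (default 10).
#' @param band Band object or name.
#' @param context Named list carrying `subject_id`, `group`, `state` and the
#'   hemisphere index sets `left`, `right` (row indices into `state_data`).
#' @return List of `band_epoch` objects (possibly empty).
#' @export
band_epochs <- function(state_data, sampling_rate, epoch_seconds = 10,
                        band, context = list()) {
  band <- as_band(band)
  if (epoch_seconds <= 0) stop("epoch_seconds must be positive")
  len <- as.integer(round(epoch_seconds * sampling_rate))
  n <- ncol(state_data)
  k <- n %/% len
  if (k == 0L) return(list())
  filtered <- bandpass(state_data, sampling_rate, band)
  lapply(seq_len(k), function(i) {
    structure(list(
      subject_id = context$subject_id %||% NA_character_,
      group = context$group %||% NA_character_,
      state = context$state %||% NA_character_,
      band = band,
      epoch_index = i,
      data = filtered[, ((i - 1L) * len + 1L):(i * len), drop = FALSE],
      sampling_rate = sampling_rate,
      left = context$left %||% seq_len(nrow(state_data) %/% 2L),
      right = context$right %||% (nrow(state_data) %/% 2L + seq_len(nrow(state_data) %/% 2L))
    ), class = "band_epoch")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.band_epoch <- function(x, ...) {
  cat(sprintf("<band_epoch %s/%s/%s band=%s #%d: %d ch x %d samples @ %g Hz>\n",
              x$subject_id, x$group, x$state, x$band$name, x$epoch_index,
              nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}
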