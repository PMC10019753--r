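#' Pearson correlation between two signals
#'
#' Product-moment correlation, the covariance of the two signals normalised by
#' their standard deviations: +1 perfect positive, -1 perfect negative,
#' 0 uncorrelated. Constant input has undefined correlation and yields `NA`
#' with a warning rather than a silent zero.
#'
#' @param x,y Equal-length numeric vectors of at least 2 samples.
#' @return Scalar in `[-1, 1]`, or `NA` for constant input.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 2L) stop("need at least 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# analytic signal via FFT: positive frequencies doubled, negatives zeroed
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# column-wise analytic signal of a samples x channels matrix (single FFT pass)
analytic_signal_mat <- function(xm) {
  n <- nrow(xm)
  X <- stats::mvfft(xm)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a narrowband signal
#'
#' Phase of the analytic signal obtained through the Hilbert transform
#' (FFT construction). Valid for narrowband input; the first and last few
#' percent of samples are distorted by the transform's circular boundary and
#' should be trimmed before averaging -- [plv()] does this internally.
#'
#' @param x Numeric vector, length >= 16, band-limited.
#' @return Phase vector in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(x) {
  if (length(x) < 16L) stop("need at least 16 samples for phase estimation")
  if (all(x == 0)) stop("all-zero input: phase undefined")
  Arg(analytic_signal(x))
}

#' Phase-locking value between two narrowband signals
#'
#' Modulus of the time-averaged unit phasor of the per-sample phase
#' difference: `PLV = |mean(exp(1i * (phi_x - phi_y)))|`. 1 means the phase
#' difference is constant (perfect synchronisation); independent phases give
#' values near `1/sqrt(L)`. Phases are estimated by the Hilbert transform and
#' a fraction of samples is trimmed from each end before averaging to discard
#' the transform's boundary distortion.
#'
#' @param x,y Equal-length narrowband signals in the same band.
#' @param trim Fraction of samples trimmed at each end (default 0.05).
#' @return Scalar in `[0, 1]`.
#' @export
plv <- function(x, y, trim = 0.05) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  px <- instantaneous_phase(x)
  py <- instantaneous_phase(y)
  k <- floor(trim * length(x))
  idx <- (k + 1L):(length(x) - k)
  Mod(mean(exp(1i * (px[idx] - py[idx]))))
}

#' Pairwise connectivity matrix for one band epoch
#'
#' Computes the full symmetric channels x channels matrix of either Pearson
#' correlations or phase-locking values over all pairs. The inter-hemispheric
#' left x right sub-block -- the feature source downstream -- is available via
#' [interhemispheric_block()].
#'
#' @param epoch A `band_epoch` (see [band_epochs()]).
#' @param method `"correlation"` or `"plv"`.
#' @param trim Edge-trim fraction for phase series (PLV only).
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(epoch, method = c("correlation", "plv"),
                                trim = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(epoch, "band_epoch"))
  d <- epoch$data
  sds <- apply(d, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant channel(s) within epoch: ",
         paste(rownames(d)[sds == 0], collapse = ", "))
  if (method == "correlation") {
    m <- stats::cor(t(d))
  } else {
    z <- analytic_signal_mat(t(d))          # samples x channels
    k <- floor(trim * nrow(z))
    z <- z[(k + 1L):(nrow(z) - k), , drop = FALSE]
    u <- exp(1i * Arg(z))
    m <- Mod(t(Conj(u)) %*% u) / nrow(u)
    m <- (m + t(m)) / 2                      # enforce exact symmetry
    diag(m) <- 1
  }
  dimnames(m) <- list(rownames(d), rownames(d))
  structure(list(
    method = method,
    band = epoch$band$name,
    state = epoch$state,
    subject_id = epoch$subject_id,
    group = epoch$group,
    epoch_index = epoch$epoch_index,
    matrix = m,
    left = epoch$left,
    right = epoch$right,
    n_samples = if (method == "plv") nrow(u) else ncol(d)
  ), class = "connectivity_matrix")
}

#' Inter-hemispheric block of a connectivity matrix
#'
#' @param cm A `connectivity_matrix`.
#' @return The left x right rectangular sub-matrix (10 x 10 in the default
#'   montage), i.e. connectivity of every cross-hemisphere channel pair.
#' @export
interhemispheric_block <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  cm$matrix[cm$left, cm$right, drop = FALSE]
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix %s (%s band, %s) %dx%d subject=%s epoch=%d>\n",
              x$method, x$band, x$state, nrow(x$matrix), ncol(x$matrix),
              x$subject_id, x$epoch_index))
  cat(sprintf("  inter-hemispheric mean: %.4f\n",
              mean(interhemispheric_block(x))))
  invisible(x)
}

#' Write a connectivity matrix to CSV with a JSON metadata sidecar
#'
#' @param cm A `connectivity_matrix`.
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.csv(cm$matrix, path)
  meta <- cm[c("method", "band", "state", "subject_id", "group",
               "epoch_index", "n_samples")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
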