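#' Canonical EEG frequency bands
#'
#' The four bands used throughout the pipeline: delta (0.3--4 Hz), theta
#' (4--8 Hz), alpha (8--12 Hz) and beta (12--30 Hz). The delta band starts at
#' 0.3 Hz rather than DC so that the band-pass filter has a proper high-pass
#' edge.
#'
#' @return Named list of band objects (see [band()]).
#' @export
#' @examples
#' eeg_bands()$alpha
eeg_bands <- function() {
  list(
    delta = band("delta", 0.3, 4),
    theta = band("theta", 4, 8),
    alpha = band("alpha", 8, 12),
    beta  = band("beta", 12, 30)
  )
}

#' Define a frequency band
#'
#' @param name Band label.
#' @param low Lower edge in Hz, must satisfy `0 <= low < high`.
#' @param high Upper edge in Hz.
#' @return An object of class `"eeg_band"`.
#' @export
band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || low >= high)
    stop("band edges must satisfy 0 <= low < high, got [", low, ", ", high, "]")
  structure(list(name = name, low = low, high = high), class = "eeg_band")
}

#' @export
print.eeg_band <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$low, x$high))
  invisible(x)
}

band_names <- function(bands) vapply(bands, `[[`, "", "name")

# resolve a band given either an eeg_band or a name from eeg_bands()
as_band <- function(band) {
  if (inherits(band, "eeg_band")) return(band)
  if (is.character(band) && length(band) == 1L) {
    b <- eeg_bands()[[band]]
    if (is.null(b)) stop("unknown band name: ", band)
    return(b)
  }
  stop("'band' must be an eeg_band object or one of ",
       paste(names(eeg_bands()), collapse = ", "))
}
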