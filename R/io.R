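SIDECAR_SCHEMA_VERSION <- "1.0"

#' Write a recording as CSV plus a JSON sidecar
#'
#' The signal goes to `<basename>.csv` (channels x samples, one row per
#' channel, label in the first column); montage, sampling rate, group label
#' and state schedule go to `<basename>.json`. The sidecar schema is
#' versioned.
#'
#' @param recording An `eeg_recording`.
#' @param basename Output path without extension.
#' @return `basename`, invisibly.
#' @export
write_recording <- function(recording, basename) {
  stopifnot(inherits(recording, "eeg_recording"))
  d <- data.frame(label = rownames(recording$data), recording$data,
                  stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(d, paste0(basename, ".csv"), row.names = FALSE)
  meta <- list(
    schema_version = SIDECAR_SCHEMA_VERSION,
    subject_id = recording$subject_id,
    group = recording$group,
    sampling_rate = recording$sampling_rate,
    montage = recording$montage,
    schedule = recording$schedule
  )
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(basename)
}

#' Read a recording written by [write_recording()]
#'
#' @param basename Path without extension (expects `.csv` and `.json`).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  if (is.null(meta$schema_version))
    stop("sidecar lacks schema_version: not a recording sidecar?")
  d <- utils::read.csv(paste0(basename, ".csv"), check.names = FALSE)
  data <- as.matrix(d[, -1L, drop = FALSE])
  rownames(data) <- d$label
  colnames(data) <- NULL
  structure(list(
    subject_id = meta$subject_id,
    group = meta$group,
    montage = as.data.frame(meta$montage, stringsAsFactors = FALSE),
    sampling_rate = meta$sampling_rate,
    data = data,
    schedule = as.data.frame(meta$schedule, stringsAsFactors = FALSE)
  ), class = "eeg_recording")
}

#' Read a montage map from a two-column CSV
#'
#' @param path CSV with columns `label` and `hemisphere`
#'   (`left`/`right`/`drop`).
#' @return Data frame usable as `montage_map` in [select_prefrontal()].
#' @export
read_montage_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "hemisphere") %in% names(m)))
    stop("montage map CSV needs columns 'label' and 'hemisphere'")
  bad <- setdiff(unique(m$hemisphere), c("left", "right", "drop"))
  if (length(bad))
    stop("invalid hemisphere value(s): ", paste(bad, collapse = ", "))
  m
}
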