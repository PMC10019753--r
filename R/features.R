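#' Summarise one epoch's connectivity into the four scalar features
#'
#' `r` and `plv` are the means over the 10 x 10 inter-hemispheric block of the
#' correlation and PLV matrices; `cc` is the mean weighted clustering
#' coefficient and `sp` the characteristic path length of the connectivity
#' graph.
#'
#' @param cm_r Correlation `connectivity_matrix`.
#' @param cm_plv PLV `connectivity_matrix`.
#' @param gm `graph_metrics` for the same epoch.
#' @return Named numeric vector `c(r, plv, cc, sp)`.
#' @export
summarize_epoch <- function(cm_r, cm_plv, gm) {
  stopifnot(inherits(cm_r, "connectivity_matrix"),
            inherits(cm_plv, "connectivity_matrix"),
            inherits(gm, "graph_metrics"))
  keys <- c("subject_id", "state", "band", "epoch_index")
  if (!identical(cm_r[keys], cm_plv[keys]))
    stop("correlation and PLV matrices refer to different epochs")
  c(r = mean(interhemispheric_block(cm_r)),
    plv = mean(interhemispheric_block(cm_plv)),
    cc = gm$mean_cc,
    sp = gm$char_path_length)
}

#' Epoch-level connectivity features for a whole cohort
#'
#' Runs the full feature pipeline on every recording: state segmentation,
#' band-pass decomposition, epoching, correlation and PLV matrices, and graph
#' metrics on the connectivity graph. This long table feeds both
#' [build_feature_table()] (classification) and [comparison_grid()]
#' (group statistics).
#'
#' @param cohort List of `eeg_recording` objects.
#' @param bands Bands to analyse (default the four canonical bands).
#' @param epoch_seconds Epoch window length in seconds (default 10).
#' @param graph_from Which connectivity matrix the graph metrics use:
#'   `"plv"` (default; weights natively in `[0, 1]`) or `"correlation"`.
#' @param q Proportional edge threshold for [to_weighted_graph()] (default 1).
#' @param dist_transform Passed to [shortest_paths()].
#' @return Data frame with one row per (subject, state, band, epoch) and
#'   columns `subject_id`, `group`, `state`, `band`, `epoch_index`,
#'   `r`, `plv`, `cc`, `sp`.
#' @export
cohort_features <- function(cohort, bands = eeg_bands(), epoch_seconds = 10,
                            graph_from = c("plv", "correlation"), q = 1,
                            dist_transform = "inverse") {
  graph_from <- match.arg(graph_from)
  rows <- list()
  for (rec in cohort) {
    stopifnot(inherits(rec, "eeg_recording"))
    left <- which(rec$montage$hemisphere == "left")
    right <- which(rec$montage$hemisphere == "right")
    segs <- segment_states(rec)
    for (st in names(segs)) {
      ctx <- list(subject_id = rec$subject_id, group = rec$group,
                  state = st, left = left, right = right)
      for (b in bands) {
        eps <- band_epochs(segs[[st]], rec$sampling_rate, epoch_seconds, b, ctx)
        for (ep in eps) {
          cm_r <- connectivity_matrix(ep, "correlation")
          cm_plv <- connectivity_matrix(ep, "plv")
          gsrc <- if (graph_from == "plv") cm_plv else cm_r
          gm <- graph_metrics(to_weighted_graph(gsrc, q = q), dist_transform)
          feats <- summarize_epoch(cm_r, cm_plv, gm)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = rec$subject_id, group = rec$group, state = st,
            band = b$name, epoch_index = ep$epoch_index,
            r = feats[["r"]], plv = feats[["plv"]],
            cc = feats[["cc"]], sp = feats[["sp"]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) stop("cohort produced no epochs")
  do.call(rbind, rows)
}

measure_names <- c("r", "plv", "cc", "sp")

#' Assemble a classification feature table
#'
#' Two layouts mirror the two classification designs. `statewise` fixes a
#' state and spreads the four measures across the four bands (16 columns,
#' e.g. `r_delta ... sp_beta`); `bandwise` fixes a band and spreads the four
#' measures across the four states (16 columns, e.g. `r_baseline ...
#' sp_post`), pairing epochs across states by epoch index truncated to the
#' shortest state. One row per (subject, epoch); missing feature cells are an
#' error, never silently imputed.
#'
#' @param feats Long feature table from [cohort_features()].
#' @param layout `"statewise"` or `"bandwise"`.
#' @param fixed_factor The state (statewise) or band (bandwise) conditioned on.
#' @return A `feature_table` data frame: `subject_id`, `group`,
#'   `epoch_index`, then 16 feature columns.
#' @export
build_feature_table <- function(feats, layout = c("statewise", "bandwise"),
                                fixed_factor) {
  layout <- match.arg(layout)
  if (layout == "statewise") {
    sub <- feats[feats$state == fixed_factor, , drop = FALSE]
    if (!nrow(sub)) stop("no epochs for state ", fixed_factor)
    varying <- sort(unique(sub$band))
    sub$vary <- sub$band
  } else {
    sub <- feats[feats$band == fixed_factor, , drop = FALSE]
    if (!nrow(sub)) stop("no epochs for band ", fixed_factor)
    varying <- unique(feats$state)
    sub$vary <- sub$state
    # pair epochs across states: truncate each subject to its shortest state
    keep <- unlist(lapply(split(sub, sub$subject_id), function(d) {
      counts <- tapply(d$epoch_index, d$vary, max)
      if (length(counts) < length(varying))
        stop("subject ", d$subject_id[1L], " lacks state(s): ",
             paste(setdiff(varying, names(counts)), collapse = ", "))
      rownames(d)[d$epoch_index <= min(counts)]
    }))
    sub <- sub[rownames(sub) %in% keep, , drop = FALSE]
  }
  wide <- NULL
  for (m in measure_names) {
    w <- stats::reshape(
      sub[, c("subject_id", "group", "epoch_index", "vary", m)],
      direction = "wide", idvar = c("subject_id", "group", "epoch_index"),
      timevar = "vary", v.names = m)
    names(w) <- sub("^(r|plv|cc|sp)\\.", "\\1_", names(w))
    wide <- if (is.null(wide)) w else merge(wide, w,
      by = c("subject_id", "group", "epoch_index"))
  }
  featcols <- setdiff(names(wide), c("subject_id", "group", "epoch_index"))
  expect <- as.vector(outer(measure_names, varying, paste, sep = "_"))
  missing_cols <- setdiff(expect, featcols)
  if (length(missing_cols))
    stop("incomplete feature set, missing: ", paste(missing_cols, collapse = ", "))
  bad <- which(is.na(wide[expect]), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing feature cells: ",
         paste(sprintf("(%s, epoch %d, %s)", wide$subject_id[bad[, 1L]],
                       wide$epoch_index[bad[, 1L]], expect[bad[, 2L]]),
               collapse = "; "))
  wide <- wide[order(wide$subject_id, wide$epoch_index),
               c("subject_id", "group", "epoch_index", expect)]
  rownames(wide) <- NULL
  structure(wide, layout = layout, fixed_factor = fixed_factor,
            class = c("feature_table", "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table %s/%s: %d samples x %d features, groups: %s>\n",
              attr(x, "layout"), attr(x, "fixed_factor"), nrow(x),
              ncol(x) - 3L,
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = " ")))
  NextMethod()
}
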