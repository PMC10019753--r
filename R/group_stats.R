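#' Significance stars from a p-value
#'
#' Conventional thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p p-value in `[0, 1]`.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
p_to_star <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Between-group comparison of one connectivity feature
#'
#' Compares two groups on one (measure, band, state) cell. Epoch values are
#' first averaged within subject -- the subject, not the epoch, is the
#' sampling unit, so epoch-level testing would pseudo-replicate. The default
#' test is Welch's two-sample t-test on the subject means.
#'
#' @param feats Long feature table from [cohort_features()].
#' @param measure One of `"r"`, `"plv"`, `"cc"`, `"sp"`.
#' @param band Band name.
#' @param state State name.
#' @param pair Two group labels, e.g. `c("LTM", "NM")`.
#' @param method `"welch"` (default) or `"student"` (pooled variance).
#' @return A `group_comparison`: group means/SDs/ns on subject-level values,
#'   the p-value and its significance star.
#' @export
compare_groups <- function(feats, measure, band, state, pair,
                           method = c("welch", "student")) {
  method <- match.arg(method)
  stopifnot(measure %in% measure_names)
  pair <- parse_comparison(pair)
  sub <- feats[feats$band == band & feats$state == state &
                 feats$group %in% pair, , drop = FALSE]
  if (!nrow(sub)) stop("no data for (", measure, ", ", band, ", ", state, ")")
  subj <- stats::aggregate(sub[[measure]],
                           by = list(subject_id = sub$subject_id,
                                     group = sub$group), FUN = mean)
  ns <- table(factor(subj$group, levels = pair))
  if (any(ns < 2L))
    stop("group(s) with fewer than 2 subjects: ",
         paste(names(ns)[ns < 2L], collapse = ", "))
  vals <- split(subj$x, factor(subj$group, levels = pair))
  tt <- stats::t.test(vals[[1L]], vals[[2L]], var.equal = method == "student")
  structure(list(
    measure = measure, band = band, state = state,
    groups = pair,
    group_means = vapply(vals, mean, 0),
    group_sds = vapply(vals, stats::sd, 0),
    n = as.integer(ns),
    p_value = tt$p.value,
    star = p_to_star(tt$p.value)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s | %s band | %s: %s %.4f (sd %.4f, n=%d) vs %s %.4f (sd %.4f, n=%d), p=%.4g %s>\n",
              x$measure, x$band, x$state,
              x$groups[1L], x$group_means[1L], x$group_sds[1L], x$n[1L],
              x$groups[2L], x$group_means[2L], x$group_sds[2L], x$n[2L],
              x$p_value, x$star))
  invisible(x)
}

#' Full grid of between-group comparisons
#'
#' Tabular twin of the bar-chart panels: every (measure, band, state) cell for
#' every group pair (LTM vs NM, STM vs NM, LTM vs STM). With four bands and
#' four states this is 4 x 4 x 4 x 3 = 192 rows. No multiple-testing
#' correction is applied by default (stars are per-cell);
#' `adjust = "BH"` adds Benjamini-Hochberg adjusted p-values and stars.
#'
#' @param feats Long feature table from [cohort_features()].
#' @param pairs List of group pairs to compare.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param method Passed to [compare_groups()].
#' @return Data frame, one row per (measure, band, state, pair).
#' @export
comparison_grid <- function(feats,
                            pairs = list(c("LTM", "NM"), c("STM", "NM"),
                                         c("LTM", "STM")),
                            adjust = c("none", "BH"),
                            method = "welch") {
  adjust <- match.arg(adjust)
  if (!nrow(feats)) stop("empty cohort features")
  bands <- unique(feats$band)
  states <- unique(feats$state)
  need <- unique(unlist(pairs))
  missing_g <- setdiff(need, unique(feats$group))
  if (length(missing_g))
    stop("missing group(s): ", paste(missing_g, collapse = ", "))
  out <- list()
  for (m in measure_names) for (b in bands) for (s in states) for (p in pairs) {
    gc <- compare_groups(feats, m, b, s, p, method = method)
    out[[length(out) + 1L]] <- data.frame(
      measure = m, band = b, state = s,
      pair = paste(p, collapse = " vs "),
      mean_1 = gc$group_means[1L], mean_2 = gc$group_means[2L],
      sd_1 = gc$group_sds[1L], sd_2 = gc$group_sds[2L],
      n_1 = gc$n[1L], n_2 = gc$n[2L],
      p_value = gc$p_value, star = gc$star,
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  if (adjust == "BH") {
    grid$p_adjusted <- stats::p.adjust(grid$p_value, method = "BH")
    grid$star_adjusted <- vapply(grid$p_adjusted, p_to_star, "")
  }
  grid
}

#' Bar chart of group means for one measure
#'
#' Base-graphics rendering in the style of grouped bar panels: group means of
#' a connectivity measure per band, grouped by state, with SD whiskers.
#'
#' @param feats Long feature table from [cohort_features()].
#' @param measure One of `"r"`, `"plv"`, `"cc"`, `"sp"`.
#' @param groups Groups to display.
#' @return Invisibly, the matrix of plotted means.
#' @export
plot_group_means <- function(feats, measure = "plv",
                             groups = c("LTM", "STM", "NM")) {
  stopifnot(measure %in% measure_names)
  subj <- stats::aggregate(feats[[measure]],
                           by = list(group = feats$group, band = feats$band,
                                     state = feats$state,
                                     subject_id = feats$subject_id),
                           FUN = mean)
  agg <- stats::aggregate(subj$x,
                          by = list(group = subj$group, band = subj$band,
                                    state = subj$state), FUN = mean)
  states <- unique(feats$state)
  bands <- unique(feats$band)
  old <- graphics::par(mfrow = c(1, length(states)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  res <- list()
  for (s in states) {
    m <- sapply(bands, function(b)
      sapply(groups, function(g)
        agg$x[agg$group == g & agg$band == b & agg$state == s]))
    graphics::barplot(m, beside = TRUE, names.arg = bands,
                      legend.text = if (s == states[1L]) groups else NULL,
                      main = s, ylab = sprintf("mean %s", measure))
    res[[s]] <- m
  }
  invisible(res)
}
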