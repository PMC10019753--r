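classifier_names <- c("DT", "LDA", "LR", "SVM", "KNN", "Ensemble")

# fit one classifier on standardized training features and predict test labels.
# Hyperparameters are fixed: DT = rpart defaults; SVM = RBF kernel, cost 1,
# gamma 1/p; KNN k = 5; Ensemble = 100-tree bagging (random forest, mtry = p).
fit_predict <- function(classifier, xtr, ytr, xte) {
  p <- ncol(xtr)
  switch(classifier,
    DT = {
      d <- data.frame(y = ytr, xtr)
      fit <- rpart::rpart(y ~ ., data = d, method = "class")
      stats::predict(fit, data.frame(xte), type = "class")
    },
    LDA = {
      fit <- MASS::lda(xtr, grouping = ytr)
      stats::predict(fit, xte)$class
    },
    LR = {
      d <- data.frame(y = ytr, xtr)
      fit <- suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
      pr <- suppressWarnings(stats::predict(fit, data.frame(xte), type = "response"))
      factor(levels(ytr)[1L + (pr > 0.5)], levels = levels(ytr))
    },
    SVM = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1,
                        gamma = 1 / p, scale = FALSE)
      stats::predict(fit, xte)
    },
    KNN = class::knn(xtr, xte, cl = ytr, k = 5L),
    Ensemble = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 100L, mtry = p)
      stats::predict(fit, xte)
    },
    stop("unknown classifier: ", classifier)
  )
}

# deal units (subjects or rows) into k folds, stratified by class:
# within each class, shuffle then assign round-robin, so fold sizes differ
# by at most one per class.
make_folds <- function(units, classes, k) {
  fold <- integer(length(units))
  names(fold) <- units
  for (cl in unique(classes)) {
    u <- sample(units[classes == cl])
    fold[u] <- (seq_along(u) - 1L) %% k + 1L
  }
  fold
}

parse_comparison <- function(comparison) {
  if (is.character(comparison) && length(comparison) == 1L)
    comparison <- strsplit(comparison, "\\s+vs\\s+")[[1L]]
  if (length(comparison) != 2L)
    stop("comparison must name two groups, e.g. \"LTM vs NM\"")
  comparison
}

#' Cross-validated classification of two meditator groups
#'
#' 10-fold stratified cross-validation of one classifier on a feature table.
#' Folds are assigned at the subject level by default, so all epochs of a
#' subject land in the same fold and no subject appears in both training and
#' test data. Features are standardized per fold using training-fold mean and
#' SD only. With fewer than 10 subjects in total, folds fall back to the
#' epoch level with a leakage warning.
#'
#' @param table A [build_feature_table()] output.
#' @param comparison Two group labels, e.g. `"LTM vs NM"` or `c("LTM", "NM")`.
#' @param classifier One of `"DT"`, `"LDA"`, `"LR"`, `"SVM"`, `"KNN"`,
#'   `"Ensemble"`.
#' @param seed RNG seed controlling the fold assignment.
#' @param k Number of folds (default 10).
#' @param grouping `"subject"` (default) or `"epoch"` fold granularity.
#' @return A `cv_result`: fold accuracies, their mean, the pooled 2 x 2
#'   confusion matrix, the per-sample fold assignment and predictions, and the
#'   run metadata.
#' @export
crossvalidate <- function(table, comparison, classifier, seed = 1L,
                          k = 10L, grouping = c("subject", "epoch")) {
  grouping <- match.arg(grouping)
  ci <- match(toupper(classifier), toupper(classifier_names))
  if (is.na(ci)) stop("unknown classifier: ", classifier)
  classifier <- classifier_names[ci]
  comparison <- parse_comparison(comparison)
  missing_g <- setdiff(comparison, unique(table$group))
  if (length(missing_g))
    stop("group(s) absent from table: ", paste(missing_g, collapse = ", "))
  d <- table[table$group %in% comparison, , drop = FALSE]
  y <- factor(d$group, levels = comparison)
  if (any(tabulate(y, 2L) < k))
    stop("need at least ", k, " samples per class")
  featcols <- setdiff(names(d), c("subject_id", "group", "epoch_index"))
  x <- as.matrix(d[featcols])

  set.seed(as.integer(seed %% .Machine$integer.max))
  if (grouping == "subject") {
    subj <- unique(d$subject_id)
    if (length(subj) < k) {
      warning("fewer than ", k, " subjects: falling back to epoch-level ",
              "folds; training and test epochs may share subjects (leakage)")
      grouping <- "epoch"
    }
  }
  if (grouping == "subject") {
    sgroup <- d$group[match(subj, d$subject_id)]
    sfold <- make_folds(subj, sgroup, k)
    fold <- sfold[d$subject_id]
  } else {
    fold <- make_folds(as.character(seq_len(nrow(d))), as.character(y), k)
  }

  acc <- numeric(k)
  conf <- matrix(0L, 2L, 2L, dimnames = list(truth = comparison,
                                             predicted = comparison))
  predictions <- factor(rep(NA_character_, nrow(d)), levels = comparison)
  for (f in seq_len(k)) {
    te <- fold == f
    if (!any(te)) { acc[f] <- NA_real_; next }
    mu <- colMeans(x[!te, , drop = FALSE])
    sdv <- apply(x[!te, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(x[!te, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    pred <- fit_predict(classifier, xtr, y[!te], xte)
    predictions[te] <- as.character(pred)
    acc[f] <- mean(pred == y[te])
    conf <- conf + table(factor(y[te], comparison), factor(pred, comparison))
  }
  structure(list(
    comparison = paste(comparison, collapse = " vs "),
    layout = attr(table, "layout"),
    fixed_factor = attr(table, "fixed_factor"),
    classifier = classifier,
    grouping = grouping,
    fold_accuracies = acc,
    mean_accuracy = mean(acc, na.rm = TRUE),
    confusion_matrix = conf,
    fold_of_sample = unname(fold),
    sample_ids = d$subject_id,
    predictions = predictions,
    seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s | %s/%s | %s (%s-level folds): mean accuracy %.3f>\n",
              x$comparison, x$layout, x$fixed_factor, x$classifier,
              x$grouping, x$mean_accuracy))
  invisible(x)
}

#' Sensitivity and specificity from a cross-validation result
#'
#' Supplementary to the headline accuracy: the first comparison group is
#' treated as the positive class.
#'
#' @param x A `cv_result`.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
cv_sensitivity_specificity <- function(x) {
  stopifnot(inherits(x, "cv_result"))
  cm <- x$confusion_matrix
  c(sensitivity = cm[1L, 1L] / sum(cm[1L, ]),
    specificity = cm[2L, 2L] / sum(cm[2L, ]))
}

#' Full state-wise and band-wise classifier comparison
#'
#' Runs the whole classification design: for each comparison (LTM vs NM,
#' STM vs NM), each state-wise table (default: baseline, meditation,
#' transmission) and each band-wise table (all four bands), all six classifier
#' families under 10-fold cross-validation. Default dimensions give
#' 2 x (3 + 4) x 6 = 84 rows.
#'
#' @param feats Long feature table from [cohort_features()].
#' @param seed RNG seed for fold assignment.
#' @param states States used for state-wise tables.
#' @param bands Band names for band-wise tables.
#' @param classifiers Classifier subset (default all six).
#' @param comparisons List of group pairs.
#' @param ... Passed to [crossvalidate()].
#' @return Tidy data frame: `comparison`, `layout`, `fixed_factor`,
#'   `classifier`, `mean_accuracy`, `sd_accuracy`, `n_samples`.
#' @export
run_full_comparison <- function(feats, seed = 1L,
                                states = c("baseline", "meditation", "transmission"),
                                bands = names(eeg_bands()),
                                classifiers = classifier_names,
                                comparisons = list(c("LTM", "NM"), c("STM", "NM")),
                                ...) {
  need <- unique(unlist(comparisons))
  missing_g <- setdiff(need, unique(feats$group))
  if (length(missing_g))
    stop("cohort lacks group(s): ", paste(missing_g, collapse = ", "))
  grid <- rbind(
    data.frame(layout = "statewise", fixed_factor = states,
               stringsAsFactors = FALSE),
    data.frame(layout = "bandwise", fixed_factor = bands,
               stringsAsFactors = FALSE)
  )
  out <- list()
  for (cmp in comparisons) for (gi in seq_len(nrow(grid))) {
    tab <- build_feature_table(feats, grid$layout[gi], grid$fixed_factor[gi])
    for (cl in classifiers) {
      res <- crossvalidate(tab, cmp, cl, seed = seed, ...)
      out[[length(out) + 1L]] <- data.frame(
        comparison = res$comparison, layout = res$layout,
        fixed_factor = res$fixed_factor, classifier = cl,
        mean_accuracy = res$mean_accuracy,
        sd_accuracy = stats::sd(res$fold_accuracies, na.rm = TRUE),
        n_samples = sum(res$confusion_matrix),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
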