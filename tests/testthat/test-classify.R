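test_that("cross-validation partitions samples once each, at the subject level", {
  feats <- fake_feats(n_subj = c(LTM = 12, NM = 10), n_epochs = 4, effect = 2)
  tab <- build_feature_table(feats, "statewise", "meditation")
  res <- crossvalidate(tab, "LTM vs NM", "KNN", seed = 3)
  expect_s3_class(res, "cv_result")
  expect_length(res$fold_accuracies, 10L)
  expect_equal(res$mean_accuracy, mean(res$fold_accuracies, na.rm = TRUE))
  # every sample tested exactly once: confusion totals = n
  expect_equal(sum(res$confusion_matrix), nrow(tab))
  expect_equal(res$grouping, "subject")
})

test_that("subject-level folds keep all epochs of a subject together", {
  feats <- fake_feats(n_subj = c(LTM = 12, NM = 10), n_epochs = 4, effect = 2)
  tab <- build_feature_table(feats, "statewise", "meditation")
  res <- crossvalidate(tab, "LTM vs NM", "DT", seed = 5)
  folds <- res$fold_of_sample
  expect_length(folds, nrow(tab))
  per_subject <- tapply(folds, tab$subject_id[tab$group %in% c("LTM", "NM")],
                        function(f) length(unique(f)))
  expect_true(all(per_subject == 1L))
  # subject-level fold sizes differ by at most one within each class
  sub_fold <- tapply(folds, tab$subject_id, unique)
  sub_group <- tab$group[match(names(sub_fold), tab$subject_id)]
  for (g in c("LTM", "NM")) {
    sizes <- table(factor(unlist(sub_fold[sub_group == g]), levels = 1:10))
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("cross-validation is deterministic given the seed", {
  feats <- fake_feats(n_subj = c(LTM = 11, NM = 10), n_epochs = 3, effect = 1)
  tab <- build_feature_table(feats, "statewise", "meditation")
  a <- crossvalidate(tab, "LTM vs NM", "Ensemble", seed = 9)
  b <- crossvalidate(tab, "LTM vs NM", "Ensemble", seed = 9)
  expect_identical(a$fold_accuracies, b$fold_accuracies)
  expect_identical(a$confusion_matrix, b$confusion_matrix)
})

test_that("few subjects trigger the epoch-level fallback with a leakage warning", {
  feats <- fake_feats(n_subj = c(LTM = 4, NM = 4), n_epochs = 5, effect = 2)
  tab <- build_feature_table(feats, "statewise", "meditation")
  expect_warning(res <- crossvalidate(tab, "LTM vs NM", "KNN", seed = 1),
                 "leakage")
  expect_equal(res$grouping, "epoch")
  expect_equal(sum(res$confusion_matrix), nrow(tab))
})

test_that("separated groups classify nearly perfectly; duplication does not hurt", {
  feats <- fake_feats(n_subj = c(LTM = 10, NM = 10), n_epochs = 4, effect = 4)
  tab <- build_feature_table(feats, "statewise", "meditation")
  res <- crossvalidate(tab, "LTM vs NM", "SVM", seed = 2)
  expect_gt(res$mean_accuracy, 0.9)

  dup <- rbind(tab, tab)
  attributes(dup)[c("layout", "fixed_factor")] <-
    attributes(tab)[c("layout", "fixed_factor")]
  class(dup) <- class(tab)
  res_dup <- suppressWarnings(
    crossvalidate(dup, "LTM vs NM", "SVM", seed = 2, grouping = "epoch"))
  expect_gte(res_dup$mean_accuracy, res$mean_accuracy - 0.05)
})

test_that("classifier arguments are validated", {
  feats <- fake_feats(n_subj = c(LTM = 10, NM = 10), n_epochs = 2)
  tab <- build_feature_table(feats, "statewise", "meditation")
  expect_error(crossvalidate(tab, "LTM vs NM", "MLP", seed = 1),
               "unknown classifier")
  expect_error(crossvalidate(tab, "LTM vs STM", "KNN", seed = 1),
               "absent from table")
  few <- tab[tab$epoch_index == 1 & !duplicated(tab$subject_id), ]
  attributes(few)[c("layout", "fixed_factor")] <-
    attributes(tab)[c("layout", "fixed_factor")]
  class(few) <- class(tab)
  expect_error(suppressWarnings(crossvalidate(few[1:12, ], "LTM vs NM", "KNN")),
               "samples per class")
})

test_that("the full comparison emits the 2 x (3 + 4) x 6 grid", {
  feats <- cached_feats()
  grid <- suppressWarnings(run_full_comparison(feats, seed = 4))
  expect_equal(nrow(grid), 2 * (3 + 4) * 6)
  expect_setequal(unique(grid$comparison), c("LTM vs NM", "STM vs NM"))
  expect_setequal(unique(grid$classifier),
                  c("DT", "LDA", "LR", "SVM", "KNN", "Ensemble"))
  expect_setequal(unique(grid$fixed_factor[grid$layout == "statewise"]),
                  c("baseline", "meditation", "transmission"))
  expect_setequal(unique(grid$fixed_factor[grid$layout == "bandwise"]),
                  c("delta", "theta", "alpha", "beta"))
  expect_true(all(grid$mean_accuracy >= 0 & grid$mean_accuracy <= 1))

  grid2 <- suppressWarnings(run_full_comparison(feats, seed = 4))
  expect_identical(grid$mean_accuracy, grid2$mean_accuracy)

  no_stm <- feats[feats$group != "STM", ]
  expect_error(run_full_comparison(no_stm, seed = 4), "STM")
})

test_that("standardization is fit on training folds only (deliberate-leak regression)", {
  # Corrupt one subject with a gigantic offset. In that subject's own test
  # fold the training data are unchanged, so with train-only standardization
  # the fitted model and the scaler are identical -- predictions for the OTHER
  # subjects sharing that fold must not move. Leaky (test-inclusive)
  # standardization would rescale the whole fold and change them.
  feats <- fake_feats(n_subj = c(LTM = 10, NM = 10), n_epochs = 3, effect = 1)
  tab <- build_feature_table(feats, "statewise", "meditation")
  tab2 <- tab
  i <- which(tab2$subject_id == "LTM_01")
  tab2$r_alpha[i] <- tab2$r_alpha[i] + 1e6
  a <- crossvalidate(tab, "LTM vs NM", "KNN", seed = 6)
  b <- crossvalidate(tab2, "LTM vs NM", "KNN", seed = 6)
  expect_identical(a$fold_of_sample, b$fold_of_sample)
  f1 <- a$fold_of_sample[match("LTM_01", a$sample_ids)]
  cofold <- a$fold_of_sample == f1 & a$sample_ids != "LTM_01"
  expect_true(any(cofold))
  expect_identical(a$predictions[cofold], b$predictions[cofold])
})

test_that("sensitivity and specificity derive from the confusion matrix", {
  feats <- fake_feats(n_subj = c(LTM = 10, NM = 10), n_epochs = 3, effect = 3)
  tab <- build_feature_table(feats, "statewise", "meditation")
  res <- crossvalidate(tab, "LTM vs NM", "LDA", seed = 8)
  ss <- cv_sensitivity_specificity(res)
  cm <- res$confusion_matrix
  expect_equal(ss[["sensitivity"]], cm[1, 1] / sum(cm[1, ]))
  expect_equal(ss[["specificity"]], cm[2, 2] / sum(cm[2, ]))
})
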