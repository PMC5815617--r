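test_that("confusion matrices conserve counts and accuracy identities", {
  truth <- rep(terrain_levels(), each = 10)
  cm <- confusion_matrix(truth, truth)
  expect_equal(diag(unclass(cm)), c(eversion = 10, flush = 10,
                                    inversion = 10))
  expect_equal(accuracy_report(cm)$overall, 1)

  all_flush <- rep("flush", 30)
  cm2 <- confusion_matrix(truth, all_flush)
  expect_equal(sum(unclass(cm2)[, "flush"]), 30)
  rep2 <- accuracy_report(cm2)
  expect_equal(rep2$overall, 10 / 30)
  expect_equal(rep2$error, 20 / 30)
  expect_equal(unname(rowSums(unclass(cm2))), c(10, 10, 10))

  # permutation invariance of paired labels
  set.seed(3)
  pred <- sample(terrain_levels(), 30, replace = TRUE)
  perm <- sample(30)
  expect_equal(unclass(confusion_matrix(truth, pred)),
               unclass(confusion_matrix(truth[perm], pred[perm])))
  expect_error(confusion_matrix(truth, pred[-1]), "length")
})

test_that("per-class range brackets overall accuracy for balanced classes", {
  set.seed(21)
  truth <- rep(terrain_levels(), each = 40)
  pred <- ifelse(runif(120) < 0.7, truth,
                 sample(terrain_levels(), 120, replace = TRUE))
  rep <- accuracy_report(confusion_matrix(truth, pred))
  expect_gte(rep$overall, rep$per_class_range[["min"]])
  expect_lte(rep$overall, rep$per_class_range[["max"]])
  expect_equal(rep$overall, sum(diag(unclass(confusion_matrix(truth, pred)))) /
                 120)
})

test_that("trial-level LOOCV separates a large-margin synthetic benchmark", {
  cfg <- preset_single_signal(seed = 31, n_subjects = 3, trials_per_class = 3)
  fm <- build_feature_matrix(generate_dataset(cfg), cfg$inventory)
  res <- loocv(fm)
  expect_gte(res$report$overall, 0.95)
  expect_equal(res$report$n, nrow(fm$values))
  expect_equal(sum(unclass(res$confusion)), nrow(fm$values))
  # no held-out window is predicted by a model trained on its own trial
  expect_equal(sort(res$predictions$row), seq_len(nrow(fm$values)))
})

test_that("label permutation drops LOOCV to the chance band", {
  cfg <- preset_single_signal(seed = 32, n_subjects = 3, trials_per_class = 3)
  fm <- build_feature_matrix(generate_dataset(cfg), cfg$inventory)
  set.seed(320)
  ids <- unique(fm$info$trial_id)
  lab <- vapply(ids, function(i) fm$info$label[fm$info$trial_id == i][1], "")
  perm <- setNames(sample(lab), ids)
  fm$info$label <- unname(perm[fm$info$trial_id])
  acc <- loocv(fm)$report$overall
  # 99% binomial band around 1/3 at trial granularity (windows within a
  # trial are correlated, so n = number of trials)
  half <- stats::qnorm(0.995) * sqrt((1 / 3) * (2 / 3) / length(ids))
  expect_gt(acc, 1 / 3 - half)
  expect_lt(acc, 1 / 3 + half)
})

test_that("resubstitution is at least as accurate as LOOCV", {
  worse <- 0L
  for (s in 1:8) {
    cfg <- synthetic_config(inventory = signal_inventory("ips_only"),
                            class_effects = list(
                              ips_ml_acc = c(eversion = -1, inversion = 1)),
                            n_subjects = 2, trials_per_class = 2,
                            seed = 100 + s)
    fm <- build_feature_matrix(generate_dataset(cfg), cfg$inventory)
    resub <- evaluate_on_test(fm, fm)$report$overall
    cv <- loocv(fm)$report$overall
    if (resub < cv) worse <- worse + 1L
  }
  # the optimism inequality can fluctuate on single draws; it must hold in
  # the clear majority of replicates
  expect_lte(worse, 1L)
})

test_that("distribution shift degrades test accuracy", {
  cfg <- preset_single_signal(seed = 41, n_subjects = 3, trials_per_class = 3)
  train_fm <- build_feature_matrix(generate_dataset(cfg), cfg$inventory)
  matched <- preset_single_signal(seed = 42, n_subjects = 3,
                                  trials_per_class = 3)
  shifted <- preset_single_signal(seed = 42, n_subjects = 3,
                                  trials_per_class = 3,
                                  subject_sd = cfg$subject_sd * 4)
  acc_m <- evaluate_on_test(
    train_fm, build_feature_matrix(generate_dataset(matched),
                                   cfg$inventory))$report$overall
  acc_s <- evaluate_on_test(
    train_fm, build_feature_matrix(generate_dataset(shifted),
                                   cfg$inventory))$report$overall
  expect_lte(acc_s, acc_m + 0.02)
})

test_that("folds missing a class are skipped and reported", {
  cfg <- preset_single_signal(seed = 51, n_subjects = 1, trials_per_class = 2)
  ds <- generate_dataset(cfg)
  # keep a single eversion trial: its fold must be skipped
  keep <- c("S01_eversion_01",
            "S01_flush_01", "S01_flush_02",
            "S01_inversion_01", "S01_inversion_02")
  ds$trials <- ds$trials[keep]
  fm <- build_feature_matrix(ds, cfg$inventory)
  expect_warning(res <- loocv(fm), "skipped")
  expect_equal(res$skipped_folds, "S01_eversion_01")
})

test_that("empty test sets and key mismatches are rejected", {
  cfg <- preset_single_signal(seed = 61, n_subjects = 1, trials_per_class = 2)
  fm <- build_feature_matrix(generate_dataset(cfg), cfg$inventory)
  other <- restrict_to_signals(fm, "ips_ml_acc")
  expect_error(evaluate_on_test(fm, other), "different feature keys")
  empty <- fm_rows(fm, integer(0))
  expect_error(evaluate_on_test(fm, empty), "empty")
})
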