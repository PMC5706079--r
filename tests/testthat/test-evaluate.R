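test_that("confusion counts match direct tallies", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(tidy(cc), tibble::tibble(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(tidy(cc), tibble::tibble(TP = 0L, TN = 0L, FP = 1L, FN = 1L))

  set.seed(9)
  truth <- rbinom(100, 1, 0.5)
  pred <- rbinom(100, 1, 0.5)
  cc <- confusion_counts(truth, pred)
  # element-wise tally oracle
  tally <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in 1:100) {
    key <- if (truth[i] == 1 && pred[i] == 1) "TP"
           else if (truth[i] == 0 && pred[i] == 0) "TN"
           else if (truth[i] == 0) "FP" else "FN"
    tally[key] <- tally[key] + 1
  }
  expect_equal(unlist(unclass(cc)), tally)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 100)

  expect_error(confusion_counts(c(1, 0), c(1)),
               class = "profgram_invalid_input")
})

test_that("metric formulas reproduce hand-evaluated values and conventions", {
  perfect <- classification_metrics(
    structure(list(TP = 50, TN = 50, FP = 0, FN = 0),
              class = "confusion_counts"))
  expect_equal(unlist(perfect[1:4]),
               c(accuracy = 1, sensitivity = 1, specificity = 1, mcc = 1))

  worst <- classification_metrics(
    structure(list(TP = 0, TN = 0, FP = 50, FN = 50),
              class = "confusion_counts"))
  expect_equal(worst$accuracy, 0)
  expect_equal(worst$mcc, -1)

  # hand evaluation at TP=80, TN=70, FP=30, FN=20
  m <- classification_metrics(
    structure(list(TP = 80, TN = 70, FP = 30, FN = 20),
              class = "confusion_counts"))
  expect_equal(m$accuracy, 150 / 200)
  expect_equal(m$sensitivity, 80 / 100)
  expect_equal(m$specificity, 70 / 100)
  expect_equal(m$mcc,
               (80 * 70 - 30 * 20) / sqrt(110 * 100 * 100 * 90))
  expect_false(m$degenerate)

  # zero-denominator ratios return 0 with the degenerate flag
  deg <- classification_metrics(
    structure(list(TP = 0, TN = 5, FP = 0, FN = 0),
              class = "confusion_counts"))
  expect_equal(deg$sensitivity, 0)
  expect_true(deg$degenerate)
  expect_error(classification_metrics(
    structure(list(TP = 0, TN = 0, FP = 0, FN = 0),
              class = "confusion_counts")),
    class = "profgram_invalid_input")
})

test_that("metric identities hold on random confusion counts", {
  set.seed(21)
  for (r in 1:25) {
    cc <- structure(as.list(stats::setNames(sample.int(60, 4),
                                            c("TP", "TN", "FP", "FN"))),
                    class = "confusion_counts")
    m <- classification_metrics(cc)
    P <- cc$TP + cc$FN
    N <- cc$TN + cc$FP
    expect_equal(m$accuracy,
                 (m$sensitivity * P + m$specificity * N) / (P + N))
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
    # MCC invariant under TP<->TN, FP<->FN swap
    sw <- structure(list(TP = cc$TN, TN = cc$TP, FP = cc$FN, FN = cc$FP),
                    class = "confusion_counts")
    expect_equal(classification_metrics(sw)$mcc, m$mcc)
  }
})

test_that("auROC matches the pairwise-concordance oracle and tie conventions", {
  labels <- c(1, 1, 0, 0)
  expect_equal(roc_auc(labels, labels), 1)          # perfect ranking
  expect_equal(roc_auc(rep(0.3, 4), labels), 0.5)   # all scores tied

  set.seed(13)
  for (r in 1:10) {
    n <- 200
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)  # rounding forces ties
    a <- roc_auc(scores, labels)
    expect_equal(a, oracle_auroc(scores, labels), tolerance = 1e-12)
    # complement symmetry
    expect_equal(roc_auc(-scores, labels), 1 - a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "profgram_undefined_metric")
})

test_that("auROC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  labels <- rbinom(150, 1, 0.4)
  scores <- rnorm(150) + labels
  expect_equal(
    roc_auc(scores, labels),
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   direction = "<"))),
    tolerance = 1e-12)
})

test_that("auPR behaves correctly at the extremes and in [0,1]", {
  labels <- c(1, 1, 0, 0)
  expect_equal(pr_auc(labels, labels), 1)
  # constant scores: auPR equals the positive prevalence
  expect_equal(pr_auc(rep(1, 4), labels), 0.5)
  set.seed(23)
  for (r in 1:10) {
    labels <- rbinom(80, 1, 0.5)
    if (length(unique(labels)) < 2) next
    v <- pr_auc(rnorm(80), labels)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("stratified k-fold CV partitions instances exactly once and is seed-stable", {
  ds <- generate_dataset(small_config(n_pos = 12, n_neg = 12, seed = 2),
                         "MONOGRAM")
  r <- kfold_cv(ds, classifier_spec("svm_linear"), k = 4, seed = 1)
  fa <- r$fold_assignments
  expect_setequal(fa$instance_id, ds$instance_id)
  expect_equal(nrow(fa), nrow(ds))
  expect_equal(sort(unique(fa$fold)), 1:4)
  # stratification: each fold holds an equal share of each class
  per_fold <- table(fa$fold, ds$label[match(fa$instance_id, ds$instance_id)])
  expect_true(all(per_fold == 3))
  # pooled confusion counts sum to n
  cc <- r$confusion
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, nrow(ds))
  # determinism of assignments
  r2 <- kfold_cv(ds, classifier_spec("svm_linear"), k = 4, seed = 1)
  expect_identical(r$fold_assignments, r2$fold_assignments)
  expect_equal(r$pooled, r2$pooled)
  # aggregate equals the sum of per-fold confusion counts
  per_fold_cc <- lapply(split(r$predictions, r$predictions$fold),
                        function(q) confusion_counts(q$truth, q$label))
  expect_equal(Reduce(`+`, lapply(per_fold_cc, function(x) x$TP)), cc$TP)
  expect_error(kfold_cv(ds, classifier_spec(), k = nrow(ds) + 1),
               class = "profgram_invalid_input")
  expect_warning(kfold_cv(ds, classifier_spec("svm_linear"), k = 15, seed = 1),
                 "stratified")
})

test_that("jack-knife runs n rounds, each instance held out once", {
  ds <- generate_dataset(small_config(n_pos = 5, n_neg = 5, seed = 4),
                         "MONOGRAM")
  r <- jackknife(ds, classifier_spec("svm_linear"))
  expect_equal(r$protocol, "jackknife")
  expect_equal(nrow(r$predictions), nrow(ds))
  expect_setequal(r$predictions$instance_id, ds$instance_id)
  cc <- r$confusion
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, nrow(ds))
  expect_error(jackknife(ds[1:2, ], classifier_spec()),
               class = "profgram_invalid_input")
})

test_that("jack-knife coincides with k-fold CV at k = n under a fixed ordering", {
  ds <- generate_dataset(small_config(n_pos = 4, n_neg = 4, seed = 6),
                         "MONOGRAM")
  jk <- jackknife(ds, classifier_spec("svm_linear"))
  # k = n: every fold is a singleton, so the training sets are the same
  # n leave-one-out sets regardless of shuffle; pooled metrics must agree
  kf <- suppressWarnings(
    kfold_cv(ds, classifier_spec("svm_linear"), k = nrow(ds), seed = 1))
  jo <- jk$predictions[order(jk$predictions$instance_id), ]
  ko <- kf$predictions[order(kf$predictions$instance_id), ]
  expect_equal(jo$label, ko$label)
  expect_equal(jo$score, ko$score, tolerance = 1e-10)
  expect_equal(jk$pooled[1:4], kf$pooled[1:4])
})

test_that("reports serialise to JSON and tidy/glance/autoplot work", {
  ds <- generate_dataset(small_config(n_pos = 10, n_neg = 10, seed = 8),
                         "MONOGRAM")
  r <- kfold_cv(ds, classifier_spec("svm_linear"), k = 5, seed = 2)
  expect_equal(nrow(tidy(r)), 5)
  g <- glance(r)
  expect_equal(g$n, 20)
  expect_true(all(c("auroc", "aupr") %in% names(g)))
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(r, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$pooled[[1]]$accuracy, r$pooled$accuracy)
  expect_equal(length(back$fold_assignments), 20)
  expect_s3_class(autoplot(r, "roc"), "ggplot")
  expect_s3_class(autoplot(r, "pr"), "ggplot")
})
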