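#' Confusion counts for binary predictions
#'
#' @param truth Binary vector of reference labels (1 = DNA-binding).
#' @param predicted Binary vector of predicted labels, same length.
#' @return A `confusion_counts` object with fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 1) {
    abort("truth and predicted must be equal-length, non-empty vectors",
          class = "profgram_invalid_input")
  }
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    abort("labels must be binary 0/1", class = "profgram_invalid_input")
  }
  structure(list(
    TP = sum(truth == 1 & predicted == 1),
    TN = sum(truth == 0 & predicted == 0),
    FP = sum(truth == 0 & predicted == 1),
    FN = sum(truth == 1 & predicted == 0)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP =", x$TP, " TN =", x$TN,
      " FP =", x$FP, " FN =", x$FN, "\n")
  invisible(x)
}

#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(TP = x$TP, TN = x$TN, FP = x$FP, FN = x$FN)
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A ratio with a
#' zero denominator is reported as 0 and flagged via the `degenerate`
#' column (the MCC formula is undefined there; 0 is the standard
#' convention).
#'
#' @param cc A `confusion_counts` object, or `truth` when `predicted` is
#'   also given.
#' @param predicted Optional binary prediction vector (with `cc` a truth
#'   vector), for convenience.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `mcc`, `degenerate`.
#' @export
classification_metrics <- function(cc, predicted = NULL) {
  if (!is.null(predicted)) cc <- confusion_counts(cc, predicted)
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- as.numeric(cc$TP); tn <- as.numeric(cc$TN)
  fp <- as.numeric(cc$FP); fn <- as.numeric(cc$FN)
  total <- tp + tn + fp + fn
  if (total == 0) {
    abort("all confusion counts are zero", class = "profgram_invalid_input")
  }
  degenerate <- FALSE
  ratio0 <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  tibble::tibble(
    accuracy = (tp + tn) / total,
    sensitivity = ratio0(tp, tp + fn),
    specificity = ratio0(tn, tn + fp),
    mcc = ratio0(tp * tn - fp * fn, mcc_den),
    degenerate = degenerate
  )
}

#' Area under the ROC curve
#'
#' Computed in the rank-statistic (Mann-Whitney) formulation: the
#' probability that a random positive outranks a random negative, with
#' tied scores contributing 1/2. With all scores equal this yields
#' exactly 0.5.
#'
#' @param scores Real-valued classifier scores (higher = more positive).
#' @param labels Binary labels; both classes must be present.
#' @return A number in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  pos <- labels == 1
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over the distinct score thresholds, from the most
#' to the least confident: auPR = sum over thresholds of
#' (recall_t - recall_{t-1}) * precision_t. A perfect ranking yields 1;
#' uninformative constant scores yield the positive-class prevalence.
#'
#' @inheritParams roc_auc
#' @return A number in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  pts <- pr_points(scores, labels)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) < 1) {
    abort("scores and labels must be equal-length, non-empty vectors",
          class = "profgram_invalid_input")
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    abort("labels must contain both classes (0 and 1)",
          class = "profgram_undefined_metric")
  }
  invisible(TRUE)
}

#' ROC / precision-recall curve points
#'
#' One row per distinct score threshold (descending), suitable for
#' plotting or TSV export.
#'
#' @inheritParams roc_auc
#' @return A tibble: `threshold`, `tpr`/`fpr` (ROC) or
#'   `recall`/`precision` (PR).
#' @export
roc_points <- function(scores, labels) {
  check_scores_labels(scores, labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, tp / sum(labels == 1)),
    fpr = c(0, fp / sum(labels == 0))
  )
}

#' @rdname roc_points
#' @export
pr_points <- function(scores, labels) {
  check_scores_labels(scores, labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  tibble::tibble(
    threshold = s[keep],
    recall = tp / sum(labels == 1),
    precision = tp / (tp + fp)
  )
}

#' Stratified k-fold cross-validation
#'
#' Shuffles each class with the given seed, deals instances round-robin
#' into k folds (so folds are stratified), then for each fold trains on
#' the remaining k-1 folds and predicts the held-out fold. Metrics are
#' reported two ways: pooled over all out-of-fold predictions (the
#' canonical aggregate, matching jack-knife semantics) and as the mean of
#' per-fold values; auROC/auPR are computed on the pooled scores.
#'
#' @param dataset A `labeled_dataset`; each class needs at least k
#'   members.
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle (defaults to
#'   `spec$seed`).
#' @return An `evaluation_report`; see [tidy.evaluation_report()],
#'   [glance.evaluation_report()], [autoplot.evaluation_report()].
#' @export
kfold_cv <- function(dataset, spec = classifier_spec(), k = 10,
                     seed = spec$seed) {
  n <- nrow(dataset)
  class_sizes <- table(dataset$label)
  if (length(class_sizes) < 2) {
    abort("k-fold CV needs both classes present",
          class = "profgram_invalid_input")
  }
  if (k < 2 || k > n) {
    abort(paste0("k = ", k, " must lie in [2, n = ", n, "]"),
          class = "profgram_invalid_input")
  }
  if (min(class_sizes) < k && k < n) {
    warn(paste0("smallest class has ", min(class_sizes), " < k = ", k,
                " members; folds cannot be fully stratified"))
  }
  set.seed(seed)
  # shuffle within class, then deal round-robin with a counter that runs on
  # across classes: folds stay class-balanced when k divides the class sizes
  # and are never empty for any k <= n
  fold <- integer(n)
  idx_all <- c(sample(which(dataset$label == 1)),
               sample(which(dataset$label == 0)))
  fold[idx_all] <- rep_len(seq_len(k), n)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- train_classifier(dataset[!test, ], spec)
    p <- predict(fit, dataset[test, ])
    preds[[f]] <- dplyr::mutate(p, fold = f, truth = dataset$label[test],
                                instance_id = dataset$instance_id[test])
  }
  build_report(dplyr::bind_rows(preds), protocol = "kfold", k = k,
               seed = seed, spec = spec, dataset = dataset, fold = fold)
}

#' Jack-knife (leave-one-out) evaluation
#'
#' Runs n train/test rounds, each holding out exactly one instance, and
#' pools the n predictions. Deterministic: there is no fold randomness.
#' Rounds whose training remainder would hold a single class are flagged
#' and predicted by the majority class (this can only occur when one
#' class has a single member).
#'
#' @param dataset A `labeled_dataset` with at least 3 instances.
#' @param spec A [classifier_spec()].
#' @return An `evaluation_report` with `protocol = "jackknife"`.
#' @export
jackknife <- function(dataset, spec = classifier_spec()) {
  n <- nrow(dataset)
  if (n < 3) {
    abort("jack-knife needs at least 3 instances",
          class = "profgram_invalid_input")
  }
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    train <- dataset[-i, ]
    if (length(unique(train$label)) < 2) {
      maj <- as.integer(mean(train$label) >= 0.5)
      preds[[i]] <- tibble::tibble(
        instance_id = dataset$instance_id[i], label = maj,
        score = if (maj == 1) 1 else -1, score_kind = "margin",
        fold = i, truth = dataset$label[i], degenerate_round = TRUE)
      next
    }
    fit <- train_classifier(train, spec)
    p <- predict(fit, dataset[i, ])
    preds[[i]] <- dplyr::mutate(p, fold = i, truth = dataset$label[i],
                                instance_id = dataset$instance_id[i],
                                degenerate_round = FALSE)
  }
  build_report(dplyr::bind_rows(preds), protocol = "jackknife", k = n,
               seed = spec$seed, spec = spec, dataset = dataset,
               fold = seq_len(n), per_fold_metrics = FALSE)
}

#' Hold-out evaluation of a trained model
#'
#' Applies a fitted model to an independent labeled table and reports the
#' full metric bundle.
#'
#' @param model A `dbp_model`.
#' @param dataset A `labeled_dataset` (the independent test set).
#' @return An `evaluation_report` with `protocol = "holdout"`.
#' @export
evaluate_holdout <- function(model, dataset) {
  p <- predict(model, dataset)
  p <- dplyr::mutate(p, fold = 1L, truth = dataset$label,
                     instance_id = dataset$instance_id)
  build_report(p, protocol = "holdout", k = 1L, seed = model$spec$seed,
               spec = model$spec, dataset = dataset,
               fold = rep(1L, nrow(dataset)), per_fold_metrics = FALSE)
}

build_report <- function(preds, protocol, k, seed, spec, dataset, fold,
                         per_fold_metrics = TRUE) {
  pooled_cc <- confusion_counts(preds$truth, preds$label)
  pooled <- classification_metrics(pooled_cc)
  pooled$auroc <- roc_auc(preds$score, preds$truth)
  pooled$aupr <- pr_auc(preds$score, preds$truth)
  per_fold <- if (per_fold_metrics) {
    dplyr::bind_rows(lapply(sort(unique(preds$fold)), function(f) {
      q <- preds[preds$fold == f, ]
      dplyr::bind_cols(tibble::tibble(fold = f),
                       classification_metrics(q$truth, q$label))
    }))
  } else NULL
  fold_mean <- if (!is.null(per_fold)) {
    dplyr::summarise(per_fold, dplyr::across(
      c("accuracy", "sensitivity", "specificity", "mcc"), mean))
  } else NULL
  structure(
    list(protocol = protocol, k = k, seed = seed, spec = spec,
         feature_group = attr(dataset, "feature_group"),
         origin = attr(dataset, "origin"),
         n = nrow(dataset),
         predictions = preds,
         confusion = pooled_cc,
         pooled = pooled,
         per_fold = per_fold,
         fold_mean = fold_mean,
         fold_assignments = tibble::tibble(
           instance_id = dataset$instance_id, fold = fold)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$protocol,
      if (x$protocol == "kfold") paste0(" (k = ", x$k, ")"),
      ", n = ", x$n, ", ", x$origin %||% "?", "/",
      x$feature_group %||% "?", ", ", x$spec$algorithm, "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy / summarise an evaluation report
#'
#' `tidy()` returns per-fold metric rows (pooled row only, for protocols
#' without per-fold bundles); `glance()` returns the one-row pooled
#' aggregate with auROC and auPR.
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  x$per_fold %||%
    dplyr::bind_cols(tibble::tibble(fold = NA_integer_),
                     x$pooled[c("accuracy", "sensitivity",
                                "specificity", "mcc", "degenerate")])
}

#' @rdname tidy.evaluation_report
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(protocol = x$protocol, algorithm = x$spec$algorithm,
                   feature_group = x$feature_group %||% NA_character_,
                   origin = x$origin %||% NA_character_, n = x$n),
    x$pooled
  )
}

#' Serialise an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    protocol = report$protocol, k = report$k, seed = report$seed, n = report$n,
    algorithm = report$spec$algorithm,
    feature_group = report$feature_group, origin = report$origin,
    confusion = tidy(report$confusion),
    pooled = report$pooled,
    per_fold = report$per_fold,
    fold_mean = report$fold_mean,
    fold_assignments = report$fold_assignments
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
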