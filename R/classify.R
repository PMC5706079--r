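#' Specify a classifier
#'
#' Captures the algorithm and hyperparameters of one classification run.
#' Four algorithms are supported: maximum-margin classifiers with linear
#' (`K(u, v) = u . v`) and radial-basis (`K(u, v) = exp(-||u - v||^2 /
#' (2 sigma^2))`) kernels, plus Random Forest and AdaBoost ensemble
#' comparators.
#'
#' Defaults: soft-margin cost `C = 1` for both kernels; RBF width by the
#' `"scale"` rule (`gamma = 1 / (d * var(X))`, i.e. `sigma^2 = d * var(X)
#' / 2`); 100 estimators for the ensembles. Feature standardisation (zero
#' mean, unit variance, fitted on training data only) defaults on for the
#' kernel machines and off for the tree ensembles; fitting it inside
#' [train_classifier()] keeps cross-validation leakage-free.
#'
#' @param algorithm One of `"svm_linear"`, `"svm_rbf"`, `"random_forest"`,
#'   `"adaboost"`.
#' @param C Positive soft-margin cost (SVM only).
#' @param gamma RBF kernel coefficient: positive number or `"scale"`.
#' @param n_estimators Number of trees / boosting rounds (ensembles only).
#' @param scaling `"standardize"` or `"none"`; `NULL` picks the
#'   per-algorithm default described above.
#' @param seed Integer seed controlling any training randomness.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(algorithm = c("svm_linear", "svm_rbf",
                                          "random_forest", "adaboost"),
                            C = 1, gamma = "scale", n_estimators = 100L,
                            scaling = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(C) || C <= 0) {
    abort("C must be a positive real", class = "profgram_invalid_input")
  }
  if (!(identical(gamma, "scale") || (is.numeric(gamma) && gamma > 0))) {
    abort("gamma must be a positive real or \"scale\"",
          class = "profgram_invalid_input")
  }
  if (!is.numeric(n_estimators) || n_estimators < 1) {
    abort("n_estimators must be a positive integer",
          class = "profgram_invalid_input")
  }
  scaling <- scaling %||%
    if (algorithm %in% c("svm_linear", "svm_rbf")) "standardize" else "none"
  scaling <- match.arg(scaling, c("standardize", "none"))
  structure(list(algorithm = algorithm, C = C, gamma = gamma,
                 n_estimators = as.integer(n_estimators),
                 scaling = scaling, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec> ", x$algorithm,
      " (C = ", x$C, ", gamma = ", format(x$gamma),
      ", n_estimators = ", x$n_estimators,
      ", scaling = ", x$scaling, ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Train a classifier on a labeled feature table
#'
#' Fits the classifier described by `spec` to a [featurize_profiles()]
#' table. Training is deterministic given `(dataset, spec)`: all
#' randomness is controlled by `spec$seed`. When `spec$scaling ==
#' "standardize"`, per-column centring and scaling parameters are
#' estimated from this training data and stored in the model, so held-out
#' data is standardised with training statistics only.
#'
#' @param dataset A `labeled_dataset` with at least one instance of each
#'   class.
#' @param spec A [classifier_spec()].
#' @return A `dbp_model` object; use [predict.dbp_model()],
#'   [save_model()], [tidy()] and [glance()] on it.
#' @export
train_classifier <- function(dataset, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- feature_matrix(dataset)
  y <- dataset$label
  if (length(unique(y)) < 2) {
    abort("training data holds a single class; cannot fit a classifier",
          class = "profgram_untrainable")
  }
  center <- NULL
  scale_ <- NULL
  if (spec$scaling == "standardize") {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0] <- 1  # constant columns pass through unchanged
    x <- scale(x, center = center, scale = scale_)
  }
  set.seed(spec$seed)
  yf <- factor(y, levels = c(1, 0))  # level 1 first: decision values > 0 => class 1
  fit <- switch(spec$algorithm,
    svm_linear = e1071::svm(x, yf, kernel = "linear", cost = spec$C,
                            scale = FALSE),
    svm_rbf = {
      g <- if (identical(spec$gamma, "scale")) {
        v <- stats::var(as.vector(x))
        1 / (ncol(x) * max(v, .Machine$double.eps))
      } else spec$gamma
      e1071::svm(x, yf, kernel = "radial", cost = spec$C, gamma = g,
                 scale = FALSE)
    },
    random_forest = randomForest::randomForest(
      x = x, y = yf, ntree = spec$n_estimators),
    adaboost = ada_fit(x, y, n_estimators = spec$n_estimators)
  )
  structure(
    list(spec = spec,
         feature_group = attr(dataset, "feature_group"),
         origin = attr(dataset, "origin"),
         columns = colnames(x),
         center = center, scale = scale_,
         fit = fit,
         n_train = nrow(x),
         training_fingerprint = rlang::hash(list(unname(x), y)),
         format_version = MODEL_FORMAT_VERSION),
    class = "dbp_model")
}

#' Predict DNA-binding labels for new instances
#'
#' Returns one prediction per input row, in input order. Kernel machines
#' and AdaBoost report a margin-type decision score (threshold 0); Random
#' Forest reports the positive-class vote fraction (threshold 0.5). A
#' score exactly at the threshold is assigned to the positive class.
#'
#' @param object A `dbp_model`.
#' @param newdata A `labeled_dataset`, a numeric matrix with the model's
#'   feature columns, or a single `feature_vector`.
#' @param ... Unused.
#' @return A tibble with `instance_id`, `label` (0/1), `score`,
#'   `score_kind` (`"margin"` or `"probability"`).
#' @export
predict.dbp_model <- function(object, newdata, ...) {
  x <- coerce_prediction_input(object, newdata)
  if (!is.null(object$center)) {
    x <- scale(x, center = object$center, scale = object$scale)
  }
  score <- switch(object$spec$algorithm,
    svm_linear = ,
    svm_rbf = {
      p <- predict(object$fit, x, decision.values = TRUE)
      dv <- attr(p, "decision.values")
      # libsvm orients decision values towards the first class it saw in
      # training; normalise so positive margin always means class "1"
      if (identical(colnames(dv), "0/1")) dv <- -dv
      as.numeric(dv)
    },
    random_forest = unname(
      predict(object$fit, x, type = "prob")[, "1"]),
    adaboost = ada_score(object$fit, x)
  )
  kind <- if (object$spec$algorithm == "random_forest") "probability" else "margin"
  thr <- if (kind == "probability") 0.5 else 0
  tibble::tibble(
    instance_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    label = as.integer(score >= thr),
    score = score,
    score_kind = kind
  )
}

coerce_prediction_input <- function(model, newdata) {
  if (inherits(newdata, "feature_vector")) {
    x <- matrix(unclass_fv(newdata), nrow = 1,
                dimnames = list(attr(newdata, "instance_id"),
                                names(newdata)))
  } else if (is.data.frame(newdata)) {
    x <- feature_matrix(newdata)
  } else {
    x <- as.matrix(newdata)
  }
  if (ncol(x) != length(model$columns)) {
    abort(paste0("feature dimension mismatch: model '", model$feature_group,
                 "' expects ", length(model$columns), " columns, input has ",
                 ncol(x)),
          class = "profgram_invalid_input")
  }
  colnames(x) <- model$columns
  x
}

#' Persist / restore a trained model
#'
#' A model file is a single-file archive (RDS) holding the fitted
#' estimator together with its [classifier_spec()], feature group and
#' origin, the canonical feature-column ordering, the standardisation
#' parameters, and a format-version string. [load_model()] refuses files
#' whose format version does not match the current one, so stale models
#' fail loudly rather than predicting garbage.
#'
#' @param model A `dbp_model`.
#' @param path File path for the model archive.
#' @return `path` invisibly (save); a `dbp_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dbp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("cannot read model file ", path, ": ", conditionMessage(e)),
          class = "profgram_model_format_error")
  })
  if (!inherits(model, "dbp_model") ||
      !identical(model$format_version, MODEL_FORMAT_VERSION)) {
    abort(paste0("model file ", path, " has an unsupported format version"),
          class = "profgram_model_format_error")
  }
  model
}

#' @export
print.dbp_model <- function(x, ...) {
  cat("<dbp_model> ", x$spec$algorithm, " on ", x$origin, "/",
      x$feature_group, " features (d = ", length(x$columns),
      ", n_train = ", x$n_train, ")\n", sep = "")
  invisible(x)
}

#' Tidy a trained model's configuration
#' @param x A `dbp_model`.
#' @param ... Unused.
#' @return One row per hyperparameter.
#' @method tidy dbp_model
#' @export
tidy.dbp_model <- function(x, ...) {
  tibble::tibble(
    parameter = c("algorithm", "C", "gamma", "n_estimators", "scaling", "seed"),
    value = as.character(c(x$spec$algorithm, x$spec$C, format(x$spec$gamma),
                           x$spec$n_estimators, x$spec$scaling, x$spec$seed))
  )
}

#' @rdname tidy.dbp_model
#' @method glance dbp_model
#' @export
glance.dbp_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$spec$algorithm,
    feature_group = x$feature_group,
    origin = x$origin,
    n_features = length(x$columns),
    n_train = x$n_train,
    format_version = x$format_version
  )
}
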