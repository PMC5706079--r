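# AdaBoost.M1 with depth-1 rpart stumps. Kept minimal and deterministic:
# sample weights are updated multiplicatively, the ensemble score is the
# alpha-weighted sum of stump votes in {-1, +1}.

ada_fit <- function(x, y, n_estimators = 100L) {
  stopifnot(all(y %in% c(0, 1)))
  y2 <- ifelse(y == 1, 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  used <- 0L
  for (m in seq_len(n_estimators)) {
    df$.y <- factor(y2, levels = c(-1, 1))
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = -1, minsplit = 2,
                          minbucket = 1, xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y2))
    if (err >= 0.5) break       # stump no better than chance: stop adding
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * y2 * pred)
    w <- w / sum(w)
    used <- m
    stumps[[m]] <- fit
    alphas[[m]] <- alpha
    if (err <= 1e-10) break     # perfect stump: ensemble is decided
  }
  if (used == 0L) {
    # degenerate data: fall back to a single majority-vote constant
    prior <- if (mean(y2 == 1) >= 0.5) 1 else -1
    return(structure(list(stumps = list(), alphas = numeric(0),
                          fallback = prior, columns = names(df)[names(df) != ".y"]),
                     class = "profgram_adaboost"))
  }
  structure(list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)],
                 fallback = NULL, columns = setdiff(names(df), ".y")),
            class = "profgram_adaboost")
}

ada_score <- function(model, x) {
  df <- as.data.frame(x)
  names(df) <- model$columns
  if (length(model$stumps) == 0) {
    return(rep(model$fallback, nrow(df)))
  }
  s <- numeric(nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(
      predict(model$stumps[[m]], df, type = "class")))
    s <- s + model$alphas[[m]] * pred
  }
  s / sum(model$alphas)
}
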