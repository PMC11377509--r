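#' Specify a classifier for benchmarking
#'
#' Four model families are available: a random forest (`"rf"`), two
#' gradient-boosted tree variants — `"xgb"`, shallow depth-3 trees, and
#' `"gbm"`, deeper depth-6 trees with row and column subsampling — and
#' a small feed-forward neural network (`"ann"`, one hidden layer on
#' standardised inputs). Both boosted variants use exact greedy splits,
#' which place thresholds mid-way between training points; at the tiny
#' sample sizes LOOCV deals in, histogram-based splitting would pin
#' thresholds onto training values and clip the margin around held-out
#' extremes. Hyperparameter defaults are fixed for reproducibility at
#' small n: forest 500 trees; boosted variants 200 rounds, learning
#' rate 0.1 (`"gbm"` additionally subsamples 80% of rows and columns
#' per tree); network 16 hidden units, weight decay 1e-3, 500
#' iterations, no early stopping.
#'
#' @param family One of `"rf"`, `"xgb"`, `"gbm"`, `"ann"`.
#' @param hyperparameters Named list overriding family defaults.
#' @param seed Integer seed used for every stochastic element of the
#'   fit.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("rf", "xgb", "gbm", "ann"),
                       hyperparameters = list(), seed = 1) {
  family <- match.arg(family)
  defaults <- switch(family,
    rf  = list(ntree = 500),
    xgb = list(nrounds = 200, max_depth = 3, eta = 0.1),
    gbm = list(nrounds = 200, max_depth = 6, eta = 0.1,
               subsample = 0.8, colsample_bytree = 0.8),
    ann = list(size = 16, decay = 1e-3, maxit = 500))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Default benchmark suite
#'
#' One [model_spec()] per family with default hyperparameters.
#'
#' @param seed Seed shared by all four specs.
#' @return Named list of `model_spec` objects.
#' @export
default_model_specs <- function(seed = 1) {
  fams <- c("rf", "xgb", "gbm", "ann")
  stats::setNames(lapply(fams, function(f) model_spec(f, seed = seed)), fams)
}

## fit on (X, y), return a function predicting labels for new rows.
## All stochastic elements are seeded from the spec.
fit_classifier <- function(X, y, spec) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  hp <- spec$hyperparameters
  lev <- levels(y)
  if (length(lev) == 1L) {
    # degenerate training fold: only one class left to learn
    return(function(newX) factor(rep(lev, nrow(as.matrix(newX))),
                                 levels = lev))
  }
  switch(spec$family,
    rf = {
      fit <- with_seed(spec$seed, randomForest::randomForest(
        x = X, y = y, ntree = hp$ntree))
      function(newX) stats::predict(fit, as.matrix(newX))
    },
    xgb = ,
    gbm = {
      params <- list(objective = "multi:softmax",
                     num_class = length(lev), eta = hp$eta,
                     tree_method = "exact", max_depth = hp$max_depth,
                     nthread = 1)
      if (spec$family == "gbm") {
        params$subsample <- hp$subsample
        params$colsample_bytree <- hp$colsample_bytree
      }
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      fit <- with_seed(spec$seed, xgboost::xgb.train(
        params = params, data = dtrain, nrounds = hp$nrounds, verbose = 0))
      function(newX) {
        pred <- stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(newX)))
        factor(lev[pred + 1L], levels = lev)
      }
    },
    ann = {
      # standardisation fitted on the training fold only
      mu <- colMeans(X)
      sdev <- apply(X, 2, stats::sd)
      sdev[sdev == 0] <- 1
      Xs <- scale(X, center = mu, scale = sdev)
      target <- nnet::class.ind(y)
      fit <- with_seed(spec$seed, nnet::nnet(
        Xs, target, size = hp$size, decay = hp$decay, maxit = hp$maxit,
        softmax = TRUE, trace = FALSE, MaxNWts = 100000))
      function(newX) {
        newXs <- scale(as.matrix(newX), center = mu, scale = sdev)
        pr <- stats::predict(fit, newXs)
        factor(lev[apply(pr, 1, which.max)], levels = lev)
      }
    })
}

#' Leave-one-out cross-validated predictions
#'
#' For each of the n samples, trains the specified model on the other
#' n - 1 and predicts the held-out one, so every sample is tested
#' exactly once and no information from the test sample (label or
#' feature scaling) reaches its training fold. A class with a single
#' member triggers a warning: its fold is still scored, with that class
#' absent from training, which is the honest LOOCV behaviour.
#'
#' @param X Feature matrix or data frame (n >= 4 rows).
#' @param y Class label per row.
#' @param spec A [model_spec()].
#' @return Factor of n predicted labels, aligned with the rows of `X`.
#' @export
loocv_predictions <- function(X, y, spec) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples for LOOCV", call. = FALSE)
  if (length(y) != n) stop("labels must match rows", call. = FALSE)
  singletons <- names(which(table(y) == 1))
  if (length(singletons))
    warning("class(es) with a single member: ",
            paste(singletons, collapse = ", "),
            "; their folds are scored with the class absent from training",
            call. = FALSE)
  preds <- character(n)
  for (i in seq_len(n)) {
    predict_fn <- fit_classifier(X[-i, , drop = FALSE], y[-i], spec)
    preds[i] <- as.character(predict_fn(X[i, , drop = FALSE]))
  }
  factor(preds, levels = levels(y))
}

#' Confusion matrix
#'
#' Tabulates (true, predicted) label pairs over the union of the two
#' label alphabets. Labels predicted outside the true alphabet are
#' counted and flagged, never dropped.
#'
#' @param y_true,y_pred Equal-length label vectors (non-empty).
#' @return A K x K table of class `confusion_matrix` (true labels in
#'   rows).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty inputs", call. = FALSE)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  lev <- union(levels(factor(y_true)), levels(factor(y_pred)))
  tab <- table(true = factor(y_true, levels = lev),
               predicted = factor(y_pred, levels = lev))
  novel <- setdiff(unique(as.character(y_pred)), unique(as.character(y_true)))
  structure(tab, class = c("confusion_matrix", class(tab)),
            novel_labels = novel)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1. For a binary matrix with a
#' declared positive class the standard TP/TN/FP/FN formulas are used:
#' accuracy (TP+TN)/total, precision TP/(TP+FP), recall TP/(TP+FN),
#' F1 the harmonic mean of precision and recall. For K > 2 classes the
#' per-class one-vs-rest values are macro-averaged. A zero denominator
#' yields 0 with the corresponding flag set rather than NaN.
#'
#' @param cm A `confusion_matrix`.
#' @param positive Positive-class label for binary scoring; ignored
#'   (macro averaging) when the matrix has more than two classes.
#' @return List: `accuracy`, `precision`, `recall`, `f1`,
#'   `zero_denominator` (character vector naming any flagged metric).
#' @export
classification_metrics <- function(cm, positive = NULL) {
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("all-zero confusion matrix", call. = FALSE)
  flags <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); 0 } else num / den
  }
  accuracy <- sum(diag(m)) / total
  lev <- rownames(m)
  if (length(lev) == 2 && !is.null(positive)) {
    stopifnot(positive %in% lev)
    neg <- setdiff(lev, positive)
    tp <- m[positive, positive]; tn <- m[neg, neg]
    fp <- m[neg, positive]; fn <- m[positive, neg]
    precision <- safe_div(tp, tp + fp, "precision")
    recall <- safe_div(tp, tp + fn, "recall")
  } else {
    pr <- vapply(lev, function(k)
      safe_div(m[k, k], sum(m[, k]), paste0("precision:", k)), numeric(1))
    rc <- vapply(lev, function(k)
      safe_div(m[k, k], sum(m[k, ]), paste0("recall:", k)), numeric(1))
    precision <- mean(pr)
    recall <- mean(rc)
  }
  f1 <- if (precision + recall == 0) {
    flags <- c(flags, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, zero_denominator = unique(flags))
}

#' Benchmark classifier families under LOOCV
#'
#' Runs [loocv_predictions()] for every spec, pools the n held-out
#' predictions into a single confusion matrix per model (per-fold
#' metrics are degenerate for single-sample folds) and scores it with
#' [classification_metrics()]. One model failing does not abort the
#' suite: its row carries `NA` metrics and the error message.
#'
#' @param X Feature matrix or data frame.
#' @param y Class labels.
#' @param specs List of [model_spec()] objects (default: all four
#'   families, seed 1).
#' @param positive Positive-class label forwarded to the metrics for
#'   binary tasks.
#' @return Data frame of class `eval_report`, one row per model,
#'   sorted by accuracy; attributes `predictions` and
#'   `confusion_matrices` carry the per-model detail.
#' @export
benchmark_models <- function(X, y, specs = default_model_specs(),
                             positive = NULL) {
  if (length(specs) < 1) stop("need at least one model spec", call. = FALSE)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, character(1), "family")
  preds <- list(); cms <- list(); rows <- list()
  for (nm in names(specs)) {
    res <- tryCatch({
      p <- loocv_predictions(X, y, specs[[nm]])
      cm <- confusion(y, p)
      met <- classification_metrics(cm, positive = positive)
      preds[[nm]] <- p; cms[[nm]] <- cm
      data.frame(model = nm, accuracy = met$accuracy,
                 precision = met$precision, recall = met$recall,
                 f1 = met$f1, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(model = nm, accuracy = NA_real_, precision = NA_real_,
                 recall = NA_real_, f1 = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    rows[[nm]] <- res
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "predictions") <- preds
  attr(out, "confusion_matrices") <- cms
  class(out) <- c("eval_report", "data.frame")
  out
}
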