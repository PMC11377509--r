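#' Rank CV features by correlation with tumor grade
#'
#' Spearman correlation of each engineered feature column against the
#' grade vector, via [spearman_test()]. Constant columns are reported
#' with `NA` and flagged `undefined` rather than dropped, so the output
#' always has one row per feature. Rows are sorted by rho, largest
#' first, undefined rows last.
#'
#' @param feature_matrix Data frame or matrix of feature columns.
#' @param grades Numeric grade per row (>= 3 rows).
#' @return Data frame: `feature`, `rho`, `p_value`, `label`,
#'   `undefined`.
#' @export
feature_target_correlations <- function(feature_matrix, grades) {
  feature_matrix <- as.data.frame(feature_matrix)
  if (nrow(feature_matrix) < 3) stop("need at least 3 samples", call. = FALSE)
  if (nrow(feature_matrix) != length(grades))
    stop("grades must match feature rows", call. = FALSE)
  grades <- as.numeric(grades)
  rows <- lapply(names(feature_matrix), function(f) {
    x <- feature_matrix[[f]]
    if (stats::sd(x) == 0) {
      data.frame(feature = f, rho = NA_real_, p_value = NA_real_,
                 label = NA_character_, undefined = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      r <- spearman_test(x, grades)
      data.frame(feature = f, rho = r$rho, p_value = r$p_value,
                 label = r$label, undefined = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rho, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random-forest feature importance
#'
#' Fits a seeded random forest of `n_trees` classification trees and
#' reports per-feature importance normalised to sum to 1. The default
#' metric is the mean decrease in node impurity (Gini); permutation
#' importance (mean decrease in out-of-bag accuracy) is available as an
#' alternative.
#'
#' @param feature_matrix Data frame or matrix of features (>= 6 rows).
#' @param labels Class label per row; >= 2 classes present.
#' @param n_trees Number of trees (default 500, chosen for importance
#'   stability at small n).
#' @param seed Integer seed; identical data + seed reproduce the table.
#' @param metric `"impurity"` (default) or `"permutation"`.
#' @return Data frame of class `importance_table`: `feature`,
#'   `importance`, `rank`, sorted by rank.
#' @export
rf_importance <- function(feature_matrix, labels, n_trees = 500, seed = 1,
                          metric = c("impurity", "permutation")) {
  metric <- match.arg(metric)
  feature_matrix <- as.data.frame(feature_matrix)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  if (nrow(feature_matrix) < 6) stop("need at least 6 samples", call. = FALSE)
  fit <- with_seed(seed, randomForest::randomForest(
    x = feature_matrix, y = labels, ntree = n_trees,
    importance = (metric == "permutation")))
  imp <- randomForest::importance(
    fit, type = if (metric == "permutation") 1L else 2L)
  scores <- pmax(imp[, 1], 0)
  scores <- scores / sum(scores)
  ord <- order(-scores)
  out <- data.frame(feature = rownames(imp)[ord],
                    importance = unname(scores[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Select features above an importance threshold
#'
#' Returns the features whose importance strictly exceeds the
#' threshold, preserving rank order. The study's working threshold for
#' this analysis is 0.08.
#'
#' @param importances An `importance_table` (or data frame with
#'   `feature`, `importance`, `rank` columns).
#' @param threshold Importance cutoff, >= 0. Default 0.08.
#' @return Character vector of feature names in rank order.
#' @examples
#' sel <- select_features(published_importance("ca153"))
#' sel
#' @export
select_features <- function(importances, threshold = 0.08) {
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be >= 0", call. = FALSE)
  stopifnot(all(c("feature", "importance", "rank") %in% names(importances)))
  imp <- importances[order(importances$rank), , drop = FALSE]
  imp$feature[imp$importance > threshold]
}

#' Published feature-importance table
#'
#' The random-forest importance scores for predicting tumor grade as
#' reported for the CA 15-3 and MUC-1 biomarkers, shipped as a fixture
#' (the underlying instrument data are not public, so these columns
#' serve selection-logic worked examples and schema tests, not
#' re-computation).
#'
#' @param biomarker `"ca153"` or `"muc1"`.
#' @return An `importance_table` data frame.
#' @export
published_importance <- function(biomarker = c("ca153", "muc1")) {
  biomarker <- match.arg(biomarker)
  path <- system.file("extdata", "feature_importance_published.csv",
                      package = "voltsense", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  col <- paste0("importance_", biomarker)
  out <- data.frame(feature = df$feature, importance = df[[col]],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Published feature-grade correlation table
#'
#' The reported Spearman correlations of the 14 CV features with tumor
#' grade for each biomarker, shipped as a fixture for schema tests and
#' comparison plots.
#'
#' @param biomarker `"ca153"` or `"muc1"`.
#' @return Data frame: `feature`, `rho`.
#' @export
published_correlations <- function(biomarker = c("ca153", "muc1")) {
  biomarker <- match.arg(biomarker)
  path <- system.file("extdata", "feature_correlation_published.csv",
                      package = "voltsense", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(feature = df$feature, rho = df[[paste0("rho_", biomarker)]],
             stringsAsFactors = FALSE)
}
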