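#' Confusion counts for a binary labelling
#'
#' @param y_true,y_pred vectors of equal length.
#' @param positive the positive class label; default the second factor level
#'   of `y_true`.
#' @return list with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) stop_input("y_true and y_pred lengths differ")
  y_true <- as.factor(y_true)
  if (is.null(positive)) positive <- levels(y_true)[min(2L, nlevels(y_true))]
  tp <- as.character(y_true) == positive
  pp <- as.character(y_pred) == positive
  list(TP = sum(tp & pp), TN = sum(!tp & !pp), FP = sum(!tp & pp), FN = sum(tp & !pp))
}

metrics_from_counts <- function(cc) {
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  safe_ratio <- function(num, den) if (den == 0) 0 else num / den
  warn <- c(precision = cc$TP + cc$FP == 0, recall = cc$TP + cc$FN == 0,
            specificity = cc$TN + cc$FP == 0)
  list(accuracy = safe_ratio(cc$TP + cc$TN, total),
       precision = safe_ratio(cc$TP, cc$TP + cc$FP),
       recall = safe_ratio(cc$TP, cc$TP + cc$FN),
       specificity = safe_ratio(cc$TN, cc$TN + cc$FP),
       undefined = warn)
}

#' Classification performance metrics
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall (sensitivity)
#' `TP/(TP+FN)` and specificity (true-negative rate) `TN/(TN+FP)`. Binary by
#' default; with more than two classes each metric is macro-averaged over
#' one-vs-rest reductions (accuracy stays the plain agreement fraction).
#' Ratios with a zero denominator are reported as 0 and flagged in the
#' `undefined` field rather than raising, so batch evaluation never aborts.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param positive positive class for the binary case; default the second
#'   level of `y_true`.
#' @return list with `accuracy`, `precision`, `recall`, `specificity`, and
#'   a logical `undefined` flag vector.
#' @export
classification_metrics <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) stop_input("y_true and y_pred lengths differ")
  y_true <- as.factor(y_true)
  if (nlevels(y_true) <= 2L) {
    return(metrics_from_counts(confusion_counts(y_true, y_pred, positive)))
  }
  per <- lapply(levels(y_true), function(cl)
    metrics_from_counts(confusion_counts(y_true, y_pred, positive = cl)))
  avg <- function(f) mean(vapply(per, `[[`, numeric(1), f))
  list(accuracy = mean(as.character(y_true) == as.character(y_pred)),
       precision = avg("precision"), recall = avg("recall"),
       specificity = avg("specificity"),
       undefined = Reduce(`|`, lapply(per, `[[`, "undefined")))
}

#' Feature reduction ratio
#'
#' Fraction of the original features retained after selection,
#' `n_selected / n_total`. Despite the conventional name, the quantity
#' measures retention; it is kept as a fraction in \[0,1\] internally and
#' rendered as a percentage only at the reporting layer.
#'
#' @param n_selected number of retained features.
#' @param n_total original feature count (>= 1).
#' @return the retention fraction in \[0,1\].
#' @export
feature_reduction_ratio <- function(n_selected, n_total) {
  if (n_total < 1) stop_input("n_total must be >= 1")
  if (n_selected < 0 || n_selected > n_total) {
    stop_input("n_selected must lie in [0, n_total]")
  }
  n_selected / n_total
}

#' Relevance score of a selected feature set
#'
#' Average weighted performance gain of the selected features,
#' \deqn{RS = \frac{1}{n}\sum_i \mathrm{Weight}(f_i)\cdot
#'   \mathrm{PerformanceGain}(f_i),}
#' where the weight is the (normalized, \[0,1\]) relevance score of the
#' feature from the selector and the gain is the add-one-in ablation delta:
#' the cross-validated accuracy of the full selected set minus that of the
#' set with the feature removed, under fixed folds and seed. Invariant to
#' the ordering of the selected features.
#'
#' @param ds a preprocessed [skr_dataset()].
#' @param selected integer indices of the selected features (length >= 1).
#' @param weights per-selected-feature weights in \[0,1\]
#'   (same length/order as `selected`).
#' @param cv_folds stratified folds (default 3).
#' @param seed fold seed (default 1).
#' @param C linear SVM regularization parameter (default 1).
#' @return scalar RS (same scale as accuracy deltas; percent rendering is
#'   the reporting layer's job).
#' @export
relevance_score <- function(ds, selected, weights, cv_folds = 3L, seed = 1L, C = 1) {
  if (!length(selected)) stop_input("empty selection")
  if (length(weights) != length(selected)) stop_input("weights length must match selection")
  if (any(weights < 0 | weights > 1)) stop_input("weights must be normalized to [0, 1]")
  X <- dataset_matrix(ds)
  full_acc <- cv_accuracy(X, ds$y, selected, C, cv_folds, seed)
  gains <- vapply(seq_along(selected), function(i) {
    rest <- selected[-i]
    if (!length(rest)) return(full_acc - 0.5)  # single feature: gain over chance
    full_acc - cv_accuracy(X, ds$y, rest, C, cv_folds, seed)
  }, numeric(1))
  mean(weights * gains)
}

#' Runtime instrumentation metrics
#'
#' Aggregates recorded task counts and durations into cumulative
#' computational time \eqn{CT = \sum_j N_j T[q_j]} (milliseconds), speedup
#' \eqn{S = CT_{single} / CT_{cluster}}, and sampled memory usage. These
#' values are hardware-dependent instrumentation: they are reported but
#' never asserted against in the test suite.
#'
#' @param tasks data frame with columns `n` (task counts) and `t_ms`
#'   (per-task duration, ms).
#' @param ct_single reference single-node time (ms); required for speedup.
#' @param ct_cluster distributed time (ms); defaults to the aggregated CT.
#' @param mem_samples optional numeric vector of sampled memory use (MB).
#' @return list with `ct_ms`, `speedup`, `mu_mb`.
#' @export
instrumentation <- function(tasks, ct_single = NULL, ct_cluster = NULL,
                            mem_samples = NULL) {
  if (is.null(tasks) || !nrow(tasks)) stop_input("no task records")
  ct <- sum(tasks$n * tasks$t_ms)
  if (is.null(ct_cluster)) ct_cluster <- ct
  speedup <- if (is.null(ct_single)) {
    stop_config("speedup requires a single-node reference run (ct_single)")
  } else ct_single / ct_cluster
  list(ct_ms = ct, speedup = speedup,
       mu_mb = if (is.null(mem_samples)) NA_real_ else mean(mem_samples))
}

#' Aggregate per-dataset results into a summary row
#'
#' Arithmetic mean of every numeric metric column across datasets, with
#' percent-scale metrics rounded half-up to the stated precision at the
#' reporting layer.
#'
#' @param results data frame: one row per dataset, numeric metric columns
#'   (non-numeric columns are ignored).
#' @param digits rounding digits for the means (default 4; use together
#'   with percent rendering when producing report tables).
#' @return named numeric vector of column means.
#' @export
aggregate_report <- function(results, digits = 4) {
  if (!nrow(results)) stop_input("no results to aggregate")
  num <- vapply(results, is.numeric, logical(1))
  means <- vapply(results[num], mean, numeric(1))
  round_half_up(means, digits)
}
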