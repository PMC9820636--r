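#' Confusion matrix for binary phenotype labels
#'
#' Counts are taken under a declared positive-class convention; swapping
#' the convention swaps tp with tn and fp with fn.
#'
#' @param y_true,y_pred Character vectors of labels in \{"good", "bad"\}.
#' @param positive_class The label counted as positive (default `"good"`).
#' @return An object of class `confusion_matrix` with fields `tp`, `fn`,
#'   `fp`, `tn`, `n`, `positive_class`.
#' @export
#' @examples
#' cm <- confusion(c("good", "bad"), c("good", "good"))
#' cm$fp
confusion <- function(y_true, y_pred, positive_class = "good") {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  ok <- c("good", "bad")
  if (!all(y_true %in% ok) || !all(y_pred %in% ok))
    stop("labels must be \"good\" or \"bad\"", call. = FALSE)
  if (!positive_class %in% ok)
    param_error("positive_class", "must be \"good\" or \"bad\"")
  pos <- y_true == positive_class
  pred_pos <- y_pred == positive_class
  structure(list(
    tp = sum(pos & pred_pos), fn = sum(pos & !pred_pos),
    fp = sum(!pos & pred_pos), tn = sum(!pos & !pred_pos),
    n = length(y_true), positive_class = positive_class),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> n = %d, positive = %s\n", x$n,
              x$positive_class))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(
                paste("actual", c(x$positive_class, "other")),
                paste("pred", c(x$positive_class, "other"))))
  print(m)
  invisible(x)
}

#' Classification quality measures from a confusion matrix
#'
#' Accuracy = (tp + tn)/n; precision = tp/(tp + fp); recall = tp/(tp + fn);
#' F1 = 2 * precision * recall / (precision + recall). A measure whose
#' denominator is zero is reported as 0 and flagged in
#' `undefined_measures`.
#'
#' @param cm A [confusion()] matrix.
#' @return An object of class `eval_metrics` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `undefined_measures` and the input
#'   confusion matrix.
#' @export
#' @examples
#' metrics(confusion_from_counts(24, 2, 4, 24))$accuracy   # 48/54
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n == 0L) stop("empty confusion matrix", call. = FALSE)
  undef <- character()
  ratio <- function(num, den, what) {
    if (den == 0) {
      undef <<- c(undef, what)
      0
    } else num / den
  }
  accuracy <- (cm$tp + cm$tn) / cm$n
  precision <- ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- ratio(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (precision + recall == 0) {
    undef <- c(undef, "f1")
    0
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, undefined_measures = undef,
                 confusion = cm),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f (positive = %s)\n",
    x$accuracy, x$precision, x$recall, x$f1, x$confusion$positive_class))
  invisible(x)
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,fn,fp,tn Nonnegative counts under `positive_class`.
#' @param positive_class Declared positive label.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn,
                                  positive_class = "good") {
  for (v in c(tp, fn, fp, tn))
    if (v < 0 || v != round(v)) param_error("counts",
                                            "must be nonnegative integers")
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 n = as.integer(tp + fn + fp + tn),
                 positive_class = positive_class),
            class = "confusion_matrix")
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from ranks: the probability that a
#' randomly chosen positive is scored above a randomly chosen negative,
#' with ties counted 1/2. Equals 1 when every positive outranks every
#' negative and 0 when the ordering is fully inverted.
#'
#' @param y_true Labels in \{"good", "bad"\} (or a 0/1 numeric vector).
#' @param scores Numeric scores, higher = more positive.
#' @param positive_class Positive label (ignored for numeric `y_true`).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c("good", "good", "bad"), c(0.9, 0.8, 0.1))
auc <- function(y_true, scores, positive_class = "good") {
  if (length(y_true) != length(scores))
    stop("y_true and scores must have equal length", call. = FALSE)
  y <- if (is.numeric(y_true)) y_true == 1 else y_true == positive_class
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)          # average ranks handle ties as 1/2
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate probabilistic predictions against true labels
#'
#' Thresholds the scores at `threshold` to get hard labels, then reports
#' the confusion matrix and all quality measures under both positive-class
#' conventions (the headline convention is good-positive, matching the
#' loss's y = 1 for good), plus the threshold-free rank AUC.
#'
#' @param y_true Character labels.
#' @param scores Predicted probabilities of the good class.
#' @param threshold Decision threshold for hard labels (default 0.5).
#' @return An object of class `eval_report`: fields `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`, `threshold`, `positive_class`,
#'   `confusion`, and `by_convention` (list with `good` and `bad` entries).
#' @export
evaluate_predictions <- function(y_true, scores, threshold = 0.5) {
  assert_scalar_num(threshold, "threshold", 0, 1)
  y_pred <- ifelse(scores >= threshold, "good", "bad")
  conv <- lapply(c(good = "good", bad = "bad"), function(pc)
    metrics(confusion(y_true, y_pred, positive_class = pc)))
  headline <- conv$good
  a <- if (all(c("good", "bad") %in% y_true))
    auc(y_true, scores, "good") else NA_real_
  structure(list(
    accuracy = headline$accuracy, precision = headline$precision,
    recall = headline$recall, f1 = headline$f1, auc = a,
    threshold = threshold, positive_class = "good",
    confusion = headline$confusion, by_convention = conv),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d  accuracy %.4f  AUC %s (threshold %.2f)\n",
    x$confusion$n, x$accuracy,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc), x$threshold))
  for (pc in c("good", "bad")) {
    m <- x$by_convention[[pc]]
    cat(sprintf(
      "  positive=%s: precision %.4f  recall %.4f  F1 %.4f\n", pc,
      m$precision, m$recall, m$f1))
  }
  invisible(x)
}

#' Evaluate a trained model on a labeled dataset
#'
#' @param model A trained [build_model()] handle.
#' @param ds A [colony_dataset()]; items are preprocessed with `preprocess`
#'   before the forward pass.
#' @param preprocess A [preprocess_spec()] (default: plain resize to the
#'   model input).
#' @param threshold Decision threshold.
#' @return An [evaluate_predictions()] report.
#' @export
evaluate_model <- function(model, ds, preprocess = NULL, threshold = 0.5) {
  side <- model$architecture$input_side
  if (is.null(preprocess))
    preprocess <- preprocess_spec("none", target_side_px = side)
  items <- lapply(ds$items, apply_preprocess, spec = preprocess)
  scores <- forward(model, as_batch(items, side,
                                    model$architecture$in_channels))
  evaluate_predictions(dataset_labels(ds), scores, threshold)
}
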