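# Scalar evaluation: confusion counts, accuracy / precision / recall / F1,
# exact rank-based AUC, and the per-country breakdown.

#' Confusion counts
#'
#' `"yes"` is the positive class: TP = predicted yes & truth yes, TN =
#' predicted no & truth no, FP = predicted yes & truth no, FN = predicted no
#' & truth yes.
#'
#' @param truth,pred equal-length `"yes"`/`"no"` vectors.
#' @return Object of class `confusion_counts`: named list `TP`, `FN`, `FP`,
#'   `TN` summing to the record count.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) == 0L) stop("confusion requires at least one record")
  stopifnot(length(truth) == length(pred))
  structure(list(
    TP = sum(pred == "yes" & truth == "yes"),
    FN = sum(pred == "no" & truth == "yes"),
    FP = sum(pred == "yes" & truth == "no"),
    TN = sum(pred == "no" & truth == "no")
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2,
              dimnames = list(predicted = c("yes", "no"),
                              truth = c("yes", "no")))
  print(m)
  invisible(x)
}

#' Scalar classification metrics from confusion counts
#'
#' Accuracy (TP+TN)/N, precision TP/(TP+FP), recall TP/(TP+FN) and their
#' harmonic mean F1. Any zero denominator yields 0, with a warning, so
#' per-country tables always render.
#'
#' @param counts a [confusion_counts()] object (or list with TP/FN/FP/TN).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0L) stop("empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; returning 0", call. = FALSE)
      0
    } else num / den
  }
  precision <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  recall <- safe_div(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = (counts$TP + counts$TN) / n,
    precision = precision, recall = recall, f1 = f1)
}

#' Exact rank-based AUC
#'
#' The Mann-Whitney statistic: the probability that a random positive's score
#' exceeds a random negative's, with ties given half credit — computed
#' exactly over all positive x negative pairs via average ranks.
#'
#' @param truth `"yes"`/`"no"` (or logical/0-1) ground truth.
#' @param score numeric positive-class scores.
#' @return AUC in `[0, 1]`; error if only one class is present.
#' @export
auc_score <- function(truth, score) {
  y <- if (is.character(truth) || is.factor(truth))
    as.character(truth) == "yes" else as.logical(truth)
  stopifnot(length(y) == length(score))
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0L || nneg == 0L)
    stop("AUC is undefined: both classes must be present")
  r <- rank(score)
  (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
}

.metrics_for <- function(rec, average) {
  cc <- confusion_counts(rec$truth, rec$pred)
  m <- suppressWarnings(classification_metrics(cc))
  if (average == "macro") {
    # class-averaged: treat each class as positive in turn
    swap <- list(TP = cc$TN, TN = cc$TP, FP = cc$FN, FN = cc$FP)
    m2 <- suppressWarnings(classification_metrics(swap))
    m[c("precision", "recall", "f1")] <-
      (m[c("precision", "recall", "f1")] + m2[c("precision", "recall", "f1")]) / 2
  }
  auc <- if (length(unique(rec$truth)) == 2L)
    auc_score(rec$truth, rec$score) else NA_real_
  list(counts = cc, metrics = c(m, auc = auc))
}

#' Evaluate prediction records
#'
#' Overall confusion counts and metrics (micro by default: pooled counts;
#' `average = "macro"` class-averages precision/recall/F1), the exact
#' rank-based AUC from the positive-vote scores, mean fit/predict seconds,
#' and the same metrics per country. Countries whose truth has a single
#' class get `auc = NA` (undefined, not 0).
#'
#' @param records prediction records (see [predict.locustlens()]).
#' @param average `"micro"` or `"macro"`.
#' @return Object of class `locustlens_eval`.
#' @export
evaluate_predictions <- function(records, average = c("micro", "macro")) {
  average <- match.arg(average)
  if (anyNA(records$truth))
    stop("evaluation requires labelled records")
  overall <- .metrics_for(records, average)
  countries <- sort(unique(records$country))
  per_country <- do.call(rbind, lapply(countries, function(cn) {
    r <- records[records$country == cn, , drop = FALSE]
    m <- .metrics_for(r, average)
    data.frame(country = cn, n = nrow(r), t(m$metrics))
  }))
  rownames(per_country) <- NULL
  structure(list(
    counts = overall$counts,
    metrics = overall$metrics,
    per_country = per_country,
    average = average,
    n = nrow(records),
    mean_fit_s = if ("fit_s" %in% names(records))
      mean(records$fit_s) else NA_real_,
    mean_predict_s = if ("predict_s" %in% names(records))
      mean(records$predict_s) else NA_real_
  ), class = "locustlens_eval")
}

#' @export
print.locustlens_eval <- function(x, digits = 4, ...) {
  cat("Evaluation of", x$n, "predictions (", x$average, "averaging )\n\n")
  print(x$counts)
  cat("\n")
  print(round(x$metrics, digits))
  if (is.finite(x$mean_fit_s))
    cat(sprintf("\nmean fit time %.4g s, mean predict time %.4g s per sample\n",
                x$mean_fit_s, x$mean_predict_s))
  cat("\nPer country:\n")
  pc <- x$per_country
  pc[-(1:2)] <- lapply(pc[-(1:2)], round, digits)
  print(pc)
  invisible(x)
}

#' Plot per-country accuracy
#'
#' @param x a `locustlens_eval`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.locustlens_eval <- function(x, ...) {
  graphics::barplot(x$per_country$accuracy,
                    names.arg = x$per_country$country,
                    ylim = c(0, 1), ylab = "accuracy",
                    main = "Per-country accuracy", ...)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param eval a `locustlens_eval`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  jsonlite::write_json(list(
    n = eval$n,
    average = eval$average,
    confusion = unclass(eval$counts),
    metrics = as.list(eval$metrics),
    per_country = eval$per_country,
    mean_fit_s = eval$mean_fit_s,
    mean_predict_s = eval$mean_predict_s
  ), path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
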