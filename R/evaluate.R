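# Confusion-matrix evaluation: overall accuracy, sensitivity, specificity,
# precision and F-measure (all as percentages), plus a per-class
# precision/recall/F1/support report.

#' Confusion counts for a declared positive class
#'
#' @param truth,pred equal-length label vectors.
#' @param positive the label treated as positive.
#' @return list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ", call. = FALSE)
  if (length(truth) == 0L) stop("no observations", call. = FALSE)
  t_pos <- truth == positive
  p_pos <- pred == positive
  list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
       fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
}

#' Evaluation metrics from confusion counts
#'
#' Accuracy = (TP+TN)/total, sensitivity (recall) = TP/(TP+FN), specificity =
#' TN/(TN+FP), precision = TP/(TP+FP), all expressed as percentages, and
#' F-measure = 2 * precision * sensitivity / (precision + sensitivity).
#' A zero denominator yields 0 with a warning.
#'
#' @param c list with `tp`, `tn`, `fp`, `fn` (see [confusion_counts()]).
#' @return named list of percentages: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f_measure`.
#' @export
eval_metrics <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  rate <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; returning 0", call. = FALSE)
      return(0)
    }
    100 * num / den
  }
  acc <- 100 * (c$tp + c$tn) / total
  sens <- rate(c$tp, c$tp + c$fn, "sensitivity")
  spec <- rate(c$tn, c$tn + c$fp, "specificity")
  prec <- rate(c$tp, c$tp + c$fp, "precision")
  f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       precision = prec, f_measure = f)
}

#' Per-class classification report
#'
#' One precision/recall/F1/support row per class, each computed with that
#' class as positive, on the 0-1 scale (multiply by 100 for percentages).
#'
#' @param truth,pred equal-length label vectors.
#' @param classes classes to report (default: classes observed in `truth`).
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`. Values are stored at full precision; round to 2 decimals for
#'   display.
#' @export
per_class_report <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(as.character(truth)))
  unseen <- setdiff(unique(as.character(pred)), classes)
  if (length(unseen))
    warning("predicted class(es) absent from `classes`: ",
            paste(unseen, collapse = ", "), call. = FALSE)
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(truth, pred, positive = cl)
    prec <- if (cc$tp + cc$fp == 0) 0 else cc$tp / (cc$tp + cc$fp)
    rec <- if (cc$tp + cc$fn == 0) 0 else cc$tp / (cc$tp + cc$fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = cc$tp + cc$fn)
  })
  do.call(rbind, rows)
}
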