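# Imbalance-aware evaluation: confusion matrix, one-vs-rest TP/FP/TN/FN,
# per-class and aggregate accuracy/recall/precision/specificity/F1, and
# per-class precision-recall curves with average precision.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of beats with true class `i - 1` predicted
#' as class `j - 1` (rows = truth, columns = prediction; labels 0-based).
#'
#' @param y_true,y_pred 0-based integer label vectors of equal length.
#' @param n_classes Number of classes C (default 8).
#' @return C x C integer matrix with class names on both dimensions.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 8L) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) && (min(y_true, y_pred) < 0L ||
                         max(y_true, y_pred) >= n_classes)) {
    stop("labels must lie in [0, n_classes)")
  }
  m <- matrix(0L, n_classes, n_classes)
  for (k in seq_along(y_true)) {
    m[y_true[[k]] + 1L, y_pred[[k]] + 1L] <- m[y_true[[k]] + 1L, y_pred[[k]] + 1L] + 1L
  }
  nm <- if (n_classes == 8L) beat_classes() else as.character(seq_len(n_classes) - 1L)
  dimnames(m) <- list(true = nm, predicted = nm)
  m
}

#' One-vs-rest counts for a class
#'
#' Reduces a multiclass confusion matrix to binary counts for one class:
#' `TP` is the diagonal cell, `FN` the rest of the row, `FP` the rest of
#' the column, `TN` the remainder. The four counts always partition the
#' total number of beats.
#'
#' @param m Confusion matrix (as from [confusion_matrix()]).
#' @param class 0-based class index.
#' @return Named integer vector with `TP`, `FP`, `TN`, `FN`.
#' @export
one_vs_rest_counts <- function(m, class) {
  i <- as.integer(class) + 1L
  stopifnot(i >= 1L, i <= nrow(m))
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Classification report
#'
#' Per-class one-vs-rest recall (`RE = TP/(TP+FN)`), precision
#' (`PR = TP/(TP+FP)`), specificity (`SP = TN/(TN+FP)`) and
#' `F1 = 2*RE*PR/(RE+PR)`, plus overall accuracy (`ACC = trace/total`)
#' and two aggregates of each per-class metric: the support-weighted mean
#' (weights = per-class true counts; this makes aggregate recall equal
#' overall accuracy identically) and the unweighted macro mean. Metric
#' cells that are 0/0 (a class absent from truth or predictions) are
#' reported as 0 and flagged.
#'
#' @param m Confusion matrix with positive total.
#' @return Object of class `beat_eval`: list with `per_class` (data
#'   frame), `weighted`, `macro` (named vectors RE/PR/SP/F1), `accuracy`,
#'   `support`, `confusion`, `degenerate` (logical flag that some 0/0
#'   metric was zero-filled).
#' @export
classification_report <- function(m) {
  total <- sum(m)
  if (total <= 0) stop("empty confusion matrix")
  C <- nrow(m)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  per <- data.frame(class = seq_len(C) - 1L,
                    name = rownames(m) %||% as.character(seq_len(C) - 1L),
                    support = as.integer(rowSums(m)),
                    RE = 0, PR = 0, SP = 0, F1 = 0)
  degenerate <- FALSE
  for (k in seq_len(C)) {
    cc <- one_vs_rest_counts(m, k - 1L)
    if ((cc[["TP"]] + cc[["FN"]]) == 0L || (cc[["TP"]] + cc[["FP"]]) == 0L) {
      degenerate <- TRUE
    }
    per$RE[k] <- safe_div(cc[["TP"]], cc[["TP"]] + cc[["FN"]])
    per$PR[k] <- safe_div(cc[["TP"]], cc[["TP"]] + cc[["FP"]])
    per$SP[k] <- safe_div(cc[["TN"]], cc[["TN"]] + cc[["FP"]])
    per$F1[k] <- safe_div(2 * per$RE[k] * per$PR[k], per$RE[k] + per$PR[k])
  }
  w <- per$support / total
  agg <- function(v, weights) sum(v * weights)
  weighted <- c(RE = agg(per$RE, w), PR = agg(per$PR, w),
                SP = agg(per$SP, w), F1 = agg(per$F1, w))
  macro <- c(RE = mean(per$RE), PR = mean(per$PR),
             SP = mean(per$SP), F1 = mean(per$F1))
  if (degenerate) {
    warning("some one-vs-rest metrics were 0/0 and reported as 0")
  }
  structure(
    list(per_class = per, weighted = weighted, macro = macro,
         accuracy = sum(diag(m)) / total, support = per$support,
         confusion = m, degenerate = degenerate),
    class = "beat_eval"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beat_eval <- function(x, digits = 2, ...) {
  cat(sprintf("Classification report (%d beats)\n", sum(x$confusion)))
  per <- x$per_class
  tab <- data.frame(class = per$name, support = per$support,
                    `ACC%` = NA, `RE%` = round(100 * per$RE, digits),
                    `SP%` = round(100 * per$SP, digits),
                    `PR%` = round(100 * per$PR, digits),
                    `F1%` = round(100 * per$F1, digits),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat(sprintf("weighted: ACC %.2f%%  RE %.2f%%  SP %.2f%%  PR %.2f%%  F1 %.2f%%\n",
              100 * x$accuracy, 100 * x$weighted[["RE"]],
              100 * x$weighted[["SP"]], 100 * x$weighted[["PR"]],
              100 * x$weighted[["F1"]]))
  invisible(x)
}

#' Evaluate a fitted model on a dataset
#'
#' Convenience wrapper: predict, build the confusion matrix, and compute
#' the classification report.
#'
#' @param model Fitted `ecg_lstm`. @param ds `beat_dataset` (or list with
#'   `x` and `y`).
#' @return A `beat_eval` report with the probability matrix attached as
#'   attribute `prob`.
#' @export
evaluate_model <- function(model, ds) {
  xy <- .as_xy(ds, ds$y)
  pred <- predict(model, xy$x, type = "both")
  rep <- classification_report(confusion_matrix(xy$y, pred$label, 8L))
  attr(rep, "prob") <- pred$prob
  rep
}

#' Precision-recall curve with average precision
#'
#' One-vs-rest precision/recall at every distinct score threshold
#' (thresholds descending, so recall is nondecreasing along the curve).
#' The area is the step-wise average precision `sum((R_i - R_(i-1)) P_i)`
#' (no trapezoidal interpolation), which is invariant to strictly
#' monotone transformations of the scores.
#'
#' @param y_true_binary Logical/0-1 indicator of the positive class; at
#'   least one positive required.
#' @param scores Predicted scores (e.g. the class's softmax probability).
#' @return Object of class `pr_curve`: list with `recall`, `precision`,
#'   `threshold` (parallel vectors) and `area` (average precision).
#' @export
pr_curve <- function(y_true_binary, scores) {
  y <- as.integer(as.logical(y_true_binary))
  stopifnot(length(y) == length(scores))
  n_pos <- sum(y)
  if (n_pos == 0L) stop("pr_curve requires at least one positive example")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp_cum <- cumsum(y)
  fp_cum <- cumsum(1L - y)
  last_of_threshold <- c(diff(s) != 0, TRUE)   # last index of each tie group
  tp <- tp_cum[last_of_threshold]
  fp <- fp_cum[last_of_threshold]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  area <- sum(diff(c(0, recall)) * precision)
  structure(list(recall = recall, precision = precision,
                 threshold = s[last_of_threshold], area = area),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("PR curve: %d threshold points, average precision %.4f\n",
              length(x$recall), x$area))
  invisible(x)
}

#' Plot a PR curve
#'
#' @param x A `pr_curve`. @param ... Passed to [graphics::plot()].
#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(c(0, x$recall), c(1, x$precision), type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "recall", ylab = "precision", ...)
  invisible(x)
}

#' Per-class PR curves from an evaluation
#'
#' @param report `beat_eval` from [evaluate_model()] (needs the attached
#'   probability matrix).
#' @param y_true 0-based true labels matching the probabilities.
#' @return Named list of `pr_curve` objects, one per class present in
#'   `y_true`.
#' @export
per_class_pr_curves <- function(report, y_true) {
  prob <- attr(report, "prob")
  if (is.null(prob)) stop("report has no attached probability matrix")
  present <- sort(unique(as.integer(y_true)))
  curves <- lapply(present, function(cl) pr_curve(y_true == cl, prob[, cl + 1L]))
  names(curves) <- beat_classes()[present + 1L]
  curves
}

#' Write a classification report to CSV
#'
#' One row per class plus `weighted` and `macro` aggregate rows; columns
#' `class`, `support`, `ACC`, `RE`, `SP`, `PR`, `F1` (percentages).
#'
#' @param report A `beat_eval`. @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_report_csv <- function(report, path) {
  per <- report$per_class
  rows <- data.frame(class = per$name, support = per$support,
                     ACC = NA_real_, RE = 100 * per$RE, SP = 100 * per$SP,
                     PR = 100 * per$PR, F1 = 100 * per$F1)
  agg <- data.frame(
    class = c("weighted", "macro"),
    support = rep(sum(per$support), 2L),
    ACC = c(100 * report$accuracy, 100 * report$accuracy),
    RE = 100 * c(report$weighted[["RE"]], report$macro[["RE"]]),
    SP = 100 * c(report$weighted[["SP"]], report$macro[["SP"]]),
    PR = 100 * c(report$weighted[["PR"]], report$macro[["PR"]]),
    F1 = 100 * c(report$weighted[["F1"]], report$macro[["F1"]])
  )
  utils::write.csv(rbind(rows, agg), path, row.names = FALSE)
  invisible(path)
}
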