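#' Confusion counts for binary classification
#'
#' The positive class is the substrate class, label 1.
#'
#' @param y_true,y_pred Vectors of labels in \{0, 1\}, equal length.
#' @return Named integer vector \code{c(TP, TN, FP, FN)}.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0 (non-substrate) or 1 (substrate)")
  }
  c(TP = sum(y_true == 1 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FP = sum(y_true == 0 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0))
}

#' Classification performance statistics
#'
#' Computes accuracy, sensitivity and specificity (as percentages) and the
#' Matthews correlation coefficient from confusion counts:
#' \deqn{ACC = 100 (TP+TN)/N, \quad SE = 100\, TP/(TP+FN), \quad
#'       SP = 100\, TN/(TN+FP)}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'       {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' MCC = 1 is a perfect prediction and MCC = 0 a random one; when any factor
#' of the denominator is zero, MCC is defined as 0 (standard convention).
#' SE or SP with a zero denominator is reported as \code{NA} (not
#' applicable). Percentages keep full precision internally; rounding is a
#' display concern only.
#'
#' @param TP,TN,FP,FN Non-negative confusion counts (or pass the vector from
#'   \code{\link{confusion}} as \code{TP}).
#' @param set_name Free-text name of the evaluated set.
#' @return An object of class \code{eval_report}: list with the counts,
#'   \code{ACC}, \code{SE}, \code{SP} (percent), \code{MCC} and
#'   \code{set_name}.
#' @export
classification_metrics <- function(TP, TN = NULL, FP = NULL, FN = NULL,
                                   set_name = "") {
  if (length(TP) == 4L && is.null(TN)) {
    cnt <- TP; TP <- cnt[["TP"]]; TN <- cnt[["TN"]]
    FP <- cnt[["FP"]]; FN <- cnt[["FN"]]
  }
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("cannot compute metrics on zero evaluated samples")
  acc <- 100 * (TP + TN) / total
  se <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
  } else 0
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 ACC = acc, SE = se, SP = sp, MCC = mcc,
                 set_name = set_name),
            class = "eval_report")
}

#' Evaluate predictions against true labels
#'
#' @inheritParams confusion
#' @param set_name Name of the evaluated set.
#' @return An \code{eval_report}.
#' @export
evaluate_predictions <- function(y_true, y_pred, set_name = "") {
  classification_metrics(confusion(y_true, y_pred), set_name = set_name)
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat(sprintf("<eval_report%s> n=%d  ACC=%.*f  SP=%.*f  SE=%.*f  MCC=%.4f\n",
              if (nzchar(x$set_name)) paste0(" ", x$set_name) else "",
              x$TP + x$TN + x$FP + x$FN,
              digits, x$ACC, digits, x$SP, digits, x$SE, x$MCC))
  invisible(x)
}

#' Write a performance report table
#'
#' Tab-separated table with one row per evaluated set and the column layout
#' Data Set / ACC / SP / SE / MCC.
#'
#' @param reports A list of \code{eval_report} objects.
#' @param file Output path (or \code{""} for stdout).
#' @param digits Display rounding for the percentage columns.
#' @return The formatted data frame, invisibly.
#' @export
write_report_table <- function(reports, file = "", digits = 2) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  df <- data.frame(
    `Data Set` = vapply(reports, function(r) r$set_name, character(1)),
    ACC = round(vapply(reports, function(r) r$ACC, numeric(1)), digits),
    SP = round(vapply(reports, function(r) r$SP, numeric(1)), digits),
    SE = round(vapply(reports, function(r) r$SE, numeric(1)), digits),
    MCC = round(vapply(reports, function(r) r$MCC, numeric(1)), 4),
    check.names = FALSE)
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
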