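# Evaluation utilities: precision/recall/F1 and the precision-recall curve
# with trapezoidal area, used to score the pipeline on labeled fixtures.

#' Precision, recall and F1 from confusion counts
#'
#' Denominator-zero cases return 0 by convention so threshold sweeps never
#' crash.
#'
#' @param tp,fp,tn,fn Confusion counts (all >= 0). Alternatively pass a
#'   single named vector/list as \code{tp}.
#' @return Named numeric \code{c(precision=, recall=, f1=)}.
#' @export
prf1 <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && (is.list(tp) || length(tp) == 4L)) {
    cc <- tp; tp <- cc[["TP"]]; fp <- cc[["FP"]]
    tn <- cc[["TN"]]; fn <- cc[["FN"]]
  }
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth Vectors of \code{"plasmid"}/\code{"non-plasmid"}
#'   labels (or logical, plasmid = \code{TRUE}).
#' @return Named integer vector \code{TP, FP, TN, FN}.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- if (is.logical(predicted)) predicted else predicted == "plasmid"
  t <- if (is.logical(truth)) truth else truth == "plasmid"
  stopifnot(length(p) == length(t))
  c(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

#' Precision-recall curve and its area
#'
#' Sweeps the decision threshold over the unique scores (ties grouped),
#' predicting positive at score >= threshold, and integrates precision over
#' recall with the trapezoidal rule, anchoring the curve at recall 0 with
#' the precision of the most stringent threshold.
#'
#' @param scores Numeric scores (higher = more plasmid-like).
#' @param truth Logical or \code{"plasmid"}/\code{"non-plasmid"} labels;
#'   both classes must be present.
#' @return List with \code{curve} (data.frame \code{threshold},
#'   \code{recall}, \code{precision}) and \code{area}.
#' @export
pr_curve <- function(scores, truth) {
  t <- if (is.logical(truth)) truth else truth == "plasmid"
  stopifnot(length(scores) == length(t))
  if (all(t) || !any(t)) {
    stop("pr_curve needs both classes in `truth`")
  }
  th <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    cc <- confusion_counts(pred, t)
    m <- prf1(cc["TP"], cc["FP"], cc["TN"], cc["FN"])
    rec[i] <- m["recall"]; prec[i] <- m["precision"]
  }
  r <- c(0, rec); p <- c(prec[1L], prec)
  area <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  list(curve = data.frame(threshold = th, recall = rec, precision = prec),
       area = area)
}
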