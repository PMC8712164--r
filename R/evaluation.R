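#' Confusion matrix with cancerous as the positive class
#'
#' @param y_true,y_pred Label vectors (+1/-1 or "cancerous"/"healthy") of
#'   equal length.
#' @return A `confusion_matrix`: list with integer counts `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  yt <- as_signed_label(y_true)
  yp <- as_signed_label(y_pred)
  if (length(yt) != length(yp))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  structure(list(tp = sum(yt == 1 & yp == 1),
                 fn = sum(yt == 1 & yp == -1),
                 fp = sum(yt == -1 & yp == 1),
                 tn = sum(yt == -1 & yp == -1)),
            class = "confusion_matrix")
}

#' Build a confusion matrix from raw counts
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (positive = cancerous)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("true cancerous", "true healthy"),
                              c("pred cancerous", "pred healthy")))
  print(m)
  invisible(x)
}

#' Accuracy, precision, recall and F1 as percentages
#'
#' `accuracy = 100 (tp + tn) / total`, `precision = 100 tp / (tp + fp)`,
#' `recall = 100 tp / (tp + fn)`, `f1 = 2 p r / (p + r)`. A metric whose
#' denominator is zero is reported as `NA` (undefined) rather than silently
#' zero-filled.
#'
#' @param cm A `confusion_matrix`.
#' @return Named list `accuracy`, `precision`, `recall`, `f1` (percent).
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  acc <- safe(cm$tp + cm$tn, total)
  prec <- safe(cm$tp, cm$tp + cm$fp)
  rec <- safe(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Five-number summaries of the nine features
#'
#' Per-feature `min / Q1 / median / Q3 / max` (quartiles by linear
#' interpolation, the default quantile definition), over the eight scalar
#' texture features plus, when a HOG block is present, its per-image mean
#' as the ninth row.
#'
#' @param features Feature data.frame from [extract_feature_table()].
#' @return Data.frame with columns `feature`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
boxplot_table <- function(features) {
  if (!is.data.frame(features) || nrow(features) < 1L)
    stop("`features` must be a non-empty data.frame", call. = FALSE)
  cols <- intersect(FEATURE_NAMES, names(features))
  vals <- features[cols]
  hog_cols <- grep("^hog_", names(features), value = TRUE)
  if (length(hog_cols) > 0)
    vals$hog <- rowMeans(features[hog_cols])
  summaries <- lapply(names(vals), function(nm) {
    q <- stats::quantile(vals[[nm]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(feature = nm, min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, summaries)
}
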