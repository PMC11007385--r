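# Confusion matrices and derived performance metrics.

#' Confusion matrix with a fixed class order
#'
#' @param truth,predicted Equal-length label vectors; every label must be in
#'   `classes`.
#' @param classes Ordered class labels (default: union in order of first
#'   appearance in `truth` then `predicted`).
#' @return Integer matrix of class `somno_cm`, rows = true class, columns =
#'   predicted class.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (is.null(classes)) classes <- unique(c(truth, predicted))
  unknown <- setdiff(unique(c(truth, predicted)), classes)
  if (length(unknown)) {
    stop("labels outside class_order: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- unclass(matrix(as.integer(cm), nrow = length(classes),
                       dimnames = list(true = classes, predicted = classes)))
  structure(cm, class = c("somno_cm", "matrix"))
}

#' Per-class precision, sensitivity, specificity and overall accuracy
#'
#' One-vs-rest definitions per class; a ratio with a zero denominator (for
#' example precision of a never-predicted class) is reported as `NA` and
#' listed in `$undefined` rather than silently coerced to 0.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `per_class` (data frame: class, precision, sensitivity,
#'   specificity), `accuracy`, and `undefined` (character vector of
#'   "metric:class" tags).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "somno_cm"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  undef <- character(0)
  per <- data.frame(class = classes, precision = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(classes)) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k]); tn <- total - tp - fp - fn
    per$precision[k] <- ratio(tp, tp + fp)
    per$sensitivity[k] <- ratio(tp, tp + fn)
    per$specificity[k] <- ratio(tn, tn + fp)
    for (m in c("precision", "sensitivity", "specificity")) {
      if (is.na(per[[m]][k])) undef <- c(undef, paste0(m, ":", classes[k]))
    }
  }
  list(per_class = per, accuracy = sum(diag(cm)) / total, undefined = undef)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with \eqn{p_o} the observed and
#' \eqn{p_e} the expected (marginal-product) agreement. In the degenerate
#' case \eqn{p_e = 1} (all mass in one cell), kappa is defined as 1 when
#' agreement is perfect and 0 otherwise.
#'
#' @param cm A [confusion_matrix()].
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(cm) {
  stopifnot(inherits(cm, "somno_cm"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (1 - pe < .Machine$double.eps) {
    return(if (po >= 1 - .Machine$double.eps) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' ROC curve and area under the curve
#'
#' Threshold sweep over the unique decision scores (ties included
#' simultaneously); AUC by trapezoidal integration, which equals the
#' tie-corrected rank statistic \eqn{U / (n_1 n_0)}.
#'
#' @param scores Numeric decision values (larger = more positive-like).
#' @param labels Binary labels, same length.
#' @param positive The label treated as positive (default: second sorted
#'   unique label).
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("need exactly two classes present", call. = FALSE)
  if (is.null(positive)) positive <- lv[2]
  pos <- labels == positive
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(pos); n0 <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n0, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

#' Bundle a confusion matrix and its metrics into an evaluation report
#'
#' @param cm A [confusion_matrix()].
#' @param meta Named list of protocol metadata (train/test rats, model id,
#'   ...); train and test rat sets, when both present, must be disjoint.
#' @param roc Optional [roc_auc()] result for binary tasks.
#' @return Object of class `somno_report` with elements `confusion`,
#'   `metrics`, `kappa`, `roc`, `meta`.
#' @export
evaluation_report <- function(cm, meta = list(), roc = NULL) {
  if (!is.null(meta$train_rats) && !is.null(meta$test_rats) &&
      length(intersect(meta$train_rats, meta$test_rats))) {
    stop("train and test rat sets overlap", call. = FALSE)
  }
  structure(
    list(confusion = cm, metrics = classification_metrics(cm),
         kappa = cohens_kappa(cm), roc = roc, meta = meta),
    class = "somno_report"
  )
}

#' @export
print.somno_report <- function(x, digits = 3, ...) {
  cat("<somno_report>")
  if (!is.null(x$meta$label)) cat(" ", x$meta$label)
  cat("\n")
  print(unclass(x$confusion))
  cat(sprintf("accuracy %.*f, kappa %.*f", digits, x$metrics$accuracy,
              digits, x$kappa))
  if (!is.null(x$roc)) cat(sprintf(", AUC %.*f", digits, x$roc$auc))
  cat("\n")
  invisible(x)
}

# stable JSON-ready representation of a report's metrics
report_metrics_list <- function(report) {
  pc <- report$metrics$per_class
  list(
    accuracy = report$metrics$accuracy,
    kappa = report$kappa,
    per_class = stats::setNames(
      lapply(seq_len(nrow(pc)), function(i) {
        list(precision = pc$precision[i], sensitivity = pc$sensitivity[i],
             specificity = pc$specificity[i])
      }),
      pc$class),
    undefined = report$metrics$undefined,
    auc = if (is.null(report$roc)) NULL else report$roc$auc
  )
}
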