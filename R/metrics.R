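# Ordinal and agreement metrics, all computable from the confusion matrix
# alone. Classes are 0..p-1 with unit spacing between consecutive classes.
# Degenerate denominators (e.g. constant predictions) yield 0 with a warning
# rather than an error, mirroring the behavior needed for collapsed models.

#' Confusion matrix for ordinal labels
#'
#' @param y_true,y_pred integer labels in `0..p-1` (equal length; may be
#'   empty, giving an all-zero matrix).
#' @param p class count.
#' @return `p x p` integer matrix, rows = true class, columns = predicted
#'   class, dimnames `0..p-1`.
#' @export
confusion_matrix <- function(y_true, y_pred, p) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) &&
      (any(y_true < 0 | y_true >= p) || any(y_pred < 0 | y_pred >= p)))
    stop("labels must lie in 0..p-1")
  cm <- matrix(0L, p, p, dimnames = list(true = 0:(p - 1), pred = 0:(p - 1)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

.as_cm <- function(y_true, y_pred, cm, p) {
  if (!is.null(cm)) return(cm)
  p <- p %||% (max(c(y_true, y_pred)) + 1L)
  confusion_matrix(y_true, y_pred, p)
}

.deg0 <- function(what) {
  warning(sprintf("%s: degenerate denominator, returning 0", what))
  structure(0, degenerate = TRUE)
}

#' Ordinal and agreement metrics
#'
#' Each metric accepts either true/predicted label vectors or a precomputed
#' confusion matrix (`cm`); every metric is a function of the confusion
#' matrix alone. `metric_mae` is the mean absolute class error under unit
#' spacing; `metric_balanced_accuracy` is the mean per-class recall;
#' `metric_macro_f1` the unweighted mean of per-class F1 (0 for a class with
#' undefined F1); `metric_cohen_kappa` the chance-corrected agreement
#' \eqn{(p_o - p_e)/(1 - p_e)}; `metric_mcc` the multiclass Matthews
#' correlation in its covariance form. Degenerate denominators return 0
#' with a warning (attribute `degenerate`).
#'
#' @param y_true,y_pred integer labels in `0..p-1`.
#' @param cm optional confusion matrix (rows true, columns predicted).
#' @param p class count (inferred when omitted).
#' @name ordpair_metrics
NULL

#' @rdname ordpair_metrics
#' @export
metric_mae <- function(y_true = NULL, y_pred = NULL, cm = NULL, p = NULL) {
  cm <- .as_cm(y_true, y_pred, cm, p)
  n <- sum(cm)
  if (n == 0) return(.deg0("metric_mae"))
  d <- abs(row(cm) - col(cm))
  sum(cm * d) / n
}

#' @rdname ordpair_metrics
#' @export
metric_accuracy <- function(y_true = NULL, y_pred = NULL, cm = NULL, p = NULL) {
  cm <- .as_cm(y_true, y_pred, cm, p)
  n <- sum(cm)
  if (n == 0) return(.deg0("metric_accuracy"))
  sum(diag(cm)) / n
}

#' @rdname ordpair_metrics
#' @export
metric_balanced_accuracy <- function(y_true = NULL, y_pred = NULL, cm = NULL,
                                     p = NULL) {
  cm <- .as_cm(y_true, y_pred, cm, p)
  support <- rowSums(cm)
  if (all(support == 0)) return(.deg0("metric_balanced_accuracy"))
  rec <- ifelse(support > 0, diag(cm) / support, NA_real_)
  if (anyNA(rec))
    warning("metric_balanced_accuracy: class(es) with no support scored as 0")
  mean(ifelse(is.na(rec), 0, rec))
}

#' @rdname ordpair_metrics
#' @export
metric_macro_f1 <- function(y_true = NULL, y_pred = NULL, cm = NULL, p = NULL) {
  cm <- .as_cm(y_true, y_pred, cm, p)
  if (sum(cm) == 0) return(.deg0("metric_macro_f1"))
  f1 <- vapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    denom <- rowSums(cm)[k] + colSums(cm)[k] # 2TP + FP + FN
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))
  mean(f1)
}

#' @rdname ordpair_metrics
#' @export
metric_cohen_kappa <- function(y_true = NULL, y_pred = NULL, cm = NULL,
                               p = NULL) {
  cm <- .as_cm(y_true, y_pred, cm, p)
  n <- sum(cm)
  if (n == 0) return(.deg0("metric_cohen_kappa"))
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5)
    return(.deg0("metric_cohen_kappa"))
  (po - pe) / (1 - pe)
}

#' @rdname ordpair_metrics
#' @export
metric_mcc <- function(y_true = NULL, y_pred = NULL, cm = NULL, p = NULL) {
  cm <- .as_cm(y_true, y_pred, cm, p)
  s <- sum(cm)
  if (s == 0) return(.deg0("metric_mcc"))
  c0 <- sum(diag(cm))
  tk <- rowSums(cm)
  pk <- colSums(cm)
  denom <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (denom == 0) return(.deg0("metric_mcc"))
  (c0 * s - sum(tk * pk)) / denom
}

#' All standard metrics at once
#'
#' @inheritParams ordpair_metrics
#' @return data frame with columns `metric`, `value`, `degenerate`.
#' @export
ordinal_metrics <- function(y_true = NULL, y_pred = NULL, cm = NULL, p = NULL) {
  cm <- .as_cm(y_true, y_pred, cm, p)
  fns <- list(mae = metric_mae, accuracy = metric_accuracy,
              balanced_accuracy = metric_balanced_accuracy,
              macro_f1 = metric_macro_f1, cohen_kappa = metric_cohen_kappa,
              mcc = metric_mcc)
  vals <- lapply(fns, function(f) suppressWarnings(f(cm = cm)))
  data.frame(metric = names(fns),
             value = vapply(vals, as.numeric, numeric(1)),
             degenerate = vapply(vals, function(v)
               isTRUE(attr(v, "degenerate")), logical(1)),
             row.names = NULL)
}

#' Per-class recall (accuracy within each true class)
#'
#' @inheritParams ordpair_metrics
#' @return numeric vector of recalls, one per class.
#' @export
per_class_recall <- function(y_true = NULL, y_pred = NULL, cm = NULL, p = NULL) {
  cm <- .as_cm(y_true, y_pred, cm, p)
  support <- rowSums(cm)
  ifelse(support > 0, diag(cm) / support, NA_real_)
}
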