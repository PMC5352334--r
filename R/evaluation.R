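# Classifier evaluation against a gold standard: confusion counts,
# sensitivity/specificity/accuracy/error rate, continuity-corrected
# Wilson intervals and threshold sweeps.

#' Confusion counts at a threshold
#'
#' A pair is called positive when its score strictly exceeds the
#' threshold; calls are tallied against gold-standard labels (positive
#' class MSI-H).
#'
#' @param scores named numeric vector of per-pair scores, or data.frame
#'   with columns `pair_id`, `score`.
#' @param labels data.frame with columns `pair_id`, `label`
#'   (`"MSI-H"`/`"MSS"`), or a named character vector.
#' @param threshold decision threshold.
#' @return list of class `"msi_confusion"` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(scores, labels, threshold = 0.4) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$score, scores$pair_id)
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$pair_id)
  unlabeled <- setdiff(names(scores), names(labels))
  if (length(unlabeled))
    stop("scored pairs without a label: ",
         paste(unlabeled, collapse = ", "))
  lab <- labels[names(scores)]
  if (!all(lab %in% c("MSI-H", "MSS")))
    stop("labels must be 'MSI-H' or 'MSS'")
  call_pos <- scores > threshold
  truth_pos <- lab == "MSI-H"
  structure(list(
    tp = sum(call_pos & truth_pos),
    fp = sum(call_pos & !truth_pos),
    tn = sum(!call_pos & !truth_pos),
    fn = sum(!call_pos & truth_pos)
  ), class = "msi_confusion")
}

#' Performance metrics from confusion counts
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), error rate =
#' incorrect calls / total calls, accuracy = 1 - error rate. A metric
#' with a zero denominator is reported as NA (undefined), never 0.
#' 95% confidence intervals for sensitivity and specificity use the
#' Wilson score interval with continuity correction.
#'
#' @param counts an `"msi_confusion"` object or list with `tp`, `fp`,
#'   `tn`, `fn`.
#' @param conf confidence level for the intervals.
#' @return list of class `"msi_metrics"`: `sensitivity`, `specificity`,
#'   `accuracy`, `error_rate` (proportions in \[0,1\] or NA), and
#'   `sensitivity_ci`, `specificity_ci` (length-2 vectors or NULL).
#' @examples
#' metrics(list(tp = 38, fp = 1, tn = 37, fn = 0))
#' @export
metrics <- function(counts, conf = 0.95) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total < 1L) stop("confusion counts are empty")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  err <- (fp + fn) / total
  structure(list(
    sensitivity = sens,
    specificity = spec,
    accuracy = 1 - err,
    error_rate = err,
    sensitivity_ci = if (!is.na(sens)) wilson_ci(tp, tp + fn, conf) else NULL,
    specificity_ci = if (!is.na(spec)) wilson_ci(tn, tn + fp, conf) else NULL
  ), class = "msi_metrics")
}

#' @export
print.msi_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  ci <- function(v) if (is.null(v)) "" else
    sprintf(" (95%% CI %.1f-%.1f%%)", 100 * v[1], 100 * v[2])
  cat("Sensitivity: ", pct(x$sensitivity), ci(x$sensitivity_ci), "\n",
      "Specificity: ", pct(x$specificity), ci(x$specificity_ci), "\n",
      "Accuracy:    ", pct(x$accuracy), "\n",
      "Error rate:  ", pct(x$error_rate), "\n", sep = "")
  invisible(x)
}

#' Wilson score interval with continuity correction
#'
#' Closed-form continuity-corrected Wilson interval for a binomial
#' proportion, bounds clipped to \[0, 1\]; the lower bound is exactly 0
#' when no successes are observed and the upper bound exactly 1 when
#' all trials succeed.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  if (n < 1L) stop("n must be >= 1")
  if (successes < 0L || successes > n)
    stop("successes must be in [0, n]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  q <- 1 - p
  lower <- if (successes == 0L) 0 else
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * q + 1))) / (2 * (n + z^2))
  upper <- if (successes == n) 1 else
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * q - 1))) / (2 * (n + z^2))
  c(max(0, lower), min(1, upper))
}

#' Sweep classification thresholds
#'
#' Evaluates the confusion metrics at every threshold in the grid and
#' reports the accuracy-maximizing threshold (ties resolved to the
#' smallest threshold, for determinism).
#'
#' @param scores,labels as in [confusion()].
#' @param grid numeric vector of thresholds, e.g.
#'   `seq(0.001, 0.6, length.out = 600)`.
#' @return data.frame with one row per threshold (`threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `accuracy`,
#'   `error_rate`); the best threshold is attached as attribute
#'   `"best_threshold"`.
#' @export
threshold_sweep <- function(scores, labels, grid) {
  if (length(grid) == 0L) stop("threshold grid is empty")
  grid <- sort(grid)
  rows <- lapply(grid, function(th) {
    cm <- confusion(scores, labels, th)
    m <- metrics(cm)
    data.frame(threshold = th, tp = cm$tp, fp = cm$fp, tn = cm$tn,
               fn = cm$fn, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy,
               error_rate = m$error_rate)
  })
  out <- do.call(rbind, rows)
  best <- out$threshold[which.max(out$accuracy)]  # first max = smallest
  attr(out, "best_threshold") <- best
  out
}
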