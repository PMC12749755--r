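#' Confusion matrix and diagnostic summary against a reference standard
#'
#' Cross-tabulates predicted against reference severity flags and reports
#' sensitivity, specificity (Wilson score 95% CIs), and positive/negative
#' likelihood ratios `PLR = sens / (1 - spec)`, `NLR = (1 - sens) / spec`
#' (log-method 95% CIs). Division-by-zero cases (e.g. a perfect classifier)
#' are reported as `NA` with an `undefined` flag rather than silently
#' continuity-corrected; set `haldane = TRUE` to add 0.5 to every cell for
#' the likelihood-ratio estimates instead.
#'
#' @param predicted Logical vector of predicted positives.
#' @param reference Logical vector of reference positives (same length).
#' @param conf_level Confidence level (default 0.95).
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to the
#'   likelihood ratios when a cell is zero?
#'
#' @return A `diagnostic_summary`: list with `confusion` (tp, fp, fn, tn),
#'   `sensitivity`/`specificity` (%, with `ci`), `plr`/`nlr` (with `ci`),
#'   and `undefined` (character vector of quantities that hit division by
#'   zero).
#' @export
#' @examples
#' confusion_and_summary(c(TRUE, TRUE, FALSE, FALSE),
#'                       c(TRUE, FALSE, TRUE, FALSE))
confusion_and_summary <- function(predicted, reference, conf_level = 0.95,
                                  haldane = FALSE) {
  if (!length(predicted)) stop_af("empty input", class = "empty_input")
  if (length(predicted) != length(reference)) {
    stop_af("predicted and reference lengths differ", class = "invalid_pairs")
  }
  predicted <- as.logical(predicted)
  reference <- as.logical(reference)
  tp <- sum(predicted & reference)
  fp <- sum(predicted & !reference)
  fn <- sum(!predicted & reference)
  tn <- sum(!predicted & !reference)
  zc <- qnorm(1 - (1 - conf_level) / 2)

  wilson <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    p <- k / n
    den <- 1 + zc^2 / n
    ctr <- (p + zc^2 / (2 * n)) / den
    hw <- zc * sqrt(p * (1 - p) / n + zc^2 / (4 * n^2)) / den
    100 * c(ctr - hw, ctr + hw)
  }

  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  undefined <- character(0)
  if (is.na(sens)) undefined <- c(undefined, "sensitivity")
  if (is.na(spec)) undefined <- c(undefined, "specificity")

  lr_est <- function(a, b, c_, d) {
    # LR and log-method CI from counts (a/b vs c_/d); NA when degenerate
    if (any(c(a + b, c_ + d) == 0) || c_ == 0) return(list(est = NA_real_, ci = c(NA_real_, NA_real_)))
    est <- (a / (a + b)) / (c_ / (c_ + d))
    if (a == 0) return(list(est = est, ci = c(NA_real_, NA_real_)))
    se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
    list(est = est, ci = exp(log(est) + c(-1, 1) * zc * se))
  }

  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (haldane && any(cells == 0)) cells <- cells + 0.5
  # PLR = [tp/(tp+fn)] / [fp/(fp+tn)]; NLR = [fn/(tp+fn)] / [tn/(fp+tn)]
  plr <- lr_est(cells["tp"], cells["fn"], cells["fp"], cells["tn"])
  nlr <- lr_est(cells["fn"], cells["tp"], cells["tn"], cells["fp"])
  if (!haldane) {
    if (fp == 0) undefined <- c(undefined, "plr")
    if (tn == 0) undefined <- c(undefined, "nlr")
  }

  structure(list(
    confusion = list(tp = tp, fp = fp, fn = fn, tn = tn),
    sensitivity = list(estimate = 100 * sens, ci = wilson(tp, tp + fn)),
    specificity = list(estimate = 100 * spec, ci = wilson(tn, tn + fp)),
    plr = list(estimate = unname(plr$est), ci = unname(plr$ci)),
    nlr = list(estimate = unname(nlr$est), ci = unname(nlr$ci)),
    undefined = unique(undefined),
    n = length(predicted)
  ), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<diagnostic_summary> n=%d  TP=%d FP=%d FN=%d TN=%d\n",
              x$n, cm$tp, cm$fp, cm$fn, cm$tn))
  cat(sprintf("  sens %.1f%% (%.1f-%.1f)  spec %.1f%% (%.1f-%.1f)\n",
              x$sensitivity$estimate, x$sensitivity$ci[1], x$sensitivity$ci[2],
              x$specificity$estimate, x$specificity$ci[1], x$specificity$ci[2]))
  cat(sprintf("  PLR %.2f (%.2f-%.2f)  NLR %.3f (%.3f-%.3f)\n",
              x$plr$estimate, x$plr$ci[1], x$plr$ci[2],
              x$nlr$estimate, x$nlr$ci[1], x$nlr$ci[2]))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as ascending minus descending (`d = x - y`), so a
#' positive bias means the ascending aorta reads higher. Limits of
#' agreement are `bias +/- 1.96 * SD(d)` with the `n - 1` SD denominator.
#'
#' @param pairs A cohort table / data frame with `x_aao` and `y_da`, or a
#'   numeric vector `x` when `y` is given.
#' @param y Optional numeric vector of descending values.
#'
#' @return A `bland_altman` object: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
#' @examples
#' bland_altman(c(10, 20, 30), c(8, 16, 24))
bland_altman <- function(pairs, y = NULL) {
  if (is.null(y)) {
    x <- pairs$x_aao
    y <- pairs$y_da
  } else {
    x <- pairs
  }
  if (length(x) < 2) stop_af("need at least 2 pairs", class = "too_few_pairs")
  if (length(x) != length(y)) stop_af("x and y lengths differ", class = "invalid_pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.2f  LoA (%.2f, %.2f)  n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps every observed score as a strict `>` classification threshold
#' (higher score means more severe, consistent with the severity flags),
#' traces the ROC curve, and integrates the AUC by the trapezoid rule. With
#' tied scores this equals the normalized Mann-Whitney pairwise count with
#' ties counted one half.
#'
#' @param scores Continuous metric values (e.g. descending-aorta RVol).
#' @param labels Logical reference severity (both classes must be present).
#'
#' @return A `roc_result`: list with `auc` and `curve` (data frame of
#'   threshold, fpr, tpr).
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop_af("scores and labels lengths differ", class = "invalid_pairs")
  }
  if (!any(labels) || all(labels)) {
    stop_af("both classes must be present for ROC analysis",
            class = "single_class")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- sum(labels)
  neg <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores > t & labels) / pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & !labels) / neg, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fpr), tpr = c(0, tpr))
  # ensure the sweep ends at (1, 1): the lowest threshold classifies
  # everything strictly above it; append the all-positive operating point
  curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  structure(list(auc = auc, curve = curve), class = "roc_result")
}
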