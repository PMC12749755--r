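#' Fit the ascending-to-descending linear relation
#'
#' Ordinary least squares of the descending-aorta metric (`y_da`) on the
#' ascending-aorta metric (`x_aao`). Reports the Pearson correlation with a
#' Fisher-z 95% confidence interval and the residual root-mean-square error
#' with the `n - 2` denominator (the residual SD of the fit).
#'
#' @param pairs A cohort table (or data frame with `x_aao`, `y_da`), or a
#'   numeric vector `x` when `y` is also given.
#' @param y Optional numeric vector of descending values.
#' @param conf_level Confidence level for the correlation CI.
#'
#' @return A `linear_fit`: list with `slope`, `intercept`, `r`, `r_ci`,
#'   `rmse`, `n`.
#' @export
#' @examples
#' fit_linear(data.frame(x_aao = c(0, 1, 2), y_da = c(0, 2, 4)))
fit_linear <- function(pairs, y = NULL, conf_level = 0.95) {
  if (is.null(y)) {
    x <- pairs$x_aao
    y <- pairs$y_da
  } else {
    x <- pairs
  }
  n <- length(x)
  if (n < 3) stop_af("need at least 3 pairs to fit", class = "too_few_pairs")
  if (length(y) != n) stop_af("x and y lengths differ", class = "invalid_pairs")
  if (sd(x) == 0) stop_af("x is constant; fit undefined", class = "constant_x")
  fit <- lm(y ~ x)
  co <- unname(coef(fit))
  r <- suppressWarnings(stats::cor(x, y))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  zc <- qnorm(1 - (1 - conf_level) / 2)
  r_ci <- tanh(c(z - zc * se, z + zc * se))
  rmse <- sqrt(sum(fit$residuals^2) / (n - 2))
  structure(list(slope = co[2], intercept = co[1], r = r, r_ci = r_ci,
                 rmse = rmse, n = n),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.3f x %+.3f  R = %.3f (%.3f-%.3f)  RMSE = %.2f  n = %d\n",
              x$slope, x$intercept, x$r, x$r_ci[1], x$r_ci[2], x$rmse, x$n))
  invisible(x)
}

#' Transfer a severity threshold along the fitted relation
#'
#' Evaluates the fitted line at an ascending-aorta reference cut-off to
#' obtain the corresponding descending-aorta cut-off: e.g. the published
#' relation `y = 0.59 x - 7.43` maps the outcome-based RVol reference of
#' 42 mL to 17.35, reported as 17 mL; `y = 1.01 x - 10.04` maps the RF
#' reference of 33% to 23.29, reported as 23%.
#'
#' @param fit A `linear_fit` (or a list with `slope` and `intercept`).
#' @param reference Ascending-aorta reference cut-off (mL or %).
#' @param rounding `"nearest"` (default) or `"floor"`; both conventions
#'   reproduce the published thresholds.
#'
#' @return A list with `threshold` (integer under the default rounding),
#'   `raw` (unrounded), `reference` and `rounding`.
#' @export
#' @examples
#' derive_threshold(list(slope = 0.59, intercept = -7.43), 42)
derive_threshold <- function(fit, reference, rounding = c("nearest", "floor")) {
  rounding <- match.arg(rounding)
  raw <- fit$slope * reference + fit$intercept
  thr <- switch(rounding, nearest = round(raw), floor = floor(raw))
  list(threshold = thr, raw = raw, reference = reference, rounding = rounding)
}

#' Invert the fitted relation
#'
#' Maps a descending-aorta value back to the implied ascending-aorta value,
#' `(da_value - intercept) / slope`.
#'
#' @param fit A `linear_fit`.
#' @param da_value Descending-aorta metric value.
#' @return The implied ascending-aorta value.
#' @export
invert_threshold <- function(fit, da_value) {
  if (fit$slope == 0) stop_af("slope is zero; inverse undefined", class = "zero_slope")
  (da_value - fit$intercept) / fit$slope
}

#' Build the full threshold set from a fitted relation pair
#'
#' @param fit_rvol,fit_rf `linear_fit` objects for RVol and RF.
#' @param reference_rvol,reference_rf Ascending references (defaults 42 mL,
#'   33%).
#' @param rounding Rounding convention passed to [derive_threshold()].
#' @return A `threshold_set`: references, derived descending thresholds
#'   (rounded and raw) and the rounding tag.
#' @export
threshold_set <- function(fit_rvol, fit_rf, reference_rvol = 42,
                          reference_rf = 33, rounding = "nearest") {
  dr <- derive_threshold(fit_rvol, reference_rvol, rounding)
  df <- derive_threshold(fit_rf, reference_rf, rounding)
  structure(list(reference_rvol = reference_rvol, reference_rf = reference_rf,
                 derived_rvol_da = dr$threshold, derived_rf_da = df$threshold,
                 raw_rvol_da = dr$raw, raw_rf_da = df$raw,
                 rounding = rounding),
            class = "threshold_set")
}
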