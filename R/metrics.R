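#' Default analysis thresholds
#'
#' Central registry of the clinical constants the pipeline uses: the
#' outcome-based ascending-aorta severity cut-offs (RVol > 42 mL,
#' RF > 33%), the transferred descending-aorta cut-offs (RVol > 17 mL,
#' RF > 23%), the holodiastolic-flow-reversal floor (10 mL/s), the
#' diastolic flow-reversal velocity cut-off (19.5 cm/s), the aortic-diameter
#' dilation boundary (40 mm) and the background-offset acceptance limit
#' (0.6 cm/s).
#'
#' @return A named list of threshold values.
#' @export
default_thresholds <- function() {
  list(aao_rvol = 42, aao_rf = 33,
       da_rvol = 17, da_rf = 23,
       hfr_flow = 10, dfr_velocity = 19.5,
       diameter_dilated = 40, offset_limit = 0.6)
}

#' Split a flow curve into systole and diastole
#'
#' End-systole is located at the first downward zero crossing of the flow
#' curve after its global maximum; the returned index is the first diastolic
#' phase (1-based). When the curve never crosses zero, the first phase after
#' the maximum where flow drops below 10% of the peak is used; failing that,
#' the phase at 40% of the cycle — both fallbacks emit a warning.
#'
#' @param curve A [flow_curve()]. The peak must be positive (forward
#'   ejection present).
#'
#' @return A `phase_split`: list with `end_systole_index` (first diastolic
#'   phase, 1-based), `systole` and `diastole` index vectors, and `method`.
#' @export
split_phases <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  q <- curve$flow
  n <- length(q)
  peak <- max(q)
  if (peak <= 0) {
    stop_af("no forward ejection: flow curve has no positive peak",
            class = "no_forward_ejection")
  }
  imax <- which.max(q)
  after <- which(q <= 0)
  after <- after[after > imax]
  if (length(after)) {
    idx <- after[1]
    method <- "zero_crossing"
  } else {
    low <- which(q < 0.1 * peak)
    low <- low[low > imax]
    if (length(low)) {
      idx <- low[1]
      method <- "low_flow_fallback"
      warn_af("no diastolic zero crossing; end-systole set where flow < 10%% of peak",
              class = "split_fallback")
    } else {
      idx <- max(2L, min(n - 1L, as.integer(round(0.4 * n)) + 1L))
      method <- "fixed_fraction_fallback"
      warn_af("no zero crossing or low-flow point; end-systole set at 40%% of cycle",
              class = "split_fallback")
    }
  }
  if (idx <= 1L || idx > n) {
    stop_af("degenerate systole/diastole split at index %d", idx,
            class = "invalid_split")
  }
  structure(list(end_systole_index = as.integer(idx),
                 systole = seq_len(idx - 1L),
                 diastole = idx:n,
                 method = method),
            class = "phase_split")
}

# Uniform sample spacing in seconds for one cardiac cycle of n samples.
curve_dt <- function(curve) {
  d <- diff(curve$times)
  if (max(d) - min(d) > 1e-6 * max(d)) {
    warn_af("non-uniform phase spacing; using the mean interval",
            class = "nonuniform_times")
  }
  mean(d) / 1000
}

#' Compute regurgitation metrics from a flow curve
#'
#' Regurgitant volume (RVol) is the diastolic backward flow volume
#' `|sum over diastole of min(Q, 0) * dt|` in mL; the forward volume is the
#' positive flow volume over the whole cycle; the regurgitant fraction (RF)
#' is RVol as a percentage of the forward volume. The systolic backward
#' flow volume (a surrogate for complex flow) is also reported. The
#' holodiastolic-flow-reversal flag and metrics are bundled into one object.
#'
#' @param curve A [flow_curve()].
#' @param split A `phase_split` from [split_phases()]; computed if omitted.
#' @param hfr_flow HFR reversal floor in mL/s (default 10).
#'
#' @return A `regurg_metrics`: list with `rvol` (mL), `rf` (%),
#'   `forward_volume` (mL), `systolic_backward_volume` (mL, <= 0), `hfr`,
#'   `site`, and the split used.
#' @export
#' @examples
#' cv <- flow_curve(c(rep(100, 12), rep(-20, 24)), seq(0, 35) * 25)
#' compute_metrics(cv)
compute_metrics <- function(curve, split = NULL, hfr_flow = 10) {
  stopifnot(inherits(curve, "flow_curve"))
  if (is.null(split)) split <- split_phases(curve)
  q <- curve$flow
  dt <- curve_dt(curve)
  forward_volume <- sum(pmax(q, 0)) * dt
  if (forward_volume <= 0) {
    stop_af("forward volume is zero; regurgitant fraction undefined",
            class = "zero_forward_volume")
  }
  rvol <- -sum(pmin(q[split$diastole], 0)) * dt
  rf <- 100 * rvol / forward_volume
  sbv <- sum(pmin(q[split$systole], 0)) * dt
  structure(list(rvol = rvol, rf = rf, forward_volume = forward_volume,
                 systolic_backward_volume = sbv,
                 hfr = detect_hfr(curve, split, hfr_flow = hfr_flow),
                 site = curve$site_label, split = split),
            class = "regurg_metrics")
}

#' @export
print.regurg_metrics <- function(x, ...) {
  cat(sprintf(paste0("<regurg_metrics> site=%s RVol=%.1f mL RF=%.1f%% ",
                     "forward=%.1f mL sysBackward=%.1f mL HFR=%s\n"),
              x$site, x$rvol, x$rf, x$forward_volume,
              x$systolic_backward_volume, x$hfr))
  invisible(x)
}

#' Detect holodiastolic flow reversal
#'
#' Holodiastolic flow reversal (HFR) is reversed flow of at least
#' `hfr_flow` mL/s persisting through the entire diastole: TRUE iff
#' `Q(t) <= -hfr_flow` at every diastolic phase (boundary inclusive, so a
#' reversal of exactly 10 mL/s throughout diastole counts).
#'
#' @inheritParams compute_metrics
#' @return Logical flag.
#' @export
detect_hfr <- function(curve, split = NULL, hfr_flow = 10) {
  stopifnot(inherits(curve, "flow_curve"))
  if (is.null(split)) split <- split_phases(curve)
  all(curve$flow[split$diastole] <= -hfr_flow)
}

#' Diastolic flow-reversal (DFR) velocity
#'
#' Computes the reversal velocity in the descending aorta used as a severity
#' predictor (cut-off: strictly greater than 19.5 cm/s). The default
#' definition mirrors the Doppler end-diastolic measurement: the magnitude
#' of the spatial-mean reversal velocity over the lumen at the final
#' diastolic phase. Alternatively the time-average of the spatial-mean
#' reversal velocity over all diastolic phases can be selected.
#'
#' @param vel A `velocity_series` (descending aorta).
#' @param masks A `roi_mask_series` or logical mask/array.
#' @param split A `phase_split` for the corresponding flow curve.
#' @param method `"end_diastole"` (default) or `"mean_diastole"`.
#' @param cutoff Positivity cut-off in cm/s (default 19.5; strict `>`).
#'
#' @return A list with `dfr_velocity` (cm/s, >= 0; zero when the mean
#'   velocity is forward) and `dfr_positive`.
#' @export
compute_dfr_velocity <- function(vel, masks, split,
                                 method = c("end_diastole", "mean_diastole"),
                                 cutoff = 19.5) {
  method <- match.arg(method)
  stopifnot(inherits(vel, "velocity_series"))
  if (!length(split$diastole)) {
    stop_af("no diastolic phases in split", class = "invalid_split")
  }
  dims <- dim(vel$velocity)
  mask3 <- if (inherits(masks, "roi_mask_series")) masks$masks
           else if (length(dim(masks)) == 3) masks
           else array(masks, dim = dims)
  mean_at <- function(k) mean(vel$velocity[, , k][mask3[, , k]])
  v <- if (method == "end_diastole") {
    mean_at(split$diastole[length(split$diastole)])
  } else {
    mean(vapply(split$diastole, mean_at, numeric(1)))
  }
  dfr <- max(0, -v)
  list(dfr_velocity = dfr, dfr_positive = dfr > cutoff)
}

#' Classify regurgitation severity and aortic dilation
#'
#' Applies the strict `>` severity cut-offs at both measurement sites: the
#' ascending-aorta reference (RVol > 42 mL, RF > 33%) and the transferred
#' descending-aorta cut-offs (defaults RVol > 17 mL, RF > 23%), together
#' with the aortic-diameter class (dilated iff diameter >= 40 mm).
#'
#' @param metrics_aao A `regurg_metrics` for the ascending aorta (or `NULL`).
#' @param metrics_da A `regurg_metrics` for the descending aorta (or `NULL`).
#' @param diameter Ascending aortic end-systolic diameter, mm (or `NA`).
#' @param dfr A result of [compute_dfr_velocity()] (or `NULL`).
#' @param thresholds Named list as from [default_thresholds()].
#'
#' @return A `severity_call`: list of logical flags `significant_aao_rvol`,
#'   `significant_aao_rf`, `significant_da_rvol`, `significant_da_rf`,
#'   `hfr_positive`, `dfr_positive`, and `diameter_class`.
#' @export
classify_severity <- function(metrics_aao = NULL, metrics_da = NULL,
                              diameter = NA_real_, dfr = NULL,
                              thresholds = default_thresholds()) {
  flag <- function(m, field, thr) {
    if (is.null(m)) NA else isTRUE(m[[field]] > thr)
  }
  structure(list(
    significant_aao_rvol = flag(metrics_aao, "rvol", thresholds$aao_rvol),
    significant_aao_rf = flag(metrics_aao, "rf", thresholds$aao_rf),
    significant_da_rvol = flag(metrics_da, "rvol", thresholds$da_rvol),
    significant_da_rf = flag(metrics_da, "rf", thresholds$da_rf),
    hfr_positive = if (is.null(metrics_da)) NA else metrics_da$hfr,
    dfr_positive = if (is.null(dfr)) NA else dfr$dfr_positive,
    diameter_class = if (is.na(diameter)) NA_character_
                     else if (diameter >= thresholds$diameter_dilated) "dilated"
                     else "normal"
  ), class = "severity_call")
}

#' Test-retest reproducibility percentage
#'
#' Relative absolute difference between two repeat measurements of the same
#' metric: `100 * |m1 - m2| / mean(m1, m2)`. Undefined (error) when the
#' pair mean is zero.
#'
#' @param m1,m2 Paired repeat measurements (vectors allowed).
#' @return Reproducibility percentages.
#' @export
#' @examples
#' reproducibility_pct(10, 20)  # 66.7%
reproducibility_pct <- function(m1, m2) {
  if (length(m1) != length(m2)) {
    stop_af("m1 and m2 must have equal length", class = "invalid_pairs")
  }
  mn <- (m1 + m2) / 2
  if (any(mn == 0)) {
    stop_af("reproducibility undefined when the pair mean is zero",
            class = "zero_pair_mean")
  }
  100 * abs(m1 - m2) / mn
}
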