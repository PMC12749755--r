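#' Pipeline configuration
#'
#' Resolves all tunable constants of the analysis into one record that is
#' embedded verbatim (plus a hash) in every report, so any output can be
#' reproduced from its own metadata.
#'
#' @param thresholds Named list as from [default_thresholds()].
#' @param reference_rvol,reference_rf Ascending-aorta reference cut-offs
#'   used for threshold transfer (defaults 42 mL, 33%).
#' @param rounding Threshold rounding convention, `"nearest"` or `"floor"`.
#' @param dfr_method DFR velocity definition, `"end_diastole"` or
#'   `"mean_diastole"`.
#' @param ci_method Proportion CI method (`"wilson"`; placeholder for
#'   future exact CIs).
#' @param seed Master RNG seed.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(thresholds = default_thresholds(),
                            reference_rvol = 42, reference_rf = 33,
                            rounding = "nearest",
                            dfr_method = "end_diastole",
                            ci_method = "wilson", seed = 1L) {
  if (any(unlist(thresholds) <= 0)) {
    stop_af("all thresholds must be positive", class = "invalid_config")
  }
  structure(list(thresholds = thresholds, reference_rvol = reference_rvol,
                 reference_rf = reference_rf, rounding = rounding,
                 dfr_method = dfr_method, ci_method = ci_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # order-stable djb2 hash of the serialized config; no external digest dep
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 12)
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the full threshold-transfer pipeline on simulated or provided cohorts
#'
#' Executes simulate -> fit -> derive thresholds -> evaluate: simulates (or
#' accepts) paired RVol and RF cohorts, fits the ascending-to-descending
#' linear relations, transfers the ascending reference cut-offs to the
#' descending aorta, classifies every patient at both sites, and summarizes
#' diagnostic performance (confusion matrix, sensitivity/specificity,
#' likelihood ratios), Bland-Altman agreement and ROC/AUC. Deterministic
#' for a fixed config seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort_rvol,cohort_rf Optional cohort tables; simulated from the
#'   `cohort1-rvol` / `cohort1-rf` presets when omitted.
#' @param out Optional output directory; when given, the report is written
#'   as `report.json` and the cohorts as CSVs.
#'
#' @return A `pipeline_report` list: resolved config (+hash), per-metric
#'   fit, thresholds, diagnostic summary, Bland-Altman and AUC.
#' @export
#' @examples
#' rep <- run_pipeline(pipeline_config(seed = 1))
#' rep$rvol$thresholds$derived
run_pipeline <- function(config = pipeline_config(), cohort_rvol = NULL,
                         cohort_rf = NULL, out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(cohort_rvol)) {
      cohort_rvol <- simulate_cohort(cohort_model(preset = "cohort1-rvol"),
                                     seed = config$seed)
    }
    if (is.null(cohort_rf)) {
      cohort_rf <- simulate_cohort(cohort_model(preset = "cohort1-rf"),
                                   seed = config$seed + 1L)
    }

    evaluate_metric <- function(tab, reference, metric) {
      stage <<- paste0("fit:", metric)
      fit <- fit_linear(tab)
      der <- derive_threshold(fit, reference, config$rounding)
      stage <<- paste0("evaluate:", metric)
      ref_flags <- tab$x_aao > reference
      pred_flags <- tab$y_da > der$threshold
      summ <- if (any(ref_flags) && any(!ref_flags)) {
        confusion_and_summary(pred_flags, ref_flags)
      }
      roc <- if (any(ref_flags) && any(!ref_flags)) roc_auc(tab$y_da, ref_flags)
      list(fit = fit[c("slope", "intercept", "r", "r_ci", "rmse", "n")],
           thresholds = list(reference = reference, derived = der$threshold,
                             raw = der$raw, rounding = config$rounding),
           diagnostics = summ,
           bland_altman = unclass(bland_altman(tab)),
           auc = if (!is.null(roc)) roc$auc else NA_real_)
    }

    rvol <- evaluate_metric(cohort_rvol, config$reference_rvol, "RVol")
    rf <- evaluate_metric(cohort_rf, config$reference_rf, "RF")

    list(schema_version = "1.0",
         config = unclass(config),
         config_hash = config_hash(config),
         seed = config$seed,
         rvol = rvol, rf = rf)
  }, aortaflow_error = function(e) {
    stop_af("pipeline stage '%s' failed: %s", stage, conditionMessage(e),
            class = "pipeline_error")
  })

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort_rvol, file.path(out, "cohort_rvol.csv"))
    write_cohort(cohort_rf, file.path(out, "cohort_rf.csv"))
    jsonlite::write_json(strip_classes(result), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = 12, pretty = TRUE)
  }
  structure(result, class = "pipeline_report")
}

# Recursively drop S3 classes so jsonlite serializes plain lists.
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Quantify a phantom series end to end
#'
#' Convenience wrapper chaining the flow-quantification stages on one
#' velocity-encoded series: decode, unwrap (when the truth flags aliasing or
#' `unwrap = TRUE`), segment the lumen from the magnitude images,
#' offset-correct against the segmented static tissue, and integrate the
#' ROI flow; then compute regurgitation metrics.
#'
#' @param phantom A `phantom_series`.
#' @param seed_point Seed pixel `c(col, row)`; defaults to the vessel
#'   center.
#' @param offset_correction Apply planar background-offset correction?
#' @param unwrap Force aliasing repair (default: only when the truth block
#'   flags aliasing).
#' @param static_margin Pixels eroded around the segmented lumen before
#'   declaring static tissue (default 3).
#'
#' @return A list with `curve` ([flow_curve()]), `metrics`
#'   ([compute_metrics()] result), `masks`, `offset`, and `dfr`.
#' @export
quantify_phantom <- function(phantom, seed_point = NULL,
                             offset_correction = TRUE, unwrap = NULL,
                             static_margin = 3) {
  stopifnot(inherits(phantom, "phantom_series"))
  g <- phantom$params$grid_size
  if (is.null(seed_point)) {
    ctr <- phantom$vessel$center
    if (is.null(ctr)) ctr <- c((g + 1) / 2, (g + 1) / 2)
    seed_point <- as.integer(round(ctr))
  }
  vel <- decode_velocity(phantom)
  masks <- segment_lumen(phantom, seed_point)
  if (is.null(unwrap)) unwrap <- isTRUE(phantom$truth$aliased)
  if (unwrap) vel <- unwrap_aliasing(vel, masks)
  offset <- NULL
  if (offset_correction) {
    lumen_any <- apply(masks$masks, c(1, 2), any)
    dil <- lumen_any
    for (i in seq_len(static_margin)) {
      g1 <- nrow(dil)
      up <- rbind(dil[-1, ], FALSE); dn <- rbind(FALSE, dil[-g1, ])
      lf <- cbind(dil[, -1], FALSE); rt <- cbind(FALSE, dil[, -g1])
      dil <- dil | up | dn | lf | rt
    }
    air <- phantom$truth$air_mask
    static_mask <- !dil & !air
    res <- estimate_background_offset(vel, static_mask)
    offset <- res$offset
    vel <- res$corrected
  }
  curve <- compute_flow_curve(vel, masks, site_label = "descending")
  split <- split_phases(curve)
  metrics <- compute_metrics(curve, split)
  dfr <- compute_dfr_velocity(vel, masks, split)
  list(curve = curve, metrics = metrics, masks = masks, offset = offset,
       dfr = dfr, split = split)
}
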