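#' Decode a velocity-encoded phase stack into velocities
#'
#' Standard phase-contrast relation: a pixel phase `phi` in `(-pi, pi]`
#' encodes through-plane velocity `v = venc * phi / pi` (cm/s). The decode
#' is the exact inverse of the simulator's encoding for `|v| < venc`, so the
#' round trip is bit-exact below the VENC.
#'
#' @param phase_stack Either a `phantom_series` or a numeric array
#'   `[grid, grid, n_phases]` of phase values in `(-pi, pi]`.
#' @param venc Velocity-encoding limit, cm/s (taken from the phantom's
#'   parameters when a `phantom_series` is given).
#' @param times Phase times in ms (defaults supplied by the phantom).
#' @param pixel_area Pixel area in mm^2 (defaults supplied by the phantom).
#'
#' @return A `velocity_series`: list with `velocity` (cm/s array), `times`
#'   (ms), `pixel_area` (mm^2), `venc`, and a `corrected` flag.
#' @export
decode_velocity <- function(phase_stack, venc = NULL, times = NULL,
                            pixel_area = NULL) {
  if (inherits(phase_stack, "phantom_series")) {
    p <- phase_stack
    venc <- p$params$venc
    times <- p$truth$curve$times
    pixel_area <- p$params$pixel_spacing^2
    phase_stack <- p$phase
  }
  if (is.null(venc) || venc <= 0) stop_af("venc must be > 0", class = "invalid_venc")
  n <- dim(phase_stack)[3]
  if (is.null(times)) times <- seq_len(n) - 1
  if (is.null(pixel_area)) pixel_area <- 1
  velocity_series(venc * phase_stack / pi, times, pixel_area, venc,
                  corrected = FALSE)
}

#' Velocity series container
#'
#' @param velocity Array `[grid, grid, n_phases]` of velocities, cm/s.
#' @param times Phase times, ms, strictly increasing.
#' @param pixel_area Pixel area, mm^2.
#' @param venc Velocity-encoding limit, cm/s.
#' @param corrected Has background-offset correction been applied?
#' @return A `velocity_series` object.
#' @export
velocity_series <- function(velocity, times, pixel_area, venc,
                            corrected = FALSE) {
  if (length(dim(velocity)) != 3) {
    stop_af("velocity must be a 3-d array [grid, grid, n_phases]",
            class = "invalid_series")
  }
  if (length(times) != dim(velocity)[3]) {
    stop_af("times length must equal the number of phases", class = "invalid_series")
  }
  if (any(diff(times) <= 0)) {
    stop_af("times must be strictly increasing", class = "invalid_series")
  }
  structure(list(velocity = velocity, times = as.numeric(times),
                 pixel_area = pixel_area, venc = venc, corrected = corrected),
            class = "velocity_series")
}

#' Repair velocity aliasing (phase wrapping) inside the lumen
#'
#' A velocity exceeding the VENC wraps by `2 * venc`. For each cardiac
#' phase, lumen pixels whose velocity differs from the lumen spatial median
#' by more than the VENC are shifted by `+/- 2 * venc`, choosing the sign
#' that minimizes the difference to the median. Only a single wrap order is
#' corrected; deeper wraps are declared unrecoverable, mirroring the
#' clinical practice of excluding irreparably aliased acquisitions.
#'
#' @param vel A `velocity_series`.
#' @param lumen_hint Logical mask `[grid, grid]` (applied to all phases) or
#'   a logical array `[grid, grid, n_phases]` marking lumen pixels.
#' @param max_wrap_frac Error if more than this fraction of lumen pixels
#'   needs unwrapping in any phase (default 0.20).
#'
#' @return The corrected `velocity_series`, with attributes
#'   `n_unwrapped` (pixels corrected) and `residual_discontinuity` (TRUE if
#'   any lumen pixel still deviates from the median by more than the VENC).
#' @export
unwrap_aliasing <- function(vel, lumen_hint, max_wrap_frac = 0.20) {
  stopifnot(inherits(vel, "velocity_series"))
  dims <- dim(vel$velocity)
  n <- dims[3]
  if (inherits(lumen_hint, "roi_mask_series")) lumen_hint <- lumen_hint$masks
  mask3 <- if (length(dim(lumen_hint)) == 3) lumen_hint else
    array(lumen_hint, dim = dims)
  v <- vel$velocity
  venc <- vel$venc
  n_unwrapped <- 0L
  residual <- FALSE
  for (k in seq_len(n)) {
    vk <- v[, , k]
    m <- mask3[, , k]
    lum <- vk[m]
    if (!length(lum)) next
    med <- median(lum)
    wrapped <- m & abs(vk - med) > venc
    nw <- sum(wrapped)
    if (nw > max_wrap_frac * sum(m)) {
      stop_af("unrecoverable aliasing: %d of %d lumen pixels wrapped in phase %d",
              nw, sum(m), k, class = "unrecoverable_aliasing")
    }
    if (nw > 0) {
      shift <- 2 * venc * sign(med - vk[wrapped])
      vk[wrapped] <- vk[wrapped] + shift
      n_unwrapped <- n_unwrapped + nw
      if (any(abs(vk[m] - median(vk[m])) > venc)) residual <- TRUE
      v[, , k] <- vk
    }
  }
  out <- velocity_series(v, vel$times, vel$pixel_area, vel$venc,
                         corrected = vel$corrected)
  attr(out, "n_unwrapped") <- n_unwrapped
  attr(out, "residual_discontinuity") <- residual
  out
}

#' Estimate and subtract the eddy-current background velocity offset
#'
#' Eddy currents induce a slowly varying spurious velocity offset across the
#' image plane. Following standard practice, the offset is modeled as a
#' first-order (planar) spatial polynomial, fit by least squares to the
#' time-averaged velocity of static-tissue pixels, and subtracted from every
#' phase. The residual static-tissue mean (averaged magnitude of the
#' per-phase static-region mean after correction) is reported and compared
#' against the clinical acceptance limit of 0.6 cm/s; a warning is emitted
#' if it is exceeded.
#'
#' @param vel A `velocity_series`.
#' @param static_mask Logical matrix `[grid, grid]` of static-tissue pixels
#'   (no lumen, no air); at least 50 pixels.
#' @param acceptance_limit Residual limit in cm/s (default 0.6).
#'
#' @return A list with `offset` (an `offset_model`: planar coefficients
#'   `c(constant, x, y)` in cm/s and cm/s per pixel, plus
#'   `residual_static_mean`) and `corrected` (the corrected
#'   `velocity_series`).
#' @export
estimate_background_offset <- function(vel, static_mask,
                                       acceptance_limit = 0.6) {
  stopifnot(inherits(vel, "velocity_series"))
  if (sum(static_mask) < 50) {
    stop_af("static mask too small (%d pixels; need >= 50)", sum(static_mask),
            class = "static_mask_too_small")
  }
  dims <- dim(vel$velocity)
  g1 <- dims[1]; g2 <- dims[2]
  vbar <- apply(vel$velocity, c(1, 2), mean)
  xs <- matrix(rep(seq_len(g2) - 1, each = g1), g1, g2)   # column index
  ys <- matrix(rep(seq_len(g1) - 1, times = g2), g1, g2)  # row index
  df <- data.frame(v = vbar[static_mask], x = xs[static_mask],
                   y = ys[static_mask])
  fit <- lm(v ~ x + y, data = df)
  co <- unname(coef(fit))
  plane <- co[1] + co[2] * xs + co[3] * ys
  v <- vel$velocity
  for (k in seq_len(dims[3])) v[, , k] <- v[, , k] - plane
  # temporal stability of the static region after correction
  per_phase_mean <- apply(v, 3, function(s) mean(s[static_mask]))
  residual <- mean(abs(per_phase_mean))
  if (residual > acceptance_limit) {
    warn_af("residual static-tissue offset %.3f cm/s exceeds limit %.1f cm/s",
            residual, acceptance_limit, class = "offset_above_limit")
  }
  offset <- structure(list(coefficients = co,
                           residual_static_mean = residual),
                      class = "offset_model")
  corrected <- velocity_series(v, vel$times, vel$pixel_area, vel$venc,
                               corrected = TRUE)
  list(offset = offset, corrected = corrected)
}

#' Segment the vessel lumen on the magnitude images and track it over phases
#'
#' Region growing from a seed point on the reference phase: the reference
#' mask is the 8-connected component, containing the seed, of pixels whose
#' intensity exceeds `threshold_frac` times the median intensity of the 3x3
#' neighborhood around the seed. Each subsequent phase is re-grown from the
#' previous mask's centroid (semi-automated contour propagation). An error
#' is raised when the mask area changes by more than `max_area_change`
#' between adjacent phases (tracking lost).
#'
#' @param magnitude_stack Numeric array `[grid, grid, n_phases]` or a
#'   `phantom_series`.
#' @param seed_point Integer `c(col, row)` pixel coordinates inside the
#'   lumen at the reference phase.
#' @param reference_phase Phase index used to establish the threshold.
#' @param threshold_frac Fraction of the seed-neighborhood median intensity
#'   used as the inclusion threshold (default 0.5).
#' @param max_area_change Maximum tolerated relative area change between
#'   adjacent phases (default 0.5).
#' @param pixel_area Pixel area in mm^2 (defaults supplied by the phantom).
#'
#' @return A `roi_mask_series`: list with `masks` (logical array), `areas`
#'   (mm^2 per phase) and `centroids` (n x 2 matrix of `c(col, row)`).
#' @export
segment_lumen <- function(magnitude_stack, seed_point, reference_phase = 1,
                          threshold_frac = 0.5, max_area_change = 0.5,
                          pixel_area = NULL) {
  if (inherits(magnitude_stack, "phantom_series")) {
    pixel_area <- magnitude_stack$params$pixel_spacing^2
    magnitude_stack <- magnitude_stack$magnitude
  }
  if (is.null(pixel_area)) pixel_area <- 1
  dims <- dim(magnitude_stack)
  n <- dims[3]
  sx <- as.integer(seed_point[1]); sy <- as.integer(seed_point[2])

  ref_img <- magnitude_stack[, , reference_phase]
  nb <- ref_img[max(1, sy - 1):min(dims[1], sy + 1),
                max(1, sx - 1):min(dims[2], sx + 1)]
  thr <- threshold_frac * median(nb)

  # flood fill by repeated 8-neighbor dilation restricted to supra-threshold
  # pixels; O(lumen diameter) matrix passes per phase
  dilate8 <- function(m) {
    g1 <- nrow(m); g2 <- ncol(m)
    out <- m
    out[-1, ] <- out[-1, ] | m[-g1, ]
    out[-g1, ] <- out[-g1, ] | m[-1, ]
    out[, -1] <- out[, -1] | out[, -g2]
    out[, -g2] <- out[, -g2] | out[, -1]
    out
  }
  grow <- function(img, seed_xy) {
    if (img[seed_xy[2], seed_xy[1]] < thr) return(NULL)
    above <- img >= thr
    mask <- matrix(FALSE, dims[1], dims[2])
    mask[seed_xy[2], seed_xy[1]] <- TRUE
    repeat {
      grown <- dilate8(mask) & above
      if (sum(grown) == sum(mask)) break
      mask <- grown
    }
    mask
  }

  masks <- array(FALSE, dims)
  areas <- numeric(n)
  centroids <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))

  order_idx <- c(reference_phase, setdiff(seq_len(n), reference_phase))
  # propagate forward from the reference phase, wrapping around the cycle
  order_idx <- ((reference_phase - 1 + seq_len(n) - 1) %% n) + 1
  seed_xy <- c(sx, sy)
  prev_area <- NA_real_
  for (k in order_idx) {
    m <- grow(magnitude_stack[, , k], seed_xy)
    if (is.null(m) || !any(m)) {
      stop_af("tracking lost: empty lumen mask at phase %d", k,
              class = "tracking_lost")
    }
    area <- sum(m) * pixel_area
    if (!is.na(prev_area) && abs(area - prev_area) / prev_area > max_area_change) {
      stop_af("tracking lost: lumen area changed by more than %.0f%% at phase %d",
              100 * max_area_change, k, class = "tracking_lost")
    }
    masks[, , k] <- m
    areas[k] <- area
    cy <- mean(which(m, arr.ind = TRUE)[, 1])
    cx <- mean(which(m, arr.ind = TRUE)[, 2])
    centroids[k, ] <- c(cx, cy)
    seed_xy <- c(as.integer(round(cx)), as.integer(round(cy)))
    prev_area <- area
  }

  structure(list(masks = masks, areas = areas, centroids = centroids,
                 pixel_area = pixel_area),
            class = "roi_mask_series")
}

#' Integrate velocities over the lumen ROI into a volumetric flow curve
#'
#' `flow(t) = sum over mask pixels of v * pixel_area`, converted to mL/s
#' (1 cm/s over 1 mm^2 equals 0.01 mL/s).
#'
#' @param vel A `velocity_series` (offset-corrected unless
#'   `require_corrected = FALSE`).
#' @param masks A `roi_mask_series` or a logical mask/array.
#' @param site_label `"ascending"` or `"descending"`.
#' @param require_corrected Refuse uncorrected input? Default FALSE with
#'   the understanding that simulation tests bypass correction.
#'
#' @return A [flow_curve()].
#' @export
compute_flow_curve <- function(vel, masks, site_label = "descending",
                               require_corrected = FALSE) {
  stopifnot(inherits(vel, "velocity_series"))
  if (require_corrected && !vel$corrected) {
    stop_af("velocity series is not offset-corrected", class = "uncorrected_series")
  }
  dims <- dim(vel$velocity)
  mask3 <- if (inherits(masks, "roi_mask_series")) {
    masks$masks
  } else if (length(dim(masks)) == 3) {
    masks
  } else {
    if (!identical(dim(masks), dims[1:2])) {
      stop_af("mask dimensions %s do not match image dimensions %s",
              paste(dim(masks), collapse = "x"), paste(dims[1:2], collapse = "x"),
              class = "shape_mismatch")
    }
    array(masks, dim = dims)
  }
  if (!identical(dim(mask3), dims)) {
    stop_af("mask dimensions %s do not match velocity dimensions %s",
            paste(dim(mask3), collapse = "x"), paste(dims, collapse = "x"),
            class = "shape_mismatch")
  }
  flow <- vapply(seq_len(dims[3]), function(k) {
    sum(vel$velocity[, , k][mask3[, , k]]) * vel$pixel_area * FLOW_UNIT
  }, numeric(1))
  flow_curve(flow, vel$times, site_label = site_label)
}

#' Select the velocity-encoding limit for an expected peak velocity
#'
#' Chooses the smallest candidate VENC strictly greater than the expected
#' peak velocity, and checks the optimization rule that the chosen VENC does
#' not exceed the peak by more than 20% of itself (headroom
#' `(venc - peak)/venc <= 0.20`); if no candidate satisfies both, the
#' smallest valid candidate is returned with a "rule unsatisfiable" warning.
#'
#' @param expected_peak Expected peak velocity, cm/s.
#' @param candidates Allowed VENC values, cm/s, within `[90, 480]`.
#'
#' @return The selected VENC (cm/s) with attribute `headroom`.
#' @export
#' @examples
#' select_venc(170, seq(90, 480, by = 10))
select_venc <- function(expected_peak, candidates = seq(90, 480, by = 10)) {
  if (any(candidates < 90 | candidates > 480)) {
    stop_af("candidates must lie within [90, 480] cm/s", class = "invalid_venc")
  }
  ok <- candidates > expected_peak
  if (!any(ok)) {
    stop_af("expected peak %.0f cm/s is not measurable with the candidate VENCs",
            expected_peak, class = "peak_unmeasurable")
  }
  venc <- min(candidates[ok])
  headroom <- (venc - expected_peak) / venc
  if (headroom > 0.20) {
    warn_af("VENC rule unsatisfiable: headroom %.0f%% exceeds 20%% at VENC %.0f",
            100 * headroom, venc, class = "venc_rule_unsatisfiable")
  }
  structure(venc, headroom = headroom)
}
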