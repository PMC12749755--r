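#' Acquisition parameters for a simulated PC-CMR series
#'
#' Bundles the scan settings the simulator and decoder share: the velocity
#' encoding limit (VENC), temporal and spatial sampling, the velocity noise
#' level inside tissue, and the planar eddy-current offset injected into the
#' phase images.
#'
#' @param venc Velocity-encoding limit in cm/s. Velocities beyond +/- VENC
#'   wrap (alias) in the phase image. Clinical range 90-480 cm/s.
#' @param n_phases Number of reconstructed cardiac phases per cycle.
#' @param pixel_spacing In-plane pixel edge length in mm.
#' @param grid_size Image edge length in pixels.
#' @param rr_interval Cardiac cycle length (RR interval) in ms.
#' @param noise_sd Gaussian velocity noise SD inside tissue, cm/s.
#' @param offset_coeffs Numeric length-3 planar background-offset
#'   coefficients `c(constant, per-pixel-x, per-pixel-y)`; constant in cm/s,
#'   linear terms in cm/s per pixel. Models eddy-current velocity offsets.
#' @param seed Integer RNG seed used when rendering the series.
#'
#' @return An object of class `acquisition_params`.
#' @export
#' @examples
#' acquisition_params(venc = 180, noise_sd = 1)
acquisition_params <- function(venc = 180, n_phases = 40, pixel_spacing = 2.5,
                               grid_size = 64, rr_interval = 1000,
                               noise_sd = 0, offset_coeffs = c(0, 0, 0),
                               seed = 1L) {
  if (!is.numeric(venc) || length(venc) != 1 || venc < 90 || venc > 480) {
    stop_af("venc must be a single value in [90, 480] cm/s", class = "invalid_params")
  }
  if (n_phases < 8) stop_af("n_phases must be >= 8", class = "invalid_params")
  if (pixel_spacing <= 0) stop_af("pixel_spacing must be > 0", class = "invalid_params")
  if (rr_interval <= 0) stop_af("rr_interval must be > 0", class = "invalid_params")
  if (length(offset_coeffs) != 3) {
    stop_af("offset_coeffs must have length 3 (constant, x-slope, y-slope)",
            class = "invalid_params")
  }
  structure(list(venc = venc, n_phases = as.integer(n_phases),
                 pixel_spacing = pixel_spacing, grid_size = as.integer(grid_size),
                 rr_interval = rr_interval, noise_sd = noise_sd,
                 offset_coeffs = as.numeric(offset_coeffs), seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Ground-truth aortic flow waveform specification
#'
#' Describes one cardiac cycle of volumetric aortic flow by its defining
#' volumes rather than by an explicit curve: the positive (forward) flow
#' volume, the diastolic backward (regurgitant) volume, and an optional
#' systolic backward volume used as a surrogate for complex (helical or
#' recirculating) flow. The implied regurgitant fraction is
#' `100 * rvol_true / forward_volume`.
#'
#' @param forward_volume Positive-flow volume per cycle, mL.
#' @param rvol_true Diastolic backward flow volume (regurgitant volume), mL.
#' @param systolic_fraction Fraction of the cycle occupied by systole.
#' @param reversal_shape One of `"none"`, `"holodiastolic"` (reversal
#'   persists through all of diastole, never shallower than `hfr_floor`),
#'   or `"early_only"` (reversal returns to zero by mid-diastole).
#' @param systolic_backward_volume Systolic backward flow volume, mL
#'   (must be <= 0); rendered as a brief pre-ejection reversal notch.
#' @param hfr_floor Minimum reversal magnitude maintained throughout
#'   diastole for the holodiastolic shape, mL/s.
#'
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(forward_volume, rvol_true = 0,
                          systolic_fraction = 0.35,
                          reversal_shape = c("none", "holodiastolic", "early_only"),
                          systolic_backward_volume = 0, hfr_floor = 10) {
  reversal_shape <- match.arg(reversal_shape)
  if (forward_volume <= 0) stop_af("forward_volume must be > 0", class = "invalid_spec")
  if (rvol_true < 0) stop_af("rvol_true must be >= 0", class = "invalid_spec")
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop_af("systolic_fraction must be in (0, 1)", class = "invalid_spec")
  }
  if (systolic_backward_volume > 0) {
    stop_af("systolic_backward_volume must be <= 0", class = "invalid_spec")
  }
  if (100 * rvol_true / forward_volume >= 100) {
    stop_af("implied regurgitant fraction must be < 100%%", class = "invalid_spec")
  }
  if (reversal_shape != "none" && rvol_true <= 0) {
    stop_af("reversal_shape '%s' requires rvol_true > 0", reversal_shape,
            class = "invalid_spec")
  }
  structure(list(forward_volume = forward_volume, rvol_true = rvol_true,
                 systolic_fraction = systolic_fraction,
                 reversal_shape = reversal_shape,
                 systolic_backward_volume = systolic_backward_volume,
                 hfr_floor = hfr_floor),
            class = "waveform_spec")
}

#' Construct a per-phase volumetric flow curve from a waveform specification
#'
#' Samples an analytic flow-curve family (half-sine forward ejection; for
#' holodiastolic reversal a diastolic plateau with a shallow mid-diastolic
#' bump; for early-only reversal a negative half-sine that returns to zero by
#' mid-diastole; optional pre-ejection negative notch for systolic backward
#' flow) on the acquisition's phase grid, then rescales each lobe so the
#' discrete time integrals reproduce the specified volumes exactly under the
#' same rectangle-rule integration the metrics module uses.
#'
#' @param spec A [waveform_spec()].
#' @param params An [acquisition_params()] (supplies `n_phases` and
#'   `rr_interval`).
#'
#' @return A `flow_curve` object: list with `flow` (mL/s per phase),
#'   `times` (ms, phase-start convention), `site_label`, and the generating
#'   `spec` attached as `attr(, "spec")`.
#' @export
#' @examples
#' wf <- build_waveform(waveform_spec(70, rvol_true = 30,
#'                                    reversal_shape = "holodiastolic"),
#'                      acquisition_params())
#' range(wf$flow)
build_waveform <- function(spec, params) {
  stopifnot(inherits(spec, "waveform_spec"), inherits(params, "acquisition_params"))
  n <- params$n_phases
  period <- params$rr_interval / 1000          # s
  dt <- period / n
  t <- (seq_len(n) - 1) * dt                   # phase-start times, s
  ts <- spec$systolic_fraction * period        # end-systole time
  td <- period - ts                            # diastole duration

  q <- numeric(n)
  sys_idx <- t < ts
  dia_idx <- !sys_idx

  # systole: optional pre-ejection notch then forward half-sine
  notch_frac <- if (spec$systolic_backward_volume < 0) 0.15 else 0
  t0 <- notch_frac * ts
  fwd <- sys_idx & t >= t0
  q[fwd] <- sin(pi * (t[fwd] - t0) / (ts - t0))
  if (notch_frac > 0) {
    nt <- sys_idx & t < t0
    q[nt] <- -sin(pi * t[nt] / t0)
    if (!any(q[sys_idx] < 0)) {
      stop_af("n_phases too coarse to render the systolic backward notch",
              class = "infeasible_waveform")
    }
  }

  # diastole
  if (spec$reversal_shape == "holodiastolic") {
    level <- spec$rvol_true / (td * (1 + 1 / pi))
    if (level < spec$hfr_floor) {
      stop_af(paste0("infeasible holodiastolic spec: rvol_true %.1f mL sustains ",
                     "only %.1f mL/s over diastole (< floor %.1f mL/s)"),
              spec$rvol_true, level, spec$hfr_floor,
              class = "infeasible_waveform")
    }
    u <- (t[dia_idx] - ts) / td
    q[dia_idx] <- -level * (1 + 0.5 * sin(pi * u))
  } else if (spec$reversal_shape == "early_only") {
    u <- (t[dia_idx] - ts) / (td / 2)
    q[dia_idx] <- ifelse(u < 1, -sin(pi * pmin(u, 1)), 0)
  }

  # rescale lobes so rectangle-rule integrals match the spec exactly
  pos <- q > 0
  q[pos] <- q[pos] * spec$forward_volume / (sum(q[pos]) * dt)
  dneg <- dia_idx & q < 0
  if (spec$rvol_true > 0) {
    if (!any(dneg)) {
      stop_af("no diastolic samples available for the reversal lobe",
              class = "infeasible_waveform")
    }
    q[dneg] <- q[dneg] * spec$rvol_true / (-sum(q[dneg]) * dt)
  }
  sneg <- sys_idx & q < 0
  if (spec$systolic_backward_volume < 0 && any(sneg)) {
    q[sneg] <- q[sneg] * spec$systolic_backward_volume / (sum(q[sneg]) * dt)
  }

  if (spec$reversal_shape == "holodiastolic" &&
      any(q[dia_idx] > -spec$hfr_floor + 1e-9)) {
    stop_af("holodiastolic reversal fell below the %.1f mL/s floor after sampling",
            spec$hfr_floor, class = "infeasible_waveform")
  }

  structure(flow_curve(q, t * 1000, site_label = "descending"),
            spec = spec)
}

#' Flow curve container
#'
#' @param flow Volumetric flow per cardiac phase, mL/s (forward positive).
#' @param times Phase times, strictly increasing, spanning one cycle.
#' @param site_label `"ascending"` or `"descending"`.
#' @param time_unit Unit of `times`, `"ms"` (default) or `"s"`; stored
#'   internally in ms so metrics are invariant to the declared unit.
#' @return A `flow_curve` object.
#' @export
flow_curve <- function(flow, times, site_label = c("descending", "ascending"),
                       time_unit = c("ms", "s")) {
  site_label <- match.arg(site_label)
  time_unit <- match.arg(time_unit)
  if (time_unit == "s") times <- times * 1000
  if (length(flow) != length(times)) {
    stop_af("flow and times must have equal length", class = "invalid_curve")
  }
  if (any(!is.finite(flow))) stop_af("flow must be finite", class = "invalid_curve")
  if (any(diff(times) <= 0)) {
    stop_af("times must be strictly increasing", class = "invalid_curve")
  }
  structure(list(flow = as.numeric(flow), times = as.numeric(times),
                 site_label = site_label),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %d phases, site=%s, peak=%.1f mL/s, min=%.1f mL/s\n",
              length(x$flow), x$site_label, max(x$flow), min(x$flow)))
  invisible(x)
}
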