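#' Vessel cross-section specification
#'
#' The imaging plane cuts the vessel at an angle `angulation` between the
#' plane normal and the flow direction. The lumen then appears elliptical
#' with semi-axes `radius` and `radius / cos(angulation)`, while the measured
#' through-plane velocity is reduced by `cos(angulation)`; the two effects
#' cancel so lumen-integrated flow is invariant to angulation (up to
#' partial-volume error).
#'
#' @param center Lumen center in pixel coordinates `c(x, y)` (1-based pixel
#'   units; fractional values allowed).
#' @param radius True lumen radius orthogonal to flow, mm.
#' @param angulation Angle between plane normal and flow direction, degrees,
#'   in `[0, 90)`.
#' @param profile Through-plane velocity profile, `"plug"` or `"parabolic"`.
#'
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(center = NULL, radius = 12, angulation = 0,
                        profile = c("plug", "parabolic")) {
  profile <- match.arg(profile)
  if (radius <= 0) stop_af("radius must be > 0", class = "invalid_vessel")
  if (angulation < 0 || angulation >= 90) {
    stop_af("angulation must be in [0, 90) degrees", class = "invalid_vessel")
  }
  structure(list(center = center, radius = radius, angulation = angulation,
                 profile = profile),
            class = "vessel_spec")
}

# Sub-pixel lumen coverage fraction for every pixel of the grid.
# Pixel (i=row=y, j=col=x) center is at (x=j, y=i); 4x4 supersampling.
lumen_coverage <- function(vessel, params) {
  g <- params$grid_size
  cx <- if (is.null(vessel$center)) (g + 1) / 2 else vessel$center[1]
  cy <- if (is.null(vessel$center)) (g + 1) / 2 else vessel$center[2]
  a <- vessel$radius / params$pixel_spacing                 # px, x semi-axis
  b <- a / cos(vessel$angulation * pi / 180)                # px, y semi-axis
  ss <- 4
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  cov <- matrix(0, g, g)
  for (ox in off) {
    for (oy in off) {
      xs <- matrix(rep(seq_len(g) + ox, each = g), g, g)    # col coordinate
      ys <- matrix(rep(seq_len(g) + oy, times = g), g, g)   # row coordinate
      cov <- cov + (((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1)
    }
  }
  cov / ss^2
}

#' Render a velocity-encoded phantom image series
#'
#' Forward-simulates the PC-CMR measurement for one vessel: a magnitude
#' stack (bright lumen, mid-intensity static tissue, dark air frame) and a
#' phase stack where pixel phase encodes through-plane velocity as
#' `phi = pi * v / venc`, wrapped into `(-pi, pi]`. The lumen velocity field
#' is scaled each phase so that lumen-integrated flow equals the input
#' waveform exactly (before noise). A planar eddy-current velocity offset
#' (`params$offset_coeffs`) is added to all tissue pixels before wrapping;
#' Gaussian velocity noise (`params$noise_sd`) is added inside tissue; air
#' pixels get uniform random phase. Boundary pixels receive area-weighted
#' (partial-volume) velocity and magnitude.
#'
#' If the peak lumen velocity reaches the VENC the series is still rendered
#' but flagged `aliased = TRUE` in the truth block, so downstream unwrapping
#' can be exercised.
#'
#' @param waveform A `flow_curve` from [build_waveform()] (length must equal
#'   `params$n_phases`).
#' @param vessel A [vessel_spec()].
#' @param params An [acquisition_params()].
#'
#' @return An object of class `phantom_series`: `magnitude` and `phase`
#'   arrays `[grid, grid, n_phases]`, `params`, `vessel`, and a `truth` list
#'   (input curve, lumen coverage/masks, static and air masks, HFR flag,
#'   end-diastolic reversal velocity, aliasing flag).
#' @export
render_phantom <- function(waveform, vessel, params) {
  stopifnot(inherits(waveform, "flow_curve"), inherits(vessel, "vessel_spec"),
            inherits(params, "acquisition_params"))
  n <- params$n_phases
  if (length(waveform$flow) != n) {
    stop_af("waveform length (%d) must equal n_phases (%d)",
            length(waveform$flow), n, class = "invalid_phantom")
  }
  g <- params$grid_size
  a_px <- params$pixel_spacing^2                       # mm^2

  cov <- lumen_coverage(vessel, params)
  if (sum(cov) == 0) stop_af("lumen does not intersect the grid", class = "invalid_phantom")

  air <- matrix(FALSE, g, g)
  air[c(1:2, (g - 1):g), ] <- TRUE
  air[, c(1:2, (g - 1):g)] <- TRUE
  if (any(cov > 0 & air)) {
    stop_af("lumen overlaps the air frame; shrink radius or grid margin",
            class = "invalid_phantom")
  }
  static_mask <- !air & cov == 0

  # per-pixel unit velocity field: full-lumen profile times coverage weight
  if (vessel$profile == "plug") {
    prof <- matrix(1, g, g)
  } else {
    cx <- if (is.null(vessel$center)) (g + 1) / 2 else vessel$center[1]
    cy <- if (is.null(vessel$center)) (g + 1) / 2 else vessel$center[2]
    a <- vessel$radius / params$pixel_spacing
    b <- a / cos(vessel$angulation * pi / 180)
    xs <- matrix(rep(seq_len(g), each = g), g, g)
    ys <- matrix(rep(seq_len(g), times = g), g, g)
    rho2 <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2
    prof <- 2 * pmax(0, 1 - rho2)
  }
  w <- cov * prof
  sw <- sum(w)
  if (sw <= 0) stop_af("degenerate velocity profile", class = "invalid_phantom")

  # velocity per unit flow so that sum(v * a_px) * FLOW_UNIT == Q
  v_unit <- w / (sw * a_px * FLOW_UNIT)

  peak_v <- max(v_unit) * max(abs(waveform$flow))
  aliased <- peak_v >= params$venc

  offs <- params$offset_coeffs
  xs <- matrix(rep(seq_len(g) - 1, each = g), g, g)
  ys <- matrix(rep(seq_len(g) - 1, times = g), g, g)
  offset_field <- offs[1] + offs[2] * xs + offs[3] * ys

  mag_base <- 30 + 70 * cov
  mag_base[air] <- 2

  magnitude <- array(0, dim = c(g, g, n))
  phase <- array(0, dim = c(g, g, n))
  tissue <- !air

  with_seed(params$seed, {
    for (k in seq_len(n)) {
      v <- v_unit * waveform$flow[k]
      v[tissue] <- v[tissue] + offset_field[tissue]
      if (params$noise_sd > 0) {
        v[tissue] <- v[tissue] + rnorm(sum(tissue), sd = params$noise_sd)
      }
      ph <- wrap_phase(pi * v / params$venc)
      ph[air] <- runif(sum(air), -pi, pi)
      phase[, , k] <- ph
      magnitude[, , k] <- mag_base
    }
  })

  a_eff <- sum(cov) * a_px                               # mm^2
  q_last <- waveform$flow[n]
  dfr_velocity <- max(0, -q_last / (FLOW_UNIT * a_eff))  # cm/s, end diastole

  spec <- attr(waveform, "spec")
  split_true <- if (!is.null(spec)) {
    sum(waveform$times < spec$systolic_fraction * params$rr_interval)
  } else {
    imax <- which.max(waveform$flow)
    neg <- which(waveform$flow <= 0)
    neg <- neg[neg > imax]
    if (length(neg)) neg[1] - 1L else length(waveform$flow) - 1L
  }
  truth <- list(
    curve = waveform,
    spec = spec,
    lumen_cov = cov,
    lumen_mask = cov >= 0.5,
    static_mask = static_mask,
    air_mask = air,
    lumen_area_mm2 = a_eff,
    hfr = all(waveform$flow[(split_true + 1):n] <= -10),
    dfr_velocity = dfr_velocity,
    aliased = aliased,
    end_systole_index = split_true + 1L
  )

  structure(list(magnitude = magnitude, phase = phase, params = params,
                 vessel = vessel, truth = truth),
            class = "phantom_series")
}

# Wrap values into (-pi, pi]; in-range values pass through untouched so the
# encode/decode round trip is exact to machine precision below the VENC.
wrap_phase <- function(x) {
  out <- x
  bad <- x <= -pi | x > pi
  out[bad] <- pi - ((pi - x[bad]) %% (2 * pi))
  out
}

#' @export
print.phantom_series <- function(x, ...) {
  cat(sprintf("<phantom_series> %dx%d px, %d phases, VENC %g cm/s%s\n",
              dim(x$magnitude)[1], dim(x$magnitude)[2], dim(x$magnitude)[3],
              x$params$venc, if (x$truth$aliased) " [aliased]" else ""))
  invisible(x)
}

#' Write / read a phantom series as plain-text artifacts
#'
#' The series is stored as two long-format CSVs (`magnitude.csv`,
#' `phase.csv` with columns `phase,row,col,value`) plus a JSON sidecar
#' (`sidecar.json`) carrying acquisition parameters, vessel geometry and the
#' ground-truth block. Text formats keep artifacts portable and diffable.
#'
#' @param phantom A `phantom_series`.
#' @param dir Output directory (created if missing).
#' @return `write_phantom` returns `dir` invisibly; `read_phantom` returns
#'   the reconstructed `phantom_series`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(phantom$magnitude)
  idx <- expand.grid(row = seq_len(dims[1]), col = seq_len(dims[2]),
                     phase = seq_len(dims[3]))
  write.csv(data.frame(phase = idx$phase, row = idx$row, col = idx$col,
                       value = as.vector(phantom$magnitude)),
            file.path(dir, "magnitude.csv"), row.names = FALSE)
  write.csv(data.frame(phase = idx$phase, row = idx$row, col = idx$col,
                       value = as.vector(phantom$phase)),
            file.path(dir, "phase.csv"), row.names = FALSE)
  truth <- phantom$truth
  sidecar <- list(
    params = unclass(phantom$params),
    vessel = unclass(phantom$vessel),
    truth = list(
      flow = truth$curve$flow, times = truth$curve$times,
      site_label = truth$curve$site_label,
      spec = if (!is.null(truth$spec)) unclass(truth$spec),
      lumen_cov = as.vector(truth$lumen_cov),
      static_mask = as.vector(truth$static_mask),
      air_mask = as.vector(truth$air_mask),
      lumen_area_mm2 = truth$lumen_area_mm2,
      hfr = truth$hfr, dfr_velocity = truth$dfr_velocity,
      aliased = truth$aliased, end_systole_index = truth$end_systole_index
    ),
    dims = dims
  )
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "sidecar.json"), simplifyVector = TRUE)
  dims <- as.integer(sc$dims)
  g <- dims[1]
  mag <- read.csv(file.path(dir, "magnitude.csv"))
  ph <- read.csv(file.path(dir, "phase.csv"))
  magnitude <- array(0, dims)
  phs <- array(0, dims)
  magnitude[cbind(mag$row, mag$col, mag$phase)] <- mag$value
  phs[cbind(ph$row, ph$col, ph$phase)] <- ph$value
  params <- do.call(acquisition_params, sc$params[names(sc$params) != ""])
  ctr <- sc$vessel$center
  ctr <- if (length(ctr)) as.numeric(unlist(ctr)) else NULL
  vessel <- vessel_spec(center = ctr, radius = sc$vessel$radius,
                        angulation = sc$vessel$angulation,
                        profile = sc$vessel$profile)
  spec <- if (!is.null(sc$truth$spec)) {
    do.call(waveform_spec, sc$truth$spec)
  }
  curve <- flow_curve(sc$truth$flow, sc$truth$times,
                      site_label = sc$truth$site_label)
  attr(curve, "spec") <- spec
  cov <- matrix(sc$truth$lumen_cov, g, g)
  truth <- list(curve = curve, spec = spec, lumen_cov = cov,
                lumen_mask = cov >= 0.5,
                static_mask = matrix(sc$truth$static_mask, g, g),
                air_mask = matrix(sc$truth$air_mask, g, g),
                lumen_area_mm2 = sc$truth$lumen_area_mm2,
                hfr = sc$truth$hfr, dfr_velocity = sc$truth$dfr_velocity,
                aliased = sc$truth$aliased,
                end_systole_index = as.integer(sc$truth$end_systole_index))
  structure(list(magnitude = magnitude, phase = phs, params = params,
                 vessel = vessel, truth = truth),
            class = "phantom_series")
}
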