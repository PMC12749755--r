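test_that("decode_velocity applies v = venc * phi / pi", {
  ph <- array(c(0, pi / 2, -pi, pi / 4), dim = c(2, 2, 1))
  vel <- decode_velocity(ph, venc = 180)
  expect_equal(vel$velocity[1, 1, 1], 0)
  expect_equal(vel$velocity[2, 1, 1], 90)
  expect_equal(vel$velocity[1, 2, 1], -180)
  expect_error(decode_velocity(ph, venc = 0), class = "invalid_venc")
})

test_that("encode/decode round trip is exact below the VENC", {
  set.seed(101)
  venc <- 180
  v <- runif(2000, -venc + 1e-9, venc - 1e-9)
  phi <- aortaflow:::wrap_phase(pi * v / venc)
  expect_identical(phi, pi * v / venc)            # wrap is a no-op in range
  expect_equal(venc * phi / pi, v, tolerance = 1e-14)
})

test_that("unwrap_aliasing is the identity on smooth sub-VENC data", {
  ph <- make_phantom(noise_sd = 1, seed = 8)
  vel <- decode_velocity(ph)
  out <- unwrap_aliasing(vel, ph$truth$lumen_mask)
  expect_identical(out$velocity, vel$velocity)
  expect_identical(attr(out, "n_unwrapped"), 0L)
})

test_that("a single wrapped pixel is shifted by 2 VENC toward the median", {
  venc <- 180
  g <- 8
  v <- array(150, dim = c(g, g, 1))
  v[4, 4, 1] <- -160                      # +200 wrapped once
  vel <- velocity_series(v, times = 0, pixel_area = 6.25, venc = venc)
  out <- unwrap_aliasing(vel, matrix(TRUE, g, g))
  expect_equal(out$velocity[4, 4, 1], 200)
  expect_identical(attr(out, "n_unwrapped"), 1L)
})

test_that("unwrapping an aliased phantom restores the truth peak within 5%", {
  ph <- make_phantom(forward = 70, rvol = 15, shape = "early_only",
                     radius = 10, profile = "parabolic", noise_sd = 0)
  expect_true(ph$truth$aliased)
  vel <- decode_velocity(ph)
  masks <- segment_lumen(ph, c(32, 32))
  out <- unwrap_aliasing(vel, masks)
  kpk <- which.max(ph$truth$curve$flow)
  truth_peak <- 2 * max(ph$truth$curve$flow) / (0.01 * ph$truth$lumen_area_mm2)
  expect_equal(max(out$velocity[, , kpk]), truth_peak, tolerance = 0.05)
})

test_that("deep aliasing beyond the wrap budget raises unrecoverable_aliasing", {
  ph <- make_phantom(forward = 90, rvol = 15, shape = "early_only",
                     radius = 10, profile = "parabolic", noise_sd = 0)
  vel <- decode_velocity(ph)
  masks <- segment_lumen(ph, c(32, 32))
  expect_error(unwrap_aliasing(vel, masks), class = "unrecoverable_aliasing")
})

test_that("background-offset fit recovers injected planes", {
  # zero offset, zero noise -> zero coefficients, series unchanged
  ph0 <- make_phantom(noise_sd = 0)
  vel0 <- decode_velocity(ph0)
  res0 <- estimate_background_offset(vel0, ph0$truth$static_mask)
  expect_equal(res0$offset$coefficients, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(res0$corrected$velocity, vel0$velocity, tolerance = 1e-10)

  # injected plane, no noise -> coefficients recovered to 4 decimals
  ph1 <- make_phantom(noise_sd = 0, offset_coeffs = c(1.0, 0.02, -0.01))
  res1 <- estimate_background_offset(decode_velocity(ph1), ph1$truth$static_mask)
  expect_equal(res1$offset$coefficients, c(1.0, 0.02, -0.01), tolerance = 1e-4)

  # constant 1.5 cm/s offset + 1 cm/s noise -> residual under the 0.6 limit
  ph2 <- make_phantom(noise_sd = 1, offset_coeffs = c(1.5, 0, 0), seed = 21)
  res2 <- estimate_background_offset(decode_velocity(ph2), ph2$truth$static_mask)
  expect_lte(res2$offset$residual_static_mean, 0.6)
})

test_that("offset correction subtracts a static field only", {
  ph <- make_phantom(noise_sd = 1, offset_coeffs = c(1.5, 0.02, -0.01), seed = 4)
  vel <- decode_velocity(ph)
  res <- estimate_background_offset(vel, ph$truth$static_mask)
  # phase-to-phase differences at each pixel are untouched
  d_before <- vel$velocity[, , 5] - vel$velocity[, , 20]
  d_after <- res$corrected$velocity[, , 5] - res$corrected$velocity[, , 20]
  expect_equal(d_after, d_before, tolerance = 1e-12)
})

test_that("a too-small static mask errors", {
  ph <- make_phantom()
  small <- matrix(FALSE, 64, 64)
  small[1:7, 1:7] <- TRUE
  expect_error(estimate_background_offset(decode_velocity(ph), small),
               class = "static_mask_too_small")
})

test_that("segmentation recovers a circular lumen area within 5%", {
  # radius 15 px on a 64-px grid
  params <- make_params(grid_size = 64)
  ph <- make_phantom(radius = 15 * params$pixel_spacing, grid_size = 64,
                     noise_sd = 0)
  masks <- segment_lumen(ph, c(32, 32))
  expect_equal(masks$areas[1], pi * 15^2 * params$pixel_spacing^2,
               tolerance = 0.05)
})

test_that("segmentation returns only the component containing the seed", {
  g <- 40
  img <- matrix(10, g, g)
  img[8:14, 8:14] <- 100      # vessel A
  img[26:32, 26:32] <- 100    # vessel B, disjoint
  stack <- array(img, dim = c(g, g, 2))
  masks <- segment_lumen(stack, seed_point = c(10, 10), pixel_area = 1)
  m <- masks$masks[, , 1]
  expect_true(all(which(m) %in% which(row(m) %in% 8:14 & col(m) %in% 8:14)))
  expect_equal(sum(m), 49)
})

test_that("tracking follows a pulsatile lumen and is deterministic", {
  g <- 48
  n <- 40
  stack <- array(10, dim = c(g, g, n))
  r0 <- 8
  for (k in seq_len(n)) {
    r <- r0 * (1 + 0.1 * sin(2 * pi * (k - 1) / n))   # +/-10% radius
    xs <- matrix(rep(seq_len(g), each = g), g, g)
    ys <- matrix(rep(seq_len(g), times = g), g, g)
    stack[, , k][((xs - 24)^2 + (ys - 24)^2) <= r^2] <- 100
  }
  m1 <- segment_lumen(stack, c(24, 24), pixel_area = 1)
  m2 <- segment_lumen(stack, c(24, 24), pixel_area = 1)
  expect_identical(m1$masks, m2$masks)
  expect_equal(length(m1$areas), n)
  expect_true(all(m1$areas > 0))
})

test_that("a collapsing lumen raises tracking_lost", {
  g <- 32
  stack <- array(10, dim = c(g, g, 2))
  stack[10:22, 10:22, 1] <- 100
  stack[15:17, 15:17, 2] <- 100   # area collapses by ~95%
  expect_error(segment_lumen(stack, c(16, 16), pixel_area = 1),
               class = "tracking_lost")
})

test_that("flow integration converts units correctly", {
  # plug 10 cm/s over 100 pixels of 6.25 mm^2 -> 62.5 mL/s
  v <- array(0, dim = c(20, 20, 1))
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE
  v[, , 1][mask] <- 10
  vel <- velocity_series(v, times = 0, pixel_area = 6.25, venc = 180)
  expect_equal(compute_flow_curve(vel, mask)$flow, 62.5)
  # zero velocity -> zero flow
  vel0 <- velocity_series(array(0, dim = c(20, 20, 3)), times = 0:2,
                          pixel_area = 6.25, venc = 180)
  expect_equal(compute_flow_curve(vel0, mask)$flow, c(0, 0, 0))
  # shape mismatch
  expect_error(compute_flow_curve(vel, matrix(TRUE, 5, 5)),
               class = "shape_mismatch")
})

test_that("segmented flow matches the generator truth without noise", {
  ph <- make_phantom(noise_sd = 0)
  curve <- quantify_phantom(ph, offset_correction = FALSE)$curve
  peak <- max(abs(ph$truth$curve$flow))
  # segmentation omits the faintest boundary pixels, so allow a small
  # value-proportional term on top of the 1%-of-peak conservation bound
  expect_true(all(abs(curve$flow - ph$truth$curve$flow) <=
                    0.01 * peak + 0.035 * abs(ph$truth$curve$flow)))
})

test_that("select_venc implements the 20% headroom rule", {
  v1 <- select_venc(170, seq(90, 480, by = 10))
  expect_equal(as.numeric(v1), 180)
  expect_lte(attr(v1, "headroom"), 0.20)
  expect_warning(v2 <- select_venc(60, seq(90, 480, by = 10)),
                 class = "venc_rule_unsatisfiable")
  expect_equal(as.numeric(v2), 90)
  expect_error(select_venc(480, seq(90, 480, by = 10)),
               class = "peak_unmeasurable")
})

test_that("flow recovery holds across angulation, noise and severity", {
  grid <- expand.grid(ang = c(0, 15, 30), noise = c(0, 1, 2),
                      rvol = c(0, 15, 45))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ph <- make_phantom(forward = 100, rvol = g$rvol,
                       shape = if (g$rvol > 0) "holodiastolic" else "none",
                       angulation = g$ang, noise_sd = g$noise,
                       seed = 100 + i)
    m <- quantify_phantom(ph)$metrics
    tol_fwd <- max(0.05 * 100, 2)
    tol_rvol <- max(0.05 * g$rvol, 2)
    expect_lt(abs(m$forward_volume - 100), tol_fwd,
              label = sprintf("forward (ang=%g noise=%g rvol=%g): %g",
                              g$ang, g$noise, g$rvol, m$forward_volume))
    expect_lt(abs(m$rvol - g$rvol), tol_rvol,
              label = sprintf("rvol (ang=%g noise=%g rvol=%g): %g",
                              g$ang, g$noise, g$rvol, m$rvol))
  }
})
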