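# piecewise curve: 12 phases at +100 mL/s (0.3 s), 24 phases at -20 mL/s (0.6 s)
piecewise_curve <- function() {
  flow_curve(c(rep(100, 12), rep(-20, 24)), times = (0:35) * 25)
}

test_that("split_phases finds the downward zero crossing", {
  split <- split_phases(piecewise_curve())
  expect_equal(split$end_systole_index, 13L)  # first diastolic phase (1-based)
  expect_equal(length(split$systole), 12L)
  expect_equal(split$method, "zero_crossing")
})

test_that("split_phases falls back when the curve never crosses zero", {
  decaying <- flow_curve(100 * exp(-(0:39) / 6) + 12, times = (0:39) * 25)
  expect_warning(split <- split_phases(decaying), class = "split_fallback")
  expect_true(split$method %in% c("low_flow_fallback", "fixed_fraction_fallback"))
  expect_error(split_phases(flow_curve(c(-5, -3, -1, -2, -4, -6, -2, -1),
                                       times = 0:7 * 100)),
               class = "no_forward_ejection")
})

test_that("split matches the generator truth within one phase", {
  for (frac in c(0.30, 0.35, 0.45)) {
    wf <- build_waveform(waveform_spec(80, rvol_true = 25,
                                       reversal_shape = "holodiastolic",
                                       systolic_fraction = frac),
                         make_params())
    ph <- make_phantom(forward = 80, rvol = 25)
    split <- split_phases(wf)
    truth_idx <- sum(wf$times < frac * 1000) + 1L
    expect_lte(abs(split$end_systole_index - truth_idx), 1L)
  }
})

test_that("compute_metrics reproduces piecewise-constant arithmetic", {
  m <- compute_metrics(piecewise_curve())
  expect_equal(m$forward_volume, 30)   # 100 mL/s * 0.3 s
  expect_equal(m$rvol, 12)             # 20 mL/s * 0.6 s
  expect_equal(m$rf, 40)
  expect_equal(m$systolic_backward_volume, 0)
})

test_that("an all-positive curve has zero regurgitation", {
  cv <- flow_curve(pmax(sin(2 * pi * (0:39) / 40), 0) * 100 + 1,
                   times = (0:39) * 25)
  suppressWarnings(m <- compute_metrics(cv))
  expect_equal(m$rvol, 0)
  expect_equal(m$rf, 0)
})

test_that("rf * forward / 100 equals rvol to machine precision", {
  set.seed(7)
  for (i in 1:20) {
    q <- rnorm(40, 30, 60)
    q[1:8] <- abs(q[1:8]) + 50            # guarantee forward ejection
    cv <- flow_curve(q, times = (0:39) * 25)
    m <- suppressWarnings(compute_metrics(cv))
    expect_equal(m$rf * m$forward_volume / 100, m$rvol, tolerance = 1e-12)
  }
})

test_that("deepening the diastolic reversal never decreases RVol or RF", {
  base <- c(rep(100, 12), rep(-15, 24))
  times <- (0:35) * 25
  prev <- compute_metrics(flow_curve(base, times))
  for (extra in c(2, 5, 10, 20)) {
    q <- base
    q[13:36] <- q[13:36] - extra
    m <- compute_metrics(flow_curve(q, times))
    expect_gte(m$rvol, prev$rvol)
    expect_gte(m$rf, prev$rf)
    prev <- m
  }
})

test_that("HFR detection is boundary-inclusive at -10 mL/s", {
  times <- (0:35) * 25
  hold <- function(level) {
    detect_hfr(flow_curve(c(rep(100, 12), rep(level, 24)), times))
  }
  expect_true(hold(-15))
  expect_true(hold(-10))    # exactly the floor counts
  dip <- c(rep(100, 12), rep(-15, 24))
  dip[20] <- -8             # one shallow diastolic phase
  expect_false(detect_hfr(flow_curve(dip, times)))
})

test_that("HFR implies positive RVol; no reversal implies tiny RVol", {
  ph <- make_phantom(forward = 80, rvol = 30, shape = "holodiastolic",
                     noise_sd = 1, seed = 31)
  res <- quantify_phantom(ph)
  expect_true(res$metrics$hfr)
  expect_gt(res$metrics$rvol, 0)
  ph0 <- make_phantom(forward = 80, rvol = 0, shape = "none",
                      noise_sd = 1, seed = 32)
  res0 <- quantify_phantom(ph0)
  expect_false(res0$metrics$hfr)
  expect_lt(res0$metrics$rvol, 0.5)
})

test_that("DFR velocity follows the end-diastolic spatial mean", {
  g <- 10
  v <- array(0, dim = c(g, g, 4))
  mask <- matrix(TRUE, g, g)
  v[, , 4] <- -25
  vel <- velocity_series(v, times = 0:3 * 100, pixel_area = 6.25, venc = 180)
  split <- list(diastole = 3:4, systole = 1:2)
  d <- compute_dfr_velocity(vel, mask, split)
  expect_equal(d$dfr_velocity, 25)
  expect_true(d$dfr_positive)
  # zero diastolic velocity
  v0 <- velocity_series(array(0, dim = c(g, g, 4)), times = 0:3 * 100,
                        pixel_area = 6.25, venc = 180)
  d0 <- compute_dfr_velocity(v0, mask, split)
  expect_equal(d0$dfr_velocity, 0)
  expect_false(d0$dfr_positive)
  # exactly at the cut-off: strict "greater than"
  v19 <- v0
  v19$velocity[, , 4] <- -19.5
  d19 <- compute_dfr_velocity(v19, mask, split)
  expect_equal(d19$dfr_velocity, 19.5)
  expect_false(d19$dfr_positive)
  # the time-averaged alternative
  dm <- compute_dfr_velocity(vel, mask, split, method = "mean_diastole")
  expect_equal(dm$dfr_velocity, 12.5)
})

test_that("severity flags use strict '>' and diameter uses '>='", {
  mk <- function(rvol, rf) {
    structure(list(rvol = rvol, rf = rf, hfr = FALSE), class = "regurg_metrics")
  }
  call <- classify_severity(metrics_aao = mk(42, 33), metrics_da = mk(18, 23),
                            diameter = 40)
  expect_false(call$significant_aao_rvol)   # exactly 42 is not significant
  expect_false(call$significant_aao_rf)     # exactly 33 is not significant
  expect_true(call$significant_da_rvol)     # 18 > 17
  expect_false(call$significant_da_rf)      # exactly 23 is not significant
  expect_equal(call$diameter_class, "dilated")  # 40 mm is dilated
  expect_equal(classify_severity(diameter = 39.9)$diameter_class, "normal")
})

test_that("reproducibility percentage is the relative absolute difference", {
  expect_equal(reproducibility_pct(20, 20), 0)
  expect_equal(reproducibility_pct(10, 20), 200 / 3, tolerance = 1e-12)
  expect_error(reproducibility_pct(5, -5), class = "zero_pair_mean")
})

test_that("metrics are invariant to declaring times in seconds", {
  q <- c(rep(100, 12), rep(-20, 24))
  m_ms <- compute_metrics(flow_curve(q, (0:35) * 25, time_unit = "ms"))
  m_s <- compute_metrics(flow_curve(q, (0:35) * 0.025, time_unit = "s"))
  expect_equal(m_s$rvol, m_ms$rvol)
  expect_equal(m_s$rf, m_ms$rf)
  expect_equal(m_s$hfr, m_ms$hfr)
})

test_that("metrics computed from truth curves close the generator loop", {
  grid <- expand.grid(forward = c(60, 100), rvol = c(15, 45))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    wf <- build_waveform(waveform_spec(g$forward, rvol_true = g$rvol,
                                       reversal_shape = "holodiastolic"),
                         make_params())
    m <- compute_metrics(wf)
    expect_equal(m$forward_volume, g$forward, tolerance = 0.005)
    expect_equal(m$rvol, g$rvol, tolerance = 0.005)
    expect_equal(m$rf, 100 * g$rvol / g$forward, tolerance = 0.01)
  }
})
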