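# Shared fixtures built in code: small phantoms and cohorts.

make_params <- function(venc = 180, noise_sd = 0, offset_coeffs = c(0, 0, 0),
                        seed = 1L, grid_size = 64, n_phases = 40) {
  acquisition_params(venc = venc, n_phases = n_phases, grid_size = grid_size,
                     noise_sd = noise_sd, offset_coeffs = offset_coeffs,
                     seed = seed)
}

make_phantom <- function(forward = 80, rvol = 30,
                         shape = "holodiastolic", angulation = 0,
                         radius = 12, profile = "plug", ...) {
  params <- make_params(...)
  spec <- waveform_spec(forward, rvol_true = rvol, reversal_shape = shape)
  wf <- build_waveform(spec, params)
  render_phantom(wf, vessel_spec(radius = radius, angulation = angulation,
                                 profile = profile), params)
}

# rectangle-rule cycle integrals, the package-wide convention
curve_integrals <- function(curve) {
  dt <- mean(diff(curve$times)) / 1000
  q <- curve$flow
  list(forward = sum(pmax(q, 0)) * dt, backward = -sum(pmin(q, 0)) * dt)
}

# brute-force pairwise Mann-Whitney AUC oracle (ties count one half)
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
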