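# Shared fixtures, built in code. Expensive ones are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the standard air / bone / glass stack of the synthetic studies
bone_stack <- function(thickness_um = 100) {
  sample_on_substrate(1.8, 0.08, n3 = 2.6, kappa3 = 0.15,
                      thickness_um = thickness_um)
}

# shorter pulse than the package default: 64 ps window keeps the tests fast
# while leaving ~45 bins in the 0.3-1 THz band
test_pulse <- function(span_ps = 64) pulse_spec(span_ps = span_ps)

# sample/reference pair with the reference plane on the glass surface
fixture_pair <- function(offset_um = 100, thickness_um = 100) {
  memo(sprintf("pair_%g_%g", offset_um, thickness_um), {
    scene <- synthetic_scene(bone_stack(thickness_um),
                             reference_offset = offset_um * 1e-6)
    synthesize_waveforms(scene, test_pulse())
  })
}

fixture_offset_result <- function(offset_um = 100, thickness_um = 100) {
  memo(sprintf("off_%g_%g", offset_um, thickness_um), {
    pair <- fixture_pair(offset_um, thickness_um)
    H0 <- measured_h(pair$sample, pair$reference)
    retrieve_phase_offset(H0)
  })
}

# exact model H for the bone stack on an arbitrary angular-frequency grid
bone_H_exact <- function(omega, thickness_um = 100) {
  transfer_function(bone_stack(thickness_um), omega)
}

# Lorentz-oscillator medium: causal single-resonance dielectric under the
# exp(+iwt), n - i*kappa convention. Used as the independent oracle for the
# dispersion relations.
lorentz_index <- function(omega, eps_inf = 2.25, f_plasma_thz = 1,
                          f0_thz = 1.5, gamma_thz = 0.4) {
  wp <- 2 * pi * f_plasma_thz * 1e12
  w0 <- 2 * pi * f0_thz * 1e12
  g <- 2 * pi * gamma_thz * 1e12
  nt <- sqrt(eps_inf + wp^2 / (w0^2 - omega^2 + 1i * g * omega))
  flip <- Im(nt) > 0
  nt[flip] <- -nt[flip]
  nt
}

# normal-incidence reflectivity of the Lorentz medium, sign-flipped so the
# phase tends to zero at both frequency extremes (KK-transformable as-is)
lorentz_reflectivity <- function(omega) {
  nt <- lorentz_index(omega)
  -(1 - nt) / (1 + nt)
}

# wide tabulation grid for oracle tests of the dispersion integrals
lorentz_grid <- function(n = 1500, fmax_thz = 40) {
  dw <- 2 * pi * fmax_thz * 1e12 / n
  seq(dw, 2 * pi * fmax_thz * 1e12, by = dw)
}
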