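test_that("snell_angle satisfies the refraction law", {
  air <- complex_index(1); glass <- complex_index(1.5)
  expect_equal(snell_angle(air, glass, 0), 0)
  expect_equal(snell_angle(glass, glass, 0.4), 0.4)
  expect_equal(snell_angle(air, glass, pi / 6), asin(sin(pi / 6) / 1.5))
  # total internal reflection gives a complex angle, not an error
  th <- snell_angle(glass, air, 60 * pi / 180)
  expect_true(Im(th) != 0)
  expect_lt(Mod(sin(th) - 1.5 * sin(60 * pi / 180)), 1e-12)
})

test_that("fresnel_r reproduces closed forms and the Brewster zero", {
  m <- complex_index(1.8, 0)
  expect_equal(fresnel_r(m, m, 0.3, "s"), 0 + 0i)
  expect_equal(fresnel_r(complex_index(1), complex_index(1.8), 0, "s"),
               as.complex((1 - 1.8) / (1 + 1.8)), tolerance = 1e-12)
  # antisymmetry at normal incidence
  expect_equal(fresnel_r(complex_index(1), m, 0, "p"),
               -fresnel_r(m, complex_index(1), 0, "p"), tolerance = 1e-12)
  # p-polarisation vanishes at the Brewster angle
  rb <- fresnel_r(complex_index(1), complex_index(1.5), atan(1.5), "p")
  expect_lt(Mod(rb), 1e-12)
})

test_that("fresnel_t follows the Stokes relations", {
  air <- complex_index(1); m <- complex_index(1.8)
  expect_equal(fresnel_t(m, m, 0.2, "s"), 1 + 0i)
  expect_equal(fresnel_t(air, m, 0, "s"), as.complex(2 / 2.8),
               tolerance = 1e-12)
  # T12 * T21 = 1 - R12^2 at normal incidence for lossless media
  t12 <- fresnel_t(air, m, 0, "s"); t21 <- fresnel_t(m, air, 0, "s")
  r12 <- fresnel_r(air, m, 0, "s")
  expect_equal(t12 * t21, 1 - r12^2, tolerance = 1e-12)
})

test_that("single-interface energy balance and passivity hold", {
  air <- complex_index(1)
  for (n2 in c(1.3, 1.8, 2.6)) {
    m <- complex_index(n2)
    for (th in seq(0, 80, by = 10) * pi / 180) {
      r <- fresnel_r(air, m, th, "s")
      t <- fresnel_t(air, m, th, "s")
      th2 <- Re(snell_angle(air, m, th))
      balance <- Mod(r)^2 + (n2 * cos(th2)) / cos(th) * Mod(t)^2
      expect_equal(balance, 1, tolerance = 1e-10)
      expect_lte(Mod(r), 1)
    }
  }
  # lossy media still reflect with |R| <= 1
  expect_lte(Mod(fresnel_r(air, complex_index(2.6, 0.5), 0.5, "p")), 1)
})

test_that("s and p polarisations coincide at normal incidence", {
  ni <- complex_index(1); nj <- complex_index(2.6, 0.15)
  expect_equal(fresnel_r(ni, nj, 0, "s"), fresnel_r(ni, nj, 0, "p"),
               tolerance = 1e-12)
  st_s <- bone_stack(); st_p <- bone_stack()
  st_p$polarisation <- "p"
  omega <- thz_to_omega(seq(0.3, 1, by = 0.05))
  expect_equal(transfer_function(st_s, omega), transfer_function(st_p, omega),
               tolerance = 1e-12)
})

test_that("propagation has the closed-form magnitude and exponential law", {
  m <- complex_index(1.8, 0.08)
  expect_equal(propagation(m, thz_to_omega(0.5), 0), 1 + 0i)
  p <- propagation(m, thz_to_omega(0.5), 100e-6)
  expect_equal(Mod(p),
               exp(-0.08 * thz_to_omega(0.5) * 100e-6 / 299792458),
               tolerance = 1e-12)
  expect_equal(Mod(p), 0.9196, tolerance = 1e-4)
  expect_equal(propagation(m, thz_to_omega(0.5), 30e-6) *
                 propagation(m, thz_to_omega(0.5), 70e-6),
               p, tolerance = 1e-12)
  # oblique incidence lengthens the path by 1/cos(theta)
  pob <- propagation(m, thz_to_omega(0.5), 100e-6, pi / 4)
  expect_equal(Mod(pob), Mod(p)^(1 / cos(pi / 4)), tolerance = 1e-10)
})

test_that("transfer_function: limits, series/closed-form agreement, divergence", {
  omega <- thz_to_omega(seq(0.3, 1, by = 0.05))
  # sample identical to the reference layer: H = 1
  same <- sample_on_substrate(2.6, 0.15, thickness_um = 100)
  expect_equal(transfer_function(same, omega), rep(1 + 0i, length(omega)),
               tolerance = 1e-12)
  # opaque layer 2: the FP series vanishes and H -> R12 / R13
  opaque <- sample_on_substrate(1.8, 0.8, thickness_um = 2000)
  co12 <- fresnel_r(complex_index(1), complex_index(1.8, 0.8), 0, "s")
  co13 <- fresnel_r(complex_index(1), complex_index(2.6, 0.15), 0, "s")
  expect_equal(transfer_function(opaque, omega),
               rep(co12 / co13, length(omega)), tolerance = 1e-8)
  # geometric-series oracle: 50 explicit echo terms match the closed form
  st <- bone_stack()
  expect_equal(transfer_function(st, omega, n_terms = 50),
               transfer_function(st, omega), tolerance = 1e-10)
  # per-order walk-off factors break the geometric structure
  st$walkoff <- c(1, 0.9, 0.8)
  expect_error(transfer_function(st, omega), "walk-off")
  expect_silent(transfer_function(st, omega, n_terms = 20))
  # gain media make the series diverge
  gain <- bone_stack()
  gain$layers[[2]]$index$kappa <- -2   # bypass the passivity check on purpose
  expect_error(transfer_function(gain, thz_to_omega(0.5)), "divergent")
})

test_that("transfer_function is continuous in (n2, kappa2)", {
  omega <- thz_to_omega(0.6)
  base <- transfer_function(bone_stack(), omega)
  for (d in c(1e-6, 1e-7)) {
    st <- sample_on_substrate(1.8 + d, 0.08 + d, thickness_um = 100)
    expect_lt(Mod(transfer_function(st, omega) - base), 100 * d)
  }
})

test_that("synthesized waveforms obey the reflection geometry", {
  pulse <- test_pulse()
  # layer 2 identical to layer 3, no offset: sample == reference
  same <- synthetic_scene(sample_on_substrate(2.6, 0.15, thickness_um = 50))
  pr <- synthesize_waveforms(same, pulse)
  expect_equal(pr$sample$amplitude, pr$reference$amplitude, tolerance = 1e-12)
  expect_equal(pr$sample$time, pr$reference$time)

  # echo delay of an intermediate-thickness layer: 2 n2 L / c after the
  # front-surface reflection, within one sample
  L <- 800e-6
  sc <- synthetic_scene(sample_on_substrate(1.8, 0.02, thickness_um = L * 1e6))
  pr2 <- synthesize_waveforms(sc, pulse_spec(span_ps = 128))
  dtv <- pr2$sample$time[2] - pr2$sample$time[1]
  main <- which.max(abs(pr2$sample$amplitude))
  later <- abs(pr2$sample$amplitude)
  later[seq_len(main + round(4e-12 / dtv))] <- 0   # blank the main pulse
  echo <- which.max(later)
  delay <- (echo - main) * dtv
  expect_lt(abs(delay - 2 * 1.8 * L / 299792458), dtv)

  # a thick lossy layer shows no echo inside the span
  thick <- synthetic_scene(sample_on_substrate(1.8, 0.3, thickness_um = 2e4))
  pr3 <- synthesize_waveforms(thick, pulse)
  a <- abs(pr3$sample$amplitude)
  m3 <- which.max(a)
  tail_start <- m3 + round(8e-12 / dtv)
  expect_lt(max(a[tail_start:length(a)]), 1e-3 * max(a))

  # determinism: identical scene and seed reproduce bit-identical noise
  noisy <- synthetic_scene(bone_stack(), reference_offset = 1e-4,
                           noise_rms = 0.01, seed = 7)
  n1 <- synthesize_waveforms(noisy, pulse)
  n2 <- synthesize_waveforms(noisy, pulse)
  expect_identical(n1$sample$amplitude, n2$sample$amplitude)
  expect_identical(n1$reference$amplitude, n2$reference$amplitude)
})

test_that("pulse_spec rejects undersampled bands", {
  expect_error(pulse_spec(band_thz = c(0.3, 3), dt_ps = 0.25), "Nyquist")
  expect_error(pulse_spec(band_thz = c(1, 0.3)), "lower")
})
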