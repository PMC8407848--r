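# Oracles: a Lorentz-oscillator dielectric provides causally self-consistent
# (amplitude, phase) pairs; brute-force quadrature checks the PV integral.

test_that("pv_integral vanishes for constants and matches a closed form", {
  grid <- seq(thz_to_omega(0.01), thz_to_omega(40), by = thz_to_omega(0.01))
  w <- thz_to_omega(3); w1 <- thz_to_omega(7)
  # constant numerator: the two PV pieces cancel over [0, Inf); on the
  # finite 0-40 THz grid the value must be small relative to the constant
  expect_lt(abs(pv_integral(rep(2, length(grid)), grid, w, w1)), 1e-3 * 2)
  # numerator (x - w)(x^2 - w1^2) cancels one pole factor of each kind,
  # leaving int 1/(x + w) dx = log((X + w)/(x0 + w)) exactly
  f <- (grid - w) * (grid^2 - w1^2)
  closed <- log((grid[length(grid)] + w) / (grid[1] + w))
  expect_equal(pv_integral(f, grid, w, w1), closed, tolerance = 1e-5)
})

test_that("pv_integral matches dense-grid brute-force quadrature", {
  step <- thz_to_omega(0.005)
  grid <- seq(step, thz_to_omega(40), by = step)
  f <- 1 / (1 + ((grid - thz_to_omega(5)) / thz_to_omega(1))^2)
  w <- thz_to_omega(3); w1 <- thz_to_omega(7)
  v <- pv_integral(f, grid, w, w1)
  # independent oracle: trapezoid on a 10x finer grid, the singular samples
  # excluded symmetrically
  h <- grid[2] - grid[1]
  fine <- seq(grid[1], grid[length(grid)], by = h / 10)
  ff <- 1 / (1 + ((fine - thz_to_omega(5)) / thz_to_omega(1))^2)
  integ <- ff / ((fine^2 - w^2) * (fine^2 - w1^2))
  integ[abs(fine - w) < h / 25 | abs(fine - w1) < h / 25] <- 0
  brute <- sum(integ) * h / 10
  expect_equal(v, brute, tolerance = 1e-4)
})

test_that("pv_integral validates its inputs", {
  grid <- seq(1, 100, by = 1)
  f <- rep(1, 100)
  expect_error(pv_integral(f, grid, 150, 7), "outside")
  expect_error(pv_integral(f, grid, 50, 50), "coincide")
  expect_error(pv_integral(f, c(grid[-100], 104), 50, 7), "uniform")
})

lorentz_tab <- function() {
  wb <- lorentz_grid()
  r <- lorentz_reflectivity(wb)
  list(wb = wb, lnA = log(Mod(r)), th = unwrap_phase(Arg(r)))
}
wide_settings <- function(anchor_thz = 0.6)
  kk_settings(anchor_thz = anchor_thz, grid_refine = 1, grid_extent = 1,
              extrapolation = "hold")
central <- function(wb) wb > thz_to_omega(0.35) & wb < thz_to_omega(0.95)

test_that("sskk_phase: flat amplitude gives zero phase; Lorentz oracle agrees", {
  tab <- lorentz_tab()
  # flat amplitude is minimum phase with zero phase, also on a narrow band
  wb2 <- thz_to_omega(seq(0.3, 1, by = 0.01))
  flat <- sskk_phase(wb2, rep(log(0.5), length(wb2)),
                     anchor_phase = 0,
                     settings = kk_settings(extrapolation = "hold"))
  expect_lt(max(abs(flat)), 1e-3)
  ix <- which.min(abs(tab$wb - thz_to_omega(0.6)))
  ph <- sskk_phase(tab$wb, tab$lnA, anchor_phase = tab$th[ix],
                   settings = wide_settings())
  expect_lt(max(abs(ph - tab$th)[central(tab$wb)]), 0.05)
})

test_that("sskk_phase is robust to the anchor choice", {
  tab <- lorentz_tab()
  ix1 <- which.min(abs(tab$wb - thz_to_omega(0.6)))
  ix2 <- which.min(abs(tab$wb - thz_to_omega(0.85)))
  ph1 <- sskk_phase(tab$wb, tab$lnA, tab$th[ix1], wide_settings(0.6))
  ph2 <- sskk_phase(tab$wb, tab$lnA, tab$th[ix2], wide_settings(0.85))
  expect_lt(max(abs(ph1 - ph2)[central(tab$wb)]), 0.02)
})

test_that("sskk_lnamp mirrors the phase relation and round-trips", {
  tab <- lorentz_tab()
  ix <- which.min(abs(tab$wb - thz_to_omega(0.6)))
  # zero phase: log-amplitude constant at the anchor value
  const <- sskk_lnamp(tab$wb, rep(0, length(tab$wb)),
                      anchor_lnamp = -1.2, settings = wide_settings())
  expect_equal(const, rep(-1.2, length(const)), tolerance = 1e-9)
  la <- sskk_lnamp(tab$wb, tab$th, anchor_lnamp = tab$lnA[ix],
                   settings = wide_settings())
  expect_lt(max(abs(la - tab$lnA)[central(tab$wb)]), 0.05)
  # round trip on self-consistent data: phase of the reconstructed
  # amplitude reproduces the input phase within quadrature error
  ph_rt <- sskk_phase(tab$wb, la, anchor_phase = tab$th[ix],
                      settings = wide_settings())
  expect_lt(max(abs(ph_rt - tab$th)[central(tab$wb)]), 0.05)
})

test_that("consistency_error separates causal pairs from ramp-corrupted ones", {
  # causal fixture: exact transfer function of the bone stack on the band
  wb <- thz_to_omega(seq(0.3, 1, by = 0.01))
  H <- bone_H_exact(wb)
  lnA <- log(Mod(H)); th <- unwrap_phase(Arg(H))
  st <- kk_settings()
  good <- consistency_error(wb, lnA, th, st)
  expect_lt(good, 0.05)    # ~10x the quadrature tolerance of the transforms
  ramp <- th + wb * 2 * 200e-6 / 299792458
  bad <- consistency_error(wb, lnA, ramp, st)
  expect_gt(bad, 10 * good)
  expect_error(consistency_error(wb[1], lnA[1], th[1], st), "degenerate")
})

test_that("plane offsets are recovered within tolerance in few iterations", {
  # injected 200 um offset (the magnitude of the paraffin-wax demonstration)
  pair <- fixture_pair(offset_um = 200)
  H0 <- measured_h(pair$sample, pair$reference)
  off <- retrieve_phase_offset(H0)
  expect_lt(abs(off$delta_L - 200e-6), 2e-6)
  expect_lte(off$iterations, 10)
  expect_true(off$converged)

  # zero injected offset: recovered within one first-level grid step
  pair0 <- fixture_pair(offset_um = 0, thickness_um = 1e-4)  # near-bare glass
  H00 <- measured_h(pair0$sample, pair0$reference)
  off0 <- retrieve_phase_offset(H00)
  step1 <- diff(range(kk_settings()$offset_range_m)) / (256 - 1)
  expect_lt(abs(off0$delta_L), step1)
})

test_that("the consistency score is minimised at the true offset", {
  # coarse exhaustive scan on exact-model data, true offset on the grid
  wb <- thz_to_omega(seq(0.3, 1, by = 0.01))
  dL <- 100e-6
  H <- bone_H_exact(wb) * exp(1i * wb * 2 * dL / 299792458)
  lnA <- log(Mod(H)); th <- unwrap_phase(Arg(H))
  st <- kk_settings()
  cands <- seq(-500e-6, 500e-6, by = 100e-6)
  scores <- vapply(cands, function(D)
    consistency_error(wb, lnA, th - D * 2 * wb / 299792458, st), numeric(1))
  expect_equal(cands[which.min(scores)], dL)
})

test_that("offset retrieval reporting: history, flags, warnings", {
  off <- fixture_offset_result()
  expect_true(all(diff(off$consistency_history) <= 0))
  # narrow candidate range pushes the minimum onto the boundary
  pair <- fixture_pair()
  H0 <- measured_h(pair$sample, pair$reference)
  expect_warning(
    retrieve_phase_offset(H0, kk_settings(offset_range_m = c(-50e-6, 50e-6),
                                          max_iterations = 2)),
    "too narrow")
  # starved iteration budget yields a flagged (not failed) result
  expect_message(
    res <- retrieve_phase_offset(H0, kk_settings(max_iterations = 1)),
    "flagged")
  expect_false(res$converged)
})

test_that("recovered offset is insensitive to the anchor frequency", {
  pair <- fixture_pair()
  H0 <- measured_h(pair$sample, pair$reference)
  d1 <- retrieve_phase_offset(H0, kk_settings(anchor_thz = 0.45))$delta_L
  d2 <- retrieve_phase_offset(H0, kk_settings(anchor_thz = 0.85))$delta_L
  expect_lt(abs(d1 - d2), 1e-6)
})

test_that("offset converts to thickness for the sample-on-reference geometry", {
  expect_equal(offset_to_thickness(100e-6), 100e-6)
  expect_warning(z <- offset_to_thickness(0), "no sample layer")
  expect_equal(z, 0)
  expect_error(offset_to_thickness(-1e-6), "negative")
  # synthetic bone-on-glass round trip: retrieved thickness within 2 um
  off <- fixture_offset_result(offset_um = 100, thickness_um = 100)
  expect_lt(abs(offset_to_thickness(off) - 100e-6), 2e-6)
  # the corrected phase has residual slope equivalent to < 2 um
  wb <- off$omega_band
  truth <- unwrap_phase(Arg(bone_H_exact(wb)))
  resid <- off$corrected_phase - truth
  slope <- stats::coef(stats::lm(resid ~ wb))[["wb"]]
  expect_lt(abs(slope * 299792458 / 2), 2e-6)
})
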