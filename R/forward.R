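#' Complex Snell refraction angle
#'
#' Solves \eqn{\tilde n_1 \sin\theta_1 = \tilde n_2 \sin\theta_2}. Beyond the
#' critical angle the returned angle is complex (evanescent transmission);
#' no error is raised.
#'
#' @param n1,n2 [complex_index] objects (or complex numbers) of the incidence
#'   and refraction media.
#' @param theta1 angle of incidence, radians.
#' @return complex refraction angle (real for transparent media below the
#'   critical angle).
#' @export
snell_angle <- function(n1, n2, theta1) {
  z <- as_ntilde(n1) / as_ntilde(n2) * sin(theta1)
  th2 <- casin(z)
  if (all(abs(Im(th2)) < 1e-12 * pmax(1, abs(Re(th2))))) Re(th2) else th2
}

# complex arcsine, principal branch
casin <- function(z) {
  z <- as.complex(z)
  -1i * log(1i * z + sqrt(1 - z^2))
}

fresnel_cos_j <- function(ni, nj, thetai) {
  sqrt(1 - (ni / nj * sin(thetai))^2)
}

#' Fresnel reflection coefficient of a single interface
#'
#' Field reflection coefficient \eqn{R_{ij}} for a wave in medium `i`
#' incident on medium `j` at angle `thetai`, for s- or p-polarisation. At
#' normal incidence the two polarisations coincide and
#' \eqn{R_{ij} = -R_{ji}}.
#'
#' @param ni,nj [complex_index] objects (or complex numbers) for media `i`
#'   and `j`.
#' @param thetai angle of incidence in medium `i`, radians.
#' @param pol `"s"` or `"p"`.
#' @return complex reflection coefficient (vector if the indices are
#'   tabulated).
#' @export
fresnel_r <- function(ni, nj, thetai, pol = c("s", "p")) {
  pol <- match.arg(pol)
  ni <- as_ntilde(ni); nj <- as_ntilde(nj)
  cj <- fresnel_cos_j(ni, nj, thetai)
  ci <- cos(thetai)
  if (pol == "s") (ni * ci - nj * cj) / (ni * ci + nj * cj)
  else            (ni * cj - nj * ci) / (ni * cj + nj * ci)
}

#' Fresnel transmission coefficient of a single interface
#'
#' Related to the reflection coefficient by \eqn{T_{kl,s} = 1 + R_{kl,s}} and
#' \eqn{T_{kl,p} = (1 + R_{kl,p}) \cos\theta_k / \cos\theta_l}.
#'
#' @inheritParams fresnel_r
#' @param nk,nl [complex_index] objects (or complex numbers) for media `k`
#'   and `l`.
#' @param thetak angle of incidence in medium `k`, radians.
#' @return complex transmission coefficient.
#' @export
fresnel_t <- function(nk, nl, thetak, pol = c("s", "p")) {
  pol <- match.arg(pol)
  nk <- as_ntilde(nk); nl <- as_ntilde(nl)
  r <- fresnel_r(nk, nl, thetak, pol)
  if (pol == "s") 1 + r
  else (1 + r) * cos(thetak) / fresnel_cos_j(nk, nl, thetak)
}

#' Plane-wave propagation factor through a layer
#'
#' \eqn{P_q(\omega, L) = \exp(-i \tilde n_q \omega L_{eff} / c)} with the
#' oblique-incidence path \eqn{L_{eff} = L / \cos\theta_q}. The magnitude is
#' \eqn{\exp(-\kappa \omega L_{eff} / c)}.
#'
#' @param nq [complex_index] (or complex number) of the traversed medium.
#' @param omega angular frequency, rad/s (vector allowed).
#' @param L geometric path length in metres, `>= 0`.
#' @param thetaq propagation angle inside the medium, radians (complex
#'   allowed).
#' @return complex propagation factor.
#' @export
propagation <- function(nq, omega, L, thetaq = 0) {
  if (any(L < 0)) stop("L must be >= 0")
  exp(-1i * as_ntilde(nq) * omega * (L / cos(thetaq)) / C_LIGHT)
}

# interface/propagation ingredients for the three-layer stack at omega
stack_coefficients <- function(stack, omega, L2 = NULL) {
  l <- stack$layers
  if (is.null(L2)) L2 <- l[[2]]$thickness
  n1 <- as_ntilde(l[[1]]$index)
  n2 <- as_ntilde(l[[2]]$index)
  n3 <- as_ntilde(l[[3]]$index)
  pol <- stack$polarisation
  th1 <- stack$theta1
  th2 <- snell_angle(l[[1]]$index, l[[2]]$index, th1)
  list(
    R12 = fresnel_r(n1, n2, th1, pol),
    R21 = fresnel_r(n2, n1, th2, pol),
    R13 = fresnel_r(n1, n3, th1, pol),
    R23 = fresnel_r(n2, n3, th2, pol),
    T12 = fresnel_t(n1, n2, th1, pol),
    T21 = fresnel_t(n2, n1, th2, pol),
    P2  = propagation(n2, omega, L2, th2),
    th2 = th2
  )
}

#' Reflection transfer function of the three-layer stack
#'
#' Ratio of the sample-reflected to reference-reflected field for the
#' air/sample/substrate geometry, with the incidence-medium propagation
#' \eqn{P_1} set to unity (the plane-offset correction is handled separately
#' by the Kramers-Kronig stage):
#' \deqn{H(\omega) = \frac{1}{R_{13}}\left[A_{wo,1} R_{12} +
#'   A_{wo,2} T_{12} P_2^2 R_{23} T_{21} +
#'   A_{wo,3} T_{12} P_2^4 R_{23}^2 R_{21} T_{21} + \dots\right]}
#' The Fabry-Perot series is summed in closed form (exact geometric sum) when
#' all walk-off factors are 1, and term by term otherwise or when `n_terms`
#' is given. Echoes inside the substrate are taken to fall outside the
#' measurement window and are not modelled.
#'
#' @param stack a [layer_stack]; layer 3 is the known reference.
#' @param omega angular frequency grid, rad/s.
#' @param L2 sample thickness in metres; defaults to the layer-2 thickness
#'   stored in the stack.
#' @param n_terms `"closed_form"` (default when all walk-off factors are 1)
#'   or a positive integer number of echo terms to sum explicitly.
#' @return complex vector `H(omega)`.
#' @export
transfer_function <- function(stack, omega, L2 = NULL, n_terms = "closed_form") {
  co <- stack_coefficients(stack, omega, L2)
  ratio <- co$P2^2 * co$R23 * co$R21
  closed <- identical(n_terms, "closed_form")
  if (closed && !all(stack$walkoff == 1))
    stop("closed-form sum requires all walk-off factors equal to 1; ",
         "pass an integer n_terms instead")
  if (any(Mod(ratio) >= 1))
    stop("divergent Fabry-Perot series: |P2^2 R23 R21| >= 1 (unphysical gain)")
  if (closed) {
    fp <- co$T12 * co$T21 * co$P2^2 * co$R23 / (1 - ratio)
    num <- co$R12 + fp
  } else {
    m <- as.integer(n_terms)
    stopifnot(m >= 1)
    A <- rep_len(stack$walkoff, m)
    num <- A[1] * co$R12
    if (m >= 2) {
      term <- co$T12 * co$T21 * co$P2^2 * co$R23
      for (k in 2:m) {
        num <- num + A[k] * term
        term <- term * ratio
      }
    }
  }
  num / co$R13
}

#' Gaussian excitation pulse
#'
#' Gaussian magnitude spectrum with flat (pure-delay) phase; the stated band
#' edges are the -20 dB points of the magnitude.
#'
#' @param band_thz lower and upper band edges in THz.
#' @param amplitude peak spectral amplitude, arbitrary units.
#' @param span_ps length of the time window, ps.
#' @param dt_ps sampling interval, ps; must oversample the upper band edge by
#'   at least 4x Nyquist.
#' @param delay_ps arrival time of the pulse centre, ps.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(band_thz = c(0.3, 1.0), amplitude = 1,
                       span_ps = 128, dt_ps = 0.0625, delay_ps = 25) {
  band_thz <- as.numeric(band_thz)
  if (length(band_thz) != 2 || band_thz[1] <= 0 || band_thz[1] >= band_thz[2])
    stop("band_thz must be positive with lower < upper")
  if (1 / (2 * dt_ps) < 4 * band_thz[2])
    stop("sampling must satisfy Nyquist for the upper band edge with ",
         ">= 4x margin: need dt_ps <= ", format(1 / (8 * band_thz[2])))
  if (delay_ps <= 0 || delay_ps >= span_ps)
    stop("delay_ps must lie inside the time window")
  structure(list(band_thz = band_thz, amplitude = amplitude,
                 span_ps = span_ps, dt_ps = dt_ps, delay_ps = delay_ps),
            class = "pulse_spec")
}

# one-sided incident-field spectrum of a pulse on the FFT grid it implies
pulse_spectrum <- function(pulse) {
  n <- round(pulse$span_ps / pulse$dt_ps)
  dt <- pulse$dt_ps * 1e-12
  f <- (0:(n %/% 2)) / (n * dt)
  omega <- 2 * pi * f
  f0 <- mean(pulse$band_thz) * 1e12
  # -20 dB at the band edges: |E|/|E|max = 0.1 at f0 +/- df
  df <- diff(pulse$band_thz) / 2 * 1e12
  sig <- df / sqrt(2 * log(10))
  val <- exp(-(f - f0)^2 / (2 * sig^2)) *
    exp(-1i * omega * pulse$delay_ps * 1e-12)
  s <- thz_spectrum(omega, val, band = 2 * pi * pulse$band_thz * 1e12,
                    label = "incident pulse")
  # normalise so the incident time-domain pulse peaks at `amplitude`
  peak <- max(abs(from_spectrum(s)$amplitude))
  s$value <- s$value * pulse$amplitude / peak
  s
}

#' Synthetic measurement scene
#'
#' Describes one simulated acquisition: the layer stack, the distance by
#' which the bare-reference reflection plane sits behind the sample surface,
#' and optional additive detector noise.
#'
#' @param stack a [layer_stack].
#' @param reference_offset plane offset \eqn{\Delta L} in metres, `>= 0`.
#' @param noise_rms RMS of additive Gaussian noise in field units.
#' @param seed integer seed for the noise generator.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(stack, reference_offset = 0, noise_rms = 0,
                            seed = 1L) {
  stopifnot(inherits(stack, "layer_stack"))
  if (reference_offset < 0) stop("reference_offset must be >= 0")
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  structure(list(stack = stack, reference_offset = reference_offset,
                 noise_rms = noise_rms, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' Synthesize a sample/reference waveform pair
#'
#' Frequency-domain realisation of the reflection model, transformed to the
#' time domain on a common grid. The reference field is
#' \eqn{E_{ref} = P_1^2 R_{13} E_0} with \eqn{P_1} the one-way air
#' propagation over the plane offset (round trip `2 * reference_offset`);
#' the sample field is the Fabry-Perot echo series reflected at the sample
#' plane. Additive Gaussian noise of the stated RMS is drawn from the scene
#' seed.
#'
#' @param scene a [synthetic_scene].
#' @param pulse a [pulse_spec].
#' @return list with elements `sample` and `reference`, both [thz_waveform]
#'   objects on the same time grid.
#' @export
synthesize_waveforms <- function(scene, pulse) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(pulse, "pulse_spec"))
  E0 <- pulse_spectrum(pulse)
  omega <- E0$omega
  stack <- scene$stack
  co <- stack_coefficients(stack, omega)
  H <- transfer_function(stack, omega)
  P1 <- propagation(stack$layers[[1]]$index, omega, scene$reference_offset,
                    stack$theta1)
  Esamp <- H * co$R13 * E0$value           # echo series at the sample plane
  Eref <- P1^2 * co$R13 * E0$value
  ws <- from_spectrum(thz_spectrum(omega, Esamp, band = E0$band,
                                   label = "sample"))
  wr <- from_spectrum(thz_spectrum(omega, Eref, band = E0$band,
                                   label = "reference"))
  if (scene$noise_rms > 0) {
    rng <- local({
      set.seed(scene$seed)
      matrix(stats::rnorm(2 * length(ws$amplitude), sd = scene$noise_rms), ncol = 2)
    })
    ws$amplitude <- ws$amplitude + rng[, 1]
    wr$amplitude <- wr$amplitude + rng[, 2]
  }
  list(sample = ws, reference = wr)
}
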