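#' Settings for the Kramers-Kronig offset retrieval
#'
#' @param anchor_thz anchor frequency \eqn{\omega_1} in THz; `NULL` picks the
#'   centre of the measured band. Must lie inside the band.
#' @param epsilon stopping tolerance on the relative improvement of the best
#'   consistency score between successive refinement levels; default 0.01.
#' @param max_iterations cap on refinement levels.
#' @param offset_range_m candidate plane-offset range in metres (positive
#'   offsets put the reference plane behind the sample plane).
#' @param n_candidates candidates per refinement level.
#' @param shrink bracket shrink factor per refinement level.
#' @param n_air refractive index of the incidence medium.
#' @param extrapolation out-of-band extension used by the dispersion
#'   integrals: `"dc"` (anchored at zero value at zero frequency, exact for
#'   transfer-function input) or `"hold"` (edge value held).
#' @param grid_refine integration grid oversampling factor relative to the
#'   band grid.
#' @param grid_extent upper end of the integration grid as a multiple of the
#'   upper band edge.
#' @return An object of class `kk_settings`.
#' @export
kk_settings <- function(anchor_thz = NULL, epsilon = 0.01,
                        max_iterations = 20,
                        offset_range_m = c(-1e-3, 1e-3),
                        n_candidates = 256, shrink = 4, n_air = 1,
                        extrapolation = c("dc", "hold"),
                        grid_refine = 4, grid_extent = 8) {
  extrapolation <- match.arg(extrapolation)
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (length(offset_range_m) != 2 || offset_range_m[1] >= offset_range_m[2])
    stop("offset_range_m must be an increasing pair")
  if (n_candidates < 8) stop("n_candidates must be >= 8")
  structure(list(anchor_thz = anchor_thz, epsilon = epsilon,
                 max_iterations = as.integer(max_iterations),
                 offset_range_m = offset_range_m,
                 n_candidates = as.integer(n_candidates),
                 shrink = shrink, n_air = n_air,
                 extrapolation = extrapolation,
                 grid_refine = grid_refine, grid_extent = grid_extent),
            class = "kk_settings")
}

#' Principal-value dispersion integral
#'
#' Evaluates \deqn{P\int f(\omega')
#'   \big/\big[(\omega'^2-\omega^2)(\omega'^2-\omega_1^2)\big]\, d\omega'}
#' over the tabulated range by partial fractions and a singularity-subtracting
#' trapezoidal quadrature: at each pole the integrand is split into a finite
#' difference-quotient part, integrated numerically, and an analytic
#' principal-value remainder.
#'
#' @param f numeric vector, the function tabulated on `grid`.
#' @param grid uniform strictly increasing angular-frequency grid covering
#'   both `omega` and `omega1`.
#' @param omega,omega1 evaluation and anchor frequencies, rad/s; must be
#'   distinct and lie inside the grid.
#' @return the (finite) value of the integral.
#' @export
pv_integral <- function(f, grid, omega, omega1) {
  if (length(f) != length(grid)) stop("f and grid lengths differ")
  h <- diff(grid)
  if (any(abs(h - h[1]) > 1e-9 * h[1])) stop("grid must be uniform")
  rng <- range(grid)
  for (a in c(omega, omega1))
    if (a < rng[1] || a > rng[2])
      stop("singular point ", format(a), " outside the tabulated grid")
  if (abs(omega - omega1) < h[1] / 2)
    stop("omega and omega1 coincide on this grid")
  (pv_simple(f, grid, omega) - pv_simple(f, grid, omega1)) /
    (omega^2 - omega1^2)
}

# P int f(x)/(x^2 - a^2) dx over the grid range. With from_zero = TRUE the
# analytic principal-value remainder is taken from 0 instead of grid[1]
# (used by the dispersion transforms, whose extensions are defined down to
# zero frequency; the [0, grid[1]] regular remainder is negligible there).
pv_simple <- function(f, grid, a, from_zero = FALSE) {
  h <- grid[2] - grid[1]
  fa <- stats::approx(grid, f, xout = a)$y
  integrand <- (f - fa) / (grid^2 - a^2)
  near <- which(abs(grid - a) < h / 2)
  if (length(near)) {
    i <- near[1]
    # removable singularity: limit f'(a) / (2a)
    dfa <- if (i > 1 && i < length(grid)) (f[i + 1] - f[i - 1]) / (2 * h)
           else if (i == 1) (f[2] - f[1]) / h
           else (f[i] - f[i - 1]) / h
    integrand[i] <- dfa / (2 * a)
  }
  reg <- sum((integrand[-1] + integrand[-length(integrand)]) / 2) * h
  X <- grid[length(grid)]; x0 <- grid[1]
  anal <- log(abs((X - a) / (X + a)))
  if (!from_zero) anal <- anal - log(abs((x0 - a) / (x0 + a)))
  reg + fa / (2 * a) * anal
}

# Extend band-limited values onto the integration grid.
# "dc": linear to value 0 at omega = 0 (exact for transfer functions, which
#       tend to unity amplitude / zero phase at zero frequency);
# "hold": lower edge value held.
# Above the band the values relax from the edge to the band mean through a
# raised-cosine taper one octave wide, then stay constant. Linear in the
# band values, which retrieve_phase_offset exploits.
kk_extend <- function(omega_band, values, grid, scheme = "dc") {
  lo <- omega_band[1]; hi <- omega_band[length(omega_band)]
  out <- stats::approx(omega_band, values, xout = grid, rule = 2)$y
  below <- grid < lo
  if (any(below)) {
    out[below] <- if (scheme == "dc") values[1] * grid[below] / lo
                  else values[1]
  }
  above <- grid > hi
  if (any(above)) {
    edge <- values[length(values)]
    target <- mean(values)
    tt <- pmin(1, (grid[above] - hi) / hi)   # one octave: hi -> 2*hi
    mix <- 0.5 * (1 - cos(pi * tt))
    out[above] <- edge * (1 - mix) + target * mix
  }
  out
}

# shared integration grid for a band; always extends a little beyond the
# band top so the boundary principal-value term stays regular
kk_grid <- function(omega_band, settings) {
  top <- omega_band[length(omega_band)]
  dw <- (omega_band[2] - omega_band[1]) / settings$grid_refine
  seq(dw, max(settings$grid_extent * top, 1.05 * top), by = dw)
}

resolve_anchor <- function(omega_band, settings) {
  w1 <- if (is.null(settings$anchor_thz)) mean(range(omega_band))
        else thz_to_omega(settings$anchor_thz)
  if (w1 < omega_band[1] || w1 > omega_band[length(omega_band)])
    stop("anchor frequency must lie inside the measured band")
  ix <- which.min(abs(omega_band - w1))
  if (ix == 1 || ix == length(omega_band))
    warning("anchor on the band edge: poorly conditioned")
  list(w1 = omega_band[ix], ix = ix)
}

# dispersion kernel evaluated at every band frequency (0 at the anchor bin)
kk_transform <- function(fgrid, grid, omega_band, w1) {
  dw <- omega_band[2] - omega_band[1]
  p1 <- pv_simple(fgrid, grid, w1, from_zero = TRUE)
  vapply(omega_band, function(w) {
    if (abs(w - w1) < dw / 2) 0
    else (pv_simple(fgrid, grid, w, from_zero = TRUE) - p1) / (w^2 - w1^2)
  }, numeric(1))
}

#' Singly-subtractive Kramers-Kronig phase from log-amplitude
#'
#' Anchored dispersion relation: given \eqn{\ln|r(\omega)|} on the measured
#' band and the phase at the anchor frequency, returns the causal phase
#' \deqn{\theta(\omega) = \omega\left[\theta(\omega_1)/\omega_1 +
#'  \frac{2(\omega^2-\omega_1^2)}{\pi} P\!\!\int_0^\infty
#'  \frac{\ln|r(\omega')|\, d\omega'}
#'  {(\omega'^2-\omega^2)(\omega'^2-\omega_1^2)} \right].}
#' Out-of-band values are extrapolated per `settings$extrapolation`; the
#' anchoring suppresses the resulting truncation error.
#'
#' @param omega_band uniform angular-frequency grid of the measured band.
#' @param ln_amp \eqn{\ln|r|} tabulated on `omega_band`; must be finite.
#' @param anchor_phase \eqn{\theta(\omega_1)} in radians.
#' @param settings a [kk_settings]; `anchor_thz` fixes \eqn{\omega_1}.
#' @return numeric vector: phase in radians on `omega_band`.
#' @export
sskk_phase <- function(omega_band, ln_amp, anchor_phase = 0,
                       settings = kk_settings()) {
  if (any(!is.finite(ln_amp))) stop("ln_amp must be finite on the band")
  an <- resolve_anchor(omega_band, settings)
  grid <- kk_grid(omega_band, settings)
  ext <- kk_extend(omega_band, ln_amp, grid, settings$extrapolation)
  I <- kk_transform(ext, grid, omega_band, an$w1)
  omega_band * (anchor_phase / an$w1 +
                  (2 * (omega_band^2 - an$w1^2) / pi) * I)
}

#' Singly-subtractive Kramers-Kronig log-amplitude from phase
#'
#' Mirror relation of [sskk_phase()] with the \eqn{\omega'\theta(\omega')}
#' numerator:
#' \deqn{\ln|r(\omega)| = \ln|r(\omega_1)| -
#'  \frac{2(\omega^2-\omega_1^2)}{\pi} P\!\!\int_0^\infty
#'  \frac{\omega'\theta(\omega')\, d\omega'}
#'  {(\omega'^2-\omega^2)(\omega'^2-\omega_1^2)}.}
#'
#' @inheritParams sskk_phase
#' @param theta unwrapped phase tabulated on `omega_band`, radians.
#' @param anchor_lnamp \eqn{\ln|r(\omega_1)|}.
#' @return numeric vector: \eqn{\ln|r|} on `omega_band`.
#' @export
sskk_lnamp <- function(omega_band, theta, anchor_lnamp = 0,
                       settings = kk_settings()) {
  if (any(!is.finite(theta))) stop("theta must be finite on the band")
  an <- resolve_anchor(omega_band, settings)
  grid <- kk_grid(omega_band, settings)
  ext <- kk_extend(omega_band, theta, grid, settings$extrapolation)
  I <- kk_transform(grid * ext, grid, omega_band, an$w1)
  anchor_lnamp - (2 * (omega_band^2 - an$w1^2) / pi) * I
}

#' Self-consistency error of an (amplitude, phase) pair
#'
#' Builds \eqn{r_{guess} = \exp(\ln|r|)\exp(i\theta)} and the
#' Kramers-Kronig-corrected counterpart
#' \eqn{r_{corrected} = \exp(\mathrm{KK}[\theta])\exp(i\,\mathrm{KK}[\ln|r|])}
#' and returns the size-normalised discrete L2 norm of their difference over
#' the band. A causally consistent pair scores near zero (up to quadrature
#' error).
#'
#' @inheritParams sskk_phase
#' @param theta candidate unwrapped phase on `omega_band`.
#' @return non-negative scalar.
#' @export
consistency_error <- function(omega_band, ln_amp, theta,
                              settings = kk_settings()) {
  if (length(omega_band) < 2) stop("degenerate band: need at least 2 points")
  if (length(ln_amp) != length(omega_band) ||
      length(theta) != length(omega_band))
    stop("ln_amp and theta must be tabulated on omega_band")
  an <- resolve_anchor(omega_band, settings)
  ph_kk <- sskk_phase(omega_band, ln_amp, anchor_phase = theta[an$ix],
                      settings = settings)
  ln_kk <- sskk_lnamp(omega_band, theta, anchor_lnamp = ln_amp[an$ix],
                      settings = settings)
  r_guess <- exp(ln_amp + 1i * theta)
  r_corr <- exp(ln_kk + 1i * ph_kk)
  sqrt(mean(Mod(r_guess - r_corr)^2))
}

#' Retrieve the sample/reference plane offset by Kramers-Kronig consistency
#'
#' The plane misalignment adds \eqn{\Delta\theta(\omega) = \omega n\,
#' 2\Delta L / c} to the measured phase of the reflection ratio. For each
#' candidate \eqn{\Delta L} the corrected phase
#' \eqn{\theta_{meas} - \omega n 2\Delta L/c} is scored with
#' [consistency_error()]; a coarse-to-fine bracket (shrink factor
#' `settings$shrink`) refines around the running minimum until the relative
#' improvement of the best score falls below `settings$epsilon` or
#' `settings$max_iterations` is reached. Ties resolve to the smaller
#' \eqn{|\Delta L|}. Positive \eqn{\Delta L} means the reference plane lies
#' behind the sample plane.
#'
#' @param r_meas a [thz_spectrum]: the measured sample/reference ratio with
#'   a non-empty band.
#' @param settings a [kk_settings]; the candidate range must span the true
#'   offset.
#' @return An object of class `phase_offset_result` with fields `delta_L`
#'   (metres), `delta_theta` (the removed phase ramp on the band),
#'   `corrected_phase`, `omega_band`, `iterations`, `consistency_history`
#'   (best score per level, non-increasing), `converged`, `ln_amp`.
#' @export
retrieve_phase_offset <- function(r_meas, settings = kk_settings()) {
  stopifnot(inherits(r_meas, "thz_spectrum"))
  bi <- band_indices(r_meas)
  if (length(bi) < 8) stop("band too short for offset retrieval")
  wb <- r_meas$omega[bi]
  ln_amp <- log(Mod(r_meas$value[bi]))
  if (any(!is.finite(ln_amp))) stop("zero magnitude inside the band")
  th_meas <- unwrap_phase(Arg(r_meas$value[bi]))
  an <- resolve_anchor(wb, settings)
  grid <- kk_grid(wb, settings)
  sch <- settings$extrapolation
  ramp <- 2 * settings$n_air * wb / C_LIGHT       # d(delta_theta)/d(delta_L)

  # the dispersion transforms are linear in their inputs, so precompute the
  # pieces once and evaluate every candidate offset algebraically
  I_amp <- kk_transform(kk_extend(wb, ln_amp, grid, sch), grid, wb, an$w1)
  ph_kk_base <- wb * (2 * (wb^2 - an$w1^2) / pi) * I_amp
  I_th <- kk_transform(grid * kk_extend(wb, th_meas, grid, sch), grid, wb, an$w1)
  I_ramp <- kk_transform(grid * kk_extend(wb, ramp, grid, sch), grid, wb, an$w1)
  pref <- -(2 * (wb^2 - an$w1^2) / pi)

  score <- function(dL) {
    th_c <- th_meas - dL * ramp
    ph_kk <- wb * th_c[an$ix] / an$w1 + ph_kk_base
    ln_kk <- ln_amp[an$ix] + pref * (I_th - dL * I_ramp)
    sqrt(mean(Mod(exp(ln_amp + 1i * th_c) - exp(ln_kk + 1i * ph_kk))^2))
  }

  cand <- seq(settings$offset_range_m[1], settings$offset_range_m[2],
              length.out = settings$n_candidates)
  best <- Inf; best_dL <- NA_real_
  history <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  boundary <- FALSE
  while (iterations < settings$max_iterations) {
    iterations <- iterations + 1L
    sc <- vapply(cand, score, numeric(1))
    ties <- which(sc == min(sc))
    i <- ties[which.min(abs(cand[ties]))]
    if (iterations == 1L && (i == 1L || i == length(cand))) {
      boundary <- TRUE
      warning("offset grid likely too narrow: minimum at candidate boundary")
    }
    rel <- (best - sc[i]) / best
    if (sc[i] < best) { best <- sc[i]; best_dL <- cand[i] }
    history <- c(history, best)
    if (is.finite(rel) && rel < settings$epsilon) { converged <- TRUE; break }
    span <- (cand[length(cand)] - cand[1]) / settings$shrink
    cand <- seq(best_dL - span / 2, best_dL + span / 2,
                length.out = settings$n_candidates)
  }
  if (!converged)
    message("offset retrieval did not reach epsilon within max_iterations; ",
            "result flagged")
  delta_theta <- best_dL * ramp
  structure(list(delta_L = best_dL,
                 delta_theta = delta_theta,
                 corrected_phase = th_meas - delta_theta,
                 omega_band = wb,
                 ln_amp = ln_amp,
                 iterations = iterations,
                 consistency_history = history,
                 converged = converged,
                 boundary = boundary,
                 anchor = an$w1,
                 settings = settings),
            class = "phase_offset_result")
}

#' @export
print.phase_offset_result <- function(x, ...) {
  cat(sprintf("<phase_offset_result> delta_L = %.4g um (%s after %d iterations)\n",
              x$delta_L * 1e6,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  consistency: %s\n",
              paste(sprintf("%.3g", x$consistency_history), collapse = " -> ")))
  invisible(x)
}

#' Interpret a plane offset as the sample thickness
#'
#' For the sample-on-reference geometry the bare-reference reflection plane
#' is the substrate surface, which sits exactly one layer thickness behind
#' the sample surface, so the retrieved \eqn{\Delta L} is the layer-2
#' thickness.
#'
#' @param result a [retrieve_phase_offset()] result, or a plane offset in
#'   metres.
#' @return thickness in metres.
#' @export
offset_to_thickness <- function(result) {
  dL <- if (inherits(result, "phase_offset_result")) result$delta_L
        else as.numeric(result)
  if (dL < 0) stop("negative plane offset cannot be a thickness")
  if (dL == 0) warning("zero offset: no sample layer")
  dL
}
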