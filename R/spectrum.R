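#' Complex field spectrum
#'
#' Complex amplitude versus angular frequency, together with the usable band.
#' Holds reflected-field ratios \eqn{r(\omega) = |r|\exp(i\theta)} and
#' transfer functions \eqn{H(\omega)}.
#'
#' @param omega angular frequency grid in rad/s; non-negative, strictly
#'   increasing.
#' @param value complex amplitude, same length as `omega`.
#' @param band usable `(omega_min, omega_max)` range; must lie within the
#'   grid.
#' @param label free text.
#' @return An object of class `thz_spectrum`.
#' @export
thz_spectrum <- function(omega, value, band = range(omega), label = "") {
  omega <- as.numeric(omega)
  value <- as.complex(value)
  if (length(omega) != length(value))
    stop("omega and value must have the same length")
  if (any(omega < 0)) stop("omega must be non-negative")
  if (any(diff(omega) <= 0)) stop("omega must be strictly increasing")
  band <- as.numeric(band)
  if (length(band) != 2 || band[1] >= band[2])
    stop("band must be (omega_min, omega_max) with omega_min < omega_max")
  if (band[1] < omega[1] || band[2] > omega[length(omega)])
    stop("band must be contained in the omega grid")
  structure(list(omega = omega, value = value, band = band,
                 label = as.character(label)),
            class = "thz_spectrum")
}

#' @export
print.thz_spectrum <- function(x, ...) {
  cat(sprintf("<thz_spectrum> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d bins, grid %.4g-%.4g THz, band %.4g-%.4g THz\n",
              length(x$omega), omega_to_thz(x$omega[1]),
              omega_to_thz(x$omega[length(x$omega)]),
              omega_to_thz(x$band[1]), omega_to_thz(x$band[2])))
  invisible(x)
}

#' Indices of the usable band
#' @param s a [thz_spectrum].
#' @return integer indices of grid points inside `s$band`.
#' @export
band_indices <- function(s) {
  which(s$omega >= s$band[1] & s$omega <= s$band[2])
}

#' Restrict a spectrum to a frequency band
#'
#' Keeps the grid points overlapping `[fmin, fmax]` and updates the usable
#' band accordingly.
#'
#' @param s a [thz_spectrum].
#' @param fmin,fmax band edges in THz, `fmin < fmax`.
#' @return A [thz_spectrum] on the restricted grid.
#' @export
band_select <- function(s, fmin, fmax) {
  stopifnot(inherits(s, "thz_spectrum"))
  if (fmin >= fmax) stop("fmin must be < fmax")
  wlo <- thz_to_omega(fmin)
  whi <- thz_to_omega(fmax)
  keep <- s$omega >= wlo & s$omega <= whi
  if (!any(keep)) stop("requested band does not overlap the spectrum grid")
  omega <- s$omega[keep]
  thz_spectrum(omega, s$value[keep], band = range(omega), label = s$label)
}

#' Unwrap the phase of a spectrum over its band
#'
#' Returns a continuous phase: jumps between adjacent samples are brought
#' below pi in magnitude, and the value at the lowest band frequency lies in
#' `(-pi, pi]`.
#'
#' @param s a [thz_spectrum] (or a numeric vector of wrapped phases).
#' @return numeric vector of unwrapped phase in radians, one value per band
#'   grid point.
#' @export
unwrap_phase <- function(s) {
  ph <- if (inherits(s, "thz_spectrum")) Arg(s$value[band_indices(s)]) else as.numeric(s)
  if (length(ph) == 0) stop("empty band")
  out <- signal::unwrap(ph)
  # re-reference the first sample into (-pi, pi]
  shift <- out[1] - wrap_to_pi(out[1])
  out - shift
}

# wrap scalar/vector phases into (-pi, pi]
wrap_to_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
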