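#' Time-domain terahertz waveform
#'
#' A sampled electric-field trace on a strictly increasing, uniform time grid.
#' This is the container for incident, sample, reference and Fabry-Perot
#' fields throughout the package.
#'
#' @param time time axis in seconds; uniform spacing (relative tolerance 1e-9)
#'   and at least 16 samples.
#' @param amplitude field amplitude, arbitrary units; same length as `time`.
#' @param label free-text label carried through plots and files.
#' @return An object of class `thz_waveform` with fields `time`, `amplitude`,
#'   `label`.
#' @examples
#' t <- seq(0, 63.75e-12, by = 0.25e-12)
#' w <- thz_waveform(t, exp(-(t - 20e-12)^2 / (2e-12)^2))
#' @export
thz_waveform <- function(time, amplitude, label = "") {
  time <- as.numeric(time)
  amplitude <- as.numeric(amplitude)
  if (length(time) != length(amplitude))
    stop("time and amplitude must have the same length")
  if (length(time) < 16)
    stop("waveform needs at least 16 samples, got ", length(time))
  dt <- diff(time)
  if (any(dt <= 0))
    stop("time grid must be strictly increasing (first violation at sample ",
         which(dt <= 0)[1] + 1, ")")
  rel <- abs(dt - dt[1]) / dt[1]
  if (any(rel > 1e-9))
    stop("time grid must be uniform: sample ",
         which(rel > 1e-9)[1] + 1, " deviates by relative ",
         format(max(rel), digits = 3))
  structure(list(time = time, amplitude = amplitude, label = as.character(label)),
            class = "thz_waveform")
}

#' @export
print.thz_waveform <- function(x, ...) {
  dt <- x$time[2] - x$time[1]
  cat(sprintf("<thz_waveform> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d samples, dt = %.4g ps, span %.4g ps, peak-to-peak %.4g\n",
              length(x$time), dt * 1e12,
              (x$time[length(x$time)] - x$time[1]) * 1e12,
              diff(range(x$amplitude))))
  invisible(x)
}

#' @export
plot.thz_waveform <- function(x, ...) {
  graphics::plot(x$time * 1e12, x$amplitude, type = "l",
                 xlab = "time (ps)", ylab = "field (a.u.)", main = x$label, ...)
  invisible(x)
}

#' Read / write waveform files
#'
#' Two-column delimited text: column 1 time in picoseconds, column 2 field
#' amplitude in arbitrary units. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @param label label for the returned waveform; defaults to the file name.
#' @return `read_waveform()`: a [thz_waveform].
#' @export
read_waveform <- function(path, label = basename(path)) {
  tab <- utils::read.table(path, comment.char = "#", col.names = c("t_ps", "amp"))
  thz_waveform(tab$t_ps * 1e-12, tab$amp, label = label)
}

#' @rdname read_waveform
#' @param w a [thz_waveform].
#' @return `write_waveform()`: `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "thz_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# %s", w$label), "# time_ps amplitude"), con)
  utils::write.table(data.frame(t = sprintf("%.9g", w$time * 1e12),
                                a = sprintf("%.9g", w$amplitude)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tapered analysis windows
#'
#' Tukey (cosine-tapered) window; `alpha = 0` gives the rectangular window,
#' `alpha = 1` the Hann window. The default taper fraction 0.1 suppresses
#' truncation ringing while leaving the pulse untouched.
#'
#' @param n number of samples.
#' @param alpha cosine fraction in `[0, 1]`.
#' @return numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.1) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  if (alpha == 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  win <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  win[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  win[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  win
}

resolve_window <- function(window, n) {
  if (is.numeric(window)) {
    stopifnot(length(window) == n)
    return(window)
  }
  switch(match.arg(window, c("tukey", "rectangular")),
         tukey = tukey_window(n, 0.1),
         rectangular = rep(1, n))
}

#' Discrete Fourier transform of a waveform
#'
#' One-sided spectrum on the non-negative frequency grid implied by the
#' sampling; negative frequencies are handled by the conjugate symmetry of
#' real signals. The window is applied before the transform; the transform is
#' scaled by the sampling interval so that it approximates the continuous
#' Fourier integral \eqn{\int E(t) e^{-i\omega t} dt}.
#'
#' @param w a [thz_waveform].
#' @param window `"tukey"` (cosine fraction 0.1, the default), `"rectangular"`,
#'   or a numeric vector of window weights of the same length as the trace.
#' @return A [thz_spectrum] on the one-sided grid (N/2 + 1 bins).
#' @export
to_spectrum <- function(w, window = "tukey") {
  stopifnot(inherits(w, "thz_waveform"))
  n <- length(w$time)
  dt <- w$time[2] - w$time[1]
  win <- resolve_window(window, n)
  spec <- stats::fft(w$amplitude * win)
  half <- seq_len(n %/% 2 + 1)
  omega <- 2 * pi * (half - 1) / (n * dt)
  # time origin: phase referenced to t = time[1]
  val <- spec[half] * dt * exp(-1i * omega * w$time[1])
  thz_spectrum(omega, val, band = range(omega), label = w$label)
}

#' Inverse transform of a one-sided spectrum
#'
#' Reconstructs the real time-domain trace from a one-sided spectrum produced
#' by [to_spectrum()] (or built analytically on the same grid). The spectrum
#' must cover the full one-sided FFT grid.
#'
#' @param s a [thz_spectrum] on a full one-sided FFT grid (uniform, starting
#'   at 0).
#' @param t0 time of the first sample of the reconstructed trace (seconds).
#' @param n number of time samples; defaults to `2 * (length(s$omega) - 1)`.
#' @return A [thz_waveform].
#' @export
from_spectrum <- function(s, t0 = 0, n = 2 * (length(s$omega) - 1)) {
  stopifnot(inherits(s, "thz_spectrum"))
  omega <- s$omega
  if (omega[1] != 0)
    stop("from_spectrum needs a one-sided grid starting at 0")
  dw <- omega[2] - omega[1]
  dt <- 2 * pi / (n * dw)
  val <- s$value * exp(1i * omega * t0)
  nyq <- n %% 2 == 0
  inner <- if (nyq) val[2:(length(val) - 1)] else val[-1]
  full <- c(val[1], inner, if (nyq) Re(val[length(val)]), Conj(rev(inner)))
  amp <- Re(stats::fft(full, inverse = TRUE)) / (n * dt)
  thz_waveform(t0 + (0:(n - 1)) * dt, amp, label = s$label)
}
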