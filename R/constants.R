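#' Physical constants and unit helpers
#'
#' Frequencies are stored internally as angular frequency in rad/s; file and
#' command-line interfaces speak THz. Times are stored in seconds; waveform
#' files store picoseconds. Lengths are metres; the CLI uses micrometres.
#'
#' @name units
NULL

# vacuum speed of light, m/s
C_LIGHT <- 299792458

#' @rdname units
#' @param f frequency in THz
#' @return `thz_to_omega()`: angular frequency in rad/s.
#' @export
thz_to_omega <- function(f) 2 * pi * f * 1e12

#' @rdname units
#' @param omega angular frequency in rad/s
#' @return `omega_to_thz()`: frequency in THz.
#' @export
omega_to_thz <- function(omega) omega / (2 * pi * 1e12)

#' @rdname units
#' @param um length in micrometres
#' @return `um_to_m()`: metres.
#' @export
um_to_m <- function(um) um * 1e-6
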