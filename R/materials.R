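#' Complex refractive index
#'
#' Time-harmonic convention: fields evolve as \eqn{\exp(+i\omega t)} and a
#' lossy medium has \eqn{\tilde n = n - i\kappa}, so the propagation factor
#' \eqn{\exp(-i \tilde n \omega L / c)} decays for \eqn{\kappa > 0}.
#'
#' @param n real refractive index, `> 0`. May be a vector for tabulated
#'   frequency dependence.
#' @param kappa extinction coefficient, `>= 0` for passive media. Scalar or
#'   same length as `n`.
#' @return An object of class `complex_index`.
#' @export
complex_index <- function(n, kappa = 0) {
  n <- as.numeric(n)
  kappa <- as.numeric(kappa)
  if (length(kappa) == 1) kappa <- rep(kappa, length(n))
  if (length(n) != length(kappa)) stop("n and kappa lengths differ")
  if (any(n <= 0)) stop("n must be > 0")
  if (any(kappa < 0)) stop("kappa must be >= 0 for passive media")
  structure(list(n = n, kappa = kappa), class = "complex_index")
}

#' @export
print.complex_index <- function(x, ...) {
  if (length(x$n) == 1)
    cat(sprintf("<complex_index> n = %.4g, kappa = %.4g\n", x$n, x$kappa))
  else
    cat(sprintf("<complex_index> tabulated, %d points, n in [%.4g, %.4g]\n",
                length(x$n), min(x$n), max(x$n)))
  invisible(x)
}

# n - i*kappa as an R complex vector
as_ntilde <- function(ci) {
  if (inherits(ci, "complex_index")) complex(real = ci$n, imaginary = -ci$kappa)
  else as.complex(ci)
}

#' Single layer of a stack
#'
#' @param index a [complex_index].
#' @param thickness thickness in metres, `> 0`, or `Inf` for the semi-infinite
#'   incidence and substrate layers.
#' @return An object of class `thz_layer`.
#' @export
thz_layer <- function(index, thickness = Inf) {
  stopifnot(inherits(index, "complex_index"))
  thickness <- as.numeric(thickness)
  if (length(thickness) != 1 || (!is.infinite(thickness) && thickness <= 0))
    stop("thickness must be > 0 or Inf (semi-infinite)")
  structure(list(index = index, thickness = thickness), class = "thz_layer")
}

#' Three-layer reflection geometry
#'
#' Layer 1 is the incidence medium (air), layer 2 the sample under study and
#' layer 3 the known reference/substrate the sample sits on. The walk-off
#' factors `walkoff` weight the successive Fabry-Perot echoes reaching the
#' detector; at normal illumination they are all 1.
#'
#' @param layers list of exactly three [thz_layer] objects; layer 1 must be
#'   lossless.
#' @param theta1 angle of incidence in layer 1, radians, in `[0, pi/2)`.
#' @param polarisation `"s"` or `"p"`.
#' @param walkoff numeric (possibly complex) vector of per-order walk-off
#'   factors A_wo; recycled over echo orders. Default 1.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers, theta1 = 0, polarisation = c("s", "p"),
                        walkoff = 1) {
  polarisation <- match.arg(polarisation)
  if (!is.list(layers) || length(layers) != 3 ||
      !all(vapply(layers, inherits, TRUE, "thz_layer")))
    stop("layers must be a list of exactly 3 thz_layer objects")
  if (any(layers[[1]]$index$kappa != 0))
    stop("layer 1 (incidence medium) must be lossless")
  if (theta1 < 0 || theta1 >= pi / 2)
    stop("theta1 must be in [0, pi/2)")
  structure(list(layers = layers, theta1 = theta1,
                 polarisation = polarisation, walkoff = walkoff),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("<layer_stack>\n")
  for (i in 1:3) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d: n = %.4g, kappa = %.4g, thickness = %s\n",
                i, l$index$n[1], l$index$kappa[1],
                if (is.infinite(l$thickness)) "semi-infinite"
                else sprintf("%.4g um", l$thickness * 1e6)))
  }
  cat(sprintf("  theta1 = %.4g rad, %s-polarisation\n", x$theta1, x$polarisation))
  invisible(x)
}

#' Air / sample / substrate convenience constructor
#'
#' @param n2,kappa2 sample (layer 2) dielectric values.
#' @param n3,kappa3 substrate (layer 3) dielectric values; defaults are the
#'   glass values used by the synthetic test scenes.
#' @param thickness_um sample thickness in micrometres (`Inf` allowed for an
#'   optically thick sample).
#' @param theta1,polarisation,walkoff see [layer_stack()].
#' @return A [layer_stack].
#' @export
sample_on_substrate <- function(n2, kappa2, n3 = 2.6, kappa3 = 0.15,
                                thickness_um = 100, theta1 = 0,
                                polarisation = "s", walkoff = 1) {
  layer_stack(list(thz_layer(complex_index(1, 0), Inf),
                   thz_layer(complex_index(n2, kappa2),
                             if (is.infinite(thickness_um)) Inf
                             else um_to_m(thickness_um)),
                   thz_layer(complex_index(n3, kappa3), Inf)),
              theta1 = theta1, polarisation = polarisation, walkoff = walkoff)
}
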