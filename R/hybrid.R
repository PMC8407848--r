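#' Full hybrid retrieval on one waveform pair
#'
#' The end-to-end flow: plane-offset retrieval by Kramers-Kronig
#' consistency, thickness from the offset, transfer function with the
#' corrected phase (incidence propagation set to unity), then the
#' per-frequency Fabry-Perot scan. Every intermediate is kept in the
#' returned bundle. An explicit `L2` skips the thickness-from-offset step
#' (e.g. when the geometry is known).
#'
#' @param sample,reference [thz_waveform] objects on a common time grid.
#' @param stack a [layer_stack] with known layers 1 and 3.
#' @param kk a [kk_settings].
#' @param grid a [retrieval_grid].
#' @param band_thz usable band in THz.
#' @param L2 optional known layer-2 thickness (metres); default derives it
#'   from the retrieved plane offset.
#' @param window analysis window.
#' @return An object of class `hybrid_result`: list with `offset`
#'   ([retrieve_phase_offset()] result), `thickness` (m), `H` (corrected
#'   [thz_spectrum]), `fit` (the [retrieve_nk()] data frame) and the
#'   resolved parameters.
#' @export
run_hybrid <- function(sample, reference, stack, kk = kk_settings(),
                       grid = retrieval_grid(), band_thz = c(0.3, 1),
                       L2 = NULL, window = "tukey") {
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE))
  }
  H0 <- stage("transfer", measured_h(sample, reference, band_thz,
                                     window = window))
  off <- stage("kk", retrieve_phase_offset(H0, kk))
  thickness <- if (is.null(L2)) stage("thickness", offset_to_thickness(off))
               else L2
  H <- stage("transfer", measured_h(sample, reference, band_thz,
                                    corrected = off, window = window))
  fit <- stage("retrieve", retrieve_nk(H, stack, thickness, grid))
  structure(list(offset = off, thickness = thickness, H = H, fit = fit,
                 band_thz = band_thz, stack = stack,
                 kk = kk, grid = grid),
            class = "hybrid_result")
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat("<hybrid_result>\n")
  cat(sprintf("  plane offset: %.4g um (%d iterations, %s)\n",
              x$offset$delta_L * 1e6, x$offset$iterations,
              if (x$offset$converged) "converged" else "not converged"))
  cat(sprintf("  thickness:    %.4g um\n", x$thickness * 1e6))
  cat(sprintf("  band:         %.3g-%.3g THz (%d bins)\n",
              x$band_thz[1], x$band_thz[2], nrow(x$fit)))
  cat(sprintf("  n:     mean %.4f (range %.4f-%.4f)\n",
              mean(x$fit$n), min(x$fit$n), max(x$fit$n)))
  cat(sprintf("  kappa: mean %.4f (range %.4f-%.4f)\n",
              mean(x$fit$kappa), min(x$fit$kappa), max(x$fit$kappa)))
  invisible(x)
}
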