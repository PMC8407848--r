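#' Raster-scan waveform cube
#'
#' Per-pixel time-domain traces of a single-pixel raster scan, sharing one
#' time axis. Missing pixels are masked, not absent. The reference trace is
#' either an external waveform or designated by pixel coordinates (the
#' glass-pixel convention).
#'
#' @param time common time axis in seconds.
#' @param traces numeric array `rows x cols x samples`.
#' @param mask logical `rows x cols` matrix, `TRUE` = usable pixel.
#' @param pitch_mm physical pixel pitch in millimetres.
#' @param reference either a [thz_waveform] or `c(row, col)` coordinates of
#'   the reference pixel.
#' @return An object of class `raster_cube`.
#' @export
raster_cube <- function(time, traces, mask = NULL, pitch_mm = 1,
                        reference = c(1, 1)) {
  stopifnot(is.array(traces), length(dim(traces)) == 3)
  d <- dim(traces)
  if (length(time) != d[3]) stop("time length must match trace samples")
  # validate the grid via the waveform invariants
  thz_waveform(time, traces[1, 1, ])
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  stopifnot(is.logical(mask), all(dim(mask) == d[1:2]))
  if (!inherits(reference, "thz_waveform")) {
    reference <- as.integer(reference)
    stopifnot(length(reference) == 2, all(reference >= 1),
              reference[1] <= d[1], reference[2] <= d[2])
  }
  structure(list(time = time, traces = traces, mask = mask,
                 pitch_mm = pitch_mm, reference = reference),
            class = "raster_cube")
}

#' @export
print.raster_cube <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf("<raster_cube> %d x %d pixels (%d masked), %d samples, pitch %.3g mm\n",
              d[1], d[2], sum(!x$mask), d[3], x$pitch_mm))
  invisible(x)
}

pixel_waveform <- function(cube, i, j) {
  thz_waveform(cube$time, cube$traces[i, j, ],
               label = sprintf("pixel (%d, %d)", i, j))
}

reference_waveform <- function(cube) {
  if (inherits(cube$reference, "thz_waveform")) return(cube$reference)
  i <- cube$reference[1]; j <- cube$reference[2]
  if (!cube$mask[i, j]) stop("reference pixel is masked")
  pixel_waveform(cube, i, j)
}

#' Peak-to-peak field map
#'
#' `max - min` of every trace; the standard quick-look image of a raster
#' scan.
#'
#' @param cube a [raster_cube].
#' @return numeric `rows x cols` matrix (NA on masked pixels).
#' @export
peak_to_peak_map <- function(cube) {
  stopifnot(inherits(cube, "raster_cube"))
  out <- apply(cube$traces, c(1, 2), function(a) max(a) - min(a))
  out[!cube$mask] <- NA_real_
  out
}

#' Apply the hybrid retrieval to every pixel of a cube
#'
#' Each unmasked pixel is processed against the shared reference trace:
#' plane-offset retrieval, thickness, transfer function with corrected
#' phase, then the per-frequency (n, kappa) scan sampled at the requested
#' map frequencies (nearest band bin). Pixels whose peak-to-peak amplitude
#' falls below `snr_floor` times the cube maximum are skipped and flagged as
#' low-SNR. Results are deterministic and independent across pixels.
#'
#' @param cube a [raster_cube].
#' @param stack a [layer_stack] describing the known geometry.
#' @param kk a [kk_settings].
#' @param grid a [retrieval_grid].
#' @param freqs_thz map frequencies in THz.
#' @param band_thz usable band in THz.
#' @param snr_floor low-SNR mask threshold (fraction of the cube's maximum
#'   peak-to-peak).
#' @return An object of class `dielectric_map`: list with matrices
#'   `thickness` (m), `peak_to_peak`, per-frequency lists `n` and `kappa`,
#'   `flags` (character matrix: "" ok, else comma-joined flags),
#'   `freqs_thz` (the nearest band bins actually used) and `pitch_mm`.
#' @export
run_pixelwise <- function(cube, stack, kk = kk_settings(),
                          grid = retrieval_grid(),
                          freqs_thz = c(0.3, 0.4, 0.5),
                          band_thz = c(0.3, 1), snr_floor = 0.01) {
  stopifnot(inherits(cube, "raster_cube"))
  ref <- reference_waveform(cube)
  d <- dim(cube$traces)
  ptp <- peak_to_peak_map(cube)
  lim <- snr_floor * max(ptp, na.rm = TRUE)
  thick <- matrix(NA_real_, d[1], d[2])
  flags <- matrix("", d[1], d[2])
  # resolve requested frequencies to band bins once, via the reference grid
  sref <- band_select(to_spectrum(ref), band_thz[1], band_thz[2])
  bins <- vapply(freqs_thz, function(f)
    which.min(abs(sref$omega - thz_to_omega(f))), integer(1))
  used_thz <- omega_to_thz(sref$omega[bins])
  nmaps <- lapply(freqs_thz, function(f) matrix(NA_real_, d[1], d[2]))
  kmaps <- lapply(freqs_thz, function(f) matrix(NA_real_, d[1], d[2]))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!cube$mask[i, j]) { flags[i, j] <- "masked"; next }
    if (ptp[i, j] < lim) { flags[i, j] <- "low_snr"; next }
    w <- pixel_waveform(cube, i, j)
    fl <- character(0)
    res <- withCallingHandlers({
      H0 <- measured_h(w, ref, band_thz)
      off <- retrieve_phase_offset(H0, kk)
      if (!off$converged) fl <- c(fl, "kk_nonconverged")
      L2 <- off$delta_L
      if (L2 <= 0) { fl <- c(fl, "no_layer"); NULL }
      else {
        H <- measured_h(w, ref, band_thz, corrected = off)
        fit <- retrieve_nk(H, stack, L2, grid)
        list(off = off, fit = fit)
      }
    }, warning = function(cond) {
      if (grepl("boundary", conditionMessage(cond)))
        fl <<- c(fl, "grid_boundary")
      if (grepl("no sample layer", conditionMessage(cond)))
        fl <<- c(fl, "no_layer")
      invokeRestart("muffleWarning")
    })
    if (!is.null(res)) {
      thick[i, j] <- res$off$delta_L
      for (q in seq_along(bins)) {
        nmaps[[q]][i, j] <- res$fit$n[bins[q]]
        kmaps[[q]][i, j] <- res$fit$kappa[bins[q]]
        if (res$fit$branch[bins[q]]) fl <- c(fl, "branch")
      }
    }
    flags[i, j] <- paste(unique(fl), collapse = ",")
  }
  structure(list(thickness = thick, peak_to_peak = ptp,
                 n = stats::setNames(nmaps, sprintf("%.3f", used_thz)),
                 kappa = stats::setNames(kmaps, sprintf("%.3f", used_thz)),
                 flags = flags, freqs_thz = used_thz,
                 pitch_mm = cube$pitch_mm),
            class = "dielectric_map")
}

#' @export
print.dielectric_map <- function(x, ...) {
  d <- dim(x$thickness)
  cat(sprintf("<dielectric_map> %d x %d pixels, maps at %s THz\n",
              d[1], d[2], paste(sprintf("%.3g", x$freqs_thz), collapse = ", ")))
  flagged <- sum(nzchar(x$flags))
  cat(sprintf("  %d flagged pixel(s)\n", flagged))
  invisible(x)
}

#' Read / write raster cubes as plain text
#'
#' Serialization with the logical layout time axis / trace block / mask:
#' a commented header carrying the pitch and reference pixel, one line with
#' the time axis in ps, then one line per pixel (`row col mask amplitudes...`).
#'
#' @param cube a [raster_cube].
#' @param path file path.
#' @return `read_raster_cube()`: a [raster_cube]; `write_raster_cube()`:
#'   `path`, invisibly.
#' @export
write_raster_cube <- function(cube, path) {
  stopifnot(inherits(cube, "raster_cube"))
  d <- dim(cube$traces)
  if (inherits(cube$reference, "thz_waveform"))
    stop("only pixel-coordinate references can be serialized")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# thzretrieve raster cube v1",
               sprintf("# rows: %d cols: %d samples: %d", d[1], d[2], d[3]),
               sprintf("# pitch_mm: %.9g", cube$pitch_mm),
               sprintf("# reference_pixel: %d %d",
                       cube$reference[1], cube$reference[2]),
               paste(sprintf("%.9g", cube$time * 1e12), collapse = " ")), con)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    writeLines(paste(i, j, as.integer(cube$mask[i, j]),
                     paste(sprintf("%.9g", cube$traces[i, j, ]),
                           collapse = " ")), con)
  invisible(path)
}

#' @rdname write_raster_cube
#' @export
read_raster_cube <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  dims <- as.integer(regmatches(hdr[2], gregexpr("[0-9]+", hdr[2]))[[1]])
  pitch <- as.numeric(sub("# pitch_mm: ", "", hdr[3]))
  refpx <- as.integer(strsplit(sub("# reference_pixel: ", "", hdr[4]), " ")[[1]])
  body <- lines[!grepl("^#", lines)]
  time <- as.numeric(strsplit(body[1], " ")[[1]]) * 1e-12
  traces <- array(NA_real_, dims)
  mask <- matrix(NA, dims[1], dims[2])
  for (ln in body[-1]) {
    v <- as.numeric(strsplit(ln, " ")[[1]])
    traces[v[1], v[2], ] <- v[-(1:3)]
    mask[v[1], v[2]] <- v[3] == 1
  }
  raster_cube(time, traces, mask, pitch_mm = pitch, reference = refpx)
}

#' Simulate a raster-scan phantom
#'
#' Builds a cube in which each pixel is synthesized from a per-pixel scene:
#' `region` assigns every pixel a label, and `scenes` maps labels to
#' [synthetic_scene] objects. The reference pixel's trace is replaced by the
#' bare-reference measurement of its scene.
#'
#' @param region integer or character matrix of region labels.
#' @param scenes named list of [synthetic_scene] objects, one per label.
#' @param pulse a [pulse_spec].
#' @param pitch_mm pixel pitch in millimetres.
#' @param reference_pixel `c(row, col)`.
#' @return A [raster_cube].
#' @export
simulate_raster_cube <- function(region, scenes, pulse, pitch_mm = 0.5,
                                 reference_pixel = c(1, 1)) {
  labels <- unique(as.vector(region))
  if (!all(as.character(labels) %in% names(scenes)))
    stop("every region label needs a scene")
  pairs <- lapply(scenes, synthesize_waveforms, pulse = pulse)
  nt <- length(pairs[[1]]$sample$time)
  d <- dim(region)
  traces <- array(NA_real_, c(d, nt))
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    traces[i, j, ] <- pairs[[as.character(region[i, j])]]$sample$amplitude
  ref_lab <- as.character(region[reference_pixel[1], reference_pixel[2]])
  traces[reference_pixel[1], reference_pixel[2], ] <-
    pairs[[ref_lab]]$reference$amplitude
  raster_cube(pairs[[1]]$sample$time, traces, pitch_mm = pitch_mm,
              reference = reference_pixel)
}

#' Write dielectric maps to CSV matrices and float TIFF images
#'
#' One CSV and one 32-bit float TIFF per map, plus a JSON metadata sidecar
#' naming the frequencies, pitch and flag counts.
#'
#' @param maps a [run_pixelwise()] result.
#' @param prefix output path prefix.
#' @return character vector of written files, invisibly.
#' @export
write_dielectric_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "dielectric_map"))
  written <- character(0)
  emit <- function(mat, name) {
    csv <- sprintf("%s_%s.csv", prefix, name)
    utils::write.table(mat, csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    tif <- sprintf("%s_%s.tif", prefix, name)
    m <- mat
    m[!is.finite(m)] <- 0
    rng <- range(m)
    tiff::writeTIFF((m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps),
                    tif, bits.per.sample = 32L)
    written <<- c(written, csv, tif)
  }
  emit(maps$thickness * 1e6, "thickness_um")
  emit(maps$peak_to_peak, "peak_to_peak")
  for (q in seq_along(maps$freqs_thz)) {
    tag <- sprintf("%.0fGHz", maps$freqs_thz[q] * 1000)
    emit(maps$n[[q]], paste0("n_", tag))
    emit(maps$kappa[[q]], paste0("kappa_", tag))
  }
  meta <- sprintf("%s_meta.json", prefix)
  jsonlite::write_json(list(freqs_thz = maps$freqs_thz,
                            pitch_mm = maps$pitch_mm,
                            flagged = sum(nzchar(maps$flags)),
                            files = written),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(written, meta))
}
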