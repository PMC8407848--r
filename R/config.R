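#' Load and validate a configuration file
#'
#' YAML with sections `pulse`, `stack`, `kk`, `grid`, `imaging`; every key
#' is optional and defaults are filled in. File-level units are THz and
#' micrometres; the returned settings objects carry SI units (rad/s,
#' metres). Unknown keys are rejected so that typos fail loudly, naming the
#' offending key path.
#'
#' @param path path to a YAML config file; an empty or absent-section file
#'   yields the full defaults.
#' @return list with elements `pulse` ([pulse_spec]), `stack`
#'   ([layer_stack]), `kk` ([kk_settings]), `grid` ([retrieval_grid]) and
#'   `imaging` (plain list: `freqs_thz`, `band_thz`, `snr_floor`,
#'   `pitch_mm`, `seed`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_sections <- c("pulse", "stack", "kk", "grid", "imaging")
  extra <- setdiff(names(raw), known_sections)
  if (length(extra)) stop("unknown config section(s): ",
                          paste(extra, collapse = ", "))
  get_section <- function(name, keys) {
    sec <- raw[[name]]
    if (is.null(sec)) sec <- list()
    bad <- setdiff(names(sec), keys)
    if (length(bad)) stop("unknown config key(s): ",
                          paste(paste0(name, ".", bad), collapse = ", "))
    sec
  }
  pick <- function(sec, key, default) if (is.null(sec[[key]])) default else sec[[key]]

  p <- get_section("pulse", c("band_thz", "amplitude", "span_ps", "dt_ps",
                              "delay_ps"))
  pulse <- tryCatch(
    pulse_spec(band_thz = unlist(pick(p, "band_thz", c(0.3, 1))),
               amplitude = pick(p, "amplitude", 1),
               span_ps = pick(p, "span_ps", 128),
               dt_ps = pick(p, "dt_ps", 0.0625),
               delay_ps = pick(p, "delay_ps", 25)),
    error = function(e) stop("config section [pulse]: ",
                             conditionMessage(e), call. = FALSE))

  s <- get_section("stack", c("n2", "kappa2", "n3", "kappa3", "thickness_um",
                              "theta1_deg", "polarisation", "walkoff"))
  stack <- tryCatch(
    sample_on_substrate(n2 = pick(s, "n2", 1.8),
                        kappa2 = pick(s, "kappa2", 0.08),
                        n3 = pick(s, "n3", 2.6),
                        kappa3 = pick(s, "kappa3", 0.15),
                        thickness_um = pick(s, "thickness_um", 100),
                        theta1 = pick(s, "theta1_deg", 0) * pi / 180,
                        polarisation = pick(s, "polarisation", "s"),
                        walkoff = unlist(pick(s, "walkoff", 1))),
    error = function(e) stop("config section [stack]: ",
                             conditionMessage(e), call. = FALSE))

  k <- get_section("kk", c("anchor_thz", "epsilon", "max_iterations",
                           "offset_range_um", "n_candidates", "shrink",
                           "n_air", "extrapolation"))
  rng_um <- unlist(pick(k, "offset_range_um", c(-1000, 1000)))
  kk <- tryCatch(
    kk_settings(anchor_thz = pick(k, "anchor_thz", NULL),
                epsilon = pick(k, "epsilon", 0.01),
                max_iterations = pick(k, "max_iterations", 20),
                offset_range_m = um_to_m(rng_um),
                n_candidates = pick(k, "n_candidates", 256),
                shrink = pick(k, "shrink", 4),
                n_air = pick(k, "n_air", 1),
                extrapolation = pick(k, "extrapolation", "dc")),
    error = function(e) stop("config section [kk]: ",
                             conditionMessage(e), call. = FALSE))

  g <- get_section("grid", c("n_min", "n_max", "n_step", "kappa_min",
                             "kappa_max", "kappa_step", "refine_levels",
                             "refine_factor"))
  grid <- tryCatch(
    retrieval_grid(n_values = seq(pick(g, "n_min", 1), pick(g, "n_max", 4),
                                  by = pick(g, "n_step", 0.01)),
                   kappa_values = seq(pick(g, "kappa_min", 0),
                                      pick(g, "kappa_max", 1),
                                      by = pick(g, "kappa_step", 0.005)),
                   refine_levels = pick(g, "refine_levels", 2),
                   refine_factor = pick(g, "refine_factor", 5)),
    error = function(e) stop("config section [grid]: ",
                             conditionMessage(e), call. = FALSE))

  im <- get_section("imaging", c("freqs_thz", "band_thz", "snr_floor",
                                 "pitch_mm", "seed"))
  imaging <- list(freqs_thz = unlist(pick(im, "freqs_thz", c(0.3, 0.4, 0.5))),
                  band_thz = unlist(pick(im, "band_thz", c(0.3, 1))),
                  snr_floor = pick(im, "snr_floor", 0.01),
                  pitch_mm = pick(im, "pitch_mm", 0.5),
                  seed = pick(im, "seed", 1L))
  if (imaging$snr_floor < 0) stop("config key imaging.snr_floor must be >= 0")

  list(pulse = pulse, stack = stack, kk = kk, grid = grid, imaging = imaging)
}

#' Serialize a hybrid result to a JSON report
#'
#' @param result a [run_hybrid()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_hybrid_report <- function(result, path) {
  stopifnot(inherits(result, "hybrid_result"))
  jsonlite::write_json(
    list(delta_L_um = result$offset$delta_L * 1e6,
         thickness_um = result$thickness * 1e6,
         iterations = result$offset$iterations,
         converged = result$offset$converged,
         consistency_history = result$offset$consistency_history,
         band_thz = result$band_thz,
         n_mean = mean(result$fit$n),
         kappa_mean = mean(result$fit$kappa),
         fit = result$fit),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
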