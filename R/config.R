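#' Pipeline run configuration
#'
#' All tunable defaults of the pipeline live in one nested list with sections
#' `bins`, `eps`, `fm`, `phantom`, `map`, `stats`, plus `log_level` and
#' `out_dir`. `read_run_config()` merges a JSON file over the defaults and
#' rejects unknown keys (misspelled options fail loudly instead of being
#' ignored).
#'
#' @return `default_run_config()` returns the full default configuration
#'   list.
#' @export
default_run_config <- function() {
  list(
    bins = list(low_nm = c(640, 650, 660, 670),
                mid_nm = c(710, 720, 730, 740)),
    eps = 1e-9,
    fm = list(carrier_hz = 220, modulator_hz = 110, index_scale = 1,
              duration_s = 1, sample_rate = 44100, peak_amplitude = 0.8,
              fade_ms = 10),
    phantom = list(rows = 128, cols = 128,
                   wavelengths_nm = seq(640, 810, by = 10),
                   background_level = 100, background_slope = 0.002,
                   tumor_center = c(64, 80), tumor_axes = c(12, 9),
                   tumor_amplitude = 300, tumor_peak_nm = 720,
                   tumor_width_nm = 25,
                   skull_roi = c(10, 10, 26, 26),
                   flank_roi = c(96, 16, 112, 40),
                   noise_sd = 5, noise_model = "gaussian", seed = 1),
    map = list(threshold = 0.5, alpha = 0.6),
    stats = list(exact_limit = 12, paired = FALSE),
    log_level = "info",
    out_dir = "."
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop("configuration section '", full, "' must be an object")
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' @rdname default_run_config
#' @param path optional JSON config file; `NULL` gives pure defaults.
#' @param overrides optional named list merged over the file values.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, doc)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

config_bins <- function(cfg) {
  bin_selection(low_nm = cfg$bins$low_nm, mid_nm = cfg$bins$mid_nm)
}

config_fm <- function(cfg) {
  fm_params(carrier_hz = cfg$fm$carrier_hz, modulator_hz = cfg$fm$modulator_hz,
            index_scale = cfg$fm$index_scale, duration_s = cfg$fm$duration_s,
            sample_rate_hz = cfg$fm$sample_rate,
            peak_amplitude = cfg$fm$peak_amplitude, fade_ms = cfg$fm$fade_ms)
}

config_phantom <- function(cfg, seed = NULL) {
  p <- cfg$phantom
  phantom_config(rows = p$rows, cols = p$cols,
                 wavelengths_nm = p$wavelengths_nm,
                 background_level = p$background_level,
                 background_slope = p$background_slope,
                 tumor_center = p$tumor_center, tumor_axes = p$tumor_axes,
                 tumor_amplitude = p$tumor_amplitude,
                 tumor_peak_nm = p$tumor_peak_nm,
                 tumor_width_nm = p$tumor_width_nm,
                 skull_roi = p$skull_roi, flank_roi = p$flank_roi,
                 noise_sd = p$noise_sd, noise_model = p$noise_model,
                 seed = if (is.null(seed)) p$seed else seed)
}

log_msg <- function(cfg, level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[tolower(cfg$log_level)]])
    message(sprintf("[%s] ", toupper(level)), ...)
  invisible(NULL)
}
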