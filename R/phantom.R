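#' Synthetic NIRF tumor phantom configuration
#'
#' The phantom emulates an in vivo acquisition: an 18-channel 640-810 nm cube
#' holding a spatially uniform autofluorescence background whose intensity
#' rises across the window, an elliptical tumor carrying a cy5.5-like Gaussian
#' emission bump centered inside the mid bins, optional extravasation control
#' region, and additive noise — together with the ground-truth tumor mask and
#' the closed-form expected probe-to-background ratio.
#'
#' The background spectrum is `B * exp(-lambda * (w_max - w))`, increasing
#' with wavelength, so its target value (mid-minus-low band difference) is
#' strictly positive — the implicit assumption of the ratio method that the
#' background autofluorescence has spectral slope. Tumor pixels add
#' `A * exp(-(w - peak)^2 / (2 sigma^2))`.
#'
#' @param rows,cols image size in pixels.
#' @param wavelengths_nm channel center wavelengths (default 18 channels,
#'   640-810 nm in 10 nm steps).
#' @param background_level background intensity `B` at the longest wavelength.
#' @param background_slope spectral decay constant `lambda` per nm of the
#'   background toward shorter wavelengths.
#' @param tumor_center,tumor_axes ellipse center `(row, col)` and semi-axes
#'   `(a_row, a_col)` in pixel-index coordinates.
#' @param tumor_amplitude emission bump peak amplitude `A` (>= 0).
#' @param tumor_peak_nm,tumor_width_nm bump center and Gaussian sigma, nm.
#' @param skull_roi,flank_roi background rectangles `(row0, col0, row1, col1)`,
#'   half-open, placed away from the tumor.
#' @param noise_sd additive zero-mean Gaussian noise standard deviation.
#' @param noise_model `"gaussian"` (default; keeps closed-form ratios exact in
#'   expectation) or `"poisson"` (robustness testing).
#' @param seed integer seed; identical seeds give identical cubes.
#' @param control `NULL`, or a list with `center`, `axes` and
#'   `amplitude_factor` describing an extravasation-control region (see
#'   [extravasation_control()]).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(rows = 128, cols = 128,
                           wavelengths_nm = seq(640, 810, by = 10),
                           background_level = 100, background_slope = 0.002,
                           tumor_center = c(64, 80), tumor_axes = c(12, 9),
                           tumor_amplitude = 300, tumor_peak_nm = 720,
                           tumor_width_nm = 25,
                           skull_roi = c(10, 10, 26, 26),
                           flank_roi = c(96, 16, 112, 40),
                           noise_sd = 5, noise_model = c("gaussian", "poisson"),
                           seed = 1L, control = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(rows >= 8, cols >= 8, length(wavelengths_nm) >= 2,
            background_level > 0, background_slope > 0,
            tumor_amplitude >= 0, tumor_width_nm > 0, noise_sd >= 0,
            all(tumor_axes > 0))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 background_level = background_level,
                 background_slope = background_slope,
                 tumor_center = tumor_center, tumor_axes = tumor_axes,
                 tumor_amplitude = tumor_amplitude,
                 tumor_peak_nm = tumor_peak_nm,
                 tumor_width_nm = tumor_width_nm,
                 skull_roi = skull_roi, flank_roi = flank_roi,
                 noise_sd = noise_sd, noise_model = noise_model,
                 seed = as.integer(seed), control = control),
            class = "phantom_config")
}

# Unit spectral shapes of the phantom model.
phantom_background_spectrum <- function(config) {
  w <- config$wavelengths_nm
  config$background_level *
    exp(-config$background_slope * (max(w) - w))
}

phantom_bump_spectrum <- function(config) {
  w <- config$wavelengths_nm
  exp(-(w - config$tumor_peak_nm)^2 / (2 * config$tumor_width_nm^2))
}

#' Closed-form expected probe-to-background ratio of a phantom
#'
#' With background spectrum `bg(w)` and unit bump `h(w)`, the target value of
#' a background pixel is `d = mean(bg[mid]) - mean(bg[low])` and that of a
#' tumor pixel is `d + A * g` with `g = mean(h[mid]) - mean(h[low])`, so the
#' noise-free probe-to-background ratio is exactly `1 + A * g / d`.
#'
#' @param config a [phantom_config()].
#' @param bins a [bin_selection()].
#' @param amplitude emission amplitude; defaults to the config's
#'   `tumor_amplitude`.
#' @return The expected ratio.
#' @export
expected_ratio <- function(config, bins = bin_selection(),
                           amplitude = config$tumor_amplitude) {
  bg <- as_spectrum(phantom_background_spectrum(config), config$wavelengths_nm)
  bump <- as_spectrum(phantom_bump_spectrum(config), config$wavelengths_nm)
  d <- target_value(bg, bins)
  g <- target_value(bump, bins)
  1 + amplitude * g / d
}

#' Single-band visual contrast of a phantom
#'
#' The best-case per-pixel contrast of the tumor in any single spectral
#' channel: the maximum tumor-minus-background intensity difference across
#' channels divided by the per-channel noise standard deviation. Values below
#' ~2 mean the tumor is not visually separable in any one band.
#'
#' @inheritParams expected_ratio
#' @return Scalar contrast in noise-sd units (`Inf` when `noise_sd == 0`).
#' @export
single_band_contrast <- function(config) {
  peak <- config$tumor_amplitude * max(phantom_bump_spectrum(config))
  if (config$noise_sd == 0) return(Inf)
  peak / config$noise_sd
}

ellipse_mask <- function(rows, cols, center, axes) {
  r <- matrix(rep(seq_len(rows) - 1L, times = cols), rows, cols)
  c_ <- matrix(rep(seq_len(cols) - 1L, each = rows), rows, cols)
  ((r - center[1L]) / axes[1L])^2 + ((c_ - center[2L]) / axes[2L])^2 <= 1
}

# Largest axis-aligned half-open rect inscribed in an ellipse (by the 1/sqrt2
# rule), used as the default probe ROI so every probed pixel carries the bump.
inscribed_rect <- function(name, center, axes, role) {
  ha <- max(1L, floor(axes[1L] / sqrt(2)))
  hb <- max(1L, floor(axes[2L] / sqrt(2)))
  roi_rect(name, center[1L] - ha, center[2L] - hb,
           center[1L] + ha, center[2L] + hb, role = role)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic phantom cube with ground truth
#'
#' Builds the cube (background surface + tumor bump + optional control bump +
#' seeded noise, clipped at zero), the ground-truth tumor mask with its
#' closed-form expected ratio, and a standard ROI set: a probe rectangle
#' inscribed in the tumor ellipse (`"tumor"`), the `"skull"` and `"flank"`
#' background rectangles, and — when a control region is configured — a
#' `"tail"` control ROI. Identical seeds give identical cubes.
#'
#' @inheritParams expected_ratio
#' @return List with `cube` ([spectral_cube()]), `truth` (list with `mask`,
#'   `expected_ratio` and, if configured, `control_expected_ratio`) and
#'   `rois` (named list of [roi] objects).
#' @export
generate_phantom <- function(config = phantom_config(),
                             bins = bin_selection()) {
  stopifnot(inherits(config, "phantom_config"))
  rows <- config$rows; cols <- config$cols
  nchan <- length(config$wavelengths_nm)
  mask <- ellipse_mask(rows, cols, config$tumor_center, config$tumor_axes)
  bg <- phantom_background_spectrum(config)
  bump <- phantom_bump_spectrum(config)

  rois <- list(
    tumor = inscribed_rect("tumor", config$tumor_center, config$tumor_axes,
                           role = "probe"),
    skull = roi_rect("skull", config$skull_roi[1L], config$skull_roi[2L],
                     config$skull_roi[3L], config$skull_roi[4L],
                     role = "background"),
    flank = roi_rect("flank", config$flank_roi[1L], config$flank_roi[2L],
                     config$flank_roi[3L], config$flank_roi[4L],
                     role = "background"))

  ctrl_mask <- NULL
  if (!is.null(config$control)) {
    ctrl <- config$control
    ctrl_mask <- ellipse_mask(rows, cols, ctrl$center, ctrl$axes)
    if (any(ctrl_mask & mask))
      stop("control region overlaps the tumor ellipse")
    rois$tail <- inscribed_rect("tail", ctrl$center, ctrl$axes,
                                role = "control")
  }
  for (bgname in c("skull", "flank")) {
    px <- rasterize_roi(rois[[bgname]], c(rows, cols))
    hit <- mask[cbind(px[, 1L] + 1L, px[, 2L] + 1L)]
    if (!is.null(ctrl_mask))
      hit <- hit | ctrl_mask[cbind(px[, 1L] + 1L, px[, 2L] + 1L)]
    if (any(hit))
      stop(sprintf("background ROI '%s' overlaps the tumor/control region",
                   bgname))
  }

  cube <- array(0, c(rows, cols, nchan))
  for (k in seq_len(nchan)) {
    plane <- matrix(bg[k], rows, cols)
    plane[mask] <- plane[mask] + config$tumor_amplitude * bump[k]
    if (!is.null(ctrl_mask))
      plane[ctrl_mask] <- plane[ctrl_mask] +
        config$tumor_amplitude * config$control$amplitude_factor * bump[k]
    cube[, , k] <- plane
  }
  cube <- with_seed(config$seed, {
    if (config$noise_model == "poisson") {
      array(stats::rpois(length(cube), lambda = cube), dim(cube))
    } else if (config$noise_sd > 0) {
      pmax(cube + stats::rnorm(length(cube), sd = config$noise_sd), 0)
    } else cube
  })

  truth <- list(mask = mask, expected_ratio = expected_ratio(config, bins))
  if (!is.null(config$control))
    truth$control_expected_ratio <-
      expected_ratio(config, bins,
                     amplitude = config$tumor_amplitude *
                       config$control$amplitude_factor)
  list(cube = spectral_cube(cube, config$wavelengths_nm,
                            name = sprintf("phantom-seed%d", config$seed)),
       truth = truth, rois = rois)
}

#' Add an extravasation-control region to a phantom configuration
#'
#' Models a positive control (extravasated injection at the tail): a small
#' ellipse whose emission amplitude is `amplitude_factor` times the tumor's,
#' recorded in the ROI set with role `"control"`.
#'
#' @param config a [phantom_config()].
#' @param center,axes control ellipse geometry (pixel-index coordinates).
#' @param amplitude_factor multiplier on `tumor_amplitude` (default 5).
#' @return The modified configuration.
#' @export
extravasation_control <- function(config, center = c(116, 64),
                                  axes = c(6, 5), amplitude_factor = 5) {
  stopifnot(inherits(config, "phantom_config"), amplitude_factor >= 0)
  config$control <- list(center = center, axes = axes,
                         amplitude_factor = amplitude_factor)
  config
}

#' Weak-signal (masked tumor) phantom configuration
#'
#' Shrinks the tumor to semi-axes (3, 2) and lowers the emission amplitude so
#' the closed-form expected ratio hits `target_ratio` (default 1.7): a tumor
#' invisible in any single band (single-band contrast below 2 noise-sd at the
#' defaults) whose sonification ratio still clearly exceeds 1.
#'
#' @inheritParams expected_ratio
#' @param target_ratio desired expected ratio, in `[1.5, 2]`.
#' @return The modified configuration.
#' @export
masked_tumor_config <- function(config = phantom_config(), target_ratio = 1.7,
                                bins = bin_selection()) {
  stopifnot(inherits(config, "phantom_config"),
            target_ratio >= 1.5, target_ratio <= 2)
  config$tumor_axes <- c(3, 2)
  bg <- as_spectrum(phantom_background_spectrum(config), config$wavelengths_nm)
  bump <- as_spectrum(phantom_bump_spectrum(config), config$wavelengths_nm)
  d <- target_value(bg, bins)
  g <- target_value(bump, bins)
  config$tumor_amplitude <- (target_ratio - 1) * d / g
  config
}

#' Tabulate replicated ROI measurements from a batch of phantoms
#'
#' Emulates the drag-click measurement protocol on a cohort: for each subject
#' a phantom is generated (seed `seed + subject`), and each region (tumor
#' ellipse, skull and flank rectangles, plus the control when present) is
#' probed `replicates` times at randomly placed small circular ROIs inside the
#' region, each normalized against the full skull background ROI.
#'
#' @param n_subjects number of phantoms in the batch.
#' @param replicates measurements per region per subject.
#' @param config base [phantom_config()]; the per-subject seed is derived from
#'   `seed`.
#' @param seed integer seed for both phantom noise and probe placement.
#' @param probe_radius radius (pixels) of the per-click circular ROI.
#' @param bins a [bin_selection()].
#' @return `data.frame` with columns `subject_id`, `roi_name`, `role`,
#'   `replicate_index`, `ratio`.
#' @export
phantom_ratio_table <- function(n_subjects = 6, replicates = 3,
                                config = phantom_config(), seed = 1L,
                                probe_radius = 2.5, bins = bin_selection()) {
  out <- list()
  for (s in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- as.integer(seed + s)
    ph <- generate_phantom(cfg, bins)
    shape <- c(cfg$rows, cfg$cols)
    regions <- ph$rois
    centers <- with_seed(seed * 1000L + s, {
      lapply(regions, function(r) {
        px <- rasterize_roi(r, shape)
        # keep click centers away from the region border by the probe radius
        m <- ceiling(probe_radius)
        ok <- px[, 1L] >= min(px[, 1L]) + m & px[, 1L] <= max(px[, 1L]) - m &
          px[, 2L] >= min(px[, 2L]) + m & px[, 2L] <= max(px[, 2L]) - m
        cand <- if (any(ok)) px[ok, , drop = FALSE] else px
        cand[sample.int(nrow(cand), replicates, replace = TRUE), ,
             drop = FALSE]
      })
    })
    for (rn in names(regions)) {
      for (k in seq_len(replicates)) {
        click <- roi_circle(regions[[rn]]$name, centers[[rn]][k, 1L],
                            centers[[rn]][k, 2L], probe_radius,
                            role = regions[[rn]]$role)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = sprintf("subject%02d", s),
          roi_name = regions[[rn]]$name, role = regions[[rn]]$role,
          replicate_index = k,
          ratio = roi_ratio(ph$cube, click, ph$rois$skull, bins = bins),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
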