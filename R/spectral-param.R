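#' Wavelength bin selection for the target value
#'
#' The auditory-display parameter is built from two disjoint wavelength bin
#' sets: the target value of a spectrum is its mean intensity over the mid
#' bins minus its mean over the low bins. The defaults follow the cy5.5
#' mapping (low 640-670 nm, mid 710-740 nm); both sets are wavelength-keyed
#' and configurable so other fluorophores can be mapped.
#'
#' @param low_nm wavelengths (nm) of the low-frequency bins.
#' @param mid_nm wavelengths (nm) of the mid-frequency bins.
#' @return An object of class `bin_selection`.
#' @export
bin_selection <- function(low_nm = c(640, 650, 660, 670),
                          mid_nm = c(710, 720, 730, 740)) {
  low_nm <- as.numeric(low_nm); mid_nm <- as.numeric(mid_nm)
  if (length(low_nm) == 0L || length(mid_nm) == 0L)
    stop("both bin sets must be non-empty")
  if (length(intersect(low_nm, mid_nm)) > 0L)
    stop("low and mid bin sets must be disjoint")
  structure(list(low_nm = low_nm, mid_nm = mid_nm), class = "bin_selection")
}

bin_indices <- function(wavelengths_nm, bins_nm) {
  idx <- match(bins_nm, wavelengths_nm)
  if (anyNA(idx))
    stop(sprintf("bin wavelength(s) not present in spectrum: %s nm",
                 paste(bins_nm[is.na(idx)], collapse = ", ")))
  idx
}

#' Target value of a spectrum
#'
#' `mean(values at mid bins) - mean(values at low bins)`. Spectrally flat
#' spectra give 0 regardless of brightness: this is the mechanism that
#' suppresses broadband tissue autofluorescence. The value may be negative.
#'
#' @param spectrum an [as_spectrum()] object (or a list with `values` and
#'   `wavelengths_nm`).
#' @param bins a [bin_selection()].
#' @return A single numeric value.
#' @export
target_value <- function(spectrum, bins = bin_selection()) {
  stopifnot(inherits(bins, "bin_selection"))
  lo <- bin_indices(spectrum$wavelengths_nm, bins$low_nm)
  mi <- bin_indices(spectrum$wavelengths_nm, bins$mid_nm)
  mean(spectrum$values[mi]) - mean(spectrum$values[lo])
}

#' Normalize a probe target value against the background
#'
#' Returns the probe-to-background ratio `probe_target / background_target`.
#' The ratio is signed: a negative probe target yields a negative ratio, which
#' is preserved in numeric outputs and clamped only when mapped to the FM
#' modulation index by [modulation_index()].
#'
#' @param probe_target target value of the probed ROI.
#' @param background_target target value of the background (e.g. skull) ROI;
#'   must exceed `eps`.
#' @param eps positive guard in cube intensity units below which the
#'   background target is rejected (default `1e-9`).
#' @return The signed ratio.
#' @export
normalize_target <- function(probe_target, background_target, eps = 1e-9) {
  if (!is.finite(probe_target) || !is.finite(background_target))
    stop("target values must be finite")
  if (background_target <= eps)
    stop("background target non-positive or below eps; ",
         "choose a background ROI with autofluorescence signal")
  probe_target / background_target
}

#' Probe-to-background ratio of an ROI pair
#'
#' The per-ROI numeric output of the auditory display: the target value of the
#' probe ROI's mean spectrum divided by that of the background ROI. Invariant
#' under rescaling of the whole cube.
#'
#' @inheritParams extract_roi_spectrum
#' @param probe_roi,background_roi [roi] objects on `cube`.
#' @inheritParams normalize_target
#' @param bins a [bin_selection()].
#' @return The signed ratio.
#' @export
roi_ratio <- function(cube, probe_roi, background_roi,
                      bins = bin_selection(), eps = 1e-9) {
  pt <- target_value(extract_roi_spectrum(cube, probe_roi), bins)
  bt <- target_value(extract_roi_spectrum(cube, background_roi), bins)
  normalize_target(pt, bt, eps = eps)
}

#' Per-pixel parameter map of probe-to-background ratios
#'
#' Computes the target value of every pixel's spectrum and divides by the
#' single target value of the background ROI. This is the numeric field that
#' [rescale01()] and [rainbow_render()] turn back into an image.
#'
#' @inheritParams roi_ratio
#' @param background_roi background [roi] supplying the normalizing target.
#' @return An object of class `param_map`: list with `values` (rows x cols
#'   matrix of signed ratios), `background_target` and `bins`.
#' @export
parameter_map <- function(cube, background_roi, bins = bin_selection(),
                          eps = 1e-9) {
  stopifnot(inherits(cube, "spectral_cube"))
  bt <- target_value(extract_roi_spectrum(cube, background_roi), bins)
  if (bt <= eps)
    stop("background target non-positive or below eps; ",
         "choose a background ROI with autofluorescence signal")
  lo <- bin_indices(cube$wavelengths_nm, bins$low_nm)
  mi <- bin_indices(cube$wavelengths_nm, bins$mid_nm)
  mean_slices <- function(idx) {
    Reduce(`+`, lapply(idx, function(k) cube$intensities[, , k])) / length(idx)
  }
  values <- (mean_slices(mi) - mean_slices(lo)) / bt
  structure(list(values = values, background_target = bt, bins = bins),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf("<param_map> %d x %d, background target %.6g, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$background_target,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Probe every ROI in a set against one background ROI
#'
#' Convenience tabulation used by the stats pipeline and the CSV export:
#' each ROI (including the background itself, which probes to 1) becomes one
#' row with its target value and ratio.
#'
#' @inheritParams roi_ratio
#' @param rois list of [roi] objects.
#' @param background_name name of the ROI in `rois` used as background.
#' @return `data.frame` with columns `roi_name`, `role`, `target`,
#'   `background_target`, `ratio`.
#' @export
probe_all_rois <- function(cube, rois, background_name,
                           bins = bin_selection(), eps = 1e-9) {
  bg <- roi_by_name(rois, background_name)
  bt <- target_value(extract_roi_spectrum(cube, bg), bins)
  rows <- lapply(rois, function(r) {
    tv <- target_value(extract_roi_spectrum(cube, r), bins)
    data.frame(roi_name = r$name, role = r$role, target = tv,
               background_target = bt,
               ratio = normalize_target(tv, bt, eps = eps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname probe_all_rois
#' @param ratios data.frame as returned by `probe_all_rois()`.
#' @param path CSV output path.
#' @export
write_ratio_csv <- function(ratios, path) {
  utils::write.csv(ratios, path, row.names = FALSE)
  invisible(path)
}
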