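#' Save audio spectrum and waveform plots as PNG
#'
#' Static renderings of the per-ROI displays: the single-sided magnitude
#' spectrum (stem plot, optionally truncated at `max_hz`) and the pressure
#' waveform over time (first `max_s` seconds by default, where individual
#' modulation cycles remain visible).
#'
#' @param display a `spectrum_display` from [audio_spectrum()].
#' @param path output PNG path.
#' @param max_hz upper frequency limit of the plot; `NULL` plots to Nyquist.
#' @export
save_spectrum_png <- function(display, path, max_hz = 5000) {
  grDevices::png(path, width = 800, height = 400)
  on.exit(grDevices::dev.off())
  keep <- if (is.null(max_hz)) rep(TRUE, length(display$frequencies_hz))
          else display$frequencies_hz <= max_hz
  graphics::plot(display$frequencies_hz[keep], display$magnitudes[keep],
                 type = "h", xlab = "Frequency (Hz)",
                 ylab = "Magnitude (linear)", main = "Audio spectrum")
  invisible(path)
}

#' @rdname save_spectrum_png
#' @param buffer an `audio_buffer`.
#' @param max_s seconds of waveform to draw.
#' @export
save_waveform_png <- function(buffer, path, max_s = 0.05) {
  grDevices::png(path, width = 800, height = 300)
  on.exit(grDevices::dev.off())
  n <- min(length(buffer$samples), round(max_s * buffer$sample_rate_hz))
  t <- (seq_len(n) - 1) / buffer$sample_rate_hz
  graphics::plot(t, buffer$samples[seq_len(n)], type = "l",
                 xlab = "Time (s)", ylab = "Amplitude", main = "Waveform")
  invisible(path)
}
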