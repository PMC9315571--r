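#' FM synthesis parameters
#'
#' Two-oscillator frequency modulation: a carrier sinusoid at `carrier_hz` is
#' phase-modulated by a sinusoid at `modulator_hz`, with the modulation index
#' supplied per note by the probe-to-background ratio. The defaults use a 2:1
#' harmonic carrier/modulator ratio (220/110 Hz) so timbres stay harmonic and
#' easy to compare by ear; index changes move energy into FM sidebands at
#' `carrier_hz + k * modulator_hz` with amplitudes governed by Bessel
#' functions `J_k(I)`, so larger ratios sound brighter ("high-timbred").
#'
#' @param carrier_hz carrier frequency, Hz.
#' @param modulator_hz modulator frequency, Hz; must be below Nyquist.
#' @param index_scale linear gain applied to the (clamped) ratio to obtain the
#'   modulation index; default 1 maps the ratio directly.
#' @param duration_s note duration in seconds.
#' @param sample_rate_hz sample rate, Hz.
#' @param peak_amplitude output peak in `(0, 1]`.
#' @param fade_ms raised-cosine fade length at each end, milliseconds; 0
#'   disables fades (used for spectral measurements).
#' @return An object of class `fm_params`.
#' @export
fm_params <- function(carrier_hz = 220, modulator_hz = 110, index_scale = 1,
                      duration_s = 1, sample_rate_hz = 44100L,
                      peak_amplitude = 0.8, fade_ms = 10) {
  stopifnot(carrier_hz > 0, modulator_hz > 0, index_scale > 0, duration_s > 0,
            sample_rate_hz > 0, peak_amplitude > 0, peak_amplitude <= 1,
            fade_ms >= 0)
  if (modulator_hz >= sample_rate_hz / 2)
    stop("modulator_hz must be below Nyquist")
  structure(list(carrier_hz = carrier_hz, modulator_hz = modulator_hz,
                 index_scale = index_scale, duration_s = duration_s,
                 sample_rate_hz = as.integer(sample_rate_hz),
                 peak_amplitude = peak_amplitude, fade_ms = fade_ms),
            class = "fm_params")
}

#' Map a probe-to-background ratio to an FM modulation index
#'
#' Linear with a clamp at zero: `index_scale * max(ratio, 0)`. Negative ratios
#' (probe target below zero) are kept in numeric outputs but silence the
#' modulation here, keeping the synthesizer well-defined.
#'
#' @param ratio finite numeric probe-to-background ratio.
#' @param params an [fm_params()] object.
#' @return Nonnegative modulation index.
#' @export
modulation_index <- function(ratio, params = fm_params()) {
  if (!is.finite(ratio)) stop("ratio must be finite")
  params$index_scale * max(ratio, 0)
}

#' Render a two-oscillator FM note
#'
#' Samples are `A * sin(2*pi*f_c*n/sr + I * sin(2*pi*f_m*n/sr))` with
#' `A = peak_amplitude`, raised-cosine fades of `fade_ms` at both ends, and a
#' final peak normalization applied only if the peak exceeds
#' `peak_amplitude`. Synthesis is fully deterministic.
#'
#' @param index modulation index `I >= 0`.
#' @param params an [fm_params()] object.
#' @return An object of class `audio_buffer`: list with `samples` (numeric in
#'   `[-1, 1]`) and `sample_rate_hz`.
#' @export
render_fm <- function(index, params = fm_params()) {
  stopifnot(inherits(params, "fm_params"))
  if (!is.finite(index) || index < 0) stop("modulation index must be >= 0")
  sr <- params$sample_rate_hz
  n <- round(params$duration_s * sr)
  t <- (seq_len(n) - 1) / sr
  s <- params$peak_amplitude *
    sin(2 * pi * params$carrier_hz * t +
          index * sin(2 * pi * params$modulator_hz * t))
  nf <- round(params$fade_ms / 1000 * sr)
  if (nf > 0 && 2 * nf <= n) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nf) / nf))
    s[seq_len(nf)] <- s[seq_len(nf)] * ramp
    s[n - nf + seq_len(nf)] <- s[n - nf + seq_len(nf)] * rev(ramp)
  }
  peak <- max(abs(s))
  if (peak > params$peak_amplitude)
    s <- s * (params$peak_amplitude / peak)
  structure(list(samples = s, sample_rate_hz = sr), class = "audio_buffer")
}

#' Single-sided DFT magnitude spectrum of an audio buffer
#'
#' Linear magnitudes `|X_k|` of the discrete Fourier transform of the full
#' buffer, for frequencies 0 to Nyquist. Energy is Parseval-consistent with
#' the time domain: `sum(x^2) == sum(|X|^2) / N` over the full transform.
#'
#' @param buffer an `audio_buffer`.
#' @return An object of class `spectrum_display`: list with ascending
#'   `frequencies_hz` and nonnegative `magnitudes` of equal length.
#' @export
audio_spectrum <- function(buffer) {
  n <- length(buffer$samples)
  if (n == 0L) stop("empty audio buffer")
  X <- stats::fft(buffer$samples)
  k <- 0:(n %/% 2)
  structure(list(frequencies_hz = k * buffer$sample_rate_hz / n,
                 magnitudes = Mod(X)[k + 1L]),
            class = "spectrum_display")
}

#' Summary measures of a magnitude spectrum
#'
#' `spectral_centroid()` is the magnitude-weighted mean frequency;
#' `count_sidebands()` counts frequency bins whose magnitude is at least
#' `frac` of the spectral peak (Carson-rule style bandwidth proxy: the count
#' grows with modulation index).
#'
#' @param display a `spectrum_display`.
#' @return A scalar.
#' @export
spectral_centroid <- function(display) {
  s <- sum(display$magnitudes)
  if (s == 0) return(0)
  sum(display$frequencies_hz * display$magnitudes) / s
}

#' @rdname spectral_centroid
#' @param frac fraction of the peak magnitude above which a bin counts.
#' @export
count_sidebands <- function(display, frac = 0.01) {
  sum(display$magnitudes >= frac * max(display$magnitudes))
}

#' Sonify one ROI against a background ROI
#'
#' The four per-ROI outputs of the auditory display derived from a single
#' probe-to-background ratio: the sound itself, its audio spectrum, its
#' waveform, and the ratio as a number.
#'
#' @inheritParams roi_ratio
#' @param params an [fm_params()] object.
#' @return An object of class `sonification`: list with `audio`
#'   (`audio_buffer`), `spectrum` (`spectrum_display`), `waveform` (numeric
#'   sample vector, identical to `audio$samples`) and `ratio`.
#' @export
sonify_roi <- function(cube, probe_roi, background_roi,
                       bins = bin_selection(), params = fm_params(),
                       eps = 1e-9) {
  ratio <- roi_ratio(cube, probe_roi, background_roi, bins = bins, eps = eps)
  audio <- render_fm(modulation_index(ratio, params), params)
  structure(list(audio = audio, spectrum = audio_spectrum(audio),
                 waveform = audio$samples, ratio = ratio),
            class = "sonification")
}

#' @export
print.sonification <- function(x, ...) {
  cat(sprintf("<sonification> ratio=%.6g, %d samples @ %d Hz, centroid %.1f Hz\n",
              x$ratio, length(x$waveform), x$audio$sample_rate_hz,
              spectral_centroid(x$spectrum)))
  invisible(x)
}
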