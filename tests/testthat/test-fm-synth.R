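# Alias-safe measurement configuration: integer-periodic carrier/modulator
# over 1 s so every sideband falls exactly on a DFT bin; fades disabled.
meas_params <- function(...) {
  fm_params(carrier_hz = 2000, modulator_hz = 100, duration_s = 1,
            sample_rate_hz = 44100L, peak_amplitude = 1, fade_ms = 0, ...)
}

test_that("the index mapping is linear with a clamp at zero", {
  p <- fm_params()
  expect_identical(modulation_index(0, p), 0)
  expect_identical(modulation_index(-2.3, p), 0)
  expect_identical(modulation_index(5.0, p), 5.0)
  expect_equal(modulation_index(5.0, fm_params(index_scale = 2)), 10.0)
  expect_error(modulation_index(NaN, p), "finite")
})

test_that("index 0 degenerates to a pure carrier sinusoid", {
  buf <- render_fm(0, meas_params())
  sp <- audio_spectrum(buf)
  carrier_bin <- which.min(abs(sp$frequencies_hz - 2000))
  peak <- sp$magnitudes[carrier_bin]
  rest <- sp$magnitudes[-c(carrier_bin - 1, carrier_bin, carrier_bin + 1)]
  expect_gt(20 * log10(peak / max(rest)), 60)
})

test_that("first-sideband-to-carrier ratio follows J1/J0 at index 2", {
  sp <- audio_spectrum(render_fm(2, meas_params()))
  got <- bin_magnitude(sp, 2100) / bin_magnitude(sp, 2000)
  want <- abs(besselJ(2, 1) / besselJ(2, 0))
  expect_equal(got, want, tolerance = 0.01)
})

test_that("sideband magnitudes are proportional to |J_k(I)| for |k| <= 8", {
  for (I in c(0.5, 1, 2, 4)) {
    sp <- audio_spectrum(render_fm(I, meas_params()))
    k <- -8:8
    mags <- vapply(k, function(kk) bin_magnitude(sp, 2000 + 100 * kk),
                   numeric(1))
    bessel <- abs(besselJ(I, k))
    scale <- max(mags) / max(bessel)
    expect_lt(max(abs(mags - scale * bessel)) / max(mags), 0.01)
  }
})

test_that("sideband count above 1% of peak is non-decreasing in the index", {
  counts <- vapply(c(0, 1, 2, 4, 8), function(I) {
    count_sidebands(audio_spectrum(render_fm(I, meas_params())))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[5], counts[1])
})

test_that("rendered buffers respect the peak amplitude contract", {
  for (I in c(0, 0.7, 3, 12)) {
    buf <- render_fm(I, fm_params(peak_amplitude = 0.8))
    expect_lte(max(abs(buf$samples)), 0.8 + 1e-9)
    expect_identical(length(buf$samples), 44100L)
  }
})

test_that("synthesis is deterministic", {
  b1 <- render_fm(3.3, fm_params())
  b2 <- render_fm(3.3, fm_params())
  expect_identical(b1$samples, b2$samples)
})

test_that("long FM tones approach RMS 1/sqrt(2)", {
  buf <- render_fm(2, fm_params(carrier_hz = 2000, modulator_hz = 100,
                                duration_s = 10, peak_amplitude = 1,
                                fade_ms = 0))
  rms <- sqrt(mean(buf$samples^2))
  expect_equal(rms, 1 / sqrt(2), tolerance = 1e-3)
})

test_that("audio spectra resolve sinusoid peaks and conserve energy", {
  sr <- 8000L; n <- 8000L
  t <- (0:(n - 1)) / sr
  tone <- structure(list(samples = sin(2 * pi * 440 * t), sample_rate_hz = sr),
                    class = "audio_buffer")
  sp <- audio_spectrum(tone)
  expect_equal(sp$frequencies_hz[which.max(sp$magnitudes)], 440)

  two <- structure(list(samples = 0.6 * sin(2 * pi * 440 * t) +
                          0.2 * sin(2 * pi * 1000 * t),
                        sample_rate_hz = sr), class = "audio_buffer")
  sp2 <- audio_spectrum(two)
  expect_equal(bin_magnitude(sp2, 440) / bin_magnitude(sp2, 1000), 3,
               tolerance = 1e-6)

  set.seed(99)
  noise <- structure(list(samples = stats::rnorm(4096), sample_rate_hz = sr),
                     class = "audio_buffer")
  spn <- audio_spectrum(noise)
  # Parseval: double interior single-sided bins (n even: DC and Nyquist once)
  e_freq <- (2 * sum(spn$magnitudes^2) - spn$magnitudes[1]^2 -
               spn$magnitudes[length(spn$magnitudes)]^2) / 4096
  expect_equal(e_freq, sum(noise$samples^2), tolerance = 1e-6)
  expect_error(audio_spectrum(list(samples = numeric(0), sample_rate_hz = sr)),
               "empty")
})

test_that("WAV files round-trip within quantization and deterministically", {
  silence <- structure(list(samples = numeric(1000), sample_rate_hz = 44100L),
                       class = "audio_buffer")
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(silence, p)
  back <- read_wav(p)
  expect_identical(back$samples, numeric(1000))
  expect_identical(back$sample_rate_hz, 44100L)

  tone <- render_fm(2, fm_params())
  write_wav(tone, p)
  expect_lte(max(abs(read_wav(p)$samples - tone$samples)), 1 / 32767)

  p2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(tone, p2)
  expect_identical(unname(tools::md5sum(p)), unname(tools::md5sum(p2)))
})

test_that("sonifying an ROI against itself yields the index_scale tone", {
  cube <- make_test_cube(rows = 6, cols = 6, seed = 55)
  roi <- roi_rect("r", 1, 1, 5, 5)
  son <- sonify_roi(cube, roi, roi)
  expect_equal(son$ratio, 1.0)
  expect_identical(son$waveform, render_fm(1, fm_params())$samples)
  expect_s3_class(son$spectrum, "spectrum_display")
})

test_that("zero-contrast phantoms sound identical in tumor and background", {
  cfg <- phantom_config(tumor_amplitude = 0, noise_sd = 0)
  ph <- generate_phantom(cfg)
  son_t <- sonify_roi(ph$cube, ph$rois$tumor, ph$rois$skull)
  son_b <- sonify_roi(ph$cube, ph$rois$flank, ph$rois$skull)
  expect_equal(son_t$ratio, 1.0, tolerance = 1e-12)
  expect_equal(son_t$waveform, son_b$waveform, tolerance = 1e-12)
})
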