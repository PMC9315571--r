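test_that("uint16 cubes round-trip through TIFF + sidecar value-exactly", {
  set.seed(11)
  arr <- array(sample(0:65535, 4 * 6 * 18, replace = TRUE), c(4, 6, 18))
  cube <- spectral_cube(arr, seq(640, 810, 10), name = "roundtrip")
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_identical(back$intensities, cube$intensities)
  expect_identical(back$wavelengths_nm, cube$wavelengths_nm)
  expect_identical(back$name, "roundtrip")
})

test_that("floating cubes round-trip within the 32-bit storage quantization", {
  set.seed(12)
  arr <- array(stats::runif(5 * 5 * 6, 0, 350), c(5, 5, 6))
  cube <- spectral_cube(arr, seq(640, 690, 10))
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_lt(max(abs(back$intensities - cube$intensities)),
            max(arr) * 2^-31)
  cube0 <- spectral_cube(array(0, c(3, 3, 2)), c(640, 650))
  write_cube(cube0, path)
  expect_equal(read_cube(path)$intensities, cube0$intensities)
})

test_that("an 18-page TIFF with an 18-wavelength sidecar reads as 18 channels", {
  cube <- make_test_cube(rows = 3, cols = 3)
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path)
  expect_identical(dim(read_cube(path)$intensities)[3L], 18L)
})

test_that("page/wavelength count mismatches and missing sidecars are reported", {
  cube <- make_test_cube(rows = 3, cols = 3,
                         wavelengths = seq(640, 800, 10))  # 17 channels
  path <- withr::local_tempfile(fileext = ".tif")
  write_cube(cube, path)
  meta <- jsonlite::read_json(sub("\\.tif$", ".json", path),
                              simplifyVector = TRUE)
  meta$wavelengths_nm <- seq(640, 810, 10)  # claim 18
  jsonlite::write_json(meta, sub("\\.tif$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_cube(path), "17.*18|18.*17")
  file.remove(sub("\\.tif$", ".json", path))
  expect_error(read_cube(path), sub("\\.tif$", ".json", basename(path)),
               fixed = TRUE)
})

test_that("phantom cubes written twice from the same seed are byte-identical", {
  cfg <- phantom_config(rows = 24, cols = 24, seed = 42L,
                        tumor_center = c(12, 15), tumor_axes = c(5, 4),
                        skull_roi = c(2, 2, 8, 8), flank_roi = c(16, 2, 22, 8))
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_cube(generate_phantom(cfg)$cube, p1)
  write_cube(generate_phantom(cfg)$cube, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("rectangle and circle rasterization follow the stated conventions", {
  px <- rasterize_roi(roi_rect("r", 0, 0, 2, 2), c(4, 4))
  expect_identical(px[order(px[, 1], px[, 2]), , drop = FALSE],
                   cbind(row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L)))
  expect_identical(rasterize_roi(roi_circle("c", 1, 1, 0.4), c(4, 4)),
                   cbind(row = 1L, col = 1L))
  expect_error(rasterize_roi(roi_rect("r", 10, 10, 12, 12), c(4, 4)),
               "ROI outside image")
})

test_that("a square polygon matches the equivalent half-open rectangle", {
  V <- rbind(c(0, 0), c(0, 3), c(3, 3), c(3, 0))
  got <- rasterize_roi(roi_polygon("p", V), c(8, 8))
  want <- rasterize_roi(roi_rect("r", 0, 0, 3, 3), c(8, 8))
  ord <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
  expect_identical(ord(got), ord(want))
})

test_that("polygon rasterization agrees with exhaustive pixel-center testing", {
  set.seed(21)
  for (trial in 1:25) {
    nv <- sample(3:7, 1)
    V <- cbind(stats::runif(nv, -1, 17), stats::runif(nv, -1, 17))
    shape <- c(sample(4:16, 1), sample(4:16, 1))
    want <- NULL
    for (r in 0:(shape[1] - 1)) for (c_ in 0:(shape[2] - 1))
      if (pip_oracle(r + 0.5, c_ + 0.5, V))
        want <- rbind(want, c(r, c_))
    got <- tryCatch(rasterize_roi(roi_polygon("p", V), shape),
                    error = function(e) NULL)
    if (is.null(want)) {
      expect_null(got)
    } else {
      ord <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
      expect_equal(unname(ord(got)), unname(ord(want)))
    }
  }
})

test_that("ROI spectra equal brute-force per-pixel channel means", {
  cube <- make_test_cube(rows = 5, cols = 5, seed = 31)
  roi <- roi_rect("r", 1, 2, 4, 5)
  sp <- extract_roi_spectrum(cube, roi)
  want <- numeric(18)
  np <- 0
  for (r in 2:4) for (c_ in 3:5) {   # 1-based pixels of half-open [1,4)x[2,5)
    want <- want + cube$intensities[r, c_, ]
    np <- np + 1
  }
  expect_equal(sp$values, want / np, tolerance = 1e-12)

  one <- extract_roi_spectrum(cube, roi_circle("px", 2, 3, 0.1))
  expect_identical(one$values, as.numeric(cube$intensities[3, 4, ]))
})

test_that("spectrum extraction is linear in cube intensities", {
  c1 <- make_test_cube(seed = 41)
  c2 <- make_test_cube(seed = 42)
  mix <- spectral_cube(2 * c1$intensities + 3 * c2$intensities,
                       c1$wavelengths_nm)
  roi <- roi_circle("c", 2, 2, 1.6)
  expect_equal(extract_roi_spectrum(mix, roi)$values,
               2 * extract_roi_spectrum(c1, roi)$values +
                 3 * extract_roi_spectrum(c2, roi)$values,
               tolerance = 1e-12)
})

test_that("ROI sets round-trip through JSON", {
  rois <- list(roi_rect("tumor", 1, 2, 5, 8, role = "probe"),
               roi_circle("spot", 3.5, 4.5, 2.25, role = "control"),
               roi_polygon("skull", rbind(c(0, 0), c(0, 4), c(4, 4)),
                           role = "background"))
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_named(back, c("tumor", "spot", "skull"))
  expect_identical(back$tumor$shape$rect, c(1, 2, 5, 8))
  expect_identical(back$spot$shape$circle, c(3.5, 4.5, 2.25))
  expect_identical(back$skull$role, "background")
  expect_equal(back$skull$shape$polygon, rbind(c(0, 0), c(0, 4), c(4, 4)))
})
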