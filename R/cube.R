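#' Construct a hyperspectral cube
#'
#' A spectral cube is a 3-dimensional array of nonnegative intensities indexed
#' `(row, col, channel)` together with the center wavelength (nm) of each
#' channel. Channel semantics live in `wavelengths_nm`, not in positional
#' indices, so cubes with any number of channels (e.g. 17 or 18 acquisition
#' windows) are handled uniformly.
#'
#' @param intensities numeric array with `dim` of length 3 `(rows, cols,
#'   channels)`; all values must be finite and nonnegative.
#' @param wavelengths_nm strictly increasing numeric vector of channel center
#'   wavelengths in nanometres; its length must equal `dim(intensities)[3]`.
#' @param name free-text label carried through I/O.
#' @return An object of class `spectral_cube`: a list with elements
#'   `intensities`, `wavelengths_nm` and `name`.
#' @seealso [read_cube()], [write_cube()], [extract_roi_spectrum()]
#' @export
#' @examples
#' cube <- spectral_cube(array(1, dim = c(4, 4, 3)), c(640, 650, 660))
#' dim(cube$intensities)
spectral_cube <- function(intensities, wavelengths_nm, name = "") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3-dimensional array (row, col, channel)")
  storage.mode(intensities) <- "double"
  if (!all(is.finite(intensities)))
    stop("'intensities' must be finite")
  if (any(intensities < 0))
    stop("'intensities' must be nonnegative")
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != dim(intensities)[3L])
    stop(sprintf("channel count mismatch: cube has %d channels but %d wavelengths given",
                 dim(intensities)[3L], length(wavelengths_nm)))
  if (length(wavelengths_nm) < 1L || any(diff(wavelengths_nm) <= 0))
    stop("'wavelengths_nm' must be strictly increasing")
  structure(list(intensities = intensities,
                 wavelengths_nm = wavelengths_nm,
                 name = as.character(name)[1L]),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<spectral_cube '%s'> %d x %d pixels, %d channels (%g-%g nm)\n",
              x$name, d[1L], d[2L], d[3L],
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a spectral cube as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per channel, uncompressed so repeated writes of the same cube
#' are byte-identical. Wavelengths, the cube name and the storage encoding go
#' into a JSON sidecar with the same basename and extension `.json`.
#'
#' Integer-valued cubes with maximum below 65536 are stored as 16-bit samples
#' and round-trip value-exactly. Other cubes are stored as 32-bit integer
#' samples of `value / intensity_scale` (the TIFF format written by the
#' underlying library carries integer samples only); the scale factor is
#' recorded in the sidecar and the read-back error is bounded by
#' `intensity_scale / 2^32` per pixel.
#'
#' @param cube a [spectral_cube()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return Invisibly, the sidecar path.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$intensities)
  pages <- lapply(seq_len(d[3L]), function(k) cube$intensities[, , k])
  int_valued <- all(cube$intensities == round(cube$intensities)) &&
    max(cube$intensities) <= 65535
  if (int_valued) {
    storage <- list(type = "uint16")
    tiff::writeTIFF(lapply(pages, function(m) m / 65535),
                    path, bits.per.sample = 16L, compression = "none")
  } else {
    scale <- max(cube$intensities)
    if (scale <= 0) scale <- 1
    storage <- list(type = "int32-scaled", intensity_scale = scale)
    tiff::writeTIFF(lapply(pages, function(m) m / scale),
                    path, bits.per.sample = 32L, compression = "none")
  }
  sc <- sidecar_path(path)
  jsonlite::write_json(
    list(wavelengths_nm = cube$wavelengths_nm, name = cube$name,
         storage = storage),
    sc, auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

#' Read a spectral cube written by [write_cube()]
#'
#' @param path path to a multi-page TIFF whose page `i` is channel `i`. A JSON
#'   sidecar with the same basename and extension `.json` must carry the
#'   channel wavelengths.
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing wavelength sidecar: expected '%s' next to '%s'", sc, path))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  type <- if (is.null(meta$storage$type)) "uint16" else meta$storage$type
  wl <- as.numeric(meta$wavelengths_nm)
  if (identical(type, "uint16")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    pages <- lapply(pages, function(m) { storage.mode(m) <- "double"; m })
  } else {
    scale <- as.numeric(meta$storage$intensity_scale)
    pages <- lapply(tiff::readTIFF(path, all = TRUE), function(m) m * scale)
  }
  if (length(pages) != length(wl))
    stop(sprintf("page/wavelength count mismatch: TIFF has %d pages but sidecar lists %d wavelengths",
                 length(pages), length(wl)))
  d <- dim(pages[[1L]])
  cube <- array(unlist(pages, use.names = FALSE), dim = c(d[1L], d[2L], length(pages)))
  name <- if (is.null(meta$name)) "" else meta$name
  spectral_cube(cube, wl, name = name)
}

#' Construct a per-channel spectrum
#'
#' @param values numeric vector, one intensity per channel.
#' @param wavelengths_nm channel center wavelengths, same length as `values`.
#' @return An object of class `roi_spectrum`.
#' @export
as_spectrum <- function(values, wavelengths_nm) {
  values <- as.numeric(values)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(values) != length(wavelengths_nm))
    stop("'values' and 'wavelengths_nm' must have equal length")
  if (!all(is.finite(values))) stop("spectrum values must be finite")
  structure(list(values = values, wavelengths_nm = wavelengths_nm),
            class = "roi_spectrum")
}
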