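#' Rescale a parameter map to the 0-1 interval
#'
#' Per-pixel min-max rescaling `(v - min) / (max - min)` over the whole map,
#' the literal "mapped to a 0-1 scale" step. A constant map rescales to all
#' zeros (renders all-blue: a no-signal image should look cold, not crash).
#' An optional percentile clip is available for noisy maps but is off by
#' default.
#'
#' @param map a `param_map` (see [parameter_map()]) or a numeric matrix.
#' @param clip_percentiles `NULL` (default, plain min-max) or a length-2
#'   vector of probabilities, e.g. `c(0.01, 0.99)`: the window is taken at
#'   those quantiles and values outside it are clamped.
#' @return Numeric matrix in `[0, 1]` with attributes `scale_min` and
#'   `scale_max` recording the rescaling window.
#' @export
rescale01 <- function(map, clip_percentiles = NULL) {
  v <- if (inherits(map, "param_map")) map$values else map
  if (!is.matrix(v)) stop("'map' must be a param_map or a numeric matrix")
  if (!all(is.finite(v))) stop("parameter map values must be finite")
  if (is.null(clip_percentiles)) {
    lo <- min(v); hi <- max(v)
  } else {
    stopifnot(length(clip_percentiles) == 2L)
    qs <- stats::quantile(v, clip_percentiles, names = FALSE)
    lo <- qs[1L]; hi <- qs[2L]
    v <- pmin(pmax(v, lo), hi)
  }
  out <- if (hi == lo) array(0, dim(v)) else (v - lo) / (hi - lo)
  out <- matrix(out, nrow(v), ncol(v))
  attr(out, "scale_min") <- lo
  attr(out, "scale_max") <- hi
  out
}

# HSV -> RGB at s = v = 1, h in degrees; returns a list of r, g, b in [0, 1].
# Explicit formula (not a library colormap) so output is bit-reproducible.
hsv_sextant <- function(h) {
  hp <- (h / 60) %% 6
  x <- 1 - abs(hp %% 2 - 1)
  sx <- floor(hp)
  r <- ifelse(sx == 0 | sx == 5, 1, ifelse(sx == 1 | sx == 4, x, 0))
  g <- ifelse(sx == 1 | sx == 2, 1, ifelse(sx == 0 | sx == 3, x, 0))
  b <- ifelse(sx == 3 | sx == 4, 1, ifelse(sx == 2 | sx == 5, x, 0))
  list(r = r, g = g, b = b)
}

#' Render a 0-1 map in a rainbow scale
#'
#' Hue runs from blue (240 degrees at value 0) to red (0 degrees at value 1),
#' with full saturation and brightness; channels are quantized to 8 bits with
#' round-half-up. The hue angle is strictly decreasing in the value, so the
#' color order is monotone.
#'
#' @param map01 numeric matrix with values in `[0, 1]` (see [rescale01()]).
#' @return An object of class `rendered_map`: list with `rgb` (rows x cols x 3
#'   array of integers in 0-255), `map01`, and the `scale_min`/`scale_max`
#'   carried over from [rescale01()] when present.
#' @export
rainbow_render <- function(map01) {
  if (!is.matrix(map01)) stop("'map01' must be a numeric matrix")
  if (!all(is.finite(map01)) || any(map01 < 0) || any(map01 > 1))
    stop("'map01' values must lie in [0, 1]")
  ch <- hsv_sextant(240 * (1 - map01))
  quant <- function(x) matrix(as.integer(floor(255 * x + 0.5)),
                              nrow(map01), ncol(map01))
  rgb <- array(0L, c(nrow(map01), ncol(map01), 3L))
  rgb[, , 1L] <- quant(ch$r); rgb[, , 2L] <- quant(ch$g); rgb[, , 3L] <- quant(ch$b)
  structure(list(rgb = rgb, map01 = map01,
                 scale_min = attr(map01, "scale_min"),
                 scale_max = attr(map01, "scale_max")),
            class = "rendered_map")
}

#' Overlay a rendered map on a grayscale photograph
#'
#' Pixels whose `map01` value reaches `threshold` are alpha-blended
#' `alpha * rainbow + (1 - alpha) * gray`; the rest show the photograph
#' unchanged (replicated into RGB).
#'
#' @param gray numeric matrix in `[0, 1]`, same shape as the map.
#' @param rendered a `rendered_map` from [rainbow_render()].
#' @param threshold map01 cutoff in `[0, 1]` below which pixels stay gray.
#' @param alpha blend weight of the rainbow layer in `[0, 1]`.
#' @return rows x cols x 3 numeric array in `[0, 1]`.
#' @export
overlay_map <- function(gray, rendered, threshold = 0.5, alpha = 0.6) {
  stopifnot(inherits(rendered, "rendered_map"),
            threshold >= 0, threshold <= 1, alpha >= 0, alpha <= 1)
  if (!identical(dim(gray), dim(rendered$map01)))
    stop("shape mismatch between grayscale image and rendered map")
  sel <- rendered$map01 >= threshold
  out <- array(rep(gray, 3L), c(dim(gray), 3L))
  for (k in 1:3) {
    plane <- out[, , k]
    plane[sel] <- alpha * rendered$rgb[, , k][sel] / 255 +
      (1 - alpha) * gray[sel]
    out[, , k] <- plane
  }
  out
}

#' Otsu threshold mask of a 0-1 map
#'
#' Thresholds the map with Otsu's method (256 histogram levels over `[0, 1]`)
#' and returns the binary mask of pixels above the threshold. Used for the
#' tumor-detection check against phantom ground truth.
#'
#' @param map01 numeric matrix in `[0, 1]`.
#' @return List with `mask` (logical matrix) and `threshold`.
#' @export
otsu_mask <- function(map01) {
  thr <- EBImage::otsu(EBImage::Image(map01), range = c(0, 1), levels = 256)
  list(mask = map01 > thr, threshold = as.numeric(thr))
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b logical matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Write images and parameter values to disk
#'
#' `write_map_png()` writes a `rendered_map` (or any rows x cols x 3 array in
#' `[0, 1]`) as 8-bit RGB PNG; `write_param_csv()` dumps the raw parameter
#' map with 0-based row/col indices.
#'
#' @param rendered a `rendered_map` or a numeric array in `[0, 1]`.
#' @param path output path.
#' @export
write_map_png <- function(rendered, path) {
  img <- if (inherits(rendered, "rendered_map")) rendered$rgb / 255 else rendered
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_map_png
#' @param map a `param_map` or numeric matrix.
#' @export
write_param_csv <- function(map, path) {
  v <- if (inherits(map, "param_map")) map$values else map
  df <- data.frame(row = rep(seq_len(nrow(v)) - 1L, times = ncol(v)),
                   col = rep(seq_len(ncol(v)) - 1L, each = nrow(v)),
                   value = as.vector(v))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
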