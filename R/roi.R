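#' Regions of interest
#'
#' An ROI is a named 2D region in pixel coordinates with a role among
#' `"probe"`, `"background"` and `"control"`. Three shapes are supported:
#' axis-aligned rectangles, circles and simple polygons. Conventions (the
#' acquisition GUI this replaces left them implicit, so they are fixed here):
#' coordinates are 0-based, row-major `(row, col)`; rectangles are half-open
#' `[row0, row1) x [col0, col1)`; a pixel belongs to a polygon iff its center
#' `(row + 0.5, col + 0.5)` is inside under the even-odd rule; a pixel belongs
#' to a circle iff its index `(row, col)` is within `radius` of the center.
#'
#' @param name ROI label.
#' @param role one of `"probe"`, `"background"`, `"control"`.
#' @name roi
NULL

roi_new <- function(name, role, shape) {
  role <- match.arg(role, c("probe", "background", "control"))
  structure(list(name = as.character(name)[1L], role = role, shape = shape),
            class = "roi")
}

#' @rdname roi
#' @param row0,col0,row1,col1 rectangle bounds, half-open, `row0 < row1` and
#'   `col0 < col1`.
#' @return An object of class `roi`.
#' @export
roi_rect <- function(name, row0, col0, row1, col1, role = "probe") {
  if (!(row0 < row1 && col0 < col1))
    stop("rect requires row0 < row1 and col0 < col1")
  roi_new(name, role, list(type = "rect",
                           rect = c(row0, col0, row1, col1)))
}

#' @rdname roi
#' @param row,col circle center in pixel-index coordinates.
#' @param radius circle radius in pixels, `> 0`.
#' @export
roi_circle <- function(name, row, col, radius, role = "probe") {
  if (!(radius > 0)) stop("circle radius must be > 0")
  roi_new(name, role, list(type = "circle", circle = c(row, col, radius)))
}

#' @rdname roi
#' @param vertices numeric matrix with columns `(row, col)` and at least three
#'   rows; the polygon is closed implicitly.
#' @export
roi_polygon <- function(name, vertices, role = "probe") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("polygon requires a matrix of >= 3 (row, col) vertices")
  roi_new(name, role, list(type = "polygon", polygon = vertices))
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi '%s'> role=%s shape=%s\n", x$name, x$role, x$shape$type))
  invisible(x)
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# py/px are point rows/cols; V is the vertex matrix (row, col).
pip_even_odd <- function(py, px, V) {
  n <- nrow(V)
  inside <- logical(length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- V[i, 1L]; xi <- V[i, 2L]
    yj <- V[j, 1L]; xj <- V[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize an ROI onto a pixel grid
#'
#' @param roi an [roi] object.
#' @param shape integer vector `(rows, cols)` of the target image.
#' @return Integer matrix with columns `row`, `col` of 0-based pixel
#'   coordinates, in row-major order, clipped to the image bounds. An ROI
#'   whose pixel set is empty after clipping is an error (`"ROI outside
#'   image"`).
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "roi"), length(shape) == 2L, all(shape >= 1))
  rows <- as.integer(shape[1L]); cols <- as.integer(shape[2L])
  grid_r <- rep(seq_len(rows) - 1L, each = cols)
  grid_c <- rep(seq_len(cols) - 1L, times = rows)
  keep <- switch(roi$shape$type,
    rect = {
      b <- roi$shape$rect
      (grid_r + 0.5 >= b[1L]) & (grid_r + 0.5 < b[3L]) &
        (grid_c + 0.5 >= b[2L]) & (grid_c + 0.5 < b[4L])
    },
    circle = {
      cc <- roi$shape$circle
      (grid_r - cc[1L])^2 + (grid_c - cc[2L])^2 <= cc[3L]^2
    },
    polygon = pip_even_odd(grid_r + 0.5, grid_c + 0.5, roi$shape$polygon),
    stop("unknown ROI shape type: ", roi$shape$type)
  )
  if (!any(keep)) stop("ROI outside image")
  cbind(row = grid_r[keep], col = grid_c[keep])
}

#' Mean spectrum over an ROI
#'
#' Per-channel arithmetic mean of cube intensities over the rasterized ROI
#' pixel set. Integer cubes are promoted to double; no rescaling is applied.
#'
#' @param cube a [spectral_cube()].
#' @param roi an [roi] object.
#' @return An [as_spectrum()] object.
#' @export
extract_roi_spectrum <- function(cube, roi) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$intensities)
  px <- rasterize_roi(roi, d[1:2])
  r <- px[, 1L] + 1L
  c_ <- px[, 2L] + 1L
  vals <- vapply(seq_len(d[3L]), function(k) {
    mean(cube$intensities[cbind(r, c_, k)])
  }, numeric(1L))
  as_spectrum(vals, cube$wavelengths_nm)
}

roi_to_json_list <- function(roi) {
  shape <- switch(roi$shape$type,
    rect = list(rect = as.numeric(roi$shape$rect)),
    circle = list(circle = as.numeric(roi$shape$circle)),
    polygon = list(polygon = apply(roi$shape$polygon, 1L, as.numeric,
                                   simplify = FALSE)))
  list(name = roi$name, role = roi$role, shape = shape)
}

roi_from_json_list <- function(x) {
  sh <- x$shape
  if (!is.null(sh$rect)) {
    b <- as.numeric(unlist(sh$rect))
    roi_rect(x$name, b[1L], b[2L], b[3L], b[4L], role = x$role)
  } else if (!is.null(sh$circle)) {
    b <- as.numeric(unlist(sh$circle))
    roi_circle(x$name, b[1L], b[2L], b[3L], role = x$role)
  } else if (!is.null(sh$polygon)) {
    V <- do.call(rbind, lapply(sh$polygon, as.numeric))
    roi_polygon(x$name, V, role = x$role)
  } else stop("ROI entry '", x$name, "' has no recognized shape")
}

#' Read and write ROI sets as JSON
#'
#' The on-disk schema is `{"rois": [{"name": ..., "role": ...,
#' "shape": {"rect": [r0, c0, r1, c1]}}, ...]}` with shapes `rect`, `circle`
#' `[row, col, radius]` or `polygon` `[[row, col], ...]`.
#'
#' @param rois a named or unnamed list of [roi] objects.
#' @param path JSON file path.
#' @return `read_rois()` returns a list of [roi] objects named by ROI name.
#' @export
write_rois <- function(rois, path) {
  stopifnot(all(vapply(rois, inherits, logical(1L), "roi")))
  jsonlite::write_json(list(rois = lapply(unname(rois), roi_to_json_list)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rois <- lapply(doc$rois, roi_from_json_list)
  names(rois) <- vapply(rois, `[[`, character(1L), "name")
  rois
}

roi_by_name <- function(rois, name) {
  hit <- which(vapply(rois, `[[`, character(1L), "name") == name)
  if (length(hit) != 1L)
    stop(sprintf("unknown ROI name '%s'; available: %s", name,
                 paste(vapply(rois, `[[`, character(1L), "name"),
                       collapse = ", ")))
  rois[[hit]]
}
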