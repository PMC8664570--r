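#' Per-cell region-of-interest polygons
#'
#' Regions of analysis are hand-drawn polygons, one per cell (or tissue
#' region). Coordinates are continuous, 0-based `(y, x)` pixel-centre
#' coordinates: pixel `(i, j)` (0-based row, column) has its centre at
#' `(y = i, x = j)` and covers `[i - 0.5, i + 0.5] x [j - 0.5, j + 0.5]`.
#'
#' @param label cell identifier (string).
#' @param polygon numeric matrix with columns `y`, `x` (>= 3 vertices, simple).
#' @return an object of class `roi_mask`.
#' @examples
#' roi <- roi_mask("cell1", cbind(y = c(-0.5, -0.5, 9.5, 9.5),
#'                                x = c(-0.5, 9.5, 9.5, -0.5)))
#' m <- rasterize_roi(roi, shape = c(20, 20), pixel_size = 0.1)
#' sum(m)                 # 100 pixels
#' attr(m, "area_um2")    # 1.0 um^2
#' @export
roi_mask <- function(label, polygon) {
  polygon <- as.matrix(polygon)
  assert_that(ncol(polygon) == 2L && nrow(polygon) >= 3L,
              "polygon needs >= 3 (y, x) vertices")
  assert_that(all(is.finite(polygon)), "polygon vertices must be finite")
  colnames(polygon) <- c("y", "x")
  structure(list(label = as.character(label), polygon = polygon),
            class = "roi_mask")
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
# Points on an edge follow the half-open convention of the crossing test.
point_in_polygon <- function(py, px, poly) {
  n <- nrow(poly)
  inside <- logical(length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1L]; xi <- poly[i, 2L]
    yj <- poly[j, 1L]; xj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace area of a polygon in continuous pixel units.
polygon_area_px <- function(poly) {
  y <- poly[, 1L]; x <- poly[, 2L]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its centre lies inside the polygon under
#' the even-odd rule. The physical area (`area_um2` attribute) is the included
#' pixel count times `pixel_size^2`.
#'
#' @param roi an [roi_mask()].
#' @param shape image shape `c(h, w)` in pixels.
#' @param pixel_size pixel edge length in micrometres.
#' @return logical `h x w` matrix with attributes `area_um2` and `label`.
#' @export
rasterize_roi <- function(roi, shape, pixel_size = 1) {
  assert_that(inherits(roi, "roi_mask"), "roi must be an roi_mask")
  assert_that(is_scalar_num(pixel_size) && pixel_size > 0,
              "pixel_size must be > 0")
  h <- shape[1L]; w <- shape[2L]
  poly <- roi$polygon
  assert_that(all(poly[, 1L] >= -0.5 - 1e-9 & poly[, 1L] <= h - 0.5 + 1e-9 &
                  poly[, 2L] >= -0.5 - 1e-9 & poly[, 2L] <= w - 0.5 + 1e-9),
              sprintf("ROI '%s' extends outside image bounds", roi$label))
  r0 <- max(1L, floor(min(poly[, 1L])) + 1L)
  r1 <- min(h, ceiling(max(poly[, 1L])) + 1L)
  c0 <- max(1L, floor(min(poly[, 2L])) + 1L)
  c1 <- min(w, ceiling(max(poly[, 2L])) + 1L)
  mask <- matrix(FALSE, h, w)
  if (r1 >= r0 && c1 >= c0) {
    rows <- r0:r1; cols <- c0:c1
    g <- expand.grid(y = rows - 1, x = cols - 1)   # pixel centres, 0-based
    inside <- point_in_polygon(g$y, g$x, poly)
    mask[r0:r1, c0:c1] <- matrix(inside, nrow = length(rows))
  }
  n_in <- sum(mask)
  assert_that(n_in > 0L, sprintf("ROI '%s' covers zero pixels", roi$label))
  structure(mask, area_um2 = n_in * pixel_size^2, label = roi$label,
            pixel_size = pixel_size)
}

#' Read and write ROI polygon files
#'
#' ROIs are interchanged as a JSON array of `{label, vertices}` objects where
#' `vertices` is a list of `[y, x]` pairs in 0-based pixel-centre coordinates.
#'
#' @param path file path.
#' @param rois list of [roi_mask()] objects.
#' @return `read_rois()` returns a list of `roi_mask` objects.
#' @export
write_rois <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    verts <- lapply(seq_len(nrow(r$polygon)),
                    function(i) unname(r$polygon[i, ]))
    list(label = r$label, vertices = verts)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(p) {
    v <- do.call(rbind, lapply(p$vertices, function(q) {
      c(as.numeric(q[[1L]]), as.numeric(q[[2L]]))
    }))
    roi_mask(p$label, v)
  })
}
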