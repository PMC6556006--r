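#' Polygonal region of interest
#'
#' Regions of interest are simple (non-self-intersecting) polygons in pixel
#' coordinates, mimicking freeform pen annotations on a slide viewer.
#' Coordinates are 0-based; pixel `(row i, col j)` of an image has its
#' center at `x = j - 1`, `y = i - 1`. A pixel belongs to the ROI iff its
#' center lies inside the polygon under the even-odd rule.
#'
#' @param vertices Two-column numeric matrix (or data frame) of `(x, y)`
#'   vertices in order; the polygon is closed implicitly.
#' @return An object of class `npq_roi`.
#' @examples
#' roi <- roi_polygon(cbind(x = c(0, 40, 40, 0), y = c(0, 0, 40, 40)))
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L || anyNA(v) || !is.numeric(v)) {
    abort("`vertices` must be a numeric matrix of >= 3 (x, y) rows.")
  }
  colnames(v) <- c("x", "y")
  if (abs(.shoelace(v)) <= 0) abort("ROI polygon has zero area.")
  if (.self_intersects(v)) abort("ROI polygon is self-intersecting.")
  structure(list(vertices = v), class = "npq_roi")
}

#' @export
print.npq_roi <- function(x, ...) {
  cat(sprintf("<npq_roi> %d vertices, area %.1f px^2\n",
              nrow(x$vertices), abs(.shoelace(x$vertices))))
  invisible(x)
}

#' Read ROI polygons from JSON
#'
#' The dialect is a JSON list of polygons, each an ordered array of
#' `[x, y]` vertex pairs in pixel coordinates.
#'
#' @param path Path to a JSON file.
#' @return A named list of [roi_polygon()] objects (`roi_1`, `roi_2`, ...).
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(raw, function(p) {
    roi_polygon(do.call(rbind, lapply(p, function(v) as.numeric(unlist(v)))))
  })
  names(out) <- paste0("roi_", seq_along(out))
  out
}

#' Write ROI polygons to JSON
#'
#' @param rois A list of [roi_polygon()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(rois, path) {
  if (inherits(rois, "npq_roi")) rois <- list(rois)
  jsonlite::write_json(lapply(rois, function(r) unname(r$vertices)), path)
  invisible(path)
}

#' Rasterize an ROI to a pixel mask
#'
#' @param roi An [roi_polygon()].
#' @param dim Image dimension `c(H, W)` (rows, columns).
#' @return Logical `H x W` matrix; `TRUE` where the pixel center falls
#'   inside the polygon (even-odd rule).
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "npq_roi"), length(dim) >= 2L)
  h <- dim[1]; w <- dim[2]
  v <- roi$vertices
  if (min(v[, 1]) < -0.5 || max(v[, 1]) > w - 0.5 ||
      min(v[, 2]) < -0.5 || max(v[, 2]) > h - 0.5) {
    abort("ROI polygon extends outside the image bounds.")
  }
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  inside <- .points_in_polygon(xs, ys, v)
  matrix(inside, nrow = h, ncol = w)
}

#' ROI area in square millimetres
#'
#' Pixel-count area: the number of member pixels times the pixel area. Using
#' the same rasterization for the area and for the per-pixel metrics keeps
#' densities exactly additive across a tiling of the ROI.
#'
#' @inheritParams roi_mask
#' @param pixel_size_um Pixel size in micrometres.
#' @return Area in mm^2.
#' @export
roi_area_mm2 <- function(roi, dim, pixel_size_um) {
  sum(roi_mask(roi, dim)) * pixel_size_um^2 / 1e6
}

# Even-odd rule, vectorized over query points.
.points_in_polygon <- function(xs, ys, v) {
  n <- nrow(v)
  inside <- logical(length(xs))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  i2 <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

# O(n^2) proper-crossing check between non-adjacent edges.
.self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      a <- seg[i, ]; b <- seg[j, ]
      o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Rectangle helper used widely in examples/tests: whole-pixel rectangle
# [x0, x1) x [y0, y1) in 0-based pixel indices.
#' Axis-aligned rectangular ROI
#'
#' Convenience constructor covering pixel columns `x0..x1 - 1` and rows
#' `y0..y1 - 1` (0-based), i.e. `x1 - x0` by `y1 - y0` pixels.
#'
#' @param x0,y0,x1,y1 Corner pixel indices (0-based, exclusive upper).
#' @return An [roi_polygon()].
#' @export
roi_rect <- function(x0, y0, x1, y1) {
  roi_polygon(cbind(x = c(x0, x1, x1, x0) - 0.5,
                    y = c(y0, y0, y1, y1) - 0.5))
}
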