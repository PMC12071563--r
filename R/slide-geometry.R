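#' Slide coordinate frame
#'
#' A `slide_frame` anchors all geometry in the package. The canonical unit is
#' the micron in the level-0 pixel frame of the scan: origin at the top-left
#' corner, x growing rightward, y growing downward (image convention). Pixel
#' inputs are converted to microns on ingest via `mpp` (microns per pixel at
#' level 0); typical scanners produce mpp around 0.25.
#'
#' @param mpp Microns per pixel at level 0. Positive real.
#' @param width_px,height_px Slide extent in level-0 pixels. Positive integers.
#' @param slide_id Opaque slide identifier.
#' @return An object of class `slide_frame`.
#' @examples
#' slide_frame(mpp = 0.24, width_px = 80000, height_px = 60000, slide_id = "S1")
#' @export
slide_frame <- function(mpp, width_px, height_px, slide_id = "slide") {
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("'mpp' must be a single positive number")
  if (!is.numeric(width_px) || length(width_px) != 1L || width_px < 1 ||
      !is.numeric(height_px) || length(height_px) != 1L || height_px < 1)
    stop("'width_px' and 'height_px' must be positive")
  structure(
    list(mpp = as.numeric(mpp),
         width_px = as.numeric(width_px),
         height_px = as.numeric(height_px),
         slide_id = as.character(slide_id)),
    class = "slide_frame"
  )
}

#' @export
print.slide_frame <- function(x, ...) {
  cat(sprintf("<slide_frame> %s: %g x %g px @ %g um/px (%.1f x %.1f mm)\n",
              x$slide_id, x$width_px, x$height_px, x$mpp,
              x$width_px * x$mpp / 1000, x$height_px * x$mpp / 1000))
  invisible(x)
}

#' Points in the micron frame
#'
#' Validates and normalizes a set of planar points to a two-column data frame
#' with numeric columns `x` and `y` (microns, level-0 frame). Most functions in
#' the package accept any data frame with such columns; this helper is the
#' canonical constructor.
#'
#' @param x Numeric vector of x coordinates (um), or a data frame / matrix with
#'   columns `x` and `y`.
#' @param y Numeric vector of y coordinates, when `x` is a vector.
#' @return A data frame with columns `x`, `y`.
#' @export
points_um <- function(x, y = NULL) {
  if (is.null(y)) {
    if (is.matrix(x)) x <- as.data.frame(x)
    if (!is.data.frame(x) || !all(c("x", "y") %in% names(x)))
      stop("points must have 'x' and 'y' columns")
    pts <- data.frame(x = as.numeric(x$x), y = as.numeric(x$y))
  } else {
    pts <- data.frame(x = as.numeric(x), y = as.numeric(y))
  }
  if (nrow(pts) && !all(is.finite(pts$x) & is.finite(pts$y)))
    stop("point coordinates must be finite")
  pts
}

#' Radius of a circle of given area
#'
#' Counting zones are specified by area (1 mm^2 core, 2 mm^2 context in the
#' defaults) but all distance work happens in microns, so the radius
#' r = sqrt(A / pi) is needed throughout. Vectorized.
#'
#' @param area_mm2 Circle area(s) in mm^2; must be positive.
#' @return Radius in microns: `sqrt(area_mm2 / pi) * 1000`.
#' @examples
#' area_to_radius(1)  # 564.19 um
#' area_to_radius(2)  # 797.88 um
#' @export
area_to_radius <- function(area_mm2) {
  if (!is.numeric(area_mm2) || any(!is.finite(area_mm2)) || any(area_mm2 <= 0))
    stop("'area_mm2' must be positive and finite")
  sqrt(area_mm2 / pi) * 1000
}

#' Euclidean distance between points
#'
#' @param a,b Points as length-2 numeric vectors `c(x, y)`, or data frames with
#'   `x`/`y` columns (recycled row-wise against each other). Microns in, microns
#'   out.
#' @return Numeric vector of Euclidean distances.
#' @export
point_distance <- function(a, b) {
  pa <- if (is.data.frame(a)) a else data.frame(x = a[[1]], y = a[[2]])
  pb <- if (is.data.frame(b)) b else data.frame(x = b[[1]], y = b[[2]])
  sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
}

#' Circular counting zone
#'
#' A circle in the micron frame, used both for hotspot display zones and for
#' reader-selected counting zones. The area field is derived from the radius
#' (`pi * r^2 / 1e6` mm^2) and kept consistent by construction.
#'
#' @param x,y Center coordinates in microns.
#' @param radius_um Radius in microns (positive), or give `area_mm2` instead.
#' @param area_mm2 Alternative to `radius_um`: circle area in mm^2.
#' @return An object of class `circle_zone` with fields `center` (named vector
#'   x, y), `radius_um` and `area_mm2`.
#' @examples
#' circle_zone(1000, 2000, area_mm2 = 2)
#' @export
circle_zone <- function(x, y, radius_um = NULL, area_mm2 = NULL) {
  if (is.null(radius_um)) {
    if (is.null(area_mm2)) stop("give 'radius_um' or 'area_mm2'")
    radius_um <- area_to_radius(area_mm2)
  }
  if (!is.finite(x) || !is.finite(y)) stop("zone center must be finite")
  if (!is.finite(radius_um) || radius_um <= 0) stop("'radius_um' must be positive")
  structure(
    list(center = c(x = as.numeric(x), y = as.numeric(y)),
         radius_um = as.numeric(radius_um),
         area_mm2 = pi * as.numeric(radius_um)^2 / 1e6),
    class = "circle_zone"
  )
}

#' @export
print.circle_zone <- function(x, ...) {
  cat(sprintf("<circle_zone> center (%.1f, %.1f) um, r = %.1f um, area = %.3f mm^2\n",
              x$center[["x"]], x$center[["y"]], x$radius_um, x$area_mm2))
  invisible(x)
}

#' Do two circular zones intersect?
#'
#' Inclusive convention: tangency counts as intersecting, i.e. the zones
#' intersect iff the center distance is at most the sum of the radii. This
#' mirrors the inclusive `dist <= r` convention used by the radius counting and
#' is the convention behind the counting-zone spatial-agreement metric.
#'
#' @param a,b `circle_zone` objects.
#' @return Logical scalar.
#' @export
circles_intersect <- function(a, b) {
  stopifnot(inherits(a, "circle_zone"), inherits(b, "circle_zone"))
  d <- point_distance(a$center, b$center)
  d <= a$radius_um + b$radius_um
}

## ---- tumor region polygons ------------------------------------------------

#' Tumor region polygons
#'
#' A set of simple polygons (with optional holes) in the micron frame,
#' delineating invasive-carcinoma tissue. Each polygon is a list of rings;
#' the first ring is the outer boundary, any further rings are holes. Rings are
#' two-column matrices of vertices (um), implicitly closed (first vertex is not
#' repeated internally; a repeated closing vertex on input is dropped).
#'
#' @param ... Polygons, one argument each. Each polygon is either a ring
#'   (two-column matrix or data frame of x/y vertices) or a list of rings
#'   (outer first, then holes). To build from a list of polygons use
#'   `do.call(slide_regions, polys)`.
#' @return An object of class `slide_regions`: a list of polygons, each a list
#'   of rings stored as matrices with columns x, y.
#' @seealso [rect_region()], [read_regions()]
#' @export
slide_regions <- function(...) {
  polys <- list(...)
  out <- lapply(polys, function(p) {
    rings <- if (is_ring_like(p)) list(p) else p
    lapply(rings, normalize_ring)
  })
  structure(out, class = "slide_regions")
}

is_ring_like <- function(p) is.matrix(p) || is.data.frame(p)

normalize_ring <- function(r) {
  m <- if (is.data.frame(r)) {
    if (all(c("x", "y") %in% names(r))) cbind(r$x, r$y) else as.matrix(r)
  } else as.matrix(r)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("a polygon ring needs two coordinate columns")
  if (nrow(m) >= 2L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("a polygon ring needs at least 3 distinct vertices")
  colnames(m) <- c("x", "y")
  m
}

#' Rectangular tumor region
#'
#' Convenience constructor for an axis-aligned rectangular region, mostly used
#' by the synthetic-slide generator and in examples.
#'
#' @param xmin,ymin,xmax,ymax Rectangle corners in microns.
#' @return A `slide_regions` object with one 4-vertex polygon.
#' @export
rect_region <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  slide_regions(cbind(x = c(xmin, xmax, xmax, xmin),
                      y = c(ymin, ymin, ymax, ymax)))
}

# Signed shoelace area of one ring, in um^2.
ring_area_um2 <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' Total region area
#'
#' Shoelace area of the outer rings minus hole rings, summed over polygons.
#'
#' @param regions A `slide_regions` object.
#' @return Area in mm^2.
#' @export
region_area_mm2 <- function(regions) {
  stopifnot(inherits(regions, "slide_regions"))
  a <- sum(vapply(regions, function(p) {
    abs(ring_area_um2(p[[1L]])) -
      sum(vapply(p[-1L], function(h) abs(ring_area_um2(h)), 0))
  }, 0))
  a / 1e6
}

# NA-separated boundary matrix for mgcv::in.out (all rings of all polygons;
# crossing parity makes holes and disjoint polygons come out right).
region_bnd <- function(regions) {
  rings <- unlist(regions, recursive = FALSE)
  parts <- lapply(rings, function(m) rbind(m, m[1L, ], c(NA, NA)))
  m <- do.call(rbind, parts)
  m[-nrow(m), , drop = FALSE]
}

#' Which points fall inside the tumor regions?
#'
#' Even-odd (crossing-parity) point-in-polygon test over all rings, so holes
#' exclude and disjoint polygons union. Delegates to [mgcv::in.out()].
#'
#' @param pts Points (data frame with `x`, `y` in um).
#' @param regions A `slide_regions` object.
#' @return Logical vector, one entry per point.
#' @export
points_in_regions <- function(pts, regions) {
  stopifnot(inherits(regions, "slide_regions"))
  pts <- points_um(pts)
  if (nrow(pts) == 0L || length(regions) == 0L)
    return(logical(nrow(pts)))
  mgcv::in.out(region_bnd(regions), cbind(pts$x, pts$y))
}

#' Bounding box of the regions
#'
#' @param regions A `slide_regions` object.
#' @return Named numeric vector `xmin, ymin, xmax, ymax` (um), or `NULL` for an
#'   empty region set.
#' @export
region_bbox <- function(regions) {
  stopifnot(inherits(regions, "slide_regions"))
  if (length(regions) == 0L) return(NULL)
  outer <- do.call(rbind, lapply(regions, `[[`, 1L))
  c(xmin = min(outer[, 1L]), ymin = min(outer[, 2L]),
    xmax = max(outer[, 1L]), ymax = max(outer[, 2L]))
}

## ---- patch grid -----------------------------------------------------------

#' Hotspot candidate grid from non-overlapping patch tiling
#'
#' Tiles the bounding box of the tumor regions with non-overlapping square
#' patches of `patch_px` pixels at the tiling magnification (`level_mpp`
#' microns per pixel, so the stride is `patch_px * level_mpp` um) and keeps the
#' centers of tiles whose center point falls inside a region polygon. The grid
#' is phase-aligned to the region bounding-box top-left corner; membership is
#' decided by the center point (patch-classification semantics, where a patch
#' is labeled by its dominant content). These centers are the candidate set
#' over which hotspot scores are computed.
#'
#' @param regions A `slide_regions` object (micron frame).
#' @param patch_px Patch edge in pixels at the tiling level. Default 256.
#' @param level_mpp Microns per pixel at the tiling magnification. Default 0.5
#'   (the usual 20x level), giving a 128 um stride with the default patch size.
#' @param frame Optional `slide_frame`; recorded in the result for provenance.
#' @return An object of class `patch_grid`: list with `centers` (data frame
#'   x, y in um), `patch_px`, `level_mpp`, `stride_um`. An empty region list
#'   yields an empty grid.
#' @examples
#' r <- rect_region(0, 0, 2000, 2000)
#' build_patch_grid(r, patch_px = 256, level_mpp = 1000 / 256)  # 1 mm patches
#' @export
build_patch_grid <- function(regions, patch_px = 256L, level_mpp = 0.5,
                             frame = NULL) {
  stopifnot(inherits(regions, "slide_regions"))
  if (!is.numeric(patch_px) || patch_px < 1) stop("'patch_px' must be >= 1")
  if (!is.numeric(level_mpp) || level_mpp <= 0) stop("'level_mpp' must be positive")
  stride <- patch_px * level_mpp
  bb <- region_bbox(regions)
  centers <- data.frame(x = numeric(0), y = numeric(0))
  if (!is.null(bb) && bb[["xmax"]] > bb[["xmin"]] && bb[["ymax"]] > bb[["ymin"]]) {
    nx <- ceiling((bb[["xmax"]] - bb[["xmin"]]) / stride)
    ny <- ceiling((bb[["ymax"]] - bb[["ymin"]]) / stride)
    cx <- bb[["xmin"]] + (seq_len(nx) - 0.5) * stride
    cy <- bb[["ymin"]] + (seq_len(ny) - 0.5) * stride
    centers <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
    centers <- centers[points_in_regions(centers, regions), , drop = FALSE]
    centers <- centers[order(centers$y, centers$x), , drop = FALSE]
    rownames(centers) <- NULL
  }
  structure(
    list(centers = centers, patch_px = as.integer(patch_px),
         level_mpp = as.numeric(level_mpp), stride_um = stride,
         slide_id = if (!is.null(frame)) frame$slide_id else NA_character_),
    class = "patch_grid"
  )
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d centers, %d px @ %g um/px (stride %.1f um)\n",
              nrow(x$centers), x$patch_px, x$level_mpp, x$stride_um))
  invisible(x)
}
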