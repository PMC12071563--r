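#' @importFrom jsonlite read_json write_json
NULL

is_geojson_path <- function(path) grepl("\\.(geo)?json$", tolower(path))

#' Read mitosis detections
#'
#' Reads a per-slide detection list from CSV (dialect: header
#' `slide_id,x,y,unit,confidence` with `unit` either `px` or `um`) or from a
#' GeoJSON FeatureCollection of Points carrying a `confidence` property, and
#' normalizes all coordinates to microns in the level-0 frame. Pixel
#' coordinates are converted via `mpp`, taken from the argument or from the
#' file's metadata (`mpp` member in GeoJSON). Malformed rows are rejected with
#' an error naming the offending row.
#'
#' @param path CSV or GeoJSON file path.
#' @param mpp Microns per pixel at level 0; required when any row is in pixel
#'   units and the file carries no mpp metadata.
#' @return List with `detections` (a [mitosis_detections()] data frame, um
#'   coordinates) and `frame` (a [slide_frame()]; extent from file metadata
#'   when present, otherwise the detection bounding box).
#' @export
read_detections <- function(path, mpp = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is_geojson_path(path)) read_detections_geojson(path, mpp)
  else read_detections_csv(path, mpp)
}

read_detections_csv <- function(path, mpp) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("slide_id", "x", "y", "unit", "confidence")
  if (!all(need %in% names(df)))
    stop(sprintf("detections CSV needs header %s", paste(need, collapse = ",")))
  n <- nrow(df)
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  conf <- suppressWarnings(as.numeric(df$confidence))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop(sprintf("non-numeric coordinates in row(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path))
  bad <- which(!is.finite(conf) | conf < 0 | conf > 1)
  if (length(bad))
    stop(sprintf("confidence outside [0, 1] in row(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path))
  bad <- which(!df$unit %in% c("px", "um"))
  if (length(bad))
    stop(sprintf("unknown unit tag in row(s) %s of %s (expected 'px' or 'um')",
                 paste(bad + 1L, collapse = ", "), path))
  is_px <- df$unit == "px"
  if (any(is_px)) {
    if (is.null(mpp))
      stop(sprintf("rows in pixel units (first at row %d) but no 'mpp' given",
                   which(is_px)[1L] + 1L))
    x[is_px] <- x[is_px] * mpp
    y[is_px] <- y[is_px] * mpp
  }
  slide_id <- if (n) df$slide_id[1L] else "slide"
  dets <- mitosis_detections(data.frame(
    x = x, y = y, confidence = conf,
    id = if (!is.null(df$id)) df$id else
      (if (n) sprintf("det_%d", seq_len(n)) else character(0))))
  attr(dets, "slide_id") <- slide_id
  frame <- detection_frame(dets, mpp, slide_id)
  list(detections = dets, frame = frame)
}

read_detections_geojson <- function(path, mpp) {
  g <- jsonlite::read_json(path)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("detections GeoJSON must be a FeatureCollection")
  if (is.null(mpp) && !is.null(g$mpp)) mpp <- as.numeric(g$mpp)
  unit <- if (!is.null(g$unit)) g$unit else "um"
  if (!unit %in% c("px", "um")) stop(sprintf("unknown unit tag '%s'", unit))
  slide_id <- if (!is.null(g$slide_id)) g$slide_id else "slide"
  feats <- g$features
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (is.null(f$geometry) || f$geometry$type != "Point")
      stop(sprintf("feature %d is not a Point", i))
    cc <- unlist(f$geometry$coordinates)
    conf <- f$properties$confidence
    if (is.null(conf)) stop(sprintf("feature %d has no 'confidence' property", i))
    conf <- as.numeric(conf)
    if (!is.finite(conf) || conf < 0 || conf > 1)
      stop(sprintf("feature %d: confidence outside [0, 1]", i))
    data.frame(x = as.numeric(cc[1L]), y = as.numeric(cc[2L]),
               confidence = conf,
               id = if (!is.null(f$properties$id)) as.character(f$properties$id)
                    else sprintf("det_%d", i))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), confidence = numeric(0),
               id = character(0))
  if (unit == "px") {
    if (is.null(mpp)) stop("pixel-unit GeoJSON but no 'mpp' available")
    df$x <- df$x * mpp
    df$y <- df$y * mpp
  }
  dets <- mitosis_detections(df)
  attr(dets, "slide_id") <- slide_id
  frame <- detection_frame(dets, mpp, slide_id, g$width_px, g$height_px)
  list(detections = dets, frame = frame)
}

detection_frame <- function(dets, mpp, slide_id, width_px = NULL, height_px = NULL) {
  if (is.null(mpp)) mpp <- 1
  if (is.null(width_px))
    width_px <- max(1, ceiling(if (nrow(dets)) max(dets$x) / mpp else 1))
  if (is.null(height_px))
    height_px <- max(1, ceiling(if (nrow(dets)) max(dets$y) / mpp else 1))
  slide_frame(mpp = mpp, width_px = as.numeric(width_px),
              height_px = as.numeric(height_px), slide_id = slide_id)
}

#' Write mitosis detections
#'
#' Writes the detections CSV dialect (`slide_id,x,y,unit,confidence,id`) or,
#' for a `.geojson` path, a GeoJSON FeatureCollection of Points with
#' `confidence` properties and `mpp`/`unit`/`slide_id` metadata members.
#' Coordinates are written in microns at full precision, so a write-read round
#' trip preserves them to well below 1e-9 um.
#'
#' @param dets Detection table (um coordinates).
#' @param path Output path (`.csv` or `.geojson`).
#' @param slide_id Slide identifier to record.
#' @param mpp Optional microns per pixel recorded in GeoJSON metadata.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path, slide_id = NULL, mpp = NULL) {
  dets <- mitosis_detections(dets)
  if (is.null(slide_id)) {
    slide_id <- attr(dets, "slide_id")
    if (is.null(slide_id) || is.na(slide_id)) slide_id <- "slide"
  }
  if (is_geojson_path(path)) {
    feats <- lapply(seq_len(nrow(dets)), function(i) list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(dets$x[i], dets$y[i])),
      properties = list(confidence = dets$confidence[i], id = dets$id[i])))
    obj <- list(type = "FeatureCollection", slide_id = slide_id, unit = "um",
                features = feats)
    if (!is.null(mpp)) obj$mpp <- mpp
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(slide_id = rep(slide_id, nrow(dets)),
                     x = sprintf("%.17g", dets$x),
                     y = sprintf("%.17g", dets$y),
                     unit = rep("um", nrow(dets)),
                     confidence = sprintf("%.17g", dets$confidence),
                     id = dets$id)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

## ---- region polygons ------------------------------------------------------

# TRUE if the implicitly closed ring has two non-adjacent edges that touch.
ring_self_intersects <- function(m) {
  n <- nrow(m)
  seg <- cbind(m, m[c(2:n, 1L), , drop = FALSE])  # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d2 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      d3 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d4 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
      on_seg <- function(px, py, qx, qy, rx, ry)
        min(px, rx) <= qx && qx <= max(px, rx) &&
        min(py, ry) <= qy && qy <= max(py, ry)
      if ((d1 == 0 && on_seg(b[1], b[2], a[1], a[2], b[3], b[4])) ||
          (d2 == 0 && on_seg(b[1], b[2], a[3], a[4], b[3], b[4])) ||
          (d3 == 0 && on_seg(a[1], a[2], b[1], b[2], a[3], a[4])) ||
          (d4 == 0 && on_seg(a[1], a[2], b[3], b[4], a[3], a[4])))
        return(TRUE)
    }
  }
  FALSE
}

#' Read tumor-region polygons
#'
#' Reads a GeoJSON FeatureCollection of Polygons (first ring outer, further
#' rings holes) and converts coordinates to microns. Coordinates are level-0
#' pixels by default (`unit` metadata member may say `"um"`); `mpp` comes from
#' the argument or the file's `mpp` member. Every ring is validated:
#' self-intersecting rings raise an error. Ring orientation is normalized
#' (outer counter-clockwise in the y-down frame, holes opposite).
#'
#' @param path GeoJSON file path.
#' @param mpp Microns per pixel, overriding file metadata.
#' @return A `slide_regions` object (micron frame) with attribute `mpp`.
#' @export
read_regions <- function(path, mpp = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  g <- jsonlite::read_json(path)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("regions GeoJSON must be a FeatureCollection")
  if (is.null(mpp) && !is.null(g$mpp)) mpp <- as.numeric(g$mpp)
  unit <- if (!is.null(g$unit)) g$unit else "px"
  if (!unit %in% c("px", "um")) stop(sprintf("unknown unit tag '%s'", unit))
  scale <- if (unit == "px") {
    if (is.null(mpp)) stop("pixel-unit regions but no 'mpp' available")
    mpp
  } else 1
  polys <- lapply(seq_along(g$features), function(i) {
    f <- g$features[[i]]
    if (is.null(f$geometry) || f$geometry$type != "Polygon")
      stop(sprintf("feature %d is not a Polygon", i))
    rings <- lapply(seq_along(f$geometry$coordinates), function(j) {
      ring <- f$geometry$coordinates[[j]]
      m <- do.call(rbind, lapply(ring, function(cc) as.numeric(unlist(cc))))
      m <- normalize_ring(m * scale)
      if (ring_self_intersects(m))
        stop(sprintf("feature %d ring %d is self-intersecting", i, j))
      # outer ring positively oriented (y-down frame), holes negatively
      pos <- ring_area_um2(m) > 0
      if ((j == 1L && !pos) || (j > 1L && pos)) m <- m[rev(seq_len(nrow(m))), ]
      m
    })
    rings
  })
  out <- do.call(slide_regions, polys)
  attr(out, "mpp") <- mpp
  out
}

#' Write tumor-region polygons
#'
#' Inverse of [read_regions()]: writes a GeoJSON FeatureCollection of Polygons
#' in micron units (with `unit = "um"` and optional `mpp` metadata), full
#' precision.
#'
#' @param regions A `slide_regions` object (um).
#' @param path Output path.
#' @param mpp Optional microns per pixel recorded as metadata.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, mpp = NULL) {
  stopifnot(inherits(regions, "slide_regions"))
  feats <- lapply(regions, function(p) list(
    type = "Feature",
    geometry = list(
      type = "Polygon",
      coordinates = lapply(p, function(m) {
        closed <- rbind(m, m[1L, ])
        lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1L], closed[i, 2L]))
      })),
    properties = list(label = "tumor")))
  obj <- list(type = "FeatureCollection", unit = "um", features = feats)
  if (!is.null(mpp)) obj$mpp <- mpp
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- hotspot and assessment outputs ---------------------------------------

#' Write a hotspot result as JSON
#'
#' Echoes the parameters in force (epsilon, zone areas, confidence threshold,
#' suppression rule) alongside every selected hotspot's center (um), display
#' radius, core/context counts, score and rank, so each run is auditable.
#'
#' @param result A `hotspot_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_hotspots_json <- function(result, path) {
  stopifnot(inherits(result, "hotspot_result"))
  r_disp <- area_to_radius(result$params$context_area_mm2)
  sel <- result$selected
  obj <- list(
    slide_id = if (is.null(result$slide_id)) NA else result$slide_id,
    params = unclass(result$params),
    suppression = "greedy non-intersection of context-area display circles",
    unit = "um",
    n_detections = result$n_detections,
    n_retained = result$n_retained,
    hotspots = lapply(seq_len(nrow(sel)), function(i) list(
      rank = sel$rank[i], center = c(sel$x[i], sel$y[i]),
      radius_um = r_disp, n_core = sel$n_core[i],
      n_context = sel$n_context[i], score = sel$score[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

circle_polygon <- function(x, y, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x + r * cos(th), y + r * sin(th))
}

#' Write hotspot display zones as GeoJSON circles
#'
#' Each selected hotspot's context-area display circle is approximated by a
#' 64-gon Polygon feature (micron units) for import into slide viewers.
#'
#' @param result A `hotspot_result`.
#' @param path Output GeoJSON path.
#' @return `path`, invisibly.
#' @export
write_hotspots_geojson <- function(result, path) {
  stopifnot(inherits(result, "hotspot_result"))
  r_disp <- area_to_radius(result$params$context_area_mm2)
  sel <- result$selected
  feats <- lapply(seq_len(nrow(sel)), function(i) {
    poly <- circle_polygon(sel$x[i], sel$y[i], r_disp)
    closed <- rbind(poly, poly[1L, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(closed)),
                                                   function(k) c(closed[k, 1L], closed[k, 2L])))),
         properties = list(rank = sel$rank[i], score = sel$score[i],
                           n_core = sel$n_core[i], n_context = sel$n_context[i],
                           radius_um = r_disp))
  })
  obj <- list(type = "FeatureCollection", unit = "um", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a mitotic assessment as JSON
#'
#' @param assessment A `mitotic_assessment`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_assessment_json <- function(assessment, path) {
  stopifnot(inherits(assessment, "mitotic_assessment"))
  z <- assessment$zone
  obj <- list(
    slide_id = assessment$slide_id,
    zone = if (is.null(z)) NULL else list(center = unname(z$center),
                                          radius_um = z$radius_um,
                                          area_mm2 = z$area_mm2),
    mitotic_count = assessment$mitotic_count,
    thresholds = unclass(assessment$thresholds),
    mitotic_score = assessment$mitotic_score
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- scores, confusion matrices, reports ----------------------------------

#' Read or write reader score records
#'
#' Scores CSV dialect: header
#' `slide_id,reader_id,condition,score,specimen_type,zone_x,zone_y,zone_radius_um`
#' (zone columns optional/empty when no zone was recorded).
#'
#' @param path CSV path.
#' @return [read_scores()]: a [score_records()] data frame.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  score_records(df)
}

#' @rdname read_scores
#' @param records A [score_records()] table.
#' @return [write_scores()]: `path`, invisibly.
#' @export
write_scores <- function(records, path) {
  records <- score_records(as.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a 3x3 confusion matrix as JSON
#'
#' JSON schema: `{"labels": [1,2,3], "orientation": "rows=rater_a,cols=rater_b",
#' "counts": [[...],[...],[...]]}` with rows the first rater (investigator) and
#' columns the second (consensus).
#'
#' @param path JSON path.
#' @return [read_confusion_json()]: a `confusion_matrix3`.
#' @export
read_confusion_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(g$counts)) stop("confusion JSON needs a 'counts' member")
  confusion_matrix3(matrix(as.numeric(as.matrix(g$counts)), 3L, 3L))
}

#' @rdname read_confusion_json
#' @param cm A `confusion_matrix3`.
#' @return [write_confusion_json()]: `path`, invisibly.
#' @export
write_confusion_json <- function(cm, path) {
  cm <- confusion_matrix3(cm)
  m <- cm_unclass(cm)
  obj <- list(labels = 1:3, orientation = "rows=rater_a,cols=rater_b",
              counts = lapply(seq_len(3L), function(i) unname(m[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an agreement report
#'
#' JSON mirror of the report data frame, plus a flat CSV with one row per
#' stratum and condition.
#'
#' @param report Data frame from [agreement_report()] or [subgroup_report()].
#' @param path Output path (`.json` or `.csv` by extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  if (grepl("\\.json$", tolower(path)))
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  else
    utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
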