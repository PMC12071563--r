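#' Mitotic-count thresholds for the Elston-Ellis mitotic score
#'
#' Cut-offs mapping a mitotic count (per counting-zone area
#' `reference_area_mm2`) onto the three Elston-Ellis grades:
#' score 1 for counts up to `t1`, score 2 for counts in (`t1`, `t2`\], score 3
#' above `t2`. The defaults (7, 14) per 2 mm^2 follow the convention of the
#' 2 mm^2 hotspot-counting literature; sites using different microscope
#' field-diameter tables should substitute their own values.
#'
#' @param t1,t2 Non-negative integer cut-offs with `t1 < t2`. Defaults 7, 14.
#' @param reference_area_mm2 Counting area the thresholds refer to. Default 2.
#' @return An object of class `score_thresholds`.
#' @export
score_thresholds <- function(t1 = 7L, t2 = 14L, reference_area_mm2 = 2) {
  if (!is.numeric(t1) || !is.numeric(t2) || t1 < 0 || t2 < 0 || t1 != floor(t1) ||
      t2 != floor(t2))
    stop("'t1' and 't2' must be non-negative integers")
  if (t1 >= t2) stop("'t1' must be < 't2'")
  if (!is.numeric(reference_area_mm2) || reference_area_mm2 <= 0)
    stop("'reference_area_mm2' must be positive")
  structure(list(t1 = as.integer(t1), t2 = as.integer(t2),
                 reference_area_mm2 = as.numeric(reference_area_mm2)),
            class = "score_thresholds")
}

#' Mitotic count within a counting zone
#'
#' Number of mitosis positions inside a circular counting zone, boundary
#' inclusive. This is the count a pathologist would perform in the highlighted
#' 2 mm^2 hotspot region.
#'
#' @param zone A [circle_zone()].
#' @param mitoses Mitosis positions (data frame with `x`, `y` in um).
#' @return Non-negative integer.
#' @export
mitotic_count <- function(zone, mitoses) {
  stopifnot(inherits(zone, "circle_zone"))
  count_in_radius(zone$center, zone$radius_um, mitoses)
}

#' Elston-Ellis mitotic score from a mitotic count
#'
#' Piecewise-constant, non-decreasing mapping of counts onto grades 1/2/3:
#' 1 if `count <= t1`, 2 if `t1 < count <= t2`, 3 if `count > t2`. Vectorized.
#'
#' @param count Non-negative integer count(s).
#' @param thresholds A [score_thresholds()] object.
#' @return Integer score(s) in `{1, 2, 3}`.
#' @examples
#' assign_score(c(0, 7, 8, 14, 15))  # 1 1 2 2 3
#' @export
assign_score <- function(count, thresholds = score_thresholds()) {
  stopifnot(inherits(thresholds, "score_thresholds"))
  if (!is.numeric(count) || any(!is.finite(count)) || any(count < 0))
    stop("'count' must be non-negative")
  ifelse(count <= thresholds$t1, 1L, ifelse(count <= thresholds$t2, 2L, 3L))
}

#' Mitotic assessment of a slide at a counting zone
#'
#' Counts the retained mitoses in the supplied zone (by default the
#' context-area display zone of the top-ranked hotspot) and assigns the
#' Elston-Ellis mitotic score. Reports the thresholds used so every assessment
#' is auditable.
#'
#' @param hotspots A `hotspot_result` (see [compute_hotspots()]), or `NULL`
#'   when `zone` is given directly.
#' @param mitoses Retained mitosis positions (data frame, `x`/`y` um).
#' @param thresholds A [score_thresholds()] object.
#' @param zone Optional explicit [circle_zone()] overriding the hotspot choice.
#' @return An object of class `mitotic_assessment`: list with `zone`,
#'   `mitotic_count`, `mitotic_score`, `thresholds`, `slide_id`. When the
#'   hotspot result is empty and no zone is given, count is 0 and score 1 with
#'   a `NULL` zone.
#' @export
assess_mitotic_score <- function(hotspots = NULL, mitoses,
                                 thresholds = score_thresholds(),
                                 zone = NULL) {
  stopifnot(inherits(thresholds, "score_thresholds"))
  slide_id <- NA_character_
  if (is.null(zone)) {
    if (!is.null(hotspots)) {
      stopifnot(inherits(hotspots, "hotspot_result"))
      slide_id <- if (!is.null(hotspots$slide_id)) hotspots$slide_id else NA_character_
      if (length(hotspots$zones)) zone <- hotspots$zones[[1L]]
    }
  }
  mc <- if (is.null(zone)) 0L else mitotic_count(zone, mitoses)
  structure(
    list(zone = zone, mitotic_count = as.integer(mc),
         mitotic_score = as.integer(assign_score(mc, thresholds)),
         thresholds = thresholds, slide_id = slide_id),
    class = "mitotic_assessment"
  )
}

#' @export
print.mitotic_assessment <- function(x, ...) {
  cat(sprintf("<mitotic_assessment> count = %d, score = %d (cut-offs <=%d / <=%d per %g mm^2)\n",
              x$mitotic_count, x$mitotic_score, x$thresholds$t1, x$thresholds$t2,
              x$thresholds$reference_area_mm2))
  invisible(x)
}
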