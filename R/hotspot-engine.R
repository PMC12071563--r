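#' Hotspot computation parameters
#'
#' Parameters of the hotspot score
#' \deqn{h_p = n_1 + \epsilon (n_2 - n_1)}
#' where \eqn{n_1} is the number of retained mitosis detections within the core
#' circle (area `core_area_mm2`, default 1 mm^2) centered on patch center p,
#' \eqn{n_2} the number within the broader context circle (area
#' `context_area_mm2`, default 2 mm^2, concentric), and \eqn{\epsilon \in
#' [0, 1]} a tunable weight for surrounding mitotic activity: at epsilon = 0
#' the score is the pure core count, at epsilon = 1 the pure context count.
#' The default 0.5 is the midpoint of the admissible range and is configurable.
#'
#' @param core_area_mm2 Core circle area in mm^2. Default 1.
#' @param context_area_mm2 Context circle area in mm^2; must be at least the
#'   core area. Default 2; this circle is also the displayed counting zone.
#' @param epsilon Context weight in \[0, 1\]. Default 0.5.
#' @param confidence_threshold Detections with confidence strictly greater than
#'   this are retained. Default 0.5.
#' @param top_k Maximum number of non-overlapping hotspots selected. Default 5.
#' @return An object of class `hotspot_params`.
#' @export
hotspot_params <- function(core_area_mm2 = 1, context_area_mm2 = 2,
                           epsilon = 0.5, confidence_threshold = 0.5,
                           top_k = 5L) {
  if (!is.numeric(core_area_mm2) || core_area_mm2 <= 0)
    stop("'core_area_mm2' must be positive")
  if (!is.numeric(context_area_mm2) || context_area_mm2 < core_area_mm2)
    stop("'context_area_mm2' must be >= 'core_area_mm2'")
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon > 1)
    stop("'epsilon' must be in [0, 1]")
  if (!is.numeric(confidence_threshold) || confidence_threshold < 0 ||
      confidence_threshold > 1)
    stop("'confidence_threshold' must be in [0, 1]")
  if (!is.numeric(top_k) || top_k < 1)
    stop("'top_k' must be a positive integer")
  structure(
    list(core_area_mm2 = as.numeric(core_area_mm2),
         context_area_mm2 = as.numeric(context_area_mm2),
         epsilon = as.numeric(epsilon),
         confidence_threshold = as.numeric(confidence_threshold),
         top_k = as.integer(top_k)),
    class = "hotspot_params"
  )
}

#' Mitosis detection table
#'
#' Validates a detection table: one row per candidate mitotic figure with
#' position in microns and classifier confidence in \[0, 1\]. Extra columns are
#' preserved.
#'
#' @param x Data frame with columns `x`, `y` (um) and `confidence`; an `id`
#'   column is added when absent.
#' @return The validated data frame, class `mitosis_detections`.
#' @export
mitosis_detections <- function(x) {
  if (!is.data.frame(x) || !all(c("x", "y", "confidence") %in% names(x)))
    stop("detections need columns 'x', 'y', 'confidence'")
  if (nrow(x) && (any(!is.finite(x$x)) || any(!is.finite(x$y))))
    stop("detection coordinates must be finite")
  if (nrow(x) && (any(x$confidence < 0) || any(x$confidence > 1)))
    stop("detection confidence must be in [0, 1]")
  if (is.null(x$id)) x$id <- if (nrow(x)) sprintf("det_%d", seq_len(nrow(x))) else character(0)
  class(x) <- unique(c("mitosis_detections", class(x)))
  x
}

#' Confidence filtering of detections
#'
#' Keeps exactly the detections whose confidence strictly exceeds the
#' threshold (predictions must *exceed* the threshold to be retained), in their
#' original order.
#'
#' @param dets Detection table (see [mitosis_detections()]).
#' @param threshold Confidence threshold in \[0, 1\].
#' @return The retained subset of `dets`.
#' @export
filter_detections <- function(dets, threshold = 0.5) {
  dets <- mitosis_detections(dets)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("'threshold' must be in [0, 1]")
  out <- dets[dets$confidence > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count mitoses within a radius
#'
#' Number of mitosis positions at Euclidean distance less than or equal to
#' `radius_um` from `center` (inclusive boundary). Exact distance comparison,
#' no spatial-index approximation.
#'
#' @param center Length-2 numeric `c(x, y)` in um.
#' @param radius_um Positive radius in um.
#' @param mitoses Data frame of positions with `x`, `y` columns (um).
#' @return Non-negative integer count.
#' @export
count_in_radius <- function(center, radius_um, mitoses) {
  if (!is.numeric(radius_um) || radius_um <= 0) stop("'radius_um' must be positive")
  mitoses <- points_um(mitoses)
  if (nrow(mitoses) == 0L) return(0L)
  dx <- mitoses$x - center[[1L]]
  dy <- mitoses$y - center[[2L]]
  sum(dx * dx + dy * dy <= radius_um * radius_um)
}

#' Hotspot scores over a candidate grid
#'
#' For every candidate patch center p computes the core count `n_core`
#' (mitoses within the core circle), the context count `n_context` (mitoses
#' within the context circle) and the hotspot score
#' `n_core + epsilon * (n_context - n_core)`. All grid centers are scored,
#' including centers with no nearby mitosis (their score is 0). Counting uses
#' exact Euclidean distance with inclusive boundaries; `mitoses` is expected to
#' be confidence-filtered already.
#'
#' @param centers Candidate centers: a `patch_grid` or a data frame with
#'   `x`/`y` columns (um).
#' @param mitoses Retained mitosis positions (data frame, `x`/`y` in um).
#' @param params A [hotspot_params()] object.
#' @return Data frame of class `hotspot_candidates` with columns `x`, `y`,
#'   `n_core`, `n_context`, `score`, carrying `params` as an attribute.
#' @export
hotspot_scores <- function(centers, mitoses, params = hotspot_params()) {
  stopifnot(inherits(params, "hotspot_params"))
  if (inherits(centers, "patch_grid")) centers <- centers$centers
  centers <- points_um(centers)
  mitoses <- points_um(mitoses)
  r1sq <- (area_to_radius(params$core_area_mm2))^2
  r2sq <- (area_to_radius(params$context_area_mm2))^2
  n <- nrow(centers)
  n_core <- integer(n)
  n_context <- integer(n)
  if (nrow(mitoses) > 0L && n > 0L) {
    mx <- mitoses$x; my <- mitoses$y
    for (i in seq_len(n)) {
      d2 <- (mx - centers$x[i])^2 + (my - centers$y[i])^2
      n_core[i] <- sum(d2 <= r1sq)
      n_context[i] <- sum(d2 <= r2sq)
    }
  }
  out <- data.frame(x = centers$x, y = centers$y,
                    n_core = n_core, n_context = n_context,
                    score = n_core + params$epsilon * (n_context - n_core))
  attr(out, "params") <- params
  class(out) <- c("hotspot_candidates", class(out))
  out
}

#' Rank candidates and select non-overlapping hotspots
#'
#' Sorts candidates by score descending (ties broken by core count descending,
#' then x, then y ascending, making the ranking deterministic) and greedily
#' accepts candidates whose context-area display circle does not intersect any
#' already-accepted display circle (non-maximum suppression with the inclusive
#' tangency convention of [circles_intersect()]), stopping after `top_k`
#' acceptances or exhaustion.
#'
#' @param cands A `hotspot_candidates` data frame (see [hotspot_scores()]).
#' @param params A [hotspot_params()] object; `context_area_mm2` sets the
#'   display-zone size and `top_k` the maximum number of hotspots.
#' @return An object of class `hotspot_result`: list with `selected` (data
#'   frame `rank`, `x`, `y`, `n_core`, `n_context`, `score`), `zones` (list of
#'   `circle_zone` display zones, one per selection) and `params`.
#' @export
rank_and_select <- function(cands, params = hotspot_params()) {
  stopifnot(inherits(params, "hotspot_params"))
  if (params$top_k < 1) stop("'top_k' must be >= 1")
  need <- c("x", "y", "n_core", "n_context", "score")
  if (!is.data.frame(cands) || !all(need %in% names(cands)))
    stop("candidates need columns x, y, n_core, n_context, score")
  ord <- order(-cands$score, -cands$n_core, cands$x, cands$y)
  sorted <- cands[ord, need, drop = FALSE]
  r_disp <- area_to_radius(params$context_area_mm2)
  sel <- integer(0)
  for (i in seq_len(nrow(sorted))) {
    if (length(sel) >= params$top_k) break
    ok <- TRUE
    for (j in sel) {
      d <- sqrt((sorted$x[i] - sorted$x[j])^2 + (sorted$y[i] - sorted$y[j])^2)
      if (d <= 2 * r_disp) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, i)
  }
  selected <- sorted[sel, , drop = FALSE]
  rownames(selected) <- NULL
  if (nrow(selected))
    selected <- cbind(rank = seq_len(nrow(selected)), selected)
  else
    selected <- data.frame(rank = integer(0), x = numeric(0), y = numeric(0),
                           n_core = integer(0), n_context = integer(0),
                           score = numeric(0))
  zones <- lapply(seq_len(nrow(selected)), function(i)
    circle_zone(selected$x[i], selected$y[i], radius_um = r_disp))
  structure(list(selected = selected, zones = zones, params = params),
            class = "hotspot_result")
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat(sprintf("<hotspot_result> %d hotspot(s), epsilon = %g, zone area = %g mm^2\n",
              nrow(x$selected), x$params$epsilon, x$params$context_area_mm2))
  if (nrow(x$selected)) print(x$selected, ...)
  invisible(x)
}

#' Full hotspot pipeline for one slide
#'
#' Composition of the per-slide stages: confidence filtering of the detections,
#' candidate-grid construction over the tumor regions, hotspot scoring, and
#' ranked non-overlapping selection. A slide with no retained detections (or no
#' tumor region) yields an empty result, not an error.
#'
#' @param dets Detection table (`x`, `y` um, `confidence`; see
#'   [mitosis_detections()]).
#' @param regions A `slide_regions` object (micron frame).
#' @param frame Optional `slide_frame` for provenance and slide-id checking; if
#'   both `dets` and `frame` carry a slide id they must agree.
#' @param params A [hotspot_params()] object.
#' @param patch_px,level_mpp Tiling geometry passed to [build_patch_grid()].
#' @return A `hotspot_result` (see [rank_and_select()]).
#' @examples
#' r <- rect_region(0, 0, 4000, 4000)
#' set.seed(1)
#' dets <- data.frame(x = runif(60, 0, 4000), y = runif(60, 0, 4000),
#'                    confidence = runif(60))
#' compute_hotspots(dets, r, params = hotspot_params(top_k = 2))
#' @export
compute_hotspots <- function(dets, regions, frame = NULL,
                             params = hotspot_params(),
                             patch_px = 256L, level_mpp = 0.5) {
  dets <- mitosis_detections(dets)
  stopifnot(inherits(regions, "slide_regions"), inherits(params, "hotspot_params"))
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "slide_frame"))
    det_sid <- attr(dets, "slide_id")
    if (!is.null(det_sid) && !is.na(det_sid) && det_sid != frame$slide_id)
      stop(sprintf("slide id mismatch: detections '%s' vs frame '%s'",
                   det_sid, frame$slide_id))
  }
  kept <- filter_detections(dets, params$confidence_threshold)
  grid <- build_patch_grid(regions, patch_px = patch_px, level_mpp = level_mpp,
                           frame = frame)
  cands <- hotspot_scores(grid, kept, params)
  # a hotspot must contain at least one mitosis in its display zone; with no
  # retained detections this leaves an empty selection rather than an error
  res <- rank_and_select(cands[cands$n_context > 0L, , drop = FALSE], params)
  res$n_detections <- nrow(dets)
  res$n_retained <- nrow(kept)
  res$slide_id <- if (!is.null(frame)) frame$slide_id else attr(dets, "slide_id")
  res
}
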