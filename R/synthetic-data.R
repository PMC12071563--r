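#' Synthetic-slide configuration
#'
#' Describes a synthetic slide: a tumor region, a homogeneous Poisson
#' background of mitoses (intensity `lambda_bg` per mm^2 of tumor), planted
#' Gaussian clusters of extra mitoses (the ground-truth hotspots), and a Beta
#' confidence model for the detections. The defaults emulate a moderately
#' proliferative 5 x 5 mm tumor with one dense planted hotspot: background
#' 2 mitoses/mm^2 and a central cluster of 200 mitoses with a 200 um spread —
#' a mitotic landscape in which hotspot recovery is well-posed but not trivial.
#'
#' @param frame A [slide_frame()]. Default: 25 x 25 k px at 0.24 um/px.
#' @param regions A `slide_regions` tumor outline. Default: central 5 x 5 mm
#'   square.
#' @param lambda_bg Background intensity, mitoses per mm^2 of tumor area.
#'   Default 2.
#' @param clusters List of planted clusters, each a list with `x`, `y` (um),
#'   `sigma_um` (isotropic Gaussian spread) and `n_points`. Default: one
#'   cluster of 200 points, sigma 200 um, at the region centroid.
#' @param conf_shape1,conf_shape2 Beta parameters for detection confidences.
#'   Default Beta(8, 2) (mean 0.8: most true detections survive a 0.5
#'   threshold).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `slide_sim_config`.
#' @export
slide_sim_config <- function(frame = NULL, regions = NULL, lambda_bg = 2,
                             clusters = NULL, conf_shape1 = 8, conf_shape2 = 2,
                             seed = 1L) {
  if (is.null(frame))
    frame <- slide_frame(mpp = 0.24, width_px = 25000, height_px = 25000,
                         slide_id = "synthetic")
  stopifnot(inherits(frame, "slide_frame"))
  if (is.null(regions)) {
    w <- frame$width_px * frame$mpp
    h <- frame$height_px * frame$mpp
    cx <- w / 2; cy <- h / 2
    regions <- rect_region(cx - 2500, cy - 2500, cx + 2500, cy + 2500)
  }
  stopifnot(inherits(regions, "slide_regions"))
  if (!is.numeric(lambda_bg) || lambda_bg < 0) stop("'lambda_bg' must be >= 0")
  if (is.null(clusters)) {
    bb <- region_bbox(regions)
    clusters <- list(list(x = mean(bb[c("xmin", "xmax")]),
                          y = mean(bb[c("ymin", "ymax")]),
                          sigma_um = 200, n_points = 200L))
  }
  for (cl in clusters) {
    if (!all(c("x", "y", "sigma_um", "n_points") %in% names(cl)))
      stop("each cluster needs x, y, sigma_um, n_points")
    if (cl$sigma_um <= 0) stop("cluster 'sigma_um' must be positive")
    if (cl$n_points < 0) stop("cluster 'n_points' must be >= 0")
  }
  if (conf_shape1 <= 0 || conf_shape2 <= 0)
    stop("Beta confidence parameters must be positive")
  structure(
    list(frame = frame, regions = regions, lambda_bg = as.numeric(lambda_bg),
         clusters = clusters, conf_shape1 = as.numeric(conf_shape1),
         conf_shape2 = as.numeric(conf_shape2), seed = as.integer(seed)),
    class = "slide_sim_config"
  )
}

# Uniform points inside the region polygons by rejection from the bbox.
sample_uniform_in_regions <- function(n, regions) {
  bb <- region_bbox(regions)
  out <- matrix(numeric(0), 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, bb[["xmin"]], bb[["xmax"]]),
                  stats::runif(m, bb[["ymin"]], bb[["ymax"]]))
    keep <- points_in_regions(data.frame(x = cand[, 1L], y = cand[, 2L]), regions)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Gaussian cluster points truncated to the region polygons (redraw, not clip).
# Points are drawn one at a time so that, for a fixed seed and background, a
# cluster of n + m points extends the point set of a cluster of n points:
# hotspot counts are then monotone in n_points by construction.
sample_cluster_in_regions <- function(cl, regions) {
  n <- cl$n_points
  out <- matrix(0, n, 2L)
  i <- 0L
  while (i < n) {
    cand <- c(stats::rnorm(1L, cl$x, cl$sigma_um),
              stats::rnorm(1L, cl$y, cl$sigma_um))
    if (points_in_regions(data.frame(x = cand[1L], y = cand[2L]), regions)) {
      i <- i + 1L
      out[i, ] <- cand
    }
  }
  out
}

#' Generate a synthetic mitosis point pattern
#'
#' Draws a homogeneous Poisson number of background mitoses (expectation
#' `lambda_bg` times the tumor area in mm^2) uniformly over the tumor region
#' (rejection sampling from the bounding box), then adds each planted cluster
#' as `n_points` draws from an isotropic Gaussian truncated to the region
#' (points falling outside are redrawn, not clipped). Confidences are i.i.d.
#' Beta draws. Byte-identical output for identical configuration and seed.
#'
#' @param cfg A [slide_sim_config()].
#' @return A [mitosis_detections()] data frame with columns `x`, `y`,
#'   `confidence`, `id` and the ground-truth label `cluster` (0 = background,
#'   i = i-th planted cluster), with the config attached as attribute `config`.
#' @export
generate_point_pattern <- function(cfg) {
  stopifnot(inherits(cfg, "slide_sim_config"))
  set.seed(cfg$seed)
  area <- region_area_mm2(cfg$regions)
  n_bg <- if (cfg$lambda_bg > 0 && area > 0)
    stats::rpois(1L, cfg$lambda_bg * area) else 0L
  pts <- list()
  labels <- integer(0)
  if (n_bg > 0) {
    pts[[length(pts) + 1L]] <- sample_uniform_in_regions(n_bg, cfg$regions)
    labels <- c(labels, rep(0L, n_bg))
  }
  for (i in seq_along(cfg$clusters)) {
    cl <- cfg$clusters[[i]]
    if (cl$n_points > 0) {
      pts[[length(pts) + 1L]] <- sample_cluster_in_regions(cl, cfg$regions)
      labels <- c(labels, rep(i, cl$n_points))
    }
  }
  xy <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0L, 2L)
  n <- nrow(xy)
  dets <- data.frame(
    x = xy[, 1L][seq_len(n)], y = xy[, 2L][seq_len(n)],
    confidence = if (n) stats::rbeta(n, cfg$conf_shape1, cfg$conf_shape2) else numeric(0),
    id = if (n) sprintf("m_%04d", seq_len(n)) else character(0),
    cluster = labels
  )
  dets <- mitosis_detections(dets)
  attr(dets, "config") <- cfg
  attr(dets, "slide_id") <- cfg$frame$slide_id
  dets
}

## ---- simulated readers ----------------------------------------------------

#' Ordinal misgrading kernel
#'
#' Row-stochastic 3x3 matrix K with `K[t, s] = P(reported score s | true score
#' t)`: mass `p_correct` on the true grade and the remainder spread over the
#' other grades with weight inversely proportional to the grade distance
#' (adjacent-grade errors dominate, as they do in mitotic scoring).
#'
#' @param p_correct Probability of reporting the true grade, in (0, 1\].
#' @return A 3x3 row-stochastic matrix.
#' @examples
#' score_kernel(0.8)
#' @export
score_kernel <- function(p_correct) {
  if (!is.numeric(p_correct) || p_correct <= 0 || p_correct > 1)
    stop("'p_correct' must be in (0, 1]")
  k <- matrix(0, 3L, 3L, dimnames = list(true = 1:3, reported = 1:3))
  for (t in 1:3) {
    w <- 1 / abs(t - (1:3))
    w[t] <- 0
    k[t, ] <- (1 - p_correct) * w / sum(w)
    k[t, t] <- p_correct
  }
  k
}

check_kernel <- function(k, name) {
  k <- as.matrix(k)
  if (!all(dim(k) == c(3L, 3L))) stop(sprintf("%s must be 3x3", name))
  if (any(k < 0) || any(abs(rowSums(k) - 1) > 1e-12))
    stop(sprintf("%s rows must be non-negative and sum to 1", name))
  k
}

#' Reader-simulation configuration
#'
#' Describes a two-reader, two-condition crossover reading of a slide set with
#' known true scores: per-condition misgrading kernels (see [score_kernel()]),
#' and counting zones placed at the slide's true hotspot center plus isotropic
#' Gaussian jitter whose spread depends on the condition (AI assistance
#' concentrates readers on the same region, so its jitter is smaller). The
#' default kernels use diagonal 0.63 without AI and 0.77 with AI, and jitter
#' spreads of 1050 um and 830 um — calibrated from the reported operating
#' characteristics of AI-assisted mitotic scoring studies (accuracy in the
#' low-60s/high-70s percent and roughly 44%/60% zone-intersection rates for
#' 2 mm^2 zones).
#'
#' @param truth Data frame with `slide_id`, `score` (true grade 1/2/3),
#'   optional `specimen_type`, and optional true hotspot center `hotspot_x`,
#'   `hotspot_y` (um; default origin).
#' @param kernel_without,kernel_with 3x3 row-stochastic kernels for the two
#'   conditions, shared by both readers, or a list of two matrices (one per
#'   reader).
#' @param zone_jitter_sd_um Named vector with elements `without_AI`, `with_AI`:
#'   standard deviation (um) of the zone-center jitter in each condition.
#' @param zone_area_mm2 Area of each reader's counting zone. Default 2.
#' @param seed Integer seed.
#' @return An object of class `reader_sim_config`.
#' @export
reader_sim_config <- function(truth,
                              kernel_without = score_kernel(0.63),
                              kernel_with = score_kernel(0.77),
                              zone_jitter_sd_um = c(without_AI = 1050, with_AI = 830),
                              zone_area_mm2 = 2, seed = 1L) {
  if (!is.data.frame(truth) || !all(c("slide_id", "score") %in% names(truth)))
    stop("'truth' needs columns slide_id, score")
  if (!all(truth$score %in% 1:3)) stop("true scores must be in {1, 2, 3}")
  if (anyDuplicated(truth$slide_id)) stop("one row per slide required")
  as_pair <- function(k, nm) {
    if (is.list(k) && !is.matrix(k)) lapply(k, check_kernel, name = nm)
    else { kk <- check_kernel(k, nm); list(kk, kk) }
  }
  if (is.null(truth$hotspot_x)) truth$hotspot_x <- 0
  if (is.null(truth$hotspot_y)) truth$hotspot_y <- 0
  stopifnot(all(c("without_AI", "with_AI") %in% names(zone_jitter_sd_um)))
  structure(
    list(truth = truth,
         kernels = list(without_AI = as_pair(kernel_without, "kernel_without"),
                        with_AI = as_pair(kernel_with, "kernel_with")),
         zone_jitter_sd_um = zone_jitter_sd_um,
         zone_area_mm2 = as.numeric(zone_area_mm2),
         seed = as.integer(seed)),
    class = "reader_sim_config"
  )
}

#' Simulate reader scores and counting zones
#'
#' Independent categorical draws per slide, reader and condition from the
#' kernel row of the slide's true score; counting zones at the true hotspot
#' center plus condition-specific Gaussian jitter. Fully reproducible from the
#' configuration seed.
#'
#' @param cfg A [reader_sim_config()].
#' @return A [score_records()] data frame for two readers x two conditions,
#'   with zone columns.
#' @export
simulate_reader_scores <- function(cfg) {
  stopifnot(inherits(cfg, "reader_sim_config"))
  set.seed(cfg$seed)
  truth <- cfg$truth
  radius <- area_to_radius(cfg$zone_area_mm2)
  rows <- list()
  for (reader in 1:2) {
    for (cond in c("without_AI", "with_AI")) {
      k <- cfg$kernels[[cond]][[reader]]
      jit <- cfg$zone_jitter_sd_um[[cond]]
      n <- nrow(truth)
      sc <- vapply(truth$score, function(t)
        sample.int(3L, 1L, prob = k[t, ]), integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        slide_id = truth$slide_id,
        reader_id = sprintf("reader%d", reader),
        condition = cond,
        score = sc,
        specimen_type = if (is.null(truth$specimen_type)) NA_character_
                        else truth$specimen_type,
        zone_x = truth$hotspot_x + stats::rnorm(n, 0, jit),
        zone_y = truth$hotspot_y + stats::rnorm(n, 0, jit),
        zone_radius_um = radius,
        stringsAsFactors = FALSE
      )
    }
  }
  score_records(do.call(rbind, rows))
}

#' Expected inter-reader confusion matrix under a kernel model
#'
#' Closed-form joint distribution of the two readers' reported scores given
#' the true-score prevalence and per-reader misgrading kernels, assuming
#' conditionally independent readers:
#' \deqn{P(s_1 = i, s_2 = j) = \sum_t \pi_t K_1[t, i] K_2[t, j].}
#' Useful as an analytic oracle for the simulator: the empirical confusion
#' matrix of a large simulation converges to this matrix.
#'
#' @param prevalence Probability vector of length 3 over true scores.
#' @param k1,k2 3x3 row-stochastic kernels for readers 1 and 2.
#' @return 3x3 matrix of joint probabilities (sums to 1).
#' @export
expected_reader_confusion <- function(prevalence, k1, k2 = k1) {
  if (length(prevalence) != 3L || any(prevalence < 0))
    stop("'prevalence' must be 3 non-negative numbers")
  prevalence <- prevalence / sum(prevalence)
  k1 <- check_kernel(k1, "k1"); k2 <- check_kernel(k2, "k2")
  p <- matrix(0, 3L, 3L, dimnames = list(reader1 = 1:3, reader2 = 1:3))
  for (t in 1:3) p <- p + prevalence[t] * outer(k1[t, ], k2[t, ])
  p
}

#' Weighted kappa of a population joint distribution
#'
#' Linear weighted Cohen's kappa evaluated on an exact joint probability
#' matrix (rather than sampled counts): the population value an empirical
#' kappa estimates. No confidence interval, since there is no sampling.
#'
#' @param p 3x3 matrix of joint probabilities (normalized internally).
#' @return The population kappa value.
#' @export
kappa_linear_population <- function(p) {
  p <- as.matrix(p)
  if (!all(dim(p) == c(3L, 3L)) || any(p < 0) || sum(p) <= 0)
    stop("'p' must be a non-negative 3x3 matrix")
  p <- p / sum(p)
  w <- linear_weights(3L)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (1 - pe <= 0) stop("population kappa undefined: degenerate marginals")
  (sum(w * p) - pe) / (1 - pe)
}
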