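#' 3x3 confusion matrix of paired ordinal scores
#'
#' Builds or validates the 3x3 integer table feeding the agreement statistics.
#' Orientation convention, used in all I/O: rows are the first rater
#' (typically the investigator), columns the second (typically the expert
#' consensus); labels are the mitotic-score grades 1, 2, 3.
#'
#' @param a Either a 3x3 matrix of non-negative counts, or an integer vector
#'   of first-rater scores in `{1, 2, 3}`.
#' @param b Second-rater scores, when `a` is a vector (same length).
#' @return A 3x3 integer matrix of class `confusion_matrix3` with dimnames
#'   `rater_a` / `rater_b`.
#' @examples
#' confusion_matrix3(c(1, 2, 3, 2), c(1, 2, 2, 2))
#' @export
confusion_matrix3 <- function(a, b = NULL) {
  if (is.null(b)) {
    m <- as.matrix(a)
    if (!all(dim(m) == c(3L, 3L))) stop("confusion matrix must be 3x3")
    if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m)))
      stop("confusion matrix entries must be non-negative integers")
  } else {
    if (length(a) != length(b)) stop("score vectors must have equal length")
    if (!all(a %in% 1:3) || !all(b %in% 1:3))
      stop("scores must be in {1, 2, 3}")
    m <- table(factor(a, levels = 1:3), factor(b, levels = 1:3))
    m <- matrix(as.integer(m), 3L, 3L)
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(rater_a = c("1", "2", "3"), rater_b = c("1", "2", "3"))
  class(m) <- c("confusion_matrix3", class(m))
  m
}

cm_unclass <- function(cm) {
  m <- unclass(cm)
  attr(m, "class") <- NULL
  m
}

#' Agreement accuracy
#'
#' Proportion of slides where the two score assignments agree: the trace of
#' the confusion matrix over its total. With investigator scores in the rows
#' and expert-consensus scores in the columns this is the accuracy-vs-consensus
#' metric.
#'
#' @param cm A `confusion_matrix3`, or a vector of first-rater scores.
#' @param b Second-rater scores when `cm` is a vector.
#' @return Proportion in \[0, 1\].
#' @examples
#' agreement_accuracy(confusion_matrix3(matrix(c(20, 4, 0, 3, 10, 3, 0, 2, 8), 3)))
#' @export
agreement_accuracy <- function(cm, b = NULL) {
  if (!inherits(cm, "confusion_matrix3")) cm <- confusion_matrix3(cm, b)
  m <- cm_unclass(cm)
  n <- sum(m)
  if (n < 1) stop("accuracy is undefined for an empty confusion matrix")
  sum(diag(m)) / n
}

# Linear agreement weights for k ordered categories: w_ij = 1 - |i-j|/(k-1).
linear_weights <- function(k = 3L) {
  idx <- seq_len(k)
  1 - abs(outer(idx, idx, "-")) / (k - 1)
}

as_square_counts <- function(cm, b) {
  if (inherits(cm, "confusion_matrix3")) return(cm_unclass(cm))
  if (is.matrix(cm) && is.null(b)) {
    if (nrow(cm) != ncol(cm) || nrow(cm) < 2L)
      stop("confusion matrix must be square, at least 2x2")
    if (any(!is.finite(cm)) || any(cm < 0)) stop("counts must be non-negative")
    return(unclass(cm))
  }
  cm_unclass(confusion_matrix3(cm, b))
}

#' Linear weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal scores with linear weights
#' \eqn{w_{ij} = 1 - |i - j| / (k - 1)}: disagreement by one grade is penalized
#' half as much as by two. The estimate is
#' \eqn{\kappa_w = (p_{o(w)} - p_{e(w)}) / (1 - p_{e(w)})} with
#' \eqn{p_{o(w)} = \sum w_{ij} p_{ij}} and expected agreement
#' \eqn{p_{e(w)} = \sum w_{ij} p_{i.} p_{.j}} from the product of the marginals.
#' The default 95% confidence interval uses the large-sample (Fleiss-Cohen-
#' Everitt) variance of weighted kappa, not assuming kappa = 0; a
#' nonparametric bootstrap CI over rater pairs is available as an alternative
#' (it consumes the R random-number stream).
#'
#' A rater whose marginal is concentrated in a single category makes kappa
#' undefined and raises an error rather than returning 0.
#'
#' @param cm A `confusion_matrix3`, a square count matrix over k ordered
#'   categories, or a vector of first-rater scores.
#' @param b Second-rater scores when `cm` is a vector.
#' @param conf_level Confidence level. Default 0.95.
#' @param ci `"asymptotic"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `ci = "bootstrap"`. Default 2000.
#' @return An object of class `kappa_linear`: list with `estimate`, `se`
#'   (asymptotic), `conf_int` (length 2), `conf_level`, `n`, `method`.
#' @examples
#' cm <- confusion_matrix3(matrix(c(20, 4, 0, 3, 10, 3, 0, 2, 8), 3))
#' kappa_linear(cm)
#' @export
kappa_linear <- function(cm, b = NULL, conf_level = 0.95,
                         ci = c("asymptotic", "bootstrap"), boot_reps = 2000L) {
  ci <- match.arg(ci)
  m <- as_square_counts(cm, b)
  k <- nrow(m)
  n <- sum(m)
  if (n < 2) stop("kappa requires at least 2 paired scores")
  p <- m / n
  pa <- rowSums(p)
  pb <- colSums(p)
  if (any(pa >= 1) || any(pb >= 1))
    stop("kappa is undefined: a rater used a single category for all slides")
  w <- linear_weights(k)
  po <- sum(w * p)
  pe <- sum(w * outer(pa, pb))
  if (1 - pe <= 0)
    stop("kappa is undefined: expected agreement is 1 (degenerate marginals)")
  kap <- (po - pe) / (1 - pe)
  # large-sample variance (Fleiss, Cohen & Everitt 1969)
  wbar_i <- as.vector(w %*% pb)   # row-conditional expected weight
  wbar_j <- as.vector(pa %*% w)   # column-conditional expected weight
  dev <- w - outer(wbar_i, wbar_j, "+") * (1 - kap)
  var_k <- (sum(p * dev^2) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  alpha <- 1 - conf_level
  if (ci == "asymptotic") {
    z <- stats::qnorm(1 - alpha / 2)
    conf_int <- c(kap - z * se, kap + z * se)
  } else {
    # resample pairs: draw cell counts from the empirical joint distribution
    cells <- as.vector(m)
    reps <- vapply(seq_len(boot_reps), function(i) {
      bm <- matrix(stats::rmultinom(1L, n, cells / n), k, k)
      bp <- bm / n
      bpa <- rowSums(bp); bpb <- colSums(bp)
      bpe <- sum(w * outer(bpa, bpb))
      if (1 - bpe <= 0) return(NA_real_)
      (sum(w * bp) - bpe) / (1 - bpe)
    }, 0)
    conf_int <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                                       na.rm = TRUE))
  }
  conf_int <- pmin(pmax(conf_int, -1), 1)
  structure(list(estimate = kap, se = se, conf_int = conf_int,
                 conf_level = conf_level, n = n, weights = "linear",
                 method = ci),
            class = "kappa_linear")
}

#' @export
print.kappa_linear <- function(x, ...) {
  cat(sprintf("Linear weighted Cohen's kappa: %.3f (%d%% CI %.3f-%.3f, n = %d, %s)\n",
              x$estimate, round(100 * x$conf_level), x$conf_int[1], x$conf_int[2],
              x$n, x$method))
  invisible(x)
}

#' Intraclass correlation coefficient for paired scores
#'
#' Reliability of scoring between raters from the two-way mean-squares
#' decomposition. The default form is ICC(2,1): two-way random effects,
#' absolute agreement, single rater — both raters are treated as a random
#' sample from a population of raters and systematic rater offsets count as
#' disagreement. Consistency (`"ICC(3,1)"`) and one-way (`"ICC(1,1)"`) forms
#' are available so alternative conventions can be compared. Confidence
#' intervals follow the standard F-based construction (McGraw & Wong 1996;
#' Satterthwaite degrees of freedom for the absolute-agreement form).
#'
#' @param ratings Numeric matrix with one row per subject (slide) and one
#'   column per rater, or a vector of first-rater values.
#' @param b Second-rater values when `ratings` is a vector.
#' @param model `"ICC(2,1)"` (default), `"ICC(3,1)"` or `"ICC(1,1)"`.
#' @param conf_level Confidence level. Default 0.95.
#' @return An object of class `icc_result`: list with `estimate`, `conf_int`,
#'   `model`, `n` (subjects), `k` (raters), `ms` (mean squares), `F`.
#' @examples
#' icc_scores(c(1, 2, 3, 2, 1, 3), c(1, 2, 2, 3, 1, 3))
#' @export
icc_scores <- function(ratings, b = NULL, model = c("ICC(2,1)", "ICC(3,1)", "ICC(1,1)"),
                       conf_level = 0.95) {
  model <- match.arg(model)
  if (!is.null(b)) ratings <- cbind(as.numeric(ratings), as.numeric(b))
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings))) stop("ratings must be finite and complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("ICC requires at least 2 subjects and 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  if (ss_total <= 0) stop("ICC is undefined: all ratings are identical")
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)                 # between subjects
  msc <- ss_cols / (k - 1)                 # between raters
  mse <- ss_err / ((n - 1) * (k - 1))      # residual
  msw <- (ss_total - ss_rows) / (n * (k - 1))  # within subjects (one-way)
  alpha <- 1 - conf_level
  if (model == "ICC(2,1)") {
    denom <- msr + (k - 1) * mse + k * (msc - mse) / n
    if (denom <= 0) stop("ICC is undefined: non-positive variance decomposition")
    est <- (msr - mse) / denom
    fj <- msc / mse
    a <- k * est / (n * (1 - est))
    bb <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + bb * mse)^2 /
      ((a * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    fstat <- msr / mse
  } else if (model == "ICC(3,1)") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fstat <- msr / mse
    f_l <- fstat / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_u <- fstat * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (f_l - 1) / (f_l + k - 1)
    upper <- (f_u - 1) / (f_u + k - 1)
  } else {
    est <- (msr - msw) / (msr + (k - 1) * msw)
    fstat <- msr / msw
    f_l <- fstat / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    f_u <- fstat * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    lower <- (f_l - 1) / (f_l + k - 1)
    upper <- (f_u - 1) / (f_u + k - 1)
  }
  structure(
    list(estimate = est, conf_int = c(max(lower, -1), min(upper, 1)),
         conf_level = conf_level, model = model, n = n, k = k,
         ms = c(msr = msr, msc = msc, mse = mse, msw = msw), F = fstat),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s: %.3f (%d%% CI %.3f-%.3f, n = %d subjects, k = %d raters)\n",
              x$model, x$estimate, round(100 * x$conf_level),
              x$conf_int[1], x$conf_int[2], x$n, x$k))
  invisible(x)
}

## ---- counting-zone spatial agreement --------------------------------------

zone_table <- function(z) {
  if (!is.data.frame(z) || !all(c("slide_id", "x", "y", "radius_um") %in% names(z)))
    stop("zones need columns 'slide_id', 'x', 'y', 'radius_um'")
  if (is.null(z$no_zone)) z$no_zone <- FALSE
  z$no_zone[is.na(z$no_zone)] <- FALSE
  z
}

#' Counting-zone intersection rate between two zone sets
#'
#' Spatial-agreement metric for hotspot selection: the fraction of slides on
#' which the two sides' circular counting zones intersect (inclusive tangency).
#' Side `b` may carry several zones per slide — e.g. the AI's selected hotspot
#' zones — in which case intersection with *any* of them counts, which is the
#' AI-vs-reader variant of the metric.
#'
#' Slides present on only one side are excluded from the denominator and
#' listed in `excluded`. A slide where a side explicitly recorded "no zone"
#' (`no_zone = TRUE`) counts as non-intersecting; a slide with missing zone
#' coordinates and no such flag is excluded.
#'
#' @param a Zone table for side A: data frame with `slide_id`, `x`, `y`,
#'   `radius_um` (um), optional logical `no_zone`. One zone per slide.
#' @param b Zone table for side B, same columns; may have several rows per
#'   slide.
#' @return An object of class `zone_agreement`: list with `rate`, `n`,
#'   `per_slide` (data frame `slide_id`, `intersects`), `excluded` (slide ids).
#' @export
zone_intersection_rate <- function(a, b) {
  a <- zone_table(a); b <- zone_table(b)
  if (anyDuplicated(a$slide_id)) stop("side A must have one zone per slide")
  slides <- intersect(unique(a$slide_id), unique(b$slide_id))
  excluded <- setdiff(union(unique(a$slide_id), unique(b$slide_id)), slides)
  flags <- logical(0); kept <- character(0)
  for (s in slides) {
    ra <- a[a$slide_id == s, , drop = FALSE]
    rb <- b[b$slide_id == s, , drop = FALSE]
    if (ra$no_zone[1L] || all(rb$no_zone)) {
      kept <- c(kept, s); flags <- c(flags, FALSE)
      next
    }
    rb <- rb[!rb$no_zone, , drop = FALSE]
    if (any(is.na(ra[, c("x", "y", "radius_um")])) ||
        any(is.na(rb[, c("x", "y", "radius_um")]))) {
      excluded <- c(excluded, s)
      next
    }
    za <- circle_zone(ra$x[1L], ra$y[1L], ra$radius_um[1L])
    hit <- any(vapply(seq_len(nrow(rb)), function(i)
      circles_intersect(za, circle_zone(rb$x[i], rb$y[i], rb$radius_um[i])),
      logical(1)))
    kept <- c(kept, s); flags <- c(flags, hit)
  }
  if (length(kept) == 0L) stop("no slide has zones on both sides")
  structure(
    list(rate = mean(flags), n = length(kept),
         per_slide = data.frame(slide_id = kept, intersects = flags),
         excluded = unique(excluded)),
    class = "zone_agreement"
  )
}

#' @export
print.zone_agreement <- function(x, ...) {
  cat(sprintf("Zone intersection rate: %.1f%% (n = %d slides%s)\n",
              100 * x$rate, x$n,
              if (length(x$excluded)) sprintf(", %d excluded", length(x$excluded)) else ""))
  invisible(x)
}

## ---- study-level reports ---------------------------------------------------

#' Validate a reader score-record table
#'
#' One record per (slide, reader, condition): the reader's mitotic score under
#' that condition, with optional specimen type and counting-zone circle.
#'
#' @param x Data frame with columns `slide_id`, `reader_id`, `condition`
#'   (one of `"with_AI"`, `"without_AI"`), `score` (1/2/3); optional
#'   `specimen_type` (`"biopsy"`/`"surgical"`), `zone_x`, `zone_y`,
#'   `zone_radius_um`, logical `no_zone`.
#' @return The validated data frame, class `score_records`.
#' @export
score_records <- function(x) {
  need <- c("slide_id", "reader_id", "condition", "score")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("score records need columns slide_id, reader_id, condition, score")
  if (!all(x$condition %in% c("with_AI", "without_AI")))
    stop("condition must be 'with_AI' or 'without_AI'")
  if (!all(x$score %in% 1:3)) stop("scores must be in {1, 2, 3}")
  key <- paste(x$slide_id, x$reader_id, x$condition)
  if (anyDuplicated(key))
    stop("one record per (slide, reader, condition) is required")
  class(x) <- unique(c("score_records", class(x)))
  x
}

reader_zones <- function(records, reader, condition) {
  r <- records[records$reader_id == reader & records$condition == condition, ,
               drop = FALSE]
  if (!all(c("zone_x", "zone_y", "zone_radius_um") %in% names(r))) return(NULL)
  data.frame(slide_id = r$slide_id, x = r$zone_x, y = r$zone_y,
             radius_um = r$zone_radius_um,
             no_zone = if (is.null(r$no_zone)) FALSE else r$no_zone)
}

safe_stat <- function(expr) tryCatch(expr, error = function(e) NULL)

#' Agreement report for one slide stratum
#'
#' Computes the full statistics block the clinical evaluation reports, on one
#' set of slides and one condition: per-reader accuracy against the consensus,
#' inter-reader linear weighted kappa with CI, inter-reader ICC with CI, and
#' the inter-reader counting-zone intersection rate (plus AI-vs-reader rates
#' when AI zones are supplied). Statistics whose preconditions fail on the
#' stratum (fewer than 2 slides, degenerate marginals, zero variance) are
#' reported as `NA` rather than raising, so sparse strata degrade gracefully.
#'
#' @param records A [score_records()] table (already restricted to a stratum
#'   if desired).
#' @param consensus Data frame `slide_id`, `score` with the expert-consensus
#'   score per slide.
#' @param condition `"with_AI"` or `"without_AI"`.
#' @param ai_zones Optional zone table of AI hotspot zones (`slide_id`, `x`,
#'   `y`, `radius_um`, several rows per slide allowed).
#' @param stratum Label recorded in the output row.
#' @return One-row data frame with the metrics (class `agreement_report`).
#' @export
agreement_report <- function(records, consensus, condition,
                             ai_zones = NULL, stratum = "all") {
  records <- score_records(as.data.frame(records))
  rec <- records[records$condition == condition, , drop = FALSE]
  readers <- sort(unique(records$reader_id))
  if (length(readers) != 2L) stop("exactly two readers are required")
  r1 <- rec[rec$reader_id == readers[1L], , drop = FALSE]
  r2 <- rec[rec$reader_id == readers[2L], , drop = FALSE]
  slides <- intersect(r1$slide_id, r2$slide_id)
  slides <- intersect(slides, consensus$slide_id)
  s1 <- r1$score[match(slides, r1$slide_id)]
  s2 <- r2$score[match(slides, r2$slide_id)]
  sc <- consensus$score[match(slides, consensus$slide_id)]
  n <- length(slides)
  acc1 <- if (n) mean(s1 == sc) else NA_real_
  acc2 <- if (n) mean(s2 == sc) else NA_real_
  k1c <- if (n >= 2) safe_stat(kappa_linear(s1, sc)) else NULL
  k2c <- if (n >= 2) safe_stat(kappa_linear(s2, sc)) else NULL
  k12 <- if (n >= 2) safe_stat(kappa_linear(s1, s2)) else NULL
  icc12 <- if (n >= 2) safe_stat(icc_scores(s1, s2)) else NULL
  za <- reader_zones(rec, readers[1L], condition)
  zb <- reader_zones(rec, readers[2L], condition)
  zr <- if (!is.null(za) && !is.null(zb))
    safe_stat(zone_intersection_rate(za[za$slide_id %in% slides, ],
                                     zb[zb$slide_id %in% slides, ])) else NULL
  ai1 <- ai2 <- NULL
  if (!is.null(ai_zones)) {
    if (!is.null(za)) ai1 <- safe_stat(zone_intersection_rate(
      za[za$slide_id %in% slides, ], ai_zones))
    if (!is.null(zb)) ai2 <- safe_stat(zone_intersection_rate(
      zb[zb$slide_id %in% slides, ], ai_zones))
  }
  out <- data.frame(
    stratum = stratum, condition = condition, n_slides = n,
    accuracy_reader1 = acc1, accuracy_reader2 = acc2,
    accuracy = if (n) mean(c(s1 == sc, s2 == sc)) else NA_real_,
    kappa_reader1 = if (is.null(k1c)) NA_real_ else k1c$estimate,
    kappa_reader2 = if (is.null(k2c)) NA_real_ else k2c$estimate,
    kappa = if (is.null(k12)) NA_real_ else k12$estimate,
    kappa_lo = if (is.null(k12)) NA_real_ else k12$conf_int[1],
    kappa_hi = if (is.null(k12)) NA_real_ else k12$conf_int[2],
    icc = if (is.null(icc12)) NA_real_ else icc12$estimate,
    icc_lo = if (is.null(icc12)) NA_real_ else icc12$conf_int[1],
    icc_hi = if (is.null(icc12)) NA_real_ else icc12$conf_int[2],
    zone_intersection_rate = if (is.null(zr)) NA_real_ else zr$rate,
    ai_zone_rate_reader1 = if (is.null(ai1)) NA_real_ else ai1$rate,
    ai_zone_rate_reader2 = if (is.null(ai2)) NA_real_ else ai2$rate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("agreement_report", class(out))
  out
}

#' Subgroup agreement reports
#'
#' Runs [agreement_report()] on the whole slide set and on every stratum
#' defined by the consensus mitotic score (1/2/3) and, when available, by
#' specimen type (biopsy/surgical), for both conditions. This mirrors the
#' subgroup layout of clinical reader studies: subgroup rows where a statistic
#' is undefined (e.g. a single-score stratum with degenerate kappa marginals)
#' carry `NA` in that cell with the stratum size still reported.
#'
#' @param records A [score_records()] table for two readers, both conditions.
#' @param consensus Data frame `slide_id`, `score`, optional `specimen_type`.
#' @param ai_zones Optional AI hotspot zone table (see [agreement_report()]).
#' @return Data frame with one row per stratum x condition.
#' @export
subgroup_report <- function(records, consensus, ai_zones = NULL) {
  records <- score_records(as.data.frame(records))
  conditions <- c("without_AI", "with_AI")
  strata <- list(all = consensus$slide_id)
  for (s in sort(unique(consensus$score)))
    strata[[sprintf("score_%d", s)]] <- consensus$slide_id[consensus$score == s]
  if (!is.null(consensus$specimen_type))
    for (st in sort(unique(consensus$specimen_type)))
      strata[[st]] <- consensus$slide_id[consensus$specimen_type == st]
  rows <- list()
  for (nm in names(strata)) {
    ids <- strata[[nm]]
    rec_s <- records[records$slide_id %in% ids, , drop = FALSE]
    con_s <- consensus[consensus$slide_id %in% ids, , drop = FALSE]
    for (cond in conditions) {
      rows[[length(rows) + 1L]] <- tryCatch(
        agreement_report(rec_s, con_s, cond, ai_zones = ai_zones, stratum = nm),
        error = function(e) data.frame(
          stratum = nm, condition = cond,
          n_slides = length(unique(rec_s$slide_id)),
          accuracy_reader1 = NA_real_, accuracy_reader2 = NA_real_,
          accuracy = NA_real_, kappa_reader1 = NA_real_,
          kappa_reader2 = NA_real_, kappa = NA_real_, kappa_lo = NA_real_,
          kappa_hi = NA_real_, icc = NA_real_, icc_lo = NA_real_,
          icc_hi = NA_real_, zone_intersection_rate = NA_real_,
          ai_zone_rate_reader1 = NA_real_, ai_zone_rate_reader2 = NA_real_,
          stringsAsFactors = FALSE)
      )
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) { class(r) <- "data.frame"; r }))
  rownames(out) <- NULL
  out
}
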