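# Independent reference implementations used as oracles. These deliberately
# use different algorithms / code paths from the package internals.

# Ray-casting point-in-polygon over a list of rings (even-odd rule, so holes
# and disjoint polygons behave like the package's parity convention).
oracle_point_in_rings <- function(px, py, rings) {
  crossings <- 0L
  for (m in rings) {
    n <- nrow(m)
    j <- n
    for (i in seq_len(n)) {
      xi <- m[i, 1L]; yi <- m[i, 2L]
      xj <- m[j, 1L]; yj <- m[j, 2L]
      if ((yi > py) != (yj > py)) {
        x_at <- xi + (py - yi) / (yj - yi) * (xj - xi)
        if (px < x_at) crossings <- crossings + 1L
      }
      j <- i
    }
  }
  crossings %% 2L == 1L
}

oracle_points_in_regions <- function(pts, regions) {
  rings <- unlist(unclass(regions), recursive = FALSE)
  vapply(seq_len(nrow(pts)),
         function(i) oracle_point_in_rings(pts$x[i], pts$y[i], rings),
         logical(1))
}

# Exhaustive all-pairs counting oracle: one full distance matrix, then counts.
oracle_hotspot_counts <- function(centers, mitoses, r1, r2) {
  if (nrow(mitoses) == 0L)
    return(list(n_core = integer(nrow(centers)),
                n_context = integer(nrow(centers))))
  d <- sqrt(outer(centers$x, mitoses$x, "-")^2 +
            outer(centers$y, mitoses$y, "-")^2)
  list(n_core = as.integer(rowSums(d <= r1)),
       n_context = as.integer(rowSums(d <= r2)))
}

# Reference greedy selection: rescans the full candidate list at every step.
oracle_greedy_select <- function(cands, r_disp, top_k) {
  remaining <- cands[order(-cands$score, -cands$n_core, cands$x, cands$y), ,
                     drop = FALSE]
  chosen <- remaining[0L, , drop = FALSE]
  while (nrow(chosen) < top_k && nrow(remaining) > 0L) {
    ok_idx <- NA_integer_
    for (i in seq_len(nrow(remaining))) {
      d <- sqrt((remaining$x[i] - chosen$x)^2 + (remaining$y[i] - chosen$y)^2)
      if (all(d > 2 * r_disp)) { ok_idx <- i; break }
    }
    if (is.na(ok_idx)) break
    chosen <- rbind(chosen, remaining[ok_idx, , drop = FALSE])
    remaining <- remaining[-seq_len(ok_idx), , drop = FALSE]
  }
  chosen
}

# Random simple polygon: star-shaped around a center. Jittered equally spaced
# angles keep every angular gap below pi, which guarantees simplicity.
random_star_polygon <- function(center_x, center_y, r_min, r_max, n_vertices = 12L) {
  base <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  th <- sort(base + stats::runif(n_vertices, 0, 2 * pi / n_vertices))
  r <- stats::runif(n_vertices, r_min, r_max)
  cbind(x = center_x + r * cos(th), y = center_y + r * sin(th))
}

# Random detection table on a rectangle.
random_detections <- function(n, xmax, ymax, conf = NULL) {
  data.frame(x = stats::runif(n, 0, xmax), y = stats::runif(n, 0, ymax),
             confidence = if (is.null(conf)) stats::runif(n) else conf)
}
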