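test_that("confidence filtering keeps strictly exceeding detections in order", {
  dets <- data.frame(x = 1:3, y = 1:3, confidence = c(0.2, 0.5, 0.9))
  kept <- filter_detections(dets, 0.5)
  expect_equal(kept$confidence, 0.9)  # 0.5 is not > 0.5
  all_pos <- filter_detections(dets, 0)
  expect_equal(all_pos$confidence, c(0.2, 0.5, 0.9))
  set.seed(31)
  rnd <- data.frame(x = runif(200), y = runif(200), confidence = runif(200))
  for (thr in c(0.1, 0.37, 0.8)) {
    kept <- filter_detections(rnd, thr)
    expect_equal(kept$confidence, rnd$confidence[rnd$confidence > thr])
  }
})

test_that("count_in_radius counts inclusively and matches brute force", {
  expect_identical(count_in_radius(c(0, 0), 100, data.frame(x = numeric(0), y = numeric(0))), 0L)
  # one mitosis at distance exactly r
  expect_equal(count_in_radius(c(0, 0), 5, data.frame(x = 3, y = 4)), 1L)
  set.seed(32)
  pts <- data.frame(x = runif(500, 0, 4000), y = runif(500, 0, 4000))
  for (i in 1:10) {
    ctr <- c(runif(1, 0, 4000), runif(1, 0, 4000))
    r <- runif(1, 100, 1500)
    manual <- sum(sqrt((pts$x - ctr[1])^2 + (pts$y - ctr[2])^2) <= r)
    expect_equal(count_in_radius(ctr, r, pts), manual)
  }
})

test_that("hotspot scores follow the core/context formula", {
  p <- hotspot_params(epsilon = 0.7)
  # single mitosis coincident with its only patch center
  sc <- hotspot_scores(data.frame(x = 0, y = 0), data.frame(x = 0, y = 0), p)
  expect_equal(sc$n_core, 1L)
  expect_equal(sc$n_context, 1L)
  expect_equal(sc$score, 1)

  set.seed(33)
  centers <- expand.grid(x = seq(250, 3750, by = 500), y = seq(250, 3750, by = 500))
  mits <- data.frame(x = runif(50, 0, 4000), y = runif(50, 0, 4000))
  # epsilon = 0 reduces to core counts; epsilon = 1 to context counts
  s0 <- hotspot_scores(centers, mits, hotspot_params(epsilon = 0))
  expect_equal(s0$score, as.numeric(s0$n_core))
  s1 <- hotspot_scores(centers, mits, hotspot_params(epsilon = 1))
  expect_equal(s1$score, as.numeric(s1$n_context))
  # epsilon = 0.5 equals the all-pairs distance-matrix oracle
  s5 <- hotspot_scores(centers, mits, hotspot_params(epsilon = 0.5))
  orc <- oracle_hotspot_counts(centers, mits, area_to_radius(1), area_to_radius(2))
  expect_identical(s5$n_core, orc$n_core)
  expect_identical(s5$n_context, orc$n_context)
  expect_equal(s5$score, orc$n_core + 0.5 * (orc$n_context - orc$n_core))
})

test_that("scores are permutation-invariant and monotone in the point set", {
  set.seed(34)
  centers <- expand.grid(x = seq(200, 3800, by = 400), y = seq(200, 3800, by = 400))
  mits <- data.frame(x = runif(80, 0, 4000), y = runif(80, 0, 4000))
  p <- hotspot_params(epsilon = 0.5)
  base <- hotspot_scores(centers, mits, p)
  shuf <- hotspot_scores(centers, mits[sample(nrow(mits)), ], p)
  expect_equal(base$score, shuf$score)
  perm <- sample(nrow(centers))
  permuted <- hotspot_scores(centers[perm, ], mits, p)
  expect_equal(permuted$score, base$score[perm])
  # adding a mitosis never decreases any score
  more <- hotspot_scores(centers, rbind(mits, data.frame(x = 2000, y = 2000)), p)
  expect_true(all(more$score >= base$score))
  expect_true(all(base$n_context >= base$n_core))
})

test_that("score is non-decreasing in epsilon where context exceeds core", {
  set.seed(35)
  centers <- expand.grid(x = seq(250, 3750, by = 500), y = seq(250, 3750, by = 500))
  mits <- data.frame(x = runif(60, 0, 4000), y = runif(60, 0, 4000))
  eps <- seq(0, 1, by = 0.25)
  runs <- lapply(eps, function(e) hotspot_scores(centers, mits, hotspot_params(epsilon = e)))
  for (i in seq_len(length(eps) - 1L)) {
    delta <- runs[[i + 1L]]$score - runs[[i]]$score
    expect_true(all(delta >= -1e-12))
    flat <- runs[[1L]]$n_context == runs[[1L]]$n_core
    expect_true(all(abs(delta[flat]) < 1e-12))
  }
})

test_that("ranked greedy selection matches the rescanning oracle", {
  p <- hotspot_params(top_k = 1)
  one <- rank_and_select(data.frame(x = 0, y = 0, n_core = 2L, n_context = 3L, score = 2.5), p)
  expect_equal(one$selected$rank, 1L)

  # two coincident candidates: lower score suppressed even with top_k = 2
  two <- data.frame(x = c(100, 100), y = c(100, 100),
                    n_core = c(5L, 3L), n_context = c(5L, 3L), score = c(5, 3))
  res <- rank_and_select(two, hotspot_params(top_k = 2))
  expect_equal(nrow(res$selected), 1L)
  expect_equal(res$selected$score, 5)

  set.seed(36)
  for (rep in 1:10) {
    n <- 60
    cands <- data.frame(x = runif(n, 0, 8000), y = runif(n, 0, 8000),
                        n_core = rpois(n, 3))
    cands$n_context <- cands$n_core + rpois(n, 2)
    cands$score <- cands$n_core + 0.5 * (cands$n_context - cands$n_core)
    prm <- hotspot_params(top_k = 4)
    got <- rank_and_select(cands, prm)$selected
    want <- oracle_greedy_select(cands, area_to_radius(2), 4)
    expect_equal(got$x, want$x)
    expect_equal(got$y, want$y)
    expect_equal(got$score, want$score)
    # idempotence: reselecting the selected set returns it unchanged
    again <- rank_and_select(got[, c("x", "y", "n_core", "n_context", "score")], prm)
    expect_equal(again$selected$x, got$x)
    expect_equal(again$selected$score, got$score)
  }
  expect_error(hotspot_params(top_k = 0), "top_k")
})

test_that("selected display zones never intersect and ranks are score-ordered", {
  set.seed(37)
  cands <- data.frame(x = runif(100, 0, 6000), y = runif(100, 0, 6000),
                      n_core = rpois(100, 4))
  cands$n_context <- cands$n_core + rpois(100, 3)
  cands$score <- cands$n_core + 0.3 * (cands$n_context - cands$n_core)
  res <- rank_and_select(cands, hotspot_params(epsilon = 0.3, top_k = 10))
  z <- res$zones
  if (length(z) > 1) {
    for (i in seq_along(z)) for (j in seq_along(z)) if (i < j)
      expect_false(circles_intersect(z[[i]], z[[j]]))
  }
  expect_true(all(diff(res$selected$score) <= 1e-12))
})

test_that("the full pipeline handles empty input and is unit-consistent", {
  reg <- rect_region(0, 0, 4000, 4000)
  empty <- data.frame(x = numeric(0), y = numeric(0), confidence = numeric(0))
  res <- compute_hotspots(empty, reg)
  expect_equal(nrow(res$selected), 0L)
  # all detections below threshold also yields an empty result
  weak <- data.frame(x = c(100, 200), y = c(100, 200), confidence = c(0.1, 0.2))
  expect_equal(nrow(compute_hotspots(weak, reg)$selected), 0L)

  set.seed(38)
  dets <- data.frame(x = runif(120, 0, 4000), y = runif(120, 0, 4000),
                     confidence = runif(120))
  p <- hotspot_params(top_k = 3)
  # the same micron geometry expressed through a different pixel scale
  f1 <- slide_frame(0.25, 16000, 16000, "A")
  f2 <- slide_frame(0.50, 8000, 8000, "A")
  r1 <- compute_hotspots(dets, reg, frame = f1, params = p)
  r2 <- compute_hotspots(dets, reg, frame = f2, params = p)
  expect_equal(r1$selected, r2$selected)
})

test_that("pipeline rejects mismatched slide ids", {
  reg <- rect_region(0, 0, 1000, 1000)
  dets <- mitosis_detections(data.frame(x = 500, y = 500, confidence = 0.9))
  attr(dets, "slide_id") <- "S_other"
  f <- slide_frame(0.25, 4000, 4000, "S1")
  expect_error(compute_hotspots(dets, reg, frame = f), "mismatch")
})

test_that("hotspot parameter invariants are enforced", {
  expect_error(hotspot_params(epsilon = 1.5), "epsilon")
  expect_error(hotspot_params(core_area_mm2 = 2, context_area_mm2 = 1), "context_area")
  expect_error(hotspot_params(confidence_threshold = 2), "confidence")
})
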