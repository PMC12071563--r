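# Frozen reference values for the fixed matrices below were computed once with
# an independent implementation of the weighted-kappa and ICC formulas
# (statsmodels cohens_kappa with linear weights; pingouin intraclass_corr).
cm_fix <- confusion_matrix3(matrix(c(20, 3, 0,
                                     4, 10, 2,
                                     0, 3, 8), nrow = 3, byrow = TRUE))
cm_fix2 <- confusion_matrix3(matrix(c(12, 5, 1,
                                      3, 9, 6,
                                      0, 4, 10), nrow = 3, byrow = TRUE))

test_that("accuracy is the trace proportion of the confusion matrix", {
  expect_equal(agreement_accuracy(confusion_matrix3(diag(c(10, 10, 10)))), 1)
  off <- matrix(c(0, 5, 5, 5, 0, 5, 5, 5, 0), 3)
  expect_equal(agreement_accuracy(confusion_matrix3(off)), 0)
  expect_equal(agreement_accuracy(cm_fix), 38 / 50)
  expect_error(agreement_accuracy(confusion_matrix3(matrix(0L, 3, 3))), "empty")
  # from score vectors, rows = rater A
  expect_equal(agreement_accuracy(c(1, 2, 3, 3), c(1, 2, 2, 3)), 0.75)
})

test_that("linear weighted kappa reproduces closed forms and frozen values", {
  expect_equal(kappa_linear(confusion_matrix3(diag(c(10, 7, 3))))$estimate, 1)
  # counts proportional to the product of their own marginals: chance level
  chance <- confusion_matrix3(outer(c(5L, 3L, 2L), c(4L, 4L, 2L)))
  expect_equal(kappa_linear(chance)$estimate, 0, tolerance = 1e-9)
  k1 <- kappa_linear(cm_fix)
  expect_equal(k1$estimate, 0.7109826589595376, tolerance = 1e-10)
  expect_equal(k1$se, 0.07599034097908712, tolerance = 1e-9)
  expect_equal(k1$conf_int, c(0.5620443274676086, 0.8599209904514666),
               tolerance = 1e-8)
  k2 <- kappa_linear(cm_fix2)
  expect_equal(k2$estimate, 0.5421245421245422, tolerance = 1e-10)
  expect_equal(k2$se, 0.09044740419763198, tolerance = 1e-9)
  expect_equal(k2$conf_int, c(0.3648508874020466, 0.7193981968470378),
               tolerance = 1e-8)
})

test_that("kappa is transpose-symmetric and invariant to count scaling", {
  for (cm in list(cm_fix, cm_fix2)) {
    kt <- kappa_linear(confusion_matrix3(t(unclass(cm))))
    k <- kappa_linear(cm)
    expect_equal(kt$estimate, k$estimate)
    expect_equal(kt$se, k$se)
    scaled <- kappa_linear(confusion_matrix3(unclass(cm) * 4L))
    expect_equal(scaled$estimate, k$estimate)
    expect_lt(diff(scaled$conf_int), diff(k$conf_int))  # CI narrows with n
  }
})

test_that("kappa on two collapsed categories equals unweighted kappa", {
  skip_if_not_installed("e1071")
  set.seed(51)
  for (rep in 1:5) {
    a <- sample(1:2, 80, replace = TRUE)
    b <- ifelse(runif(80) < 0.7, a, 3 - a)
    tab <- table(factor(a, levels = 1:2), factor(b, levels = 1:2))
    ours <- kappa_linear(matrix(as.numeric(tab), 2, 2))$estimate
    expect_equal(ours, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("degenerate kappa marginals raise instead of returning zero", {
  one_cat <- confusion_matrix3(matrix(c(10, 5, 2, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE))
  expect_error(kappa_linear(one_cat), "single category")
  expect_error(kappa_linear(confusion_matrix3(diag(c(50L, 0L, 0L)))), "single category")
})

test_that("bootstrap kappa CI brackets the estimate", {
  set.seed(52)
  k <- kappa_linear(cm_fix, ci = "bootstrap", boot_reps = 500)
  expect_lt(k$conf_int[1], k$estimate)
  expect_gt(k$conf_int[2], k$estimate)
  expect_true(all(is.finite(k$conf_int)))
})

test_that("ICC(2,1) reproduces the frozen two-rater fixture", {
  a <- c(1, 2, 3, 2, 1, 3, 2, 1, 2, 3, 1, 2)
  b <- c(1, 2, 2, 3, 1, 3, 2, 2, 2, 3, 1, 1)
  r <- icc_scores(a, b)
  expect_equal(r$estimate, 0.728395, tolerance = 1e-6)
  expect_equal(round(r$conf_int, 2), c(0.28, 0.91))
  expect_equal(r$n, 12L)
  # identical non-constant vectors give perfect reliability
  expect_equal(icc_scores(a, a)$estimate, 1)
  expect_error(icc_scores(rep(2, 10), rep(2, 10)), "identical")
})

test_that("ICC forms agree with lme4 variance components on balanced data", {
  skip_if_not_installed("lme4")
  set.seed(53)
  n <- 60
  subj <- rnorm(n, 0, sqrt(0.6))
  rater_eff <- c(0, 0.3)
  y <- cbind(subj + rater_eff[1] + rnorm(n, 0, sqrt(0.4)),
             subj + rater_eff[2] + rnorm(n, 0, sqrt(0.4)))
  ours <- icc_scores(y)$estimate
  d <- data.frame(y = c(y[, 1], y[, 2]),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  fit <- lme4::lmer(y ~ 1 + (1 | subject) + (1 | rater), data = d,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- setNames(vc$vcov, vc$grp)
  ref <- v[["subject"]] / (v[["subject"]] + v[["rater"]] + v[["Residual"]])
  expect_equal(ours, unname(ref), tolerance = 0.02)
})

test_that("ICC estimates break down to zero under subject permutation", {
  set.seed(54)
  n <- 600
  subj <- rnorm(n, 0, 1)
  a <- subj + rnorm(n, 0, 0.3)
  b <- (subj + rnorm(n, 0, 0.3))[sample(n)]  # pairing destroyed
  expect_lt(abs(icc_scores(a, b)$estimate), 0.1)
})

test_that("ICC recovers the intraclass correlation of bivariate normal raters", {
  set.seed(55)
  rho <- 0.7
  n <- 500
  subj <- rnorm(n, 0, sqrt(rho))
  a <- subj + rnorm(n, 0, sqrt(1 - rho))
  b <- subj + rnorm(n, 0, sqrt(1 - rho))
  expect_equal(icc_scores(a, b)$estimate, rho, tolerance = 0.05)
})

test_that("zone intersection rate matches enumeration on known patterns", {
  r2 <- area_to_radius(2)
  same <- data.frame(slide_id = sprintf("s%d", 1:6),
                     x = seq(0, 5e4, by = 1e4), y = 0, radius_um = r2)
  expect_equal(zone_intersection_rate(same, same)$rate, 1)
  apart <- same
  apart$x <- apart$x + 2 * r2 + 1  # just beyond tangency
  expect_equal(zone_intersection_rate(same, apart)$rate, 0)
  # exact tangency counts as intersecting (radii chosen exactly representable)
  left <- data.frame(slide_id = sprintf("t%d", 1:4), x = c(0, 4096, 8192, 12288),
                     y = 0, radius_um = 500)
  tangent <- left
  tangent$x <- tangent$x + 1000
  expect_equal(zone_intersection_rate(left, tangent)$rate, 1)

  set.seed(56)
  n <- 40
  a <- data.frame(slide_id = sprintf("s%d", 1:n),
                  x = runif(n, 0, 2e4), y = runif(n, 0, 2e4),
                  radius_um = r2)
  b <- data.frame(slide_id = a$slide_id,
                  x = a$x + rnorm(n, 0, 1200), y = a$y + rnorm(n, 0, 1200),
                  radius_um = r2)
  want <- mean(sqrt((a$x - b$x)^2 + (a$y - b$y)^2) <= 2 * r2)
  got <- zone_intersection_rate(a, b)
  expect_equal(got$rate, want)
  expect_equal(got$n, n)
})

test_that("one-sided slides are excluded and no-zone flags count as misses", {
  r2 <- area_to_radius(2)
  a <- data.frame(slide_id = c("s1", "s2", "s3"), x = 0, y = 0, radius_um = r2)
  b <- data.frame(slide_id = c("s1", "s2"), x = 0, y = 0, radius_um = r2)
  res <- zone_intersection_rate(a, b)
  expect_equal(res$n, 2L)
  expect_equal(res$excluded, "s3")
  expect_equal(res$rate, 1)
  a$no_zone <- c(FALSE, TRUE, FALSE)
  res2 <- zone_intersection_rate(a, b)
  expect_equal(res2$n, 2L)
  expect_equal(res2$rate, 0.5)  # flagged slide counts as non-intersecting
  # any overlapping zone on side B counts (AI-hotspots variant)
  multi <- data.frame(slide_id = rep("s1", 3),
                      x = c(1e5, 2e5, 100), y = 0, radius_um = r2)
  expect_equal(zone_intersection_rate(a[1, ], multi)$rate, 1)
})

test_that("subgroup reports equal recomputation on manually filtered subsets", {
  set.seed(57)
  n <- 40
  truth <- data.frame(slide_id = sprintf("S%02d", 1:n),
                      score = sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                      specimen_type = sample(c("biopsy", "surgical"), n, TRUE),
                      hotspot_x = runif(n, 0, 1e4), hotspot_y = runif(n, 0, 1e4))
  cfg <- reader_sim_config(truth, seed = 99)
  rec <- simulate_reader_scores(cfg)
  rep_all <- subgroup_report(rec, truth)
  expect_true(all(c("all", "score_1", "biopsy", "surgical") %in% rep_all$stratum))
  # the 'all' rows equal the direct global report
  for (cond in c("without_AI", "with_AI")) {
    direct <- agreement_report(rec, truth, cond)
    row <- rep_all[rep_all$stratum == "all" & rep_all$condition == cond, ]
    expect_equal(row$accuracy, direct$accuracy)
    expect_equal(row$kappa, direct$kappa)
    expect_equal(row$icc, direct$icc)
  }
  # a stratum row equals recomputation on the hand-filtered subset
  ids <- truth$slide_id[truth$specimen_type == "biopsy"]
  direct <- agreement_report(rec[rec$slide_id %in% ids, ],
                             truth[truth$slide_id %in% ids, ], "with_AI")
  row <- rep_all[rep_all$stratum == "biopsy" & rep_all$condition == "with_AI", ]
  expect_equal(row$accuracy, direct$accuracy)
  expect_equal(row$kappa, direct$kappa)
  expect_equal(row$zone_intersection_rate, direct$zone_intersection_rate)
  expect_equal(row$n_slides, direct$n_slides)
})

test_that("perfect-agreement records give accuracy and kappa of one", {
  truth <- data.frame(slide_id = sprintf("S%02d", 1:12),
                      score = rep(1:3, 4))
  rec <- rbind(
    data.frame(slide_id = truth$slide_id, reader_id = "reader1",
               condition = "without_AI", score = truth$score),
    data.frame(slide_id = truth$slide_id, reader_id = "reader2",
               condition = "without_AI", score = truth$score),
    data.frame(slide_id = truth$slide_id, reader_id = "reader1",
               condition = "with_AI", score = truth$score),
    data.frame(slide_id = truth$slide_id, reader_id = "reader2",
               condition = "with_AI", score = truth$score))
  rep1 <- agreement_report(rec, truth, "without_AI")
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$kappa, 1)
  expect_equal(rep1$icc, 1)
})

test_that("sparse strata degrade to NA statistics with n reported", {
  truth <- data.frame(slide_id = c("A", "B", "C"), score = c(1, 1, 2))
  rec <- expand.grid(slide_id = truth$slide_id,
                     reader_id = c("reader1", "reader2"),
                     condition = c("without_AI", "with_AI"),
                     stringsAsFactors = FALSE)
  rec$score <- 1L  # constant scores: kappa/ICC undefined
  rep_df <- subgroup_report(rec, truth)
  row <- rep_df[rep_df$stratum == "all" & rep_df$condition == "with_AI", ]
  expect_true(is.na(row$kappa))
  expect_true(is.na(row$icc))
  expect_equal(row$n_slides, 3L)
})
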