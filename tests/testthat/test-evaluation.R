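test_that("session-averaged correlation matches hand values", {
  pred <- c(1, 2, 3)
  expect_equal(session_avg_corr(pred, rbind(pred, pred)), 1.0)
  expect_equal(session_avg_corr(pred, rbind(c(1, 2, 3), c(3, 2, 1))), 0.0)
  # invariant under a common region permutation
  set.seed(4)
  p <- rnorm(20); obs <- matrix(rnorm(40), 2)
  perm <- sample(20)
  expect_equal(session_avg_corr(p[perm], obs[, perm]),
               session_avg_corr(p, obs))
  expect_error(session_avg_corr(c(1, 1, 1), obs[, 1:3]), "zero-variance")
  expect_error(session_avg_corr(p, matrix(1, 1, 20)), "zero-variance")
  expect_error(session_avg_corr(p[1:3], obs), "region count")
})

test_that("map R-squared is the coefficient of determination", {
  obs <- rbind(c(0, 1, 2))
  expect_equal(map_r2(c(0, 1, 2), obs), 1.0)
  expect_equal(map_r2(rep(1, 3), obs), 0.0)   # predicting the mean
  expect_equal(map_r2(c(0, 0, 0), obs), -1.5) # 1 - (0+1+4)/2
  # averaged over sessions
  expect_equal(map_r2(c(0, 1, 2), rbind(c(0, 1, 2), c(2, 1, 0))),
               mean(c(1, 1 - 8 / 2)))
  expect_error(map_r2(c(0, 1, 2), rbind(c(1, 1, 1))), "zero-variance")
})

test_that("two-way classification assigns maps independently", {
  set.seed(7)
  obs_a <- matrix(rnorm(40), 2); obs_b <- matrix(rnorm(40), 2)
  good <- two_way_classify(colMeans(obs_a), colMeans(obs_b), obs_a, obs_b,
                           tasks = c("x", "y"))
  expect_true(good$correct)
  expect_equal(good$assignment, c("x", "y"))
  # identical predictions are forced to a shared assignment: never correct
  p <- rnorm(20)
  same <- two_way_classify(p, p, obs_a, obs_b)
  expect_false(same$correct)
  expect_equal(same$assignment[1], same$assignment[2])
  # exact tie is broken toward the first task and flagged
  tie <- two_way_classify(c(1, 2, 3), c(1, 2, 3),
                          rbind(c(1, 2, 3)), rbind(c(1, 2, 3)))
  expect_true(tie$tie)
  expect_equal(tie$assignment, c("a", "a"))
})

test_that("identical predictions never classify correctly (property)", {
  set.seed(30)
  for (i in 1:25) {
    p <- rnorm(15)
    oa <- matrix(rnorm(30), 2); ob <- matrix(rnorm(30), 2)
    expect_false(two_way_classify(p, p, oa, ob)$correct)
  }
})

test_that("subject accuracy is the fraction of fully correct splits", {
  expect_equal(subject_accuracy(rep(TRUE, 10)), 1.0)
  expect_equal(subject_accuracy(rep(FALSE, 10)), 0.0)
  expect_equal(subject_accuracy(rep(c(TRUE, FALSE), c(473, 473))), 0.5)
  expect_error(subject_accuracy(logical(0)), "no splits")
})

test_that("noise ceiling is the square root of between-session reliability", {
  nr <- 50
  base <- rnorm(nr)
  # identical sessions -> ceiling 1
  ds <- manual_dataset(list(t1 = rbind(base, base), t2 = rbind(base, -base)))
  nc <- noise_ceiling(ds, "sub01")
  expect_equal(nc$ceiling[nc$task == "t1"], 1.0)
  # negative reliability -> flagged undefined, excluded
  expect_true(is.na(nc$ceiling[nc$task == "t2"]))
  expect_equal(nc$n_undefined[nc$task == "t2"], 1L)
  expect_equal(attr(nc, "n_undefined_total"), 1L)
})

test_that("ceiling averages the two timepoint estimates of 4-session tasks", {
  # construct sessions with exact within-timepoint correlations r1 and r2
  make_pair <- function(r, n = 2000, seed) {
    set.seed(seed)
    x <- rnorm(n)
    y <- r * x + sqrt(1 - r^2) * rnorm(n)
    rbind(x, y)
  }
  s12 <- make_pair(0.64, seed = 1)
  s34 <- make_pair(0.25, seed = 2)
  r1 <- cor(s12[1, ], s12[2, ]); r2 <- cor(s34[1, ], s34[2, ])
  ds <- manual_dataset(list(t1 = rbind(s12, s34),
                            t2 = rbind(s12 + 1, s34)))
  nc <- noise_ceiling(ds, "sub01")
  expect_equal(nc$ceiling[nc$task == "t1"], mean(c(sqrt(r1), sqrt(r2))))
  # the empirical r = 0.64-ish pair alone gives ceiling sqrt(r)
  expect_equal(mean(sqrt(c(r1, r2))), nc$ceiling[1], tolerance = 1e-12)
  expect_error(noise_ceiling(manual_dataset(list(t1 = rbind(rnorm(10)),
                                                 t2 = rbind(rnorm(10), rnorm(10)))),
                             "sub01"), "2 sessions")
})

test_that("aggregation yields 2*C(n,2) values and n-1 task appearances", {
  st <- tiny_study(n_tasks = 6, n_features = 6, n_cognitive = 4,
                   n_regions = 40, n_subjects = 1,
                   n_four_session_tasks = 2, seed = 23)
  cv <- run_subject_cv(st$data, "sub01", st$features, seed = 1)
  agg <- aggregate_metrics(cv, noise_ceiling(st$data, "sub01"))
  expect_equal(agg$subject$n_values, 2 * choose(6, 2))
  expect_true(all(agg$task$n_appearances == 5))
  expect_true(all(abs(agg$task$mean_r) <= 1))
  expect_false(anyNA(agg$task$ceiling))
  # the full-battery arithmetic the summaries emulate
  expect_equal(2 * choose(44, 2), 1892)
})

test_that("model correlation respects the noise ceiling on synthetic data", {
  st <- tiny_study(n_subjects = 1, seed = 61, noise_sd = 1.5)
  cv <- run_subject_cv(st$data, "sub01", st$features, seed = 6)
  agg <- aggregate_metrics(cv, noise_ceiling(st$data, "sub01"))
  expect_lt(agg$subject$mean_r,
            mean(agg$task$ceiling, na.rm = TRUE) + 0.1)
})

test_that("feature-set comparison gives RM-ANOVA F and Bonferroni t-tests", {
  # identical accuracy vectors across sets -> F = 0
  acc <- matrix(rep(runif(5), 3), 5, 3,
                dimnames = list(NULL, c("All", "Cog", "PM")))
  expect_equal(compare_feature_sets(acc)$anova$F, 0)
  # 3 sets x 23 subjects -> df (2, 44), cross-checked against aov()
  set.seed(9)
  A <- matrix(runif(23 * 3), 23, 3, dimnames = list(NULL, c("All", "Cog", "PM")))
  out <- compare_feature_sets(A)
  expect_equal(c(out$anova$df1, out$anova$df2), c(2, 44))
  long <- data.frame(acc = as.vector(A), set = factor(rep(1:3, each = 23)),
                     subj = factor(rep(1:23, 3)))
  ref <- summary(aov(acc ~ set + Error(subj / set), data = long))
  Fref <- ref[["Error: subj:set"]][[1]]["set", "F value"]
  expect_equal(out$anova$F, Fref, tolerance = 1e-10)
  # paired t against stats::t.test with Bonferroni factor 3
  tt <- t.test(A[, 1], A[, 2], paired = TRUE)
  row <- out$pairwise[out$pairwise$set1 == "All" & out$pairwise$set2 == "Cog", ]
  expect_equal(row$t, unname(tt$statistic))
  expect_equal(row$p_bonferroni, min(1, tt$p.value * 3))
  # zero-variance paired difference is degenerate, flagged
  B <- cbind(a = c(1, 2, 3), b = c(0, 1, 2), c = c(3, 1, 2))
  outB <- compare_feature_sets(B)
  expect_true(outB$pairwise$degenerate[outB$pairwise$set1 == "a" &
                                       outB$pairwise$set2 == "b"])
})

test_that("split-type breakdown counts held-out meta-task counterparts", {
  st <- tiny_study(n_tasks = 6, n_features = 6, n_cognitive = 4,
                   n_regions = 40, n_subjects = 1,
                   n_four_session_tasks = 2, seed = 23)
  cv <- run_subject_cv(st$data, "sub01", st$features, seed = 1)
  tasks <- st$data$tasks
  # every task its own meta-task -> all splits labeled 0
  own <- setNames(tasks, tasks)
  bd <- split_type_breakdown(cv, own)
  expect_equal(bd$n_splits, c(choose(6, 2), 0L, 0L))
  # first three tasks share a meta-task (like a 3-condition difficulty set)
  meta <- own
  meta[tasks[1:3]] <- "shared"
  bd2 <- split_type_breakdown(cv, meta)
  expect_equal(sum(bd2$n_splits), choose(6, 2))
  # a pair drawn from the 3-condition meta-task leaves a counterpart in
  # training for both held-out tasks -> labeled 2
  expect_equal(bd2$n_splits[bd2$n_counterparts == 2], choose(3, 2))
  expect_equal(bd2$n_splits[bd2$n_counterparts == 1], 3 * 3)
  expect_error(split_type_breakdown(cv, own[-1]), "cover")
})
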