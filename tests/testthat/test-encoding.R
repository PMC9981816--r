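test_that("ridge limits behave as expected", {
  set.seed(1)
  X <- matrix(runif(8 * 3), 8, 3, dimnames = list(NULL, paste0("f", 1:3)))
  B <- matrix(rnorm(3 * 2), 3, 2)
  Y <- X %*% B
  # vanishing penalty with full-rank X recovers the generating weights
  fit0 <- fit_ridge(X, Y, 1e-10)
  expect_equal(unname(fit0$weights), B, tolerance = 1e-6)
  # infinite penalty shrinks weights to zero, intercepts to column means
  fitInf <- fit_ridge(X, Y, 1e12)
  expect_equal(max(abs(fitInf$weights)), 0, tolerance = 1e-8)
  expect_equal(unname(fitInf$intercepts), unname(colMeans(Y)),
               tolerance = 1e-8)
  expect_error(fit_ridge(X, Y, -1), "positive")
  expect_error(fit_ridge(X, Y[1:4, ], 1), "rows")
  Xbad <- X; Xbad[1] <- NA
  expect_error(fit_ridge(Xbad, Y, 1), "finite")
})

test_that("closed-form ridge matches the optimizer oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:9, 1); p <- sample(2:4, 1); q <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * q), n, q)
    alpha <- sample(c(0.01, 0.5, 1, 5), 1)
    fit <- fit_ridge(X, Y, alpha)
    ora <- ridge_oracle(X, Y, alpha)
    scale <- max(1, max(abs(ora$weights)))
    expect_lt(max(abs(fit$weights - ora$weights)) / scale, 1e-6)
    expect_lt(max(abs(fit$intercepts - ora$intercepts)) /
                max(1, max(abs(ora$intercepts))), 1e-6)
  }
})

test_that("predicted maps are affine in the feature vector", {
  set.seed(2)
  X <- matrix(runif(10 * 4), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  Y <- matrix(rnorm(10 * 5), 10, 5)
  fit <- fit_ridge(X, Y, 1)
  expect_equal(predict_map(fit, setNames(rep(0, 4), paste0("f", 1:4))),
               fit$intercepts)
  a <- runif(4); b <- runif(4)
  names(a) <- names(b) <- paste0("f", 1:4)
  expect_equal(predict_map(fit, a + b),
               predict_map(fit, a) + predict_map(fit, b) - fit$intercepts)
  expect_error(predict_map(fit, setNames(a, paste0("g", 1:4))), "feature ids")
})

test_that("leave-two-out split enumeration is complete and ordered", {
  expect_equal(nrow(leave_two_out_splits(sprintf("t%02d", 1:44))), 946L)
  expect_equal(nrow(leave_two_out_splits(c("a", "b", "c"))), 3L)
  p5 <- leave_two_out_splits(letters[1:5])
  expect_equal(nrow(p5), 10L)
  expect_false(anyDuplicated(paste(p5[, 1], p5[, 2])) > 0)
  expect_true(all(p5[, 1] < p5[, 2]))  # lexicographic, each pair once
  expect_error(leave_two_out_splits(c("a", "b")), "at least 3")
})

test_that("alpha selection favors the smallest penalty on noiseless data", {
  # identifiable design: fewer features than inner-loop training tasks
  st <- tiny_study(n_features = 6, n_cognitive = 4, noise_sd = 0,
                   n_subjects = 1, seed = 21)
  dm <- expand_to_sessions(st$features, st$data$session_counts)
  a <- select_alpha(dm, st$data$maps[[1]], alpha_grid(), k = 10, seed = 4)
  expect_equal(as.numeric(a), 0.001)
  # one-element grid returns without cross-validation
  expect_equal(as.numeric(select_alpha(dm, st$data$maps[[1]],
                                       alpha_grid(5), k = 10)), 5)
  # constant responses score all alphas identically -> smallest wins
  Yc <- matrix(1, nrow(dm$values), 6)
  expect_equal(as.numeric(select_alpha(dm, Yc, alpha_grid(), k = 10,
                                       seed = 4)), 0.001)
  expect_error(select_alpha(dm, st$data$maps[[1]], alpha_grid(), k = 11),
               "fewer tasks")
})

test_that("inner folds group whole tasks", {
  st <- tiny_study(n_subjects = 1, seed = 31)
  dm <- expand_to_sessions(st$features, st$data$session_counts)
  a <- select_alpha(dm, st$data$maps[[1]], alpha_grid(), k = 5, seed = 9)
  folds <- attr(a, "folds")
  expect_setequal(names(folds), st$data$tasks)  # one fold id per task
  expect_equal(sort(unique(unname(folds))), 1:5)
})

test_that("subject CV is perfect on noiseless data and counts splits", {
  # feature count below the inner-loop training-task count keeps every fit
  # identifiable, so noiseless predictions are exact
  st <- tiny_study(n_tasks = 8, n_features = 4, n_cognitive = 2,
                   n_regions = 60, n_networks = 7, n_subjects = 1,
                   n_four_session_tasks = 3, noise_sd = 0, seed = 15)
  cv <- run_subject_cv(st$data, "sub01", st$features, seed = 2)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv$splits), choose(8, 2))
  expect_equal(subject_accuracy(cv), 1.0)
  expect_true(all(cv$splits$alpha %in% alpha_grid()))
})

test_that("metrics are equivariant under region permutation", {
  st <- tiny_study(n_tasks = 6, n_features = 6, n_cognitive = 4,
                   n_regions = 40, n_subjects = 1,
                   n_four_session_tasks = 2, seed = 19)
  cv1 <- run_subject_cv(st$data, "sub01", st$features, seed = 3)
  set.seed(8); perm <- sample(40)
  st2 <- st
  st2$data$maps[[1]] <- st$data$maps[[1]][, perm]
  cv2 <- run_subject_cv(st2$data, "sub01", st$features, seed = 3)
  expect_equal(cv2$splits$r_a, cv1$splits$r_a, tolerance = 1e-12)
  expect_equal(cv2$splits$correct, cv1$splits$correct)
})

test_that("noiseless full fits recover ground-truth subject weights", {
  st <- tiny_study(n_tasks = 8, n_features = 4, n_cognitive = 2,
                   n_regions = 60, n_networks = 7, n_subjects = 2,
                   n_four_session_tasks = 3, noise_sd = 0, seed = 15)
  dm <- expand_to_sessions(st$features, st$data$session_counts)
  for (s in 1:2) {
    fit <- fit_ridge(dm, st$data$maps[[s]], 0.001)
    truthW <- st$truth$subject_weights[[s]]
    cors <- vapply(seq_len(ncol(truthW)),
                   function(r) cor(fit$weights[, r], truthW[, r]),
                   numeric(1))
    expect_gt(min(cors), 0.999)
  }
})
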