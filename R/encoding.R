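#' Regularization grid for the nested cross-validation alpha search
#'
#' @param values Strictly increasing positive ridge penalties. The default
#'   grid spans three decades below 1 plus the integers 1..10.
#' @return Numeric vector of class \code{"alpha_grid"}.
#' @export
alpha_grid <- function(values = c(0.001, 0.01, 0.1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10)) {
  values <- as.numeric(values)
  if (any(values <= 0)) stop("alpha values must be positive")
  if (is.unsorted(values, strictly = TRUE))
    stop("alpha values must be strictly increasing")
  structure(values, class = "alpha_grid")
}

# Ridge solutions for every alpha from a single eigendecomposition of the
# centered Gram matrix. X: n x p design, Y: n x q responses. The intercept
# is unpenalized: columns of X and Y are centered, the penalized normal
# equations solved, and the intercept recovered from the means.
ridge_path <- function(X, Y, alphas) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) == 0L) stop("zero training rows")
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite values in the training data")
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  eg <- eigen(crossprod(Xc), symmetric = TRUE)
  G <- crossprod(eg$vectors, crossprod(Xc, Yc))  # V' X'Y
  lapply(alphas, function(a) {
    W <- eg$vectors %*% (G / (eg$values + a))
    dimnames(W) <- list(colnames(X), colnames(Y))
    list(weights = W, intercepts = ym - drop(xm %*% W))
  })
}

#' Fit region-wise ridge encoding models at a fixed penalty
#'
#' For each region r the weights minimize
#' \code{||y_r - X w - b||^2 + alpha ||w||^2} with an unpenalized intercept
#' \code{b}. All regions share the design, so one eigendecomposition solves
#' every region at once. Features are used on their native \code{[0, 1]}
#' scale; only centering is applied (for the intercept).
#'
#' @param X A \code{\link{design_matrix}} (or bare row x feature matrix).
#' @param Y Row x region activation matrix aligned with \code{X}.
#' @param alpha Positive ridge penalty.
#' @param training_tasks Optional task ids recorded in the fit.
#' @return An object of class \code{"cem_fit"}: \code{weights}
#'   (feature x region), \code{intercepts}, \code{alpha},
#'   \code{training_tasks}, \code{feature_ids}.
#' @export
fit_ridge <- function(X, Y, alpha, training_tasks = NULL) {
  if (inherits(X, "design_matrix")) {
    if (is.null(training_tasks)) training_tasks <- unique(X$task)
    X <- X$values
  }
  if (length(alpha) != 1L || alpha <= 0) stop("alpha must be a positive scalar")
  sol <- ridge_path(X, Y, alpha)[[1L]]
  structure(list(weights = sol$weights, intercepts = sol$intercepts,
                 alpha = alpha, training_tasks = training_tasks,
                 feature_ids = colnames(X)),
            class = "cem_fit")
}

#' Predict an activation map from a feature vector
#'
#' @param fit A \code{\link{fit_ridge}} result.
#' @param feature_vector Named (or positionally aligned) feature vector.
#' @return Numeric per-region prediction
#'   \code{feature_vector \%*\% weights + intercepts}.
#' @export
predict_map <- function(fit, feature_vector) {
  fv <- feature_vector
  if (!is.null(names(fv)) && !is.null(fit$feature_ids)) {
    if (!setequal(names(fv), fit$feature_ids))
      stop("feature ids do not match the fitted model")
    fv <- fv[fit$feature_ids]
  } else if (length(fv) != nrow(fit$weights)) {
    stop("feature vector length does not match the fitted model")
  }
  drop(fv %*% fit$weights) + fit$intercepts
}

#' Enumerate leave-two-out cross-validation splits
#'
#' All \code{choose(n, 2)} unordered task pairs, each once, in deterministic
#' lexicographic order. With the 44 tasks of the emulated battery this gives
#' 946 splits.
#'
#' @param tasks Character vector of task ids (>= 3).
#' @return Two-column character matrix, one row per pair.
#' @export
leave_two_out_splits <- function(tasks) {
  tasks <- as.character(tasks)
  if (length(tasks) < 3L) stop("need at least 3 tasks for leave-two-out CV")
  idx <- utils::combn(length(tasks), 2L)
  cbind(a = tasks[idx[1L, ]], b = tasks[idx[2L, ]])
}

#' Select the ridge penalty by grouped k-fold cross-validation
#'
#' Tasks -- not rows -- are partitioned into \code{k} seeded folds, so a
#' task's 2--4 session rows never straddle train and validation. For each
#' candidate alpha the model is fit on k-1 folds and every held-out row is
#' scored by the Pearson correlation between its predicted and observed
#' region map; the score is the mean over held-out rows. The alpha with the
#' highest mean score wins; ties go to the smallest alpha.
#'
#' @param X A \code{\link{design_matrix}}.
#' @param Y Aligned row x region activation matrix.
#' @param grid An \code{\link{alpha_grid}}.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Selected alpha (scalar), with the per-alpha mean scores and the
#'   fold assignment attached as attributes \code{"scores"} and
#'   \code{"folds"}.
#' @export
select_alpha <- function(X, Y, grid = alpha_grid(), k = 10L, seed = 1L) {
  if (!inherits(X, "design_matrix")) stop("X must be a design_matrix")
  tasks <- unique(X$task)
  if (length(grid) == 1L) return(as.numeric(grid))
  if (length(tasks) < k)
    stop(sprintf("fewer tasks (%d) than folds (%d)", length(tasks), k))
  folds <- with_seed(seed,
    stats::setNames(sample(rep_len(seq_len(k), length(tasks))), tasks))
  per_row <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- X$task %in% names(folds)[folds == f]
    sols <- ridge_path(X$values[!hold, , drop = FALSE],
                       Y[!hold, , drop = FALSE], as.numeric(grid))
    Xh <- X$values[hold, , drop = FALSE]
    Yh <- Y[hold, , drop = FALSE]
    per_row[[f]] <- vapply(sols, function(s) {
      P <- Xh %*% s$weights +
        matrix(s$intercepts, nrow(Xh), ncol(Yh), byrow = TRUE)
      vapply(seq_len(nrow(Xh)),
             function(i) row_cor(P[i, ], Yh[i, ]), numeric(1))
    }, numeric(sum(hold)))
    if (sum(hold) == 1L) per_row[[f]] <- matrix(per_row[[f]], 1L)
  }
  all_rows <- do.call(rbind, per_row)        # held-out rows x alphas
  mean_scores <- colMeans(all_rows)
  best <- which(mean_scores >= max(mean_scores) - 1e-12)[1L]
  structure(as.numeric(grid)[best], scores = mean_scores, folds = folds)
}

# Pearson r that tolerates zero variance (returns 0 instead of NA): inner-CV
# scoring must not fail on a degenerate constant prediction.
row_cor <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

#' Run the full leave-two-out encoding-model pipeline for one subject
#'
#' For every unordered pair of tasks: all session rows of the two held-out
#' tasks are removed from training; the penalty is selected on the remaining
#' tasks by \code{\link{select_alpha}} (fold count clamped to the number of
#' training tasks when the task set is small); region-wise models are fit at
#' that penalty; one map is predicted per held-out task; the pair is scored
#' by session-averaged correlation, R-squared and two-way classification.
#'
#' @param dataset An \code{\link{generate_activations}}-shaped dataset.
#' @param subject Subject id (name in \code{dataset$maps}).
#' @param fm The \code{\link{feature_matrix}} to encode from.
#' @param grid An \code{\link{alpha_grid}}.
#' @param k Inner fold count (default 10, clamped to the training task count).
#' @param seed Integer seed for inner-CV fold draws.
#' @param store_predictions Keep the predicted maps per split (default FALSE).
#' @return Object of class \code{"cv_result"}: \code{splits} data.frame (one
#'   row per split: tasks, alpha, per-task r and R2, assignments, tie flag,
#'   correct), \code{subject}, \code{tasks}, and optionally
#'   \code{predictions}.
#' @export
run_subject_cv <- function(dataset, subject, fm, grid = alpha_grid(),
                           k = 10L, seed = 1L, store_predictions = FALSE) {
  stopifnot(subject %in% names(dataset$maps))
  fm <- fm_for_dataset(fm, dataset)
  Y <- dataset$maps[[subject]]
  design <- expand_to_sessions(fm, dataset$session_counts)
  stopifnot(identical(design$task, dataset$info$task))
  pairs <- leave_two_out_splits(dataset$tasks)
  n <- nrow(pairs)
  res <- data.frame(task_a = pairs[, 1L], task_b = pairs[, 2L],
                    alpha = NA_real_, r_a = NA_real_, r_b = NA_real_,
                    r2_a = NA_real_, r2_b = NA_real_,
                    assign_a = NA_character_, assign_b = NA_character_,
                    tie = FALSE, correct = NA, stringsAsFactors = FALSE)
  preds <- if (store_predictions) vector("list", n) else NULL
  for (i in seq_len(n)) {
    ta <- pairs[i, 1L]; tb <- pairs[i, 2L]
    train <- !(design$task %in% c(ta, tb))
    Xtr <- structure(list(values = design$values[train, , drop = FALSE],
                          task = design$task[train],
                          session = design$session[train]),
                     class = "design_matrix")
    stopifnot(!any(c(ta, tb) %in% Xtr$task))  # no-leakage guard
    k_eff <- min(k, length(unique(Xtr$task)))
    a <- select_alpha(Xtr, Y[train, , drop = FALSE], grid, k = k_eff,
                      seed = seed + i)
    fit <- fit_ridge(Xtr, Y[train, , drop = FALSE], as.numeric(a))
    pa <- predict_map(fit, fm$values[ta, ])
    pb <- predict_map(fit, fm$values[tb, ])
    obs_a <- Y[design$task == ta, , drop = FALSE]
    obs_b <- Y[design$task == tb, , drop = FALSE]
    cls <- two_way_classify(pa, pb, obs_a, obs_b, tasks = c(ta, tb))
    res$alpha[i] <- as.numeric(a)
    res$r_a[i] <- session_avg_corr(pa, obs_a)
    res$r_b[i] <- session_avg_corr(pb, obs_b)
    res$r2_a[i] <- map_r2(pa, obs_a)
    res$r2_b[i] <- map_r2(pb, obs_b)
    res$assign_a[i] <- cls$assignment[1L]
    res$assign_b[i] <- cls$assignment[2L]
    res$tie[i] <- cls$tie
    res$correct[i] <- cls$correct
    if (store_predictions) preds[[i]] <- rbind(a = pa, b = pb)
  }
  structure(list(splits = res, subject = subject, tasks = dataset$tasks,
                 predictions = preds),
            class = "cv_result")
}

# Reorder/validate a feature matrix against a dataset's task set.
fm_for_dataset <- function(fm, dataset) {
  if (!setequal(task_ids(fm), dataset$tasks))
    stop("feature matrix and dataset cover different task sets")
  feature_matrix(fm$values[dataset$tasks, , drop = FALSE],
                 fm$feature_class, fm$parametric)
}
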