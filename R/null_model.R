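#' Sample a task permutation for the shuffled null model
#'
#' Tasks are bijectively remapped to one another so each task inherits the
#' feature vector of its donor. The global identity permutation is excluded
#' (every task keeping its own vector would reproduce the real model);
#' individual fixed points are allowed unless \code{forbid_fixed_points}
#' requests a full derangement. Each iteration's permutation is
#' reconstructible from \code{(seed, iteration)}.
#'
#' @param tasks Character vector of task ids.
#' @param seed Integer base seed.
#' @param iteration Iteration index (>= 1).
#' @param forbid_fixed_points Require a derangement (default FALSE).
#' @return Named character vector: \code{perm[t]} is the donor task of t.
#' @export
task_permutation <- function(tasks, seed = 1L, iteration = 1L,
                             forbid_fixed_points = FALSE) {
  tasks <- as.character(tasks)
  if (length(tasks) < 2L) stop("need >= 2 tasks to permute")
  with_seed(seed + 1000L * as.integer(iteration), {
    repeat {
      p <- sample(tasks)
      fixed <- p == tasks
      if (forbid_fixed_points && any(fixed)) next
      if (!all(fixed)) break
    }
    stats::setNames(p, tasks)
  })
}

#' Remap tasks' feature vectors under a permutation
#'
#' Task t's feature row becomes the row of its donor \code{perm[t]}. Task
#' order, feature classes and session counts are untouched, so when the
#' matrix is expanded to sessions all 2--4 rows of a task carry the donor's
#' vector (blocks of tasks preserved; column densities are not, since a
#' four-session task can inherit a two-session donor's vector).
#'
#' @param fm A \code{\link{feature_matrix}}.
#' @param perm A \code{\link{task_permutation}} (named bijection).
#' @return A \code{feature_matrix} with remapped rows.
#' @export
shuffle_features <- function(fm, perm) {
  tids <- task_ids(fm)
  if (!setequal(names(perm), tids) || !setequal(perm, tids))
    stop("permutation must be a bijection over the task set")
  if (anyDuplicated(perm)) stop("permutation must be a bijection over the task set")
  vals <- fm$values[perm[tids], , drop = FALSE]
  rownames(vals) <- tids
  feature_matrix(vals, fm$feature_class, fm$parametric)
}

#' Run the task-shuffled permutation null model
#'
#' For each iteration a task permutation is sampled, the feature matrix
#' shuffled, and the full nested-CV pipeline
#' (\code{\link{run_subject_cv}}) re-run; per-subject accuracy, map r and
#' R-squared are averaged across iterations. Because the shuffled features
#' carry no information about the tasks, the fitted models are biased
#' toward the training-mean map; both held-out predictions then tend to be
#' assigned to the same task, pushing accuracy below the 25\% chance level.
#'
#' @param dataset An \code{\link{generate_activations}}-shaped dataset.
#' @param subject Subject id.
#' @param fm The unshuffled \code{\link{feature_matrix}}.
#' @param grid An \code{\link{alpha_grid}}.
#' @param n_iter Number of permutation iterations (default 20).
#' @param k Inner fold count (default 10, clamped downstream).
#' @param seed Integer base seed.
#' @param forbid_fixed_points Passed to \code{\link{task_permutation}}.
#' @return List: \code{summary} (one row: subject, n_iter, mean accuracy /
#'   r / R2 across iterations), \code{per_iteration} data.frame, and
#'   \code{permutations} (list, one named vector per iteration).
#' @export
run_null <- function(dataset, subject, fm, grid = alpha_grid(),
                     n_iter = 20L, k = 10L, seed = 1L,
                     forbid_fixed_points = FALSE) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  perms <- vector("list", n_iter)
  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    perms[[it]] <- task_permutation(dataset$tasks, seed = seed,
                                    iteration = it,
                                    forbid_fixed_points = forbid_fixed_points)
    cv <- run_subject_cv(dataset, subject, shuffle_features(fm, perms[[it]]),
                         grid, k = k, seed = seed + 7L * it)
    agg <- aggregate_metrics(cv)$subject
    rows[[it]] <- data.frame(iteration = it, accuracy = agg$accuracy,
                             mean_r = agg$mean_r, mean_r2 = agg$mean_r2)
  }
  per_it <- do.call(rbind, rows)
  list(summary = data.frame(subject = subject, n_iter = n_iter,
                            accuracy = mean(per_it$accuracy),
                            mean_r = mean(per_it$mean_r),
                            mean_r2 = mean(per_it$mean_r2)),
       per_iteration = per_it, permutations = perms)
}
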