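#' Session-averaged map correlation
#'
#' A predicted task map is compared with each of the task's observed session
#' maps by Pearson correlation across regions, and the correlations are
#' averaged over sessions.
#'
#' @param pred Numeric per-region predicted map.
#' @param observed Session x region matrix (2 or 4 rows in the emulated
#'   dataset; at least 1).
#' @return Mean Pearson r over sessions.
#' @export
session_avg_corr <- function(pred, observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 1L) stop("need at least one observed session map")
  if (length(pred) != ncol(observed))
    stop("prediction and observed maps differ in region count")
  if (length(pred) < 3L) stop("need at least 3 regions for a correlation")
  if (stats::sd(pred) == 0)
    stop("zero-variance predicted map: correlation undefined")
  rs <- apply(observed, 1L, function(o) {
    if (stats::sd(o) == 0)
      stop("zero-variance observed map: correlation undefined")
    stats::cor(pred, o)
  })
  mean(rs)
}

#' Session-averaged coefficient of determination
#'
#' Per session, \code{R2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)}
#' over regions -- the coefficient of determination about the observed map's
#' mean, which can be negative -- averaged over sessions.
#'
#' @inheritParams session_avg_corr
#' @return Mean R-squared over sessions.
#' @export
map_r2 <- function(pred, observed) {
  observed <- as.matrix(observed)
  if (length(pred) != ncol(observed))
    stop("prediction and observed maps differ in region count")
  vals <- apply(observed, 1L, function(o) {
    ss_tot <- sum((o - mean(o))^2)
    if (ss_tot == 0)
      stop("zero-variance observed map: R-squared undefined")
    1 - sum((o - pred)^2) / ss_tot
  })
  mean(vals)
}

#' Two-way correlation-based minimum-distance classification
#'
#' Each of the two predicted maps is independently assigned to whichever of
#' the two held-out tasks gives the larger session-averaged correlation.
#' Because the assignments are independent, both predictions can point at
#' the same task (then the split can never be correct -- the mechanism that
#' pushes a mean-biased null model below the 25\% chance level), and chance
#' for a random classifier is 1/4. Exact ties are broken toward the first
#' task and flagged.
#'
#' @param pred_a,pred_b Predicted per-region maps for tasks a and b.
#' @param obs_a,obs_b Session x region observed maps for tasks a and b.
#' @param tasks Length-2 character vector of task ids (default
#'   \code{c("a", "b")}).
#' @return List: \code{assignment} (length 2, the task each prediction was
#'   assigned to), \code{correct} (both assigned to their own task),
#'   \code{tie} (any exact tie occurred).
#' @export
two_way_classify <- function(pred_a, pred_b, obs_a, obs_b,
                             tasks = c("a", "b")) {
  stopifnot(length(tasks) == 2L)
  assign_one <- function(pred) {
    raa <- session_avg_corr(pred, obs_a)
    rab <- session_avg_corr(pred, obs_b)
    list(task = if (raa >= rab) tasks[1L] else tasks[2L],
         tie = raa == rab)
  }
  a <- assign_one(pred_a)
  b <- assign_one(pred_b)
  list(assignment = c(a$task, b$task),
       correct = a$task == tasks[1L] && b$task == tasks[2L],
       tie = a$tie || b$tie)
}

#' Two-way classification accuracy over splits
#'
#' The fraction of leave-two-out splits in which both predicted maps were
#' classified correctly.
#'
#' @param splits A \code{\link{run_subject_cv}} result, or its \code{splits}
#'   data.frame, or a logical vector of per-split outcomes.
#' @return Accuracy in \code{[0, 1]}.
#' @export
subject_accuracy <- function(splits) {
  correct <- split_correct(splits)
  if (length(correct) == 0L) stop("no splits supplied")
  mean(correct)
}

split_correct <- function(splits) {
  if (inherits(splits, "cv_result")) splits <- splits$splits
  if (is.data.frame(splits)) splits <- splits$correct
  as.logical(splits)
}

#' Noise ceilings from between-session reliability
#'
#' The explainable-accuracy ceiling of a task's activation map is the square
#' root of its between-session reliability: Pearson r between the two
#' session maps acquired at the same timepoint, square-rooted. Tasks
#' observed at two timepoints contribute two such estimates, which are
#' averaged. Non-positive reliabilities leave the ceiling undefined for that
#' pair; those estimates are excluded (and counted) rather than clipped.
#'
#' @param dataset An \code{\link{generate_activations}}-shaped dataset.
#' @param subject Subject id.
#' @return data.frame with columns \code{task}, \code{ceiling} (NA when all
#'   of a task's reliabilities are non-positive), \code{n_undefined};
#'   attribute \code{"n_undefined_total"}.
#' @export
noise_ceiling <- function(dataset, subject) {
  out <- do.call(rbind, lapply(dataset$tasks, function(t) {
    idx <- which(dataset$info$task == t)
    if (length(idx) < 2L) stop("need at least 2 sessions per task")
    maps <- dataset$maps[[subject]][idx, , drop = FALSE]
    tp <- dataset$info$timepoint[idx]
    vals <- unlist(lapply(unique(tp), function(p) {
      m <- maps[tp == p, , drop = FALSE]
      if (nrow(m) < 2L) return(numeric(0))
      stats::cor(m[1L, ], m[2L, ])
    }))
    undef <- sum(vals <= 0)
    ok <- vals[vals > 0]
    data.frame(task = t,
               ceiling = if (length(ok)) mean(sqrt(ok)) else NA_real_,
               n_undefined = undef, stringsAsFactors = FALSE)
  }))
  structure(out, n_undefined_total = sum(out$n_undefined))
}

#' Aggregate split-level metrics into subject and task summaries
#'
#' With n tasks each split yields two per-task session-averaged values, so a
#' full run gives \code{2 * choose(n, 2)} correlations per subject (1892 for
#' 44 tasks), each task appearing in n-1 splits. The subject summary is the
#' mean accuracy, map r and R-squared over those values; the task summary
#' pairs each task's mean r with its noise ceiling.
#'
#' @param cv A \code{\link{run_subject_cv}} result.
#' @param ceilings Optional \code{\link{noise_ceiling}} table to join.
#' @return List with \code{subject} (one-row data.frame: subject, n_splits,
#'   accuracy, mean_r, mean_r2, n_values) and \code{task} (data.frame:
#'   task, mean_r, mean_r2, n_appearances, and ceiling when supplied).
#' @export
aggregate_metrics <- function(cv, ceilings = NULL) {
  sp <- cv$splits
  long <- data.frame(task = c(sp$task_a, sp$task_b),
                     r = c(sp$r_a, sp$r_b),
                     r2 = c(sp$r2_a, sp$r2_b), stringsAsFactors = FALSE)
  subject <- data.frame(subject = cv$subject, n_splits = nrow(sp),
                        accuracy = mean(sp$correct),
                        mean_r = mean(long$r), mean_r2 = mean(long$r2),
                        n_values = nrow(long), stringsAsFactors = FALSE)
  task <- do.call(rbind, lapply(cv$tasks, function(t) {
    sel <- long$task == t
    data.frame(task = t, mean_r = mean(long$r[sel]),
               mean_r2 = mean(long$r2[sel]), n_appearances = sum(sel),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ceilings))
    task$ceiling <- ceilings$ceiling[match(task$task, ceilings$task)]
  list(subject = subject, task = task)
}

#' Compare feature sets by repeated-measures ANOVA and paired t-tests
#'
#' Given per-subject accuracies under each feature set (All, Cognitive,
#' Perceptual-Motor), computes the one-way repeated-measures ANOVA F with
#' \code{(k - 1, (k - 1)(n - 1))} degrees of freedom (subject as the
#' repeated factor), followed by paired-samples t-tests for every pair of
#' sets with Bonferroni correction (p multiplied by the number of pairs,
#' capped at 1). Zero-variance paired differences yield a degenerate t,
#' flagged rather than dropped.
#'
#' @param accuracies data.frame or matrix: one row per subject, one column
#'   per feature set (same subjects in every column).
#' @return List: \code{anova} (F, df1, df2, p) and \code{pairwise}
#'   (data.frame: set1, set2, t, df, p_bonferroni, degenerate).
#' @export
compare_feature_sets <- function(accuracies) {
  A <- as.matrix(accuracies)
  if (anyNA(A)) stop("missing accuracies; subject sets must match")
  n <- nrow(A); k <- ncol(A)
  if (k < 2L || n < 2L) stop("need >= 2 feature sets and >= 2 subjects")
  grand <- mean(A)
  ss_set <- n * sum((colMeans(A) - grand)^2)
  ss_subj <- k * sum((rowMeans(A) - grand)^2)
  ss_tot <- sum((A - grand)^2)
  ss_err <- ss_tot - ss_set - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  F <- if (ss_err == 0) {
    if (ss_set == 0) 0 else Inf
  } else (ss_set / df1) / (ss_err / df2)
  pairs <- utils::combn(k, 2L)
  pw <- do.call(rbind, apply(pairs, 2L, function(ix) {
    d <- A[, ix[1L]] - A[, ix[2L]]
    degenerate <- stats::sd(d) == 0
    if (degenerate) {
      t <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(A[, ix[1L]], A[, ix[2L]], paired = TRUE)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(set1 = colnames(A)[ix[1L]] %||% ix[1L],
               set2 = colnames(A)[ix[2L]] %||% ix[2L],
               t = t, df = n - 1L,
               p_bonferroni = min(1, p * ncol(pairs)),
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  list(anova = data.frame(F = F, df1 = df1, df2 = df2,
                          p = stats::pf(F, df1, df2, lower.tail = FALSE)),
       pairwise = pw)
}

#' Accuracy by train/test relatedness of the held-out pair
#'
#' Some task conditions derive from the same meta-task (e.g. easy/medium/
#' hard variants). Each leave-two-out split is labeled 0, 1 or 2 by how many
#' of its held-out tasks have a same-meta-task counterpart among the
#' training tasks, and accuracy is reported per label -- checking that
#' generalization is not an artifact of such train/test dependencies.
#'
#' @param splits A \code{\link{run_subject_cv}} result or \code{splits}
#'   data.frame.
#' @param meta Named character vector mapping every task id to its meta-task.
#' @return data.frame: \code{n_counterparts} (0/1/2), \code{n_splits},
#'   \code{accuracy} (NA for empty labels).
#' @export
split_type_breakdown <- function(splits, meta) {
  if (inherits(splits, "cv_result")) splits <- splits$splits
  all_tasks <- unique(c(splits$task_a, splits$task_b))
  if (!all(all_tasks %in% names(meta)))
    stop("meta-task mapping does not cover all tasks")
  label <- vapply(seq_len(nrow(splits)), function(i) {
    held <- c(splits$task_a[i], splits$task_b[i])
    train <- setdiff(all_tasks, held)
    sum(vapply(held, function(t) meta[t] %in% meta[train], logical(1)))
  }, numeric(1))
  do.call(rbind, lapply(0:2, function(l) {
    sel <- label == l
    data.frame(n_counterparts = l, n_splits = sum(sel),
               accuracy = if (any(sel)) mean(splits$correct[sel]) else NA_real_)
  }))
}
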