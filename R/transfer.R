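#' Fit a subject's encoding model on all tasks
#'
#' Trains on every session row (no outer hold-out); the penalty is selected
#' by the same grouped inner k-fold procedure as the cross-validated models,
#' over the full task set.
#'
#' @inheritParams run_subject_cv
#' @return A \code{\link{fit_ridge}} result.
#' @export
fit_full <- function(dataset, subject, fm, grid = alpha_grid(),
                     k = 10L, seed = 1L) {
  fm <- fm_for_dataset(fm, dataset)
  design <- expand_to_sessions(fm, dataset$session_counts)
  Y <- dataset$maps[[subject]]
  k_eff <- min(k, length(dataset$tasks))
  a <- select_alpha(design, Y, grid, k = k_eff, seed = seed)
  fit_ridge(design, Y, as.numeric(a))
}

#' Between-subject transfer of encoding models
#'
#' Each source subject's full-data model predicts all task maps; on every
#' target subject (self included, computed identically) the predictions are
#' scored by two-way classification over every task pair against the
#' target's observed session maps. Cell (source, target) is the fraction of
#' pairs with both maps classified correctly; a companion matrix holds the
#' mean session-averaged correlation.
#'
#' @param fits Named list of \code{\link{fit_full}} results, one per source
#'   subject.
#' @param dataset Dataset holding every target subject's maps.
#' @param fm The shared \code{\link{feature_matrix}}.
#' @return List: \code{accuracy} (source x target matrix in \code{[0, 1]}),
#'   \code{mean_r} (source x target mean correlation).
#' @export
transfer_evaluate <- function(fits, dataset, fm) {
  fm <- fm_for_dataset(fm, dataset)
  tasks <- dataset$tasks
  sources <- names(fits)
  targets <- names(dataset$maps)
  pairs <- leave_two_out_splits(tasks)
  preds <- lapply(fits, function(f) {
    if (!setequal(f$feature_ids, feature_ids(fm)))
      stop("fit and feature matrix use different feature spaces")
    P <- t(apply(fm$values, 1L, function(v) predict_map(f, v)))
    rownames(P) <- tasks
    P
  })
  acc <- matrix(NA_real_, length(sources), length(targets),
                dimnames = list(sources, targets))
  mr <- acc
  for (tg in targets) {
    obs <- lapply(tasks, function(t) task_sessions(dataset, tg, t))
    names(obs) <- tasks
    for (sc in sources) {
      P <- preds[[sc]]
      correct <- logical(nrow(pairs))
      rs <- numeric(nrow(pairs) * 2L)
      for (i in seq_len(nrow(pairs))) {
        ta <- pairs[i, 1L]; tb <- pairs[i, 2L]
        cls <- two_way_classify(P[ta, ], P[tb, ], obs[[ta]], obs[[tb]],
                                tasks = c(ta, tb))
        correct[i] <- cls$correct
        rs[2L * i - 1L] <- session_avg_corr(P[ta, ], obs[[ta]])
        rs[2L * i] <- session_avg_corr(P[tb, ], obs[[tb]])
      }
      acc[sc, tg] <- mean(correct)
      mr[sc, tg] <- mean(rs)
    }
  }
  list(accuracy = acc, mean_r = mr)
}

#' Summarize a transfer matrix
#'
#' @param transfer A \code{\link{transfer_evaluate}} result.
#' @return data.frame: per source subject, self-transfer accuracy and mean
#'   cross-subject (off-diagonal) accuracy.
#' @export
transfer_summary <- function(transfer) {
  acc <- transfer$accuracy
  do.call(rbind, lapply(rownames(acc), function(s) {
    others <- setdiff(colnames(acc), s)
    data.frame(source = s, self = acc[s, s],
               cross = if (length(others)) mean(acc[s, others]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
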