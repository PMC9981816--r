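#' Build the task confusion matrix from classification outcomes
#'
#' For every split of every subject, each of the two predicted maps
#' increments \code{counts[true task, assigned task]}. With n tasks and S
#' subjects, every row sums to \code{(n - 1) * S} and the total count is
#' \code{2 * choose(n, 2) * S}.
#'
#' @param cv_results A \code{\link{run_subject_cv}} result or list of them
#'   (one per subject), all over the same task set.
#' @return Task x task integer matrix (rows = true held-out task, columns =
#'   assigned task).
#' @export
build_confusion <- function(cv_results) {
  if (inherits(cv_results, "cv_result")) cv_results <- list(cv_results)
  tasks <- cv_results[[1L]]$tasks
  for (cv in cv_results)
    if (!setequal(cv$tasks, tasks)) stop("inconsistent task sets")
  conf <- matrix(0L, length(tasks), length(tasks),
                 dimnames = list(tasks, tasks))
  for (cv in cv_results) {
    sp <- cv$splits
    for (i in seq_len(nrow(sp))) {
      conf[sp$task_a[i], sp$assign_a[i]] <- conf[sp$task_a[i], sp$assign_a[i]] + 1L
      conf[sp$task_b[i], sp$assign_b[i]] <- conf[sp$task_b[i], sp$assign_b[i]] + 1L
    }
  }
  conf
}

#' Project the confusion matrix into cognitive space
#'
#' Rows of the confusion matrix are normalized to classification
#' probabilities, then multiplied by the feature matrix:
#' \code{P \%*\% fm$values}. Row normalization keeps tasks with many
#' appearances from dominating the projection; \code{normalize = FALSE}
#' uses raw counts.
#'
#' @param conf A \code{\link{build_confusion}} matrix.
#' @param fm A \code{\link{feature_matrix}} with matching task order.
#' @param normalize Row-normalize before projecting (default TRUE).
#' @return Task x feature numeric matrix.
#' @export
project_to_cognitive <- function(conf, fm, normalize = TRUE) {
  if (!identical(rownames(conf), task_ids(fm)) ||
      !identical(colnames(conf), task_ids(fm)))
    stop("confusion matrix and feature matrix must share task order")
  M <- conf
  if (normalize) {
    rs <- rowSums(M)
    if (any(rs == 0)) stop("confusion matrix has an empty row")
    M <- M / rs
  }
  M %*% fm$values
}

#' Representational dissimilarity matrix over features
#'
#' Pairwise \code{1 - Pearson r} between feature columns of the projected
#' task x feature matrix: symmetric, zero diagonal, values in \code{[0, 2]}.
#'
#' @param projected Task x feature matrix (e.g. from
#'   \code{\link{project_to_cognitive}}); columns must be non-constant.
#' @return Feature x feature distance matrix.
#' @export
feature_rdm <- function(projected) {
  if (ncol(projected) < 2L) stop("need at least 2 features")
  sds <- apply(projected, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant feature column(s): ",
         paste(colnames(projected)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(projected)
  diag(d) <- 0
  d
}

#' UPGMA hierarchical clustering of a dissimilarity matrix
#'
#' Average-linkage agglomerative clustering (UPGMA): the distance between
#' two clusters is the arithmetic mean of all between-cluster member-pair
#' distances. Returns the merge table in \code{\link[stats]{hclust}} form
#' plus a Newick export of the dendrogram.
#'
#' @param rdm Symmetric distance matrix (e.g. \code{\link{feature_rdm}}).
#' @return List: \code{hclust} (the stats::hclust object), \code{merge},
#'   \code{height}, \code{newick} (string).
#' @export
upgma_cluster <- function(rdm) {
  if (anyNA(rdm)) stop("distance matrix contains NA")
  hc <- stats::hclust(stats::as.dist(rdm), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, merge = hc$merge, height = hc$height, newick = newick)
}
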