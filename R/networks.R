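#' Network-wise feature importances from encoding weights
#'
#' Aggregates regional model coefficients in two stages matching the order
#' of the analysis: for each region and feature, coefficients are first
#' averaged across subjects; the subject-averaged values are then averaged
#' across the regions of each resting-state network.
#'
#' @param weights_list List of feature x region weight matrices, one per
#'   subject (e.g. \code{fit$weights} from \code{\link{fit_full}}).
#' @param atlas Integer or character vector of network labels, one per
#'   region.
#' @return Network x feature matrix of mean coefficients.
#' @export
network_importance <- function(weights_list, atlas) {
  if (!length(weights_list)) stop("no weight matrices supplied")
  nr <- ncol(weights_list[[1L]])
  for (W in weights_list)
    if (!identical(dim(W), dim(weights_list[[1L]])))
      stop("weight matrices differ in shape")
  if (length(atlas) != nr) stop("every region needs a network label")
  if (anyNA(atlas)) stop("unlabeled region(s) in the atlas")
  Wbar <- Reduce(`+`, weights_list) / length(weights_list)
  nets <- sort(unique(atlas))
  imp <- t(vapply(nets, function(k)
    rowMeans(Wbar[, atlas == k, drop = FALSE]),
    numeric(nrow(Wbar))))
  dimnames(imp) <- list(as.character(nets), rownames(weights_list[[1L]]))
  imp
}

#' Within- vs between-network similarity of encoding coefficients
#'
#' Every pair of regions is scored by the Pearson correlation of their
#' subject-averaged feature-weight vectors; the statistic is the mean
#' within-network correlation minus the mean between-network correlation.
#' Its null distribution comes from permuting the region-to-network labels
#' \code{n_perm} times; the p-value counts permuted differences at least as
#' large as the observed one, with the observed statistic included in the
#' denominator so \code{p >= 1 / (n_perm + 1)}.
#'
#' @param mean_weights Feature x region matrix of subject-averaged weights.
#' @param atlas Network label per region; every network needs >= 2 regions.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed.
#' @return List: \code{within}, \code{between} (mean correlations),
#'   \code{difference}, \code{p} (permutation p-value), \code{n_perm}.
#' @export
within_between_similarity <- function(mean_weights, atlas, n_perm = 100L,
                                      seed = 1L) {
  nr <- ncol(mean_weights)
  if (length(atlas) != nr) stop("every region needs a network label")
  if (any(table(atlas) < 2L))
    stop("every network needs at least 2 regions")
  C <- stats::cor(mean_weights)      # region x region
  ut <- upper.tri(C)
  stat <- function(lab) {
    same <- outer(lab, lab, `==`)[ut]
    c(within = mean(C[ut][same]), between = mean(C[ut][!same]))
  }
  obs <- stat(atlas)
  d_obs <- obs["within"] - obs["between"]
  d_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    s <- stat(sample(atlas))
    s["within"] - s["between"]
  }, numeric(1)))
  p <- (1 + sum(d_perm >= d_obs)) / (1 + n_perm)
  list(within = unname(obs["within"]), between = unname(obs["between"]),
       difference = unname(d_obs), p = p, n_perm = n_perm)
}

#' Word-cloud sizes for one network's feature importances
#'
#' Keeps only positive-weight features and maps coefficient magnitude
#' directly to relative size: a feature with twice the magnitude of another
#' gets twice the size. Intended for rendering as a word cloud; the output
#' here is the size table.
#'
#' @param importance A \code{\link{network_importance}} matrix.
#' @param network Row name (or index) of the network.
#' @return Named numeric vector of relative sizes (max = 1), decreasing;
#'   empty (with a warning) if no feature has positive weight.
#' @export
wordcloud_weights <- function(importance, network) {
  if (is.character(network) && !network %in% rownames(importance))
    stop("unknown network: ", network)
  w <- importance[network, ]
  w <- w[w > 0]
  if (!length(w)) {
    warning("no positive-weight features for network ", network)
    return(stats::setNames(numeric(0), character(0)))
  }
  sort(w / max(w), decreasing = TRUE)
}
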