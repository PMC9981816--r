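# Shared fixtures and independent oracles for the test suite.

# Small synthetic study used across module tests.
tiny_study <- function(n_tasks = 10L, n_features = 12L, n_cognitive = 8L,
                       n_regions = 60L, n_networks = 3L, n_subjects = 3L,
                       n_four_session_tasks = 4L, seed = 42L, ...) {
  generate_study(synthetic_config(
    n_tasks = n_tasks, n_features = n_features, n_cognitive = n_cognitive,
    n_regions = n_regions, n_networks = n_networks, n_subjects = n_subjects,
    n_four_session_tasks = n_four_session_tasks, seed = seed, ...))
}

# Independent ridge oracle: minimizes the penalized objective
#   sum((y - X w - b)^2) + alpha * sum(w^2)
# per response column by generic quasi-Newton optimization (analytic
# gradient), with no reference to the closed-form solver under test.
ridge_oracle <- function(X, Y, alpha) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X)
  fit_one <- function(y) {
    obj <- function(th) {
      w <- th[1:p]; b <- th[p + 1]
      r <- y - drop(X %*% w) - b
      sum(r^2) + alpha * sum(w^2)
    }
    grad <- function(th) {
      w <- th[1:p]; b <- th[p + 1]
      r <- y - drop(X %*% w) - b
      c(-2 * drop(crossprod(X, r)) + 2 * alpha * w, -2 * sum(r))
    }
    o <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    o$par
  }
  th <- apply(Y, 2L, fit_one)
  list(weights = th[1:p, , drop = FALSE], intercepts = th[p + 1, ])
}

# Brute-force UPGMA oracle: clusters kept as explicit member sets, the
# distance between clusters recomputed each step as the arithmetic mean over
# all between-cluster member pairs of the original distances.
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- list(members = merged, height = best_d)
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Member sets after each hclust merge, in merge order, for comparison with
# the oracle (leaf indices, sorted).
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(x) if (x < 0) -x else sets[[x]]
    sets[[i]] <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
  }
  sets
}

# Hand-built two-task dataset wrapper for evaluation tests.
manual_dataset <- function(maps_by_task, timepoints = NULL) {
  tasks <- names(maps_by_task)
  counts <- vapply(maps_by_task, nrow, integer(1))
  info <- data.frame(
    task = rep(tasks, counts),
    session = unlist(lapply(counts, seq_len), use.names = FALSE))
  info$timepoint <- if (is.null(timepoints))
    ifelse(counts[info$task] == 4L, ifelse(info$session <= 2L, 1L, 2L), 1L)
  else unlist(timepoints, use.names = FALSE)
  structure(list(maps = list(sub01 = do.call(rbind, maps_by_task)),
                 info = info, tasks = tasks,
                 session_counts = counts, network_labels = NULL),
            class = "activation_dataset")
}
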