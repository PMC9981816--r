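#' Configuration for the synthetic MDTB-shaped dataset
#'
#' The generator emulates the structure of a dense-sampling task-fMRI study:
#' 44 task conditions annotated with 36 ontological features (24 cognitive,
#' 12 perceptual-motor; 3 parametric), region-level z-score maps for 1000
#' cortical regions grouped into 7 resting-state networks, 23 subjects, and
#' a mix of tasks observed in 4 imaging sessions (the conditions shared by
#' both task sets, default 14) or 2 sessions (the rest).
#'
#' @param n_tasks,n_features,n_cognitive,n_regions,n_networks,n_subjects
#'   Problem-size counts (defaults 44, 36, 24, 1000, 7, 23).
#' @param n_four_session_tasks Number of tasks observed in four sessions
#'   (default 14, clamped to \code{n_tasks} for small configurations); the
#'   remaining tasks get two.
#' @param noise_sd SD of the additive Gaussian session noise, in z-score
#'   units (default 1.5).
#' @param subject_weight_sd SD of each subject's deviation from the group
#'   encoding weights (default 0.04).
#' @param shared_scale Strength of a task-general activation component
#'   shared by all tasks (default 2); mimics the common task-positive map of
#'   real contrasts and drives the null model's mean-prediction bias.
#' @param signature_shift Mean shift added to each network's signature
#'   features (default 0.4 weight units).
#' @param base_weight_sd SD of the unstructured background weights
#'   (default 0.08).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class \code{"synthetic_config"} (named list).
#' @export
synthetic_config <- function(n_tasks = 44L, n_features = 36L,
                             n_cognitive = 24L, n_regions = 1000L,
                             n_networks = 7L, n_subjects = 23L,
                             n_four_session_tasks = min(14L, n_tasks),
                             noise_sd = 1.5, subject_weight_sd = 0.04,
                             shared_scale = 2, signature_shift = 0.4,
                             base_weight_sd = 0.08, seed = 1L) {
  cfg <- list(n_tasks = as.integer(n_tasks),
              n_features = as.integer(n_features),
              n_cognitive = as.integer(n_cognitive),
              n_regions = as.integer(n_regions),
              n_networks = as.integer(n_networks),
              n_subjects = as.integer(n_subjects),
              n_four_session_tasks = as.integer(n_four_session_tasks),
              noise_sd = noise_sd, subject_weight_sd = subject_weight_sd,
              shared_scale = shared_scale,
              signature_shift = signature_shift,
              base_weight_sd = base_weight_sd, seed = as.integer(seed))
  counts <- cfg[c("n_tasks", "n_features", "n_regions", "n_networks",
                  "n_subjects")]
  if (any(unlist(counts) < 1L)) stop("all counts must be >= 1")
  if (cfg$n_cognitive >= cfg$n_features)
    stop("n_cognitive must be smaller than n_features")
  if (cfg$n_four_session_tasks > cfg$n_tasks)
    stop("n_four_session_tasks cannot exceed n_tasks")
  if (cfg$n_four_session_tasks < 0L) stop("n_four_session_tasks must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$subject_weight_sd < 0) stop("subject_weight_sd must be >= 0")
  structure(cfg, class = "synthetic_config")
}

# Run expr under a local RNG state seeded with `seed`; caller's RNG untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic ontological annotation matrix
#'
#' Draws binary feature columns at roughly 25\% task density (columns are
#' redrawn if constant, which would make ridge weights unidentifiable),
#' makes 3 features parametric with multi-level raw magnitudes recoded by
#' \code{\link{recode_parametric}}, and assigns \code{n_cognitive} features
#' the Cognitive class and the rest Perceptual-Motor. Task rows are
#' guaranteed pairwise distinct; degenerate configurations that cannot
#' produce distinct rows fail after a bounded number of redraws.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param seed Integer seed (defaults to \code{config$seed}).
#' @return A \code{\link{feature_matrix}}.
#' @export
generate_annotation_matrix <- function(config, seed = config$seed) {
  with_seed(seed, {
    nt <- config$n_tasks; nf <- config$n_features
    n_par <- if (nf >= 4L) 3L else 0L  # tiny spaces stay all-binary
    draw_binary_col <- function() {
      for (i in 1:100) {
        x <- as.numeric(stats::runif(nt) < 0.25)
        if (nt == 1L || stats::var(x) > 0) return(x)
      }
      stop("could not draw a non-constant binary feature column")
    }
    draw_parametric_col <- function() {
      # raw magnitudes like response counts: many zeros, a few levels
      for (i in 1:100) {
        raw <- sample(c(0, 0, 0, 1, 2, 4, 6, 7, 8, 12, 15), nt, replace = TRUE)
        if (length(unique(raw)) >= 2L) return(recode_parametric(raw))
      }
      stop("could not draw a multi-level parametric column")
    }
    for (attempt in 1:50) {
      vals <- matrix(0, nt, nf)
      par_idx <- if (n_par > 0L) seq_len(n_par) else integer(0)
      for (j in seq_len(nf))
        vals[, j] <- if (j %in% par_idx) draw_parametric_col() else draw_binary_col()
      if (!anyDuplicated(apply(vals, 1L, paste, collapse = ","))) break
      if (attempt == 50)
        stop("could not generate pairwise-distinct task rows; ",
             "configuration is degenerate (too few features?)")
    }
    dimnames(vals) <- list(sprintf("task%02d", seq_len(nt)),
                           sprintf("feat%02d", seq_len(nf)))
    cls <- rep("PerceptualMotor", nf)
    cls[seq_len(config$n_cognitive)] <- "Cognitive"
    par_flag <- seq_len(nf) %in% par_idx
    feature_matrix(vals, cls, par_flag)
  })
}

#' Generate network-structured ground-truth encoding weights
#'
#' Regions are split into \code{n_networks} roughly balanced resting-state
#' networks. Each network receives 3--6 randomly chosen "signature" features
#' whose group-level weights are mean-shifted upward across that network's
#' regions, on top of unstructured Gaussian background weights; per-subject
#' weights perturb the group weights with SD \code{subject_weight_sd}. A
#' shared task-general region map (scaled by \code{shared_scale}) is also
#' drawn.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param seed Integer seed (defaults to \code{config$seed + 1}).
#' @return A list of class \code{"ground_truth"}: \code{group_weights}
#'   (feature x region), \code{subject_weights} (list of the same shape),
#'   \code{network_labels} (integer per region), \code{signatures} (list of
#'   feature indices per network), \code{shared_map}, \code{noise_sd}.
#' @export
generate_ground_truth <- function(config, seed = config$seed + 1L) {
  with_seed(seed, {
    nf <- config$n_features; nr <- config$n_regions; nn <- config$n_networks
    labels <- sort(rep_len(seq_len(nn), nr))  # balanced up to remainder
    labels <- sample(labels)                  # random region assignment
    W <- matrix(stats::rnorm(nf * nr, sd = config$base_weight_sd), nf, nr)
    signatures <- vector("list", nn)
    for (k in seq_len(nn)) {
      n_sig <- if (nf >= 6L) sample(3:6, 1L) else max(1L, nf %/% 2L)
      signatures[[k]] <- sort(sample(nf, n_sig))
      W[signatures[[k]], labels == k] <-
        W[signatures[[k]], labels == k] + config$signature_shift
    }
    dimnames(W) <- list(sprintf("feat%02d", seq_len(nf)),
                        sprintf("region%04d", seq_len(nr)))
    subj <- lapply(seq_len(config$n_subjects), function(s)
      W + matrix(stats::rnorm(nf * nr, sd = config$subject_weight_sd), nf, nr))
    shared <- config$shared_scale * stats::rnorm(nr)
    structure(list(group_weights = W, subject_weights = subj,
                   network_labels = labels, signatures = signatures,
                   shared_map = shared, noise_sd = config$noise_sd),
              class = "ground_truth")
  })
}

#' Generate session-level synthetic activation maps
#'
#' For each subject and task, draws S session maps (S = 4 for the seeded
#' random subset of \code{n_four_session_tasks} tasks, else 2):
#' \code{map = features \%*\% subject_weights + shared_map + N(0, noise_sd)}
#' per region. Four-session tasks have sessions 1--2 at timepoint 1 and
#' 3--4 at timepoint 2; two-session tasks sit at one timepoint.
#'
#' @param truth A \code{\link{generate_ground_truth}} result.
#' @param features A \code{\link{feature_matrix}}.
#' @param config The \code{\link{synthetic_config}} used for both.
#' @param seed Integer seed (defaults to \code{config$seed + 2}).
#' @return An object of class \code{"activation_dataset"}: list with
#'   \code{maps} (per-subject list of row x region matrices), \code{info}
#'   (data.frame: task, session, timepoint per row), \code{tasks},
#'   \code{session_counts} (named), \code{network_labels}.
#' @export
generate_activations <- function(truth, features, config,
                                 seed = config$seed + 2L) {
  nf <- ncol(features$values)
  if (nrow(truth$group_weights) != nf)
    stop("feature count mismatch between ground truth and feature matrix")
  if (length(truth$subject_weights) != config$n_subjects)
    stop("subject count mismatch between ground truth and config")
  with_seed(seed, {
    tasks <- task_ids(features)
    four <- sample(tasks, config$n_four_session_tasks)
    counts <- stats::setNames(ifelse(tasks %in% four, 4L, 2L), tasks)
    info <- data.frame(
      task = rep(tasks, counts[tasks]),
      session = unlist(lapply(counts[tasks], seq_len), use.names = FALSE),
      stringsAsFactors = FALSE)
    info$timepoint <- ifelse(counts[info$task] == 4L,
                             ifelse(info$session <= 2L, 1L, 2L), 1L)
    nr <- length(truth$shared_map)
    mean_rows <- function(Wsub) {
      M <- features$values %*% Wsub +
        matrix(truth$shared_map, nrow(features$values), nr, byrow = TRUE)
      M[info$task, , drop = FALSE]
    }
    maps <- lapply(truth$subject_weights, function(Wsub) {
      mu <- mean_rows(Wsub)
      noise <- if (config$noise_sd > 0)
        matrix(stats::rnorm(length(mu), sd = config$noise_sd),
               nrow(mu), ncol(mu)) else 0
      out <- mu + noise
      rownames(out) <- paste(info$task, info$session, sep = ".")
      out
    })
    names(maps) <- sprintf("sub%02d", seq_along(maps))
    structure(list(maps = maps, info = info, tasks = tasks,
                   session_counts = counts,
                   network_labels = truth$network_labels),
              class = "activation_dataset")
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining \code{\link{generate_annotation_matrix}},
#' \code{\link{generate_ground_truth}} and \code{\link{generate_activations}}
#' under one seed.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List with elements \code{features}, \code{truth}, \code{data},
#'   \code{config}.
#' @export
generate_study <- function(config = synthetic_config()) {
  features <- generate_annotation_matrix(config)
  truth <- generate_ground_truth(config)
  data <- generate_activations(truth, features, config)
  list(features = features, truth = truth, data = data, config = config)
}

#' Write a synthetic study to plain-text files
#'
#' Writes the annotation matrix (TSV dialect of
#' \code{\link{write_feature_matrix}}), long-form activations
#' (\code{activations.tsv}: subject, task, session, timepoint, region, z),
#' network labels (\code{networks.tsv}), ground-truth group weights
#' (\code{group_weights.tsv}) and the configuration (\code{config.json}).
#'
#' @param study A \code{\link{generate_study}} result.
#' @param dir Output directory (created if missing).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(study$features, file.path(dir, "features.tsv"))
  ds <- study$data
  long <- do.call(rbind, lapply(names(ds$maps), function(s) {
    m <- ds$maps[[s]]
    data.frame(subject = s,
               task = rep(ds$info$task, ncol(m)),
               session = rep(ds$info$session, ncol(m)),
               region = rep(colnames(m) %||% seq_len(ncol(m)),
                            each = nrow(m)),
               z = as.vector(m))
  }))
  utils::write.table(long, file.path(dir, "activations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(region = seq_along(ds$network_labels),
               network = ds$network_labels),
    file.path(dir, "networks.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(feature = rownames(study$truth$group_weights),
               study$truth$group_weights, check.names = FALSE),
    file.path(dir, "group_weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(unclass(study$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Session maps (rows x regions) of one task for one subject.
task_sessions <- function(dataset, subject, task) {
  idx <- which(dataset$info$task == task)
  dataset$maps[[subject]][idx, , drop = FALSE]
}
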