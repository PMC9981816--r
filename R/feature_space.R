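#' Construct an ontological feature matrix
#'
#' A feature matrix annotates each task condition with the psychological
#' functions it engages: one row per task, one column per feature, values in
#' \code{[0, 1]}. Most features are binary (presence/absence of an operation);
#' a few are parametric, recoded to \code{[0, 1]} by
#' \code{\link{recode_parametric}}. Every feature carries a class label,
#' \code{"Cognitive"} or \code{"PerceptualMotor"}, used by
#' \code{\link{subset_features}} to compare feature sets.
#'
#' @param values Numeric task x feature matrix with values in \code{[0, 1]}.
#'   Row names are task ids, column names feature ids (required, unique).
#' @param feature_class Character vector, one of \code{"Cognitive"} or
#'   \code{"PerceptualMotor"} per feature (recycled names checked against
#'   column names).
#' @param parametric Logical vector flagging parametrically coded features;
#'   defaults to all-\code{FALSE}.
#' @return An object of class \code{"feature_matrix"}: a list with elements
#'   \code{values}, \code{feature_class}, \code{parametric}.
#' @export
feature_matrix <- function(values, feature_class,
                           parametric = rep(FALSE, ncol(values))) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have task row names and feature column names")
  if (anyDuplicated(rownames(values))) stop("task ids must be unique")
  if (anyDuplicated(colnames(values))) stop("feature ids must be unique")
  if (!is.numeric(values) || anyNA(values))
    stop("`values` must be numeric with no missing entries")
  if (min(values) < 0 || max(values) > 1)
    stop("feature values must lie in [0, 1]")
  feature_class <- as.character(feature_class)
  if (length(feature_class) != ncol(values))
    stop("`feature_class` must have one entry per feature")
  if (!all(feature_class %in% c("Cognitive", "PerceptualMotor")))
    stop("feature classes must be 'Cognitive' or 'PerceptualMotor'")
  parametric <- as.logical(parametric)
  if (length(parametric) != ncol(values))
    stop("`parametric` must have one entry per feature")
  names(feature_class) <- colnames(values)
  names(parametric) <- colnames(values)
  structure(list(values = values, feature_class = feature_class,
                 parametric = parametric),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d tasks x %d features (%d Cognitive, %d Perceptual-Motor, %d parametric)\n",
              nrow(x$values), ncol(x$values),
              sum(x$feature_class == "Cognitive"),
              sum(x$feature_class == "PerceptualMotor"),
              sum(x$parametric)))
  invisible(x)
}

n_tasks <- function(fm) nrow(fm$values)
task_ids <- function(fm) rownames(fm$values)
feature_ids <- function(fm) colnames(fm$values)

#' Recode a parametric feature by rank, scaled to [0, 1]
#'
#' Parametric features (e.g. the number of response alternatives, or of
#' responses executed with one hand during a task block) are recoded as the
#' index of each raw value among the sorted distinct values -- a dense rank
#' starting at 0 -- and scaled by \code{1 / (n_distinct - 1)} so codes span
#' \code{[0, 1]}. Equal raw magnitudes therefore share a code, and the coding
#' is order-preserving.
#'
#' @param raw_levels Numeric vector of raw per-task magnitudes.
#' @return Numeric vector of codes in \code{[0, 1]}, same order as the input.
#' @examples
#' recode_parametric(c(0, 1, 2, 4, 6, 7))   # 0, .2, .4, .6, .8, 1
#' recode_parametric(c(5, 0, 5, 15))        # 0.5, 0, 0.5, 1
#' @export
recode_parametric <- function(raw_levels) {
  if (!is.numeric(raw_levels) || anyNA(raw_levels))
    stop("`raw_levels` must be numeric without missing values")
  lv <- sort(unique(raw_levels))
  if (length(lv) < 2L)
    stop("all raw values are identical; rank scaling is undefined")
  (match(raw_levels, lv) - 1) / (length(lv) - 1)
}

#' Subset a feature matrix by feature class
#'
#' Selects the \code{"Cognitive"} or \code{"PerceptualMotor"} feature columns
#' (or all of them), preserving task order. Used to compare the predictive
#' value of higher-order cognitive versus perceptual-motor annotations.
#'
#' @param fm A \code{\link{feature_matrix}}.
#' @param which One of \code{"All"}, \code{"Cognitive"},
#'   \code{"PerceptualMotor"}.
#' @return A \code{feature_matrix} restricted to the requested columns.
#' @export
subset_features <- function(fm, which = c("All", "Cognitive", "PerceptualMotor")) {
  which <- match.arg(which)
  if (which == "All") return(fm)
  keep <- fm$feature_class == which
  if (!any(keep)) stop(sprintf("no features of class '%s'", which))
  feature_matrix(fm$values[, keep, drop = FALSE],
                 fm$feature_class[keep], fm$parametric[keep])
}

#' Expand task-level features into a session-level design matrix
#'
#' Each task contributes one identical design row per imaging session it
#' appears in (two or four in the emulated dataset), so the regression sees
#' every observed session map once.
#'
#' @param fm A \code{\link{feature_matrix}}.
#' @param session_counts Named integer vector, task id -> number of sessions
#'   (each 2 or 4).
#' @return An object of class \code{"design_matrix"}: list with \code{values}
#'   (row x feature matrix), \code{task} (task id per row), \code{session}
#'   (session index per row, 1..count).
#' @export
expand_to_sessions <- function(fm, session_counts) {
  tids <- task_ids(fm)
  if (!all(tids %in% names(session_counts)))
    stop("every task needs a session count")
  cnt <- as.integer(session_counts[tids])
  if (anyNA(cnt) || !all(cnt %in% c(2L, 4L)))
    stop("session counts must be 2 or 4")
  row_task <- rep(tids, cnt)
  row_sess <- unlist(lapply(cnt, seq_len), use.names = FALSE)
  structure(list(values = fm$values[row_task, , drop = FALSE],
                 task = row_task, session = row_sess),
            class = "design_matrix")
}

#' Write a feature matrix to TSV
#'
#' The dialect has three header rows -- feature ids, feature classes
#' (\code{C} / \code{PM}), and parametric flags (0/1) -- followed by one row
#' per task (first column = task id).
#'
#' @param fm A \code{\link{feature_matrix}}.
#' @param path Output file path.
#' @export
write_feature_matrix <- function(fm, path) {
  cls <- ifelse(fm$feature_class == "Cognitive", "C", "PM")
  hdr <- c(paste(c("task", feature_ids(fm)), collapse = "\t"),
           paste(c("class", cls), collapse = "\t"),
           paste(c("parametric", as.integer(fm$parametric)), collapse = "\t"))
  body <- vapply(seq_len(n_tasks(fm)), function(i)
    paste(c(task_ids(fm)[i], format(fm$values[i, ], trim = TRUE)),
          collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' Inverse of \code{\link{write_feature_matrix}}. Feature classes come from
#' the file; the loader never guesses a class.
#'
#' @param path Input file path.
#' @return A \code{\link{feature_matrix}}.
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("feature matrix file too short")
  split_row <- function(x) strsplit(x, "\t", fixed = TRUE)[[1]]
  ids <- split_row(lines[1])[-1]
  cls <- split_row(lines[2])[-1]
  par <- as.integer(split_row(lines[3])[-1])
  body <- lapply(lines[-(1:3)], split_row)
  tasks <- vapply(body, `[`, character(1), 1L)
  vals <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1])))
  dimnames(vals) <- list(tasks, ids)
  feature_matrix(vals,
                 ifelse(cls == "C", "Cognitive", "PerceptualMotor"),
                 as.logical(par))
}
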