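#' Multi-trial trajectory dataset container
#'
#' A `trial_dataset` holds an ordered sequence of trials; each trial is a bag
#' of trajectories recorded (or simulated) under one parameter state. Trials
#' are stored internally as lists with per-trial state matrices `x`, `y`
#' (or a single `states` list of `D x N` coordinate matrices for general
#' dimension), a `class` vector of per-trajectory labels, and optionally a
#' `class_ref` vector of reference-frame labels (see
#' [generate_trial_sequence()]).
#'
#' @param trials list of trial records.
#' @param ... provenance metadata stored as attributes (generation
#'   parameters, seed, `dt`, ...).
#' @return An object of class `trial_dataset`.
#' @seealso [generate_trial_sequence()], [generate_multiclass_epochs()],
#'   [read_trajectories()]
#' @export
trial_dataset <- function(trials, ...) {
  if (!is.list(trials) || length(trials) == 0L)
    stop("trials must be a non-empty list", call. = FALSE)
  tidx <- vapply(trials, function(tr) as.integer(tr$trial), integer(1))
  if (!identical(tidx, seq_along(trials)))
    stop("trial indices must be contiguous 1..T", call. = FALSE)
  meta <- list(...)
  structure(list(trials = trials, meta = meta), class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  tr1 <- x$trials[[1L]]
  d <- dataset_dim(x)
  cat("trial_dataset:", length(x$trials), "trial(s),",
      n_trajectories(x, 1L), "trajectories of", n_timepoints(x, 1L),
      "samples each, dimension", d, "\n")
  cat("  classes:", paste(sort(unique(tr1$class)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials in a dataset
#' @param dataset a `trial_dataset`.
#' @return Integer count.
#' @export
n_trials <- function(dataset) length(dataset$trials)

#' @rdname n_trials
#' @param trial trial index.
#' @export
n_trajectories <- function(dataset, trial = 1L) {
  tr <- get_trial(dataset, trial)
  if (!is.null(tr$x)) nrow(tr$x) else nrow(tr$states[[1L]])
}

#' @rdname n_trials
#' @export
n_timepoints <- function(dataset, trial = 1L) {
  tr <- get_trial(dataset, trial)
  if (!is.null(tr$x)) ncol(tr$x) else ncol(tr$states[[1L]])
}

dataset_dim <- function(dataset) {
  tr <- dataset$trials[[1L]]
  if (!is.null(tr$x)) 2L else length(tr$states)
}

#' Extract one trial from a dataset
#' @param dataset a `trial_dataset`.
#' @param trial trial index (1-based).
#' @return The trial record (list).
#' @export
get_trial <- function(dataset, trial) {
  if (trial < 1L || trial > length(dataset$trials))
    stop("trial ", trial, " not present in dataset", call. = FALSE)
  dataset$trials[[trial]]
}

# Flatten one trial into a pattern matrix. Rows are ordered
# trajectory-major by time (pattern i of trajectory j is row (i-1)*D + j),
# matching matrix(...) column-unrolling of the D x N state matrices.
trial_patterns <- function(trial) {
  if (!is.null(trial$x)) {
    cbind(as.vector(trial$x), as.vector(trial$y))
  } else {
    do.call(cbind, lapply(trial$states, as.vector))
  }
}

# per-pattern labels aligned with trial_patterns rows
trial_pattern_labels <- function(trial, frame = c("generation", "reference")) {
  frame <- match.arg(frame)
  lab <- trial_labels(trial, frame)
  N <- if (!is.null(trial$x)) ncol(trial$x) else ncol(trial$states[[1L]])
  rep(lab, N)
}

trial_labels <- function(trial, frame = c("generation", "reference")) {
  frame <- match.arg(frame)
  if (frame == "reference" && !is.null(trial$class_ref)) trial$class_ref
  else trial$class
}

#' Convert a trial dataset to a long-format data frame
#'
#' One row per (trial, trajectory, time index) with state coordinates and the
#' trajectory's class label.
#'
#' @param x a `trial_dataset`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A data frame with columns `trial`, `traj`, `t_index`, the
#'   coordinate columns (`x`, `y` for planar data, else `s1`, `s2`, ...),
#'   and `class`.
#' @export
as.data.frame.trial_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- lapply(x$trials, function(tr) {
    P <- trial_patterns(tr)
    D <- if (!is.null(tr$x)) nrow(tr$x) else nrow(tr$states[[1L]])
    N <- nrow(P) / D
    df <- data.frame(
      trial = tr$trial,
      traj = rep(seq_len(D), N),
      t_index = rep(seq_len(N), each = D)
    )
    cn <- if (ncol(P) == 2L) c("x", "y") else paste0("s", seq_len(ncol(P)))
    for (j in seq_len(ncol(P))) df[[cn[j]]] <- P[, j]
    df$class <- rep(tr$class, N)
    df[order(df$traj, df$t_index), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read a trajectory dataset as delimited text
#'
#' `write_trajectories()` writes the long-format table as RFC-4180 CSV plus a
#' JSON sidecar (`<path>.json`) carrying generation parameters and the seed.
#' `read_trajectories()` validates the schema and rebuilds the
#' `trial_dataset`.
#'
#' @param dataset a `trial_dataset`.
#' @param path CSV file path.
#' @return `read_trajectories()` returns a `trial_dataset`;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(dataset, path) {
  df <- as.data.frame(dataset)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- dataset$meta
  meta$params <- unclass(meta$params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  need <- c("trial", "traj", "t_index", "class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory file schema violation: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  coord_cols <- setdiff(names(df), need)
  if (length(coord_cols) == 0L)
    stop("trajectory file schema violation: no coordinate columns", call. = FALSE)
  if (any(!vapply(df[coord_cols], is.numeric, logical(1))))
    stop("coordinate columns must be numeric", call. = FALSE)
  if (anyNA(df))
    stop("trajectory file contains missing values", call. = FALSE)
  trials <- lapply(sort(unique(df$trial)), function(k) {
    dk <- df[df$trial == k, , drop = FALSE]
    ids <- sort(unique(dk$traj))
    N <- length(unique(dk$t_index))
    if (nrow(dk) != length(ids) * N)
      stop("ragged trajectories in trial ", k, call. = FALSE)
    dk <- dk[order(dk$traj, dk$t_index), , drop = FALSE]
    states <- lapply(coord_cols, function(cn)
      matrix(dk[[cn]], nrow = length(ids), ncol = N, byrow = TRUE))
    cls <- dk$class[match(ids, dk$traj)]
    rec <- list(trial = as.integer(k), class = cls)
    if (identical(coord_cols, c("x", "y"))) {
      rec$x <- states[[1L]]; rec$y <- states[[2L]]
    } else {
      rec$states <- states
    }
    rec
  })
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  do.call(trial_dataset, c(list(trials = trials), meta["seed"]))
}
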