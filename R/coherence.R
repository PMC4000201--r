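#' Tail-rule convergence of a predicted label sequence
#'
#' A class-trajectory is *convergent* when all of its last `L` predicted
#' labels equal the trajectory's true class: the trajectory has settled in
#' the region of state space associated with its class. A trajectory whose
#' tail is consistently assigned any *other* class is divergent, as is one
#' whose tail keeps switching.
#'
#' @param predicted_labels length-`N` sequence of predicted labels.
#' @param true_class the trajectory's class.
#' @param L tail length, `1 <= L <= N`.
#' @return `TRUE` if convergent.
#' @export
is_convergent <- function(predicted_labels, true_class, L) {
  N <- length(predicted_labels)
  stop_if_not_scalar_number(L, "L", positive = TRUE, integerish = TRUE)
  if (L > N) stop("L must satisfy 1 <= L <= N", call. = FALSE)
  all(predicted_labels[(N - L + 1L):N] == true_class)
}

#' Trajectory incoherence per trial
#'
#' The TI of a trial is the fraction of its trajectories that are not
#' convergent under the tail rule ([is_convergent()]): the empirical
#' estimator of the probability that a whole trajectory is assigned to the
#' wrong region of state space. A single trajectory changing its basin of
#' attraction changes TI by exactly `1/D`.
#'
#' @param dataset a [trial_dataset()].
#' @param model a fitted `kfd_model`.
#' @param L tail length; default `max(1, round(0.1 * N))`.
#' @param frame `"generation"` labels each trajectory by the attractor of
#'   its own dynamics; `"reference"` uses the reference-frame labels when the
#'   dataset carries them (see [generate_trial_sequence()]).
#' @return A data frame with per-trial `trial`, `TI`, `n_divergent`, plus a
#'   `"divergent"` attribute listing divergent trajectory ids per trial.
#' @export
trajectory_incoherence <- function(dataset, model, L = NULL,
                                   frame = "generation") {
  per_trial_stat(dataset, model, L, frame)[, c("trial", "TI", "n_divergent")]
}

#' Classification error per trial
#'
#' The fraction of individual state vectors misclassified in each trial: the
#' empirical estimator of the classifier's risk. Unlike TI, CE is invariant
#' to any reordering of vectors within trajectories.
#'
#' @inheritParams trajectory_incoherence
#' @return A data frame with per-trial `trial` and `CE`.
#' @export
classification_error <- function(dataset, model, frame = "generation") {
  per_trial_stat(dataset, model, L = 1L, frame)[, c("trial", "CE")]
}

per_trial_stat <- function(dataset, model, L, frame) {
  out <- lapply(dataset$trials, function(tr) {
    if (length(tr$class) == 0L) stop("empty trial", call. = FALSE)
    N <- n_patterns_per_traj(tr)
    Luse <- if (is.null(L)) max(1L, round(0.1 * N)) else L
    ev <- evaluate_trial(model, tr, Luse, frame)
    list(row = data.frame(trial = tr$trial, TI = ev$TI, CE = ev$CE,
                          n_divergent = length(ev$divergent)),
         divergent = ev$divergent)
  })
  res <- do.call(rbind, lapply(out, `[[`, "row"))
  attr(res, "divergent") <- lapply(out, `[[`, "divergent")
  res
}

#' Fixed-reference trial-wise evaluation protocol
#'
#' The core evaluation loop: fit the discriminant on the reference trial
#' only, freeze it, and evaluate TI and CE on every other trial. Under a
#' deterministic parameter drift, trajectories near the old basin boundary
#' change their attractor; evaluated against the reference frame (labels the
#' initial conditions had under the reference dynamics), each such
#' trajectory becomes divergent -- its last vectors settle at the other
#' attractor -- so TI moves in steps of `1/D` while CE gains only about
#' `L/N` of each step. `label_frame = "reference"` (default) implements
#' exactly this; `"generation"` evaluates against each trial's own labels
#' instead.
#'
#' @param dataset a [trial_dataset()] with at least 2 trials.
#' @param spec a [kernel_spec()].
#' @param lambda ridge penalty for the reference fit; alternatively supply
#'   `validation` and a grid to tune it.
#' @param L convergence tail length; default `max(1, round(0.1 * N))`.
#' @param reference_trial index of the trial the model is fitted on.
#' @param validation optional trial (or dataset) for tuning `lambda` by
#'   minimum TI over `lam_grid`.
#' @param lam_grid penalty grid used when `validation` is given.
#' @param label_frame `"reference"` or `"generation"` (see Details).
#' @param threshold passed to [fit_kfd()].
#' @return A `coherence_result`: data frame of per-trial `trial`, `TI`,
#'   `CE`, `n_divergent` (reference trial excluded), with the fitted model,
#'   `L`, and protocol metadata in attributes.
#' @export
trialwise_protocol <- function(dataset, spec = kernel_spec(), lambda = 1e-3,
                               L = NULL, reference_trial = 1L,
                               validation = NULL,
                               lam_grid = 10^seq(-6, 1, length.out = 8L),
                               label_frame = c("reference", "generation"),
                               threshold = "gaussian") {
  label_frame <- match.arg(label_frame)
  if (n_trials(dataset) < 2L)
    stop("the trial-wise protocol needs at least 2 trials", call. = FALSE)
  ref <- get_trial(dataset, reference_trial)
  N <- n_patterns_per_traj(ref)
  if (is.null(L)) L <- max(1L, round(0.1 * N))
  if (!is.null(validation)) {
    sel <- select_regularization(ref, validation, spec, lam_grid, L = L,
                                 threshold = threshold)
    lambda <- sel$lambda
  }
  model <- fit_trial(ref, spec, lambda, threshold)
  eval_idx <- setdiff(seq_len(n_trials(dataset)), reference_trial)
  eval_ds <- dataset
  eval_ds$trials <- dataset$trials[eval_idx]
  # per_trial_stat validates contiguity through trial ids internally; keep ids
  rows <- lapply(eval_ds$trials, function(tr) {
    ev <- evaluate_trial(model, tr, L, label_frame)
    list(row = data.frame(trial = tr$trial, TI = ev$TI, CE = ev$CE,
                          n_divergent = length(ev$divergent)),
         divergent = ev$divergent)
  })
  res <- do.call(rbind, lapply(rows, `[[`, "row"))
  rownames(res) <- NULL
  structure(res,
            divergent = lapply(rows, `[[`, "divergent"),
            model = model, L = L, reference_trial = reference_trial,
            label_frame = label_frame, lambda = lambda,
            class = c("coherence_result", "data.frame"))
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("Trial-wise coherence protocol (reference trial ",
      attr(x, "reference_trial"), ", L = ", attr(x, "L"),
      ", labels: ", attr(x, "label_frame"), " frame)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Slope test for a trial-wise trend
#'
#' Ordinary least-squares regression of a per-trial statistic on the trial
#' index; returns the slope and its two-sided p-value. Used to decide
#' whether TI (or CE) exhibits a significant monotone trend across trials.
#'
#' @param values per-trial statistic (ordered by trial).
#' @return A list with `slope` and `p_value`.
#' @export
trend_slope_test <- function(values) {
  if (length(values) < 3L) stop("need at least 3 trials", call. = FALSE)
  fit <- lm(values ~ seq_along(values))
  co <- summary(fit)$coefficients
  list(slope = unname(co[2L, 1L]), p_value = unname(co[2L, 4L]))
}
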