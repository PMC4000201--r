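#' Within-trajectory shuffle surrogate
#'
#' Independently permutes the temporal order of the state vectors inside
#' every trajectory, keeping the trial structure, the class labels and the
#' multiset of vectors per trajectory untouched. Any pointwise classifier
#' therefore produces *bit-identical* CE on the surrogate, while the
#' temporal flow that makes trajectories converge is destroyed -- so a TI
#' trend that survives shuffling cannot be attributed to coherent
#' deterministic dynamics.
#'
#' @param dataset a [trial_dataset()].
#' @param seed integer seed (streams are domain-separated from the
#'   generator's).
#' @return A `trial_dataset` with shuffled within-trajectory order.
#' @export
shuffle_within_trajectories <- function(dataset, seed = 1L) {
  with_seed(derive_seed(seed, 0L, "shuffle"), {
    trials <- lapply(dataset$trials, function(tr) {
      if (!is.null(tr$x)) {
        N <- ncol(tr$x)
        for (i in seq_len(nrow(tr$x))) {
          ord <- sample.int(N)
          tr$x[i, ] <- tr$x[i, ord]
          tr$y[i, ] <- tr$y[i, ord]
        }
      } else {
        N <- ncol(tr$states[[1L]])
        for (i in seq_len(nrow(tr$states[[1L]]))) {
          ord <- sample.int(N)
          for (cc in seq_along(tr$states))
            tr$states[[cc]][i, ] <- tr$states[[cc]][i, ord]
        }
      }
      tr
    })
    out <- dataset
    out$trials <- trials
    out
  })
}

#' Random-drift surrogate dataset
#'
#' Regenerates the multi-trial Duffing dataset with the cubic coefficient of
#' each trial drawn i.i.d. uniformly over the range spanned by the
#' deterministic drift schedule, instead of increasing monotonically. The
#' within-trial dynamics stay fully deterministic; only the across-trial
#' parameter sequence is randomized. A TI trend present in the deterministic
#' schedule but absent here is evidence for a non-autonomous deterministic
#' drift rather than trial-level parameter noise.
#'
#' @param params a [duffing_params()] with a drift schedule (`drift_epsilon`,
#'   `n_trials`); with a degenerate range (zero drift) this reduces to the
#'   stationary generator.
#' @param D,N,dt,sigma as in [generate_trial_sequence()].
#' @param seed integer seed; the beta draws use a stream separated from the
#'   trajectory streams.
#' @return A `trial_dataset`; each trial records its drawn `beta`.
#' @export
random_drift_surrogate <- function(params, D = 1000L, N = 100L, dt = 0.05,
                                   sigma = 1, seed = 1L) {
  schedule <- beta_at_trial(params, seq_len(params$n_trials))
  lo <- min(schedule); hi <- max(schedule)
  betas <- with_seed(derive_seed(seed, 0L, "drift"),
                     runif(params$n_trials, lo, hi))
  betas[1L] <- params$beta   # the reference trial keeps the reference system
  if (any(betas <= 0))
    stop("surrogate drift range leaves the two-sink regime", call. = FALSE)
  trials <- vector("list", params$n_trials)
  for (k in seq_len(params$n_trials)) {
    trials[[k]] <- generate_one_trial(params, k, betas[k], D, N, dt, sigma, seed)
  }
  trial_dataset(trials, params = params, D = D, N = N, dt = dt,
                sigma = sigma, seed = seed, surrogate = "random_drift")
}

#' Surrogate battery: empirical null for per-trial TI and CE
#'
#' Runs the trial-wise protocol over `n_replicates` surrogate datasets
#' (within-trajectory shuffles of the observed dataset, or freshly generated
#' random-drift datasets) and summarizes the per-trial null distributions.
#' Empirical two-sided p-values for the observed statistics use the add-one
#' rule \eqn{(r + 1) / (n + 1)}.
#'
#' @param dataset the observed [trial_dataset()] (used directly for
#'   `mode = "shuffle"`; its stored generation parameters seed the
#'   random-drift mode).
#' @param observed a `coherence_result` for `dataset` from
#'   [trialwise_protocol()]; its model, `L` and label frame are reused.
#' @param mode `"shuffle"` or `"random_drift"`.
#' @param n_replicates number of surrogate replicates (>= 2; 200 for the
#'   standard two-sided bootstrap comparisons).
#' @param seed integer seed.
#' @return A list with `replicates` (list of per-replicate per-trial TI/CE
#'   data frames), `ti_null` (matrix replicates x trials), `p_ti` (per-trial
#'   two-sided empirical p-values for the observed TI), and `mode`.
#' @export
surrogate_battery <- function(dataset, observed,
                              mode = c("shuffle", "random_drift"),
                              n_replicates = 200L, seed = 1L) {
  mode <- match.arg(mode)
  stop_if_not_scalar_number(n_replicates, "n_replicates", positive = TRUE,
                            integerish = TRUE)
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  model <- attr(observed, "model")
  L <- attr(observed, "L")
  frame <- attr(observed, "label_frame")
  ref <- attr(observed, "reference_trial")
  meta <- dataset$meta
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rseed <- derive_seed(seed + r, r, "replicate")
    surr <- if (mode == "shuffle") {
      shuffle_within_trajectories(dataset, seed = rseed)
    } else {
      random_drift_surrogate(meta$params, D = meta$D, N = meta$N,
                             dt = meta$dt, sigma = meta$sigma, seed = rseed)
    }
    eval_idx <- setdiff(seq_len(n_trials(surr)), ref)
    rows <- lapply(surr$trials[eval_idx], function(tr) {
      ev <- evaluate_trial(model, tr, L, frame)
      data.frame(trial = tr$trial, TI = ev$TI, CE = ev$CE)
    })
    reps[[r]] <- do.call(rbind, rows)
  }
  ti_null <- t(vapply(reps, function(df) df$TI, numeric(nrow(reps[[1L]]))))
  colnames(ti_null) <- reps[[1L]]$trial
  obs_ti <- observed$TI
  center <- apply(ti_null, 2L, median)
  p_ti <- vapply(seq_along(obs_ti), function(j) {
    r_ge <- sum(abs(ti_null[, j] - center[j]) >= abs(obs_ti[j] - center[j]))
    (r_ge + 1) / (n_replicates + 1)
  }, numeric(1))
  list(replicates = reps, ti_null = ti_null, p_ti = p_ti, mode = mode)
}
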