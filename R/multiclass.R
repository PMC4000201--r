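#' Multi-class drifting task-epoch benchmark
#'
#' A desk-scale analogue of a multi-epoch experimental protocol: `K`
#' well-separated attracting regions (damped point attractors arranged on a
#' circle) stand in for task epochs, and a deterministic per-trial rotation
#' and/or radial shift of the attractor layout emulates a slow drift of the
#' underlying states from trial to trial. Trajectories relax toward their
#' class's attractor under overdamped linear dynamics with optional state
#' noise; the class label is the attractor a trajectory belongs to, and is
#' unaffected by the drift (the drift moves the states, not the task
#' structure), so `class_ref` equals `class`.
#'
#' @param K number of classes (>= 2).
#' @param D trajectories per trial (split evenly over classes).
#' @param N samples per trajectory.
#' @param n_trials number of trials.
#' @param drift_angle clockwise rotation of the attractor layout per trial,
#'   in radians (0 = stationary).
#' @param drift_shift radial displacement of the attractors per trial.
#' @param noise state-noise standard deviation per unit time.
#' @param radius circle radius of the attractor centres.
#' @param relax relaxation rate towards the attractor.
#' @param spread standard deviation of initial conditions around each
#'   attractor.
#' @param dt sampling interval.
#' @param seed integer seed.
#' @return A [trial_dataset()] with 2-dimensional states and `K` classes.
#' @examples
#' ds <- generate_multiclass_epochs(K = 3, D = 30, N = 20, n_trials = 2, seed = 1)
#' n_trials(ds)
#' @export
generate_multiclass_epochs <- function(K = 4L, D = 200L, N = 50L,
                                       n_trials = 10L, drift_angle = 0,
                                       drift_shift = 0, noise = 0.05,
                                       radius = 2, relax = 1, spread = 0.6,
                                       dt = 0.1, seed = 1L) {
  stop_if_not_scalar_number(K, "K", positive = TRUE, integerish = TRUE)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  stop_if_not_scalar_number(D, "D", positive = TRUE, integerish = TRUE)
  stop_if_not_scalar_number(N, "N", positive = TRUE, integerish = TRUE)
  stop_if_not_scalar_number(n_trials, "n_trials", positive = TRUE,
                            integerish = TRUE)
  base_angles <- 2 * pi * (seq_len(K) - 1L) / K
  cls_of <- rep(seq_len(K), length.out = D)
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    ang <- base_angles - (k - 1L) * drift_angle   # clockwise
    rad <- radius + (k - 1L) * drift_shift
    centers <- cbind(rad * cos(ang), rad * sin(ang))
    sd_step <- noise * sqrt(dt)
    st <- with_seed(derive_seed(seed, k, "multiclass"), {
      X <- matrix(NA_real_, D, N); Y <- matrix(NA_real_, D, N)
      x <- centers[cls_of, 1L] + rnorm(D, 0, spread)
      y <- centers[cls_of, 2L] + rnorm(D, 0, spread)
      X[, 1L] <- x; Y[, 1L] <- y
      for (t in seq_len(N - 1L)) {
        x <- x + dt * relax * (centers[cls_of, 1L] - x) + rnorm(D, 0, sd_step)
        y <- y + dt * relax * (centers[cls_of, 2L] - y) + rnorm(D, 0, sd_step)
        X[, t + 1L] <- x; Y[, t + 1L] <- y
      }
      list(x = X, y = Y)
    })
    trials[[k]] <- list(trial = k, x = st$x, y = st$y,
                        class = cls_of, class_ref = cls_of)
  }
  trial_dataset(trials, generator = "multiclass_epochs", K = K, D = D,
                N = N, dt = dt, seed = seed, drift_angle = drift_angle,
                drift_shift = drift_shift, noise = noise)
}
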