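#' Parameters of the (possibly drifting) Duffing oscillator
#'
#' The benchmark system is the damped Duffing oscillator written as a
#' first-order system,
#' \deqn{\dot x = y, \qquad
#'       \dot y = -\delta y + \alpha x - \beta x^3 + \gamma\cos(\omega t).}
#' With `alpha > 0`, `beta > 0`, `gamma = 0` this is a double-well system:
#' a saddle at the origin and two symmetric attractors at
#' \eqn{(\pm\sqrt{\alpha/\beta},\, 0)}, which are spiral sinks whenever
#' \eqn{\delta^2 < 8\alpha}. The basins of attraction of the two sinks define
#' a natural binary classification problem for trajectories.
#'
#' Trial-wise non-stationarity is modelled as a per-trial increment of the
#' cubic coefficient: on trial \eqn{k}, \eqn{\beta_k = \beta + (k-1)\,
#' \epsilon}. Increasing \eqn{\beta} pulls the two sinks towards each other
#' (inter-sink distance \eqn{2\sqrt{\alpha/\beta}}) without changing the
#' qualitative dynamics, which is exactly the kind of subtle drift the
#' trajectory-incoherence statistic is designed to detect. The schedule must
#' keep the system inside the two-sink regime; parameter changes that cross a
#' bifurcation are rejected.
#'
#' @param alpha linear stiffness coefficient (> 0 in the two-sink regime).
#' @param beta cubic (perturbation) coefficient (> 0 in the two-sink regime).
#' @param delta damping coefficient (> 0).
#' @param gamma forcing amplitude; must be 0 for classification benchmarks.
#' @param omega forcing angular frequency.
#' @param drift_epsilon per-trial additive increment of `beta`.
#' @param n_trials number of trials in the drift schedule.
#'
#' @return An object of class `duffing_params`.
#' @examples
#' p <- duffing_params()
#' fixed_points(p)
#' @export
duffing_params <- function(alpha = 1, beta = 1, delta = 0.9, gamma = 0,
                           omega = 0, drift_epsilon = 0, n_trials = 1L) {
  stop_if_not_scalar_number(alpha, "alpha", positive = TRUE)
  stop_if_not_scalar_number(beta, "beta", positive = TRUE)
  stop_if_not_scalar_number(delta, "delta", positive = TRUE)
  stop_if_not_scalar_number(gamma, "gamma")
  stop_if_not_scalar_number(omega, "omega")
  stop_if_not_scalar_number(drift_epsilon, "drift_epsilon")
  stop_if_not_scalar_number(n_trials, "n_trials", positive = TRUE, integerish = TRUE)
  beta_last <- beta + (n_trials - 1) * drift_epsilon
  if (beta_last <= 0)
    stop("drift schedule leaves the two-sink regime: beta + (n_trials-1)*drift_epsilon = ",
         signif(beta_last, 4), " <= 0", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, delta = delta, gamma = gamma,
         omega = omega, drift_epsilon = drift_epsilon,
         n_trials = as.integer(n_trials)),
    class = "duffing_params"
  )
}

#' @export
print.duffing_params <- function(x, ...) {
  cat("Duffing parameters: alpha =", x$alpha, " beta =", x$beta,
      " delta =", x$delta, "\n")
  if (x$gamma != 0)
    cat("  forcing: gamma =", x$gamma, " omega =", x$omega, "\n")
  if (x$drift_epsilon != 0)
    cat("  drift: beta increases by", x$drift_epsilon, "per trial over",
        x$n_trials, "trials\n")
  invisible(x)
}

# beta on trial k of the deterministic schedule
beta_at_trial <- function(params, trial) {
  params$beta + (trial - 1) * params$drift_epsilon
}

#' Duffing vector field
#'
#' Time derivative of the first-order Duffing system at a state.
#'
#' @param state numeric length-2 vector `(x, y)`.
#' @param params a [duffing_params()] object.
#' @param t time (only relevant under forcing, `gamma != 0`).
#' @return Numeric length-2 vector \eqn{(\dot x, \dot y)}.
#' @examples
#' p <- duffing_params(alpha = 1, beta = 1, delta = 0.25)
#' duffing_flow(c(2, 0), p)   # (0, -6): cubic term dominates
#' @export
duffing_flow <- function(state, params, t = 0) {
  if (!is.numeric(state) || length(state) != 2L || !all(is.finite(state)))
    stop("state must be a finite numeric vector of length 2 (integration blow-up?)",
         call. = FALSE)
  x <- state[1L]; y <- state[2L]
  c(y, -params$delta * y + params$alpha * x - params$beta * x^3 +
      params$gamma * cos(params$omega * t))
}

#' Jacobian of the Duffing vector field
#'
#' @inheritParams duffing_flow
#' @return A 2x2 numeric matrix.
#' @export
duffing_jacobian <- function(state, params) {
  x <- state[1L]
  matrix(c(0, params$alpha - 3 * params$beta * x^2,
           1, -params$delta), 2L, 2L)
}

#' Fixed points of the unforced Duffing system
#'
#' Returns the saddle at the origin and the two symmetric equilibria at
#' \eqn{(\pm\sqrt{\alpha/\beta}, 0)} with the eigenvalues of the linearized
#' system. The symmetric equilibria are tagged `"spiral sink"` when
#' \eqn{\delta^2 < 8\alpha} (complex eigenvalues with negative real part) and
#' `"sink"` otherwise.
#'
#' @param params a [duffing_params()] object with `gamma = 0`.
#' @return A data frame with columns `x`, `y`, `stability`, and complex
#'   eigenvalue columns `eig1`, `eig2`.
#' @examples
#' fixed_points(duffing_params(alpha = 1, beta = 4))  # sinks at +-0.5
#' @export
fixed_points <- function(params) {
  if (params$gamma != 0)
    stop("fixed points are only computed for the unforced system (gamma = 0)",
         call. = FALSE)
  if (params$beta <= 0 || params$alpha <= 0)
    stop("outside two-sink regime: need alpha > 0 and beta > 0", call. = FALSE)
  a <- params$alpha; d <- params$delta
  eq <- sqrt(params$alpha / params$beta)
  # Jacobian at (x*, 0) has trace -delta and determinant -(alpha - 3 beta x*^2)
  eig_at <- function(x) {
    slope <- a - 3 * params$beta * x^2
    disc <- complex(real = d^2 + 4 * slope)
    (-d + c(1, -1) * sqrt(disc)) / 2
  }
  e0 <- eig_at(0); ep <- eig_at(eq)
  tag <- if (d^2 < 8 * a) "spiral sink" else "sink"
  data.frame(
    x = c(0, eq, -eq), y = 0,
    stability = c("saddle", tag, tag),
    eig1 = c(e0[1], ep[1], ep[1]),
    eig2 = c(e0[2], ep[2], ep[2])
  )
}

#' Draw Gaussian initial conditions
#'
#' i.i.d. draws from an isotropic bivariate Gaussian centred at the origin.
#'
#' @param n number of initial conditions (>= 1).
#' @param sigma per-axis standard deviation (> 0).
#' @param seed integer seed; equal seeds give identical draws.
#' @return An `n` x 2 numeric matrix.
#' @export
sample_initial_conditions <- function(n, sigma = 1, seed = 1L) {
  stop_if_not_scalar_number(n, "n", positive = TRUE, integerish = TRUE)
  stop_if_not_scalar_number(sigma, "sigma", positive = TRUE)
  with_seed(seed, matrix(rnorm(2L * n, 0, sigma), n, 2L,
                         dimnames = list(NULL, c("x", "y"))))
}

# ---- vectorized fixed-step RK4 on (x, y) column vectors -------------------
# The batch integrator works on all trajectories simultaneously; it is the
# workhorse behind dataset generation and basin labelling. Forcing is
# supported through the time argument.

rk4_batch_step <- function(x, y, h, t, alpha, beta, delta, gamma = 0, omega = 0) {
  f <- function(x, y, t) {
    list(x = y,
         y = -delta * y + alpha * x - beta * x^3 +
           if (gamma != 0) gamma * cos(omega * t) else 0)
  }
  k1 <- f(x, y, t)
  k2 <- f(x + h / 2 * k1$x, y + h / 2 * k1$y, t + h / 2)
  k3 <- f(x + h / 2 * k2$x, y + h / 2 * k2$y, t + h / 2)
  k4 <- f(x + h * k3$x, y + h * k3$y, t + h)
  list(x = x + h / 6 * (k1$x + 2 * k2$x + 2 * k3$x + k4$x),
       y = y + h / 6 * (k1$y + 2 * k2$y + 2 * k3$y + k4$y))
}

# integrate a batch of ICs for N samples at step dt; returns list of two
# n x N matrices (x, y). Errors on divergence.
integrate_batch <- function(ic, N, dt, alpha, beta, delta, gamma = 0,
                            omega = 0, t0 = 0, blowup = 1e6) {
  n <- nrow(ic)
  X <- matrix(NA_real_, n, N); Y <- matrix(NA_real_, n, N)
  x <- ic[, 1L]; y <- ic[, 2L]
  X[, 1L] <- x; Y[, 1L] <- y
  t <- t0
  for (k in seq_len(N - 1L)) {
    s <- rk4_batch_step(x, y, dt, t, alpha, beta, delta, gamma, omega)
    x <- s$x; y <- s$y; t <- t0 + k * dt
    if (anyNA(x) || max(abs(x), abs(y)) > blowup)
      stop("trajectory diverged beyond |state| = ", blowup,
           " during integration", call. = FALSE)
    X[, k + 1L] <- x; Y[, k + 1L] <- y
  }
  list(x = X, y = Y)
}

# Continue integration of a batch of states until each is captured by a sink:
# inside `radius` of an equilibrium with speed below `speed_tol`. Returns
# +1 / -1 labels (NA when undecided within the horizon).
label_batch <- function(states, alpha, beta, delta, horizon_time = 400,
                        radius = NULL, speed_tol = 1e-3, h = 0.1) {
  if (is.null(radius)) radius <- 0.05 * sqrt(alpha / beta)
  s <- sqrt(alpha / beta)
  x <- states[, 1L]; y <- states[, 2L]
  n <- length(x)
  lab <- rep(NA_integer_, n)
  active <- seq_len(n)
  for (k in seq_len(ceiling(horizon_time / h))) {
    st <- rk4_batch_step(x, y, h, 0, alpha, beta, delta)
    x <- st$x; y <- st$y
    speed2 <- y^2 + (-delta * y + alpha * x - beta * x^3)^2
    dpos2 <- (x - s)^2 + y^2
    dneg2 <- (x + s)^2 + y^2
    done <- speed2 < speed_tol^2 & pmin(dpos2, dneg2) < radius^2
    if (any(done)) {
      lab[active[done]] <- ifelse(dpos2[done] < dneg2[done], 1L, -1L)
      keep <- !done
      active <- active[keep]; x <- x[keep]; y <- y[keep]
      if (length(active) == 0L) break
    }
  }
  lab
}

#' Integrate a single Duffing trajectory
#'
#' Samples `N` states at uniform spacing `dt`. Two integration schemes are
#' available: a fixed-step classical Runge-Kutta (`"rk4"`, the default used
#' throughout dataset generation because it is bit-reproducible), and the
#' adaptive Dormand-Prince pair from \pkg{deSolve} (`"ode45"`,
#' `rtol = atol = 1e-9`) as an accuracy reference. Along unforced damped
#' trajectories the energy-like function
#' \eqn{V(x,y) = y^2/2 - \alpha x^2/2 + \beta x^4/4} is non-increasing up to
#' integration tolerance.
#'
#' @param ic numeric length-2 initial condition.
#' @param params a [duffing_params()] object.
#' @param N number of samples (>= 2); the first sample is the initial
#'   condition itself.
#' @param dt sampling interval (> 0).
#' @param t0 initial time.
#' @param method `"rk4"` or `"ode45"`.
#' @param blowup error out when `|state|` exceeds this bound.
#' @return A `state_trajectory`: a list with `states` (`N` x 2 matrix), `dt`,
#'   `t0`, and `true_class` (`NA` until labelled by [label_by_attractor()]).
#' @export
integrate_trajectory <- function(ic, params, N, dt, t0 = 0,
                                 method = c("rk4", "ode45"), blowup = 1e6) {
  method <- match.arg(method)
  stop_if_not_scalar_number(N, "N", positive = TRUE, integerish = TRUE)
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  stop_if_not_scalar_number(dt, "dt", positive = TRUE)
  if (!is.numeric(ic) || length(ic) != 2L || !all(is.finite(ic)))
    stop("ic must be a finite numeric vector of length 2", call. = FALSE)
  if (method == "rk4") {
    b <- integrate_batch(matrix(ic, 1L), N, dt, params$alpha, params$beta,
                         params$delta, params$gamma, params$omega, t0, blowup)
    states <- cbind(x = b$x[1L, ], y = b$y[1L, ])
  } else {
    rhs <- function(t, y, parms) list(duffing_flow(y, params, t))
    sol <- deSolve::ode(y = ic, times = t0 + (0:(N - 1L)) * dt, func = rhs,
                        parms = NULL, method = "ode45",
                        rtol = 1e-9, atol = 1e-9)
    states <- unname(sol[, 2:3, drop = FALSE])
    colnames(states) <- c("x", "y")
    if (max(abs(states)) > blowup)
      stop("trajectory diverged beyond |state| = ", blowup, call. = FALSE)
  }
  structure(list(states = states, dt = dt, t0 = t0, trial_index = NA_integer_,
                 traj_id = NA_integer_, true_class = NA_integer_),
            class = "state_trajectory")
}

#' Energy-like Lyapunov function of the unforced Duffing system
#'
#' \eqn{V(x,y) = y^2/2 - \alpha x^2/2 + \beta x^4/4}; non-increasing along
#' damped, unforced trajectories.
#'
#' @param states matrix with columns `x`, `y` (or length-2 vector).
#' @param params a [duffing_params()] object.
#' @return Numeric vector of `V` values.
#' @export
duffing_energy <- function(states, params) {
  if (is.null(dim(states))) states <- matrix(states, 1L)
  states[, 2L]^2 / 2 - params$alpha * states[, 1L]^2 / 2 +
    params$beta * states[, 1L]^4 / 4
}

#' Label a trajectory by its attractor
#'
#' Continues integration from the trajectory's last stored state until the
#' state is captured by one of the two sinks (within `radius` of the
#' equilibrium and slower than `speed_tol`), and returns `+1` for the
#' positive-`x` sink or `-1` for the negative one. This long-horizon
#' continuation is the ground-truth oracle that defines class membership for
#' the benchmark.
#'
#' @param traj a `state_trajectory` from [integrate_trajectory()], or a
#'   length-2 state vector (treated as an initial condition).
#' @param params a [duffing_params()] object (two-sink regime, `gamma = 0`).
#' @param horizon_time maximum continuation time before giving up.
#' @param radius capture radius; default `0.05 * sqrt(alpha/beta)`.
#' @param speed_tol capture speed threshold.
#' @return `+1L` or `-1L`; errors with "undecided trajectory" if the horizon
#'   is exhausted (the caller may extend it).
#' @export
label_by_attractor <- function(traj, params, horizon_time = 400,
                               radius = NULL, speed_tol = 1e-3) {
  if (params$gamma != 0 || params$beta <= 0)
    stop("labelling requires the unforced two-sink regime", call. = FALSE)
  state <- if (inherits(traj, "state_trajectory"))
    traj$states[nrow(traj$states), ] else as.numeric(traj)
  lab <- label_batch(matrix(state, 1L), params$alpha, params$beta,
                     params$delta, horizon_time, radius, speed_tol)
  if (is.na(lab))
    stop("undecided trajectory: no sink capture within horizon_time = ",
         horizon_time, call. = FALSE)
  lab
}

#' Generate a multi-trial Duffing benchmark dataset
#'
#' For trial \eqn{k = 1, \dots,} `n_trials`, the cubic coefficient is
#' \eqn{\beta_k = \beta + (k-1)\,\epsilon} and `D` trajectories of `N`
#' samples are integrated from fresh i.i.d. Gaussian initial conditions.
#' Every trajectory carries two ground-truth labels: `class`, the attractor
#' of its continuation under the trial's own parameters, and `class_ref`, the
#' attractor its initial condition would reach under the *first* trial's
#' parameters. The latter is the reference frame used by the trial-wise
#' evaluation protocol: when the dynamics drift, a trajectory whose basin
#' changed is exactly one whose `class` and `class_ref` disagree.
#'
#' Per-trial random streams are derived deterministically from `seed` with a
#' counter-based scheme, so adding trials never perturbs earlier trials.
#'
#' @param params a [duffing_params()] object; its `drift_epsilon` and
#'   `n_trials` define the schedule.
#' @param D trajectories per trial.
#' @param N samples per trajectory.
#' @param dt sampling interval.
#' @param sigma standard deviation of the Gaussian initial conditions.
#' @param seed root integer seed.
#' @return A `trial_dataset`; see [trial_dataset()].
#' @examples
#' p <- duffing_params(drift_epsilon = 0.01, n_trials = 3)
#' ds <- generate_trial_sequence(p, D = 20, N = 30, dt = 0.05, sigma = 1, seed = 7)
#' ds
#' @export
generate_trial_sequence <- function(params, D = 1000L, N = 100L, dt = 0.05,
                                    sigma = 1, seed = 1L) {
  stop_if_not_scalar_number(D, "D", positive = TRUE, integerish = TRUE)
  stop_if_not_scalar_number(N, "N", positive = TRUE, integerish = TRUE)
  stop_if_not_scalar_number(dt, "dt", positive = TRUE)
  stop_if_not_scalar_number(sigma, "sigma", positive = TRUE)
  betas <- beta_at_trial(params, seq_len(params$n_trials))
  if (any(betas <= 0))
    stop("drift schedule leaves the two-sink regime before generation",
         call. = FALSE)
  trials <- vector("list", params$n_trials)
  for (k in seq_len(params$n_trials)) {
    trials[[k]] <- generate_one_trial(params, k, betas[k], D, N, dt, sigma, seed)
  }
  trial_dataset(trials, params = params, D = D, N = N, dt = dt,
                sigma = sigma, seed = seed)
}

generate_one_trial <- function(params, k, beta_k, D, N, dt, sigma, seed) {
  ic <- with_seed(derive_seed(seed, k, "initial_conditions"),
                  matrix(rnorm(2L * D, 0, sigma), D, 2L))
  b <- integrate_batch(ic, N, dt, params$alpha, beta_k, params$delta)
  # attractor of the continuation under the trial's own dynamics
  final <- cbind(b$x[, N], b$y[, N])
  lab <- label_batch(final, params$alpha, beta_k, params$delta)
  # reference-frame label: attractor of the same IC under the trial-1 system
  lab_ref <- if (beta_k == params$beta) lab else
    label_batch(ic, params$alpha, params$beta, params$delta)
  if (anyNA(lab) || anyNA(lab_ref))
    stop("undecided trajectory while labelling trial ", k, call. = FALSE)
  list(trial = k, beta = beta_k, x = b$x, y = b$y,
       class = lab, class_ref = lab_ref)
}

#' Class-posterior estimates on a rectangular grid
#'
#' Tiles the phase plane of one trial into `n_bins` x `n_bins` equal
#' rectangular bins spanning the coordinate range of the trial, counts state
#' vectors of each class per bin, and normalizes to class-posterior
#' estimates.
#'
#' @param trial one trial of a [trial_dataset()] (see [get_trial()]).
#' @param n_bins bins per axis.
#' @return A `posterior_grid`: list with `x_edges`, `y_edges`, `counts`
#'   (bins x bins x classes array), `posterior` (same shape, each nonempty
#'   bin summing to 1 over classes), and `classes`.
#' @export
estimate_posterior_grid <- function(trial, n_bins = 25L) {
  stop_if_not_scalar_number(n_bins, "n_bins", positive = TRUE, integerish = TRUE)
  if (is.null(trial$x) || length(trial$x) == 0L)
    stop("empty trial", call. = FALSE)
  xs <- as.vector(trial$x); ys <- as.vector(trial$y)
  cls <- rep(trial$class, ncol(trial$x))
  classes <- sort(unique(cls))
  xe <- seq(min(xs), max(xs), length.out = n_bins + 1L)
  ye <- seq(min(ys), max(ys), length.out = n_bins + 1L)
  ix <- pmin(pmax(findInterval(xs, xe, rightmost.closed = TRUE), 1L), n_bins)
  iy <- pmin(pmax(findInterval(ys, ye, rightmost.closed = TRUE), 1L), n_bins)
  counts <- array(0L, c(n_bins, n_bins, length(classes)))
  for (ci in seq_along(classes)) {
    sel <- cls == classes[ci]
    counts[, , ci] <- as.matrix(table(factor(ix[sel], levels = seq_len(n_bins)),
                                      factor(iy[sel], levels = seq_len(n_bins))))
  }
  tot <- apply(counts, c(1, 2), sum)
  post <- counts
  for (ci in seq_along(classes)) {
    p <- counts[, , ci] / tot
    p[tot == 0L] <- NA_real_
    post[, , ci] <- p
  }
  structure(list(x_edges = xe, y_edges = ye, counts = counts,
                 posterior = post, classes = classes),
            class = "posterior_grid")
}
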