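# Fixtures are built in code at test time; nothing is stored on disk.

# small stationary Duffing dataset (defaults scaled down for unit tests)
tiny_stationary <- function(D = 60, N = 40, seed = 7, delta = 0.9,
                            dt = 0.05, sigma = 1) {
  generate_trial_sequence(duffing_params(delta = delta), D = D, N = N,
                          dt = dt, sigma = sigma, seed = seed)
}

# small drifting Duffing dataset
tiny_drifting <- function(D = 60, N = 40, n_trials = 5, eps = 0.05,
                          seed = 7) {
  p <- duffing_params(delta = 0.9, drift_epsilon = eps, n_trials = n_trials)
  generate_trial_sequence(p, D = D, N = N, dt = 0.05, sigma = 1, seed = seed)
}

# two separable Gaussian blobs as raw patterns
blob_data <- function(n = 40, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n), n, 2) + gap)
  list(x = x, y = rep(c(-1L, 1L), each = n))
}

# hand-built single-trial dataset from a D x N x 2 state array
manual_trial_dataset <- function(xs, ys, class) {
  trial_dataset(list(list(trial = 1L, x = xs, y = ys, class = class)))
}

# a deterministic classifier fixture: order-1 discriminant separating
# x < 0 from x > 0, trained on two tight blobs at (+-1, 0)
sign_classifier <- function() {
  set.seed(42)
  x <- rbind(cbind(rnorm(50, -1, 0.05), rnorm(50, 0, 0.05)),
             cbind(rnorm(50, 1, 0.05), rnorm(50, 0, 0.05)))
  fit_kfd(x, rep(c(-1L, 1L), each = 50), kernel_spec(order = 1), 1e-4)
}

# flatten one trial into its pattern matrix (time-major blocks of size D)
patterns_of <- function(trial) cbind(as.vector(trial$x), as.vector(trial$y))

# pooled within-class scatter in a feature space, normalized by n
within_scatter <- function(Phi, y) {
  S <- matrix(0, ncol(Phi), ncol(Phi))
  for (cl in unique(y)) {
    Zc <- sweep(Phi[y == cl, , drop = FALSE], 2,
                colMeans(Phi[y == cl, , drop = FALSE]))
    S <- S + crossprod(Zc)
  }
  S / nrow(Phi)
}

# shared cache for expensive acceptance computations (filled lazily)
.acceptance_cache <- new.env(parent = emptyenv())
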