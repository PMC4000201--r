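test_that("flow and fixed points follow the double-well structure", {
  p <- duffing_params(alpha = 1, beta = 1, delta = 0.25)
  expect_equal(duffing_flow(c(0, 0), p), c(0, 0))
  eq <- sqrt(p$alpha / p$beta)
  expect_equal(duffing_flow(c(eq, 0), p), c(0, 0))
  # hand evaluation: -0.25*0 + 1*2 - 1*8 = -6
  expect_equal(duffing_flow(c(2, 0), p), c(0, -6))
  expect_error(duffing_flow(c(Inf, 0), p), "finite")

  fp <- fixed_points(p)
  expect_equal(fp$x, c(0, 1, -1))
  expect_equal(fp$stability, c("saddle", "spiral sink", "spiral sink"))
  # saddle eigenvalues: (-0.25 +- sqrt(0.0625 + 4)) / 2
  expect_equal(sort(Re(unname(unlist(fp[1, c("eig1", "eig2")])))),
               sort(c((-0.25 + sqrt(4.0625)) / 2, (-0.25 - sqrt(4.0625)) / 2)))
  # sink eigenvalues: real part -delta/2, imaginary +- sqrt(8 - delta^2)/2
  expect_equal(Re(fp$eig1[2]), -0.125)
  expect_equal(abs(Im(fp$eig1[2])), sqrt(8 - 0.0625) / 2)

  # doubling beta divides the inter-sink distance by sqrt(2)
  fp4 <- fixed_points(duffing_params(alpha = 1, beta = 4))
  expect_equal(fp4$x[2], 0.5)
  d1 <- diff(range(fixed_points(duffing_params(beta = 1))$x))
  d2 <- diff(range(fixed_points(duffing_params(beta = 2))$x))
  expect_equal(d1 / d2, sqrt(2))
})

test_that("fixed-point eigenvalues match a numerical Jacobian to 1e-8", {
  p <- duffing_params(alpha = 1.3, beta = 0.8, delta = 0.6)
  fp <- fixed_points(p)
  for (i in seq_len(nrow(fp))) {
    st <- c(fp$x[i], fp$y[i])
    # finite-difference Jacobian of the flow
    h <- 1e-6
    J <- matrix(NA_real_, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      J[, j] <- (duffing_flow(st + e, p) - duffing_flow(st - e, p)) / (2 * h)
    }
    ev_num <- eigen(J)$values
    ev_ana <- unname(unlist(fp[i, c("eig1", "eig2")]))
    ev_jac <- eigen(duffing_jacobian(st, p))$values
    expect_equal(sort(Re(ev_num)), sort(Re(ev_ana)), tolerance = 1e-7)
    expect_equal(sort(abs(Im(ev_num))), sort(abs(Im(ev_ana))), tolerance = 1e-7)
    expect_equal(sort(Re(ev_jac)), sort(Re(ev_ana)), tolerance = 1e-8)
    expect_equal(sort(abs(Im(ev_jac))), sort(abs(Im(ev_ana))), tolerance = 1e-8)
  }
  expect_error(fixed_points(duffing_params(gamma = 1)), "unforced")
})

test_that("initial-condition sampling is Gaussian, centred and reproducible", {
  ic <- sample_initial_conditions(1000, sigma = 1, seed = 11)
  expect_equal(dim(ic), c(1000L, 2L))
  expect_lt(max(abs(colMeans(ic))), 4 / sqrt(1000))
  expect_identical(ic, sample_initial_conditions(1000, sigma = 1, seed = 11))
  expect_false(identical(ic, sample_initial_conditions(1000, 1, seed = 12)))
  expect_error(sample_initial_conditions(0, 1), "positive")
})

test_that("integration is convergent, dissipative and stays at equilibria", {
  p <- duffing_params(alpha = 1, beta = 1, delta = 0.25)
  tr0 <- integrate_trajectory(c(0, 0), p, N = 50, dt = 0.1)
  expect_true(all(abs(tr0$states) < 1e-12))

  # basin membership: (1.5, 0) relaxes to the positive sink
  trl <- integrate_trajectory(c(1.5, 0), p, N = 1200, dt = 0.1)
  expect_equal(unname(trl$states[1200, ]), c(1, 0), tolerance = 1e-4)

  # step-halving convergence of the fixed-step scheme
  a <- integrate_trajectory(c(1.2, 0.3), p, N = 101, dt = 0.1)
  b <- integrate_trajectory(c(1.2, 0.3), p, N = 201, dt = 0.05)
  expect_equal(unname(a$states[101, ]), unname(b$states[201, ]),
               tolerance = 1e-5)
  # and agreement with the adaptive reference integrator
  c_ <- integrate_trajectory(c(1.2, 0.3), p, N = 101, dt = 0.1,
                             method = "ode45")
  expect_equal(unname(a$states[101, ]), unname(c_$states[101, ]),
               tolerance = 1e-5)

  # Lyapunov function non-increasing along unforced damped trajectories
  for (ic in list(c(1.5, 0), c(-0.4, 1.1), c(0.2, -0.8))) {
    tr <- integrate_trajectory(ic, p, N = 400, dt = 0.05)
    V <- duffing_energy(tr$states, p)
    expect_true(all(diff(V) <= 1e-9))
  }
})

test_that("attractor labelling is decided, symmetric and exact at sinks", {
  p <- duffing_params(delta = 0.9)
  expect_identical(label_by_attractor(c(sqrt(p$alpha / p$beta), 0), p), 1L)
  expect_identical(label_by_attractor(c(-sqrt(p$alpha / p$beta), 0), p), -1L)
  ic <- sample_initial_conditions(60, sigma = 1.2, seed = 3)
  labs <- vapply(seq_len(nrow(ic)), function(i)
    label_by_attractor(ic[i, ], p), integer(1))
  expect_true(all(labs %in% c(-1L, 1L)))
  mir <- vapply(seq_len(nrow(ic)), function(i)
    label_by_attractor(-ic[i, ], p), integer(1))
  expect_identical(mir, -labs)
  expect_error(label_by_attractor(c(0.5, 0.5), p, horizon_time = 0.2),
               "undecided")
})

test_that("trial sequences follow the drift schedule deterministically", {
  p <- duffing_params(delta = 0.9, drift_epsilon = 0.02, n_trials = 4)
  ds <- generate_trial_sequence(p, D = 40, N = 30, dt = 0.05, sigma = 1,
                                seed = 5)
  expect_equal(n_trials(ds), 4L)
  expect_equal(vapply(ds$trials, `[[`, numeric(1), "beta"),
               1 + 0:3 * 0.02)
  # same seed -> identical dataset
  ds2 <- generate_trial_sequence(p, D = 40, N = 30, dt = 0.05, sigma = 1,
                                 seed = 5)
  expect_identical(ds, ds2)
  # adding trials never perturbs earlier trials (substream derivation)
  p6 <- duffing_params(delta = 0.9, drift_epsilon = 0.02, n_trials = 6)
  ds6 <- generate_trial_sequence(p6, D = 40, N = 30, dt = 0.05, sigma = 1,
                                 seed = 5)
  expect_identical(ds$trials[[2]]$x, ds6$trials[[2]]$x)
  # regime violation rejected before generation
  expect_error(duffing_params(beta = 0.1, drift_epsilon = -0.05,
                              n_trials = 10), "two-sink")
})

test_that("basin flips accumulate as the cubic coefficient drifts", {
  # a fixed IC set relabelled under each beta of the schedule: the fraction
  # whose label differs from trial 1 grows (to within sampling slack), and a
  # sufficiently large drift flips at least one of 1000 ICs
  p <- duffing_params(delta = 0.9)
  ic <- sample_initial_conditions(1000, sigma = 1, seed = 21)
  betas <- 1 + (0:4) * 0.05
  labs <- vapply(betas, function(b) {
    pb <- duffing_params(beta = b, delta = 0.9)
    vapply(seq_len(nrow(ic)), function(i) label_by_attractor(ic[i, ], pb),
           integer(1))
  }, integer(nrow(ic)))
  flips <- colMeans(labs != labs[, 1])
  expect_true(all(diff(flips) >= -2 / 1000))
  expect_gte(sum(labs[, 2] != labs[, 1]), 1)   # Lemma-1 style consequence
})

test_that("posterior grids are exact empirical conditionals", {
  ds <- tiny_stationary(D = 20, N = 10)
  tr <- get_trial(ds, 1)
  pg <- estimate_posterior_grid(tr, n_bins = 8)
  # nonempty bins: posteriors sum to 1
  tot <- apply(pg$counts, c(1, 2), sum)
  psum <- apply(pg$posterior, c(1, 2), sum)
  expect_equal(psum[tot > 0], rep(1, sum(tot > 0)))
  # brute-force recount oracle on a 10-pattern toy set
  xs <- matrix(c(0.1, 0.9, 0.5, 0.2, 0.8, 0.3, 0.7, 0.6, 0.4, 0.25), 5, 2)
  ys <- matrix(c(0.2, 0.3, 0.8, 0.7, 0.1, 0.9, 0.4, 0.6, 0.5, 0.35), 5, 2)
  toy <- get_trial(manual_trial_dataset(xs, ys, c(1L, 1L, 2L, 2L, 1L)), 1)
  pg2 <- estimate_posterior_grid(toy, n_bins = 2)
  xall <- as.vector(xs); yall <- as.vector(ys)
  cls <- rep(toy$class, 2)
  xmid <- (min(xall) + max(xall)) / 2; ymid <- (min(yall) + max(yall)) / 2
  for (bx in 1:2) for (by in 1:2) {
    inx <- if (bx == 1) xall < xmid else xall >= xmid
    iny <- if (by == 1) yall < ymid else yall >= ymid
    sel <- inx & iny
    if (!any(sel)) next
    for (ci in seq_along(pg2$classes)) {
      expect_equal(pg2$posterior[bx, by, ci],
                   mean(cls[sel] == pg2$classes[ci]))
    }
  }
  # single-class trial: every nonempty bin is one-hot
  one <- get_trial(manual_trial_dataset(xs, ys, rep(1L, 5)), 1)
  pgo <- estimate_posterior_grid(one, n_bins = 3)
  expect_true(all(pgo$posterior[!is.na(pgo$posterior)] == 1))
})
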