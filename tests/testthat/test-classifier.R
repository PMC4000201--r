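test_that("separable blobs are classified perfectly with calibrated posteriors", {
  bd <- blob_data()
  m <- fit_kfd(bd$x, bd$y, kernel_spec(order = 1), lambda = 1e-3)
  pr <- predict(m, bd$x)
  expect_equal(mean(pr$class != bd$y), 0)
  expect_equal(rowSums(pr$posterior), rep(1, nrow(bd$x)))
  # pattern at a class mean: that class, posterior > 0.5
  mu1 <- colMeans(bd$x[bd$y == 1, ])
  p1 <- predict(m, rbind(mu1))
  expect_identical(p1$class, 1L)
  expect_gt(p1$posterior[, "1"], 0.5)
  expect_error(predict(m, matrix(rnorm(9), 3, 3)), "dimension")
})

test_that("binary KFD matches the least-squares classifier with coded targets", {
  # Fisher direction with ridge r equals, up to positive scale, the ridge
  # least-squares direction on class-centred features with +-coded targets
  set.seed(12)
  x <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60), 30, 2) + 1.2)
  y <- rep(c(-1, 1), each = 30)
  lam <- 1e-2
  spec <- kernel_spec(order = 2)
  m <- fit_kfd(x, y, spec, lam)
  # independent oracle: ridge regression in the same feature space
  Phi <- polynomial_feature_map(x, spec)
  Z <- sweep(Phi, 2, colMeans(Phi))
  n <- nrow(Z)
  St <- crossprod(Z) / n
  # total scatter = within + between; the ridge constant must match the fit
  Sw_ridge <- lam * mean(diag(within_scatter(Phi, y)))
  w_ls <- solve(St + diag(Sw_ridge, ncol(Z)), crossprod(Z, y) / n)
  s_kfd <- discriminant_projection(m, x, n_dims = 1)[, 1]
  s_ls <- drop(Z %*% w_ls)
  expect_gt(abs(cor(s_kfd, s_ls)), 1 - 1e-8)
})

test_that("primal and dual representations agree exactly", {
  set.seed(3)
  x <- rbind(matrix(rnorm(50), 25, 2), matrix(rnorm(50), 25, 2) + 1.5)
  y <- rep(c(0L, 1L), each = 25)
  for (p in c(1, 3)) {
    mp <- fit_kfd(x, y, kernel_spec(order = p, representation = "primal"), 1e-2)
    md <- fit_kfd(x, y, kernel_spec(order = p, representation = "dual"), 1e-2)
    xa <- matrix(rnorm(60), 30, 2)
    pp <- predict(mp, xa); pd <- predict(md, xa)
    expect_identical(pp$class, pd$class)
    expect_equal(pp$posterior, pd$posterior, tolerance = 1e-8)
  }
  # auto representation picks primal for small expansions
  expect_equal(fit_kfd(x, y, kernel_spec(order = 3), 1e-2)$representation,
               "primal")
})

test_that("regularization never increases the training Fisher criterion", {
  set.seed(8)
  x <- rbind(matrix(rnorm(80), 40, 2), matrix(rnorm(80), 40, 2) + 1)
  y <- rep(c(-1, 1), each = 40)
  spec <- kernel_spec(order = 3)
  Phi <- polynomial_feature_map(x, spec)
  Sw <- within_scatter(Phi, y)
  dm <- colMeans(Phi[y == 1, ]) - colMeans(Phi[y == -1, ])
  crit <- vapply(10^seq(-6, 1, length.out = 8), function(lam) {
    m <- fit_kfd(x, y, spec, lam)
    w <- m$basis[, 1]
    (sum(w * dm))^2 / drop(t(w) %*% Sw %*% w)
  }, numeric(1))
  expect_true(all(diff(crit) <= 1e-8 * max(crit)))
})

test_that("discriminant projections are orthonormal and maximally separating", {
  bd <- blob_data(n = 60, gap = 3, seed = 5)
  m <- fit_kfd(bd$x, bd$y, kernel_spec(order = 3), 1e-3)
  B <- m$basis
  expect_lt(max(abs(crossprod(B) - diag(ncol(B)))), 1e-10)
  proj <- discriminant_projection(m, bd$x, n_dims = 3)
  expect_equal(dim(proj), c(120L, 3L))
  expect_error(discriminant_projection(m, bd$x, n_dims = 10), "exceeds")
  # the leading direction separates the projected class means at least as
  # well as random orthonormal directions (Fisher criterion comparison)
  sep <- function(s) {
    (mean(s[bd$y == 1]) - mean(s[bd$y == -1]))^2 /
      (var(s[bd$y == 1]) + var(s[bd$y == -1]))
  }
  Phi <- polynomial_feature_map(bd$x, kernel_spec(order = 3))
  Zc <- sweep(Phi, 2, colMeans(Phi))
  set.seed(31)
  rand_sep <- replicate(25, {
    v <- rnorm(ncol(Phi)); v <- v / sqrt(sum(v^2))
    sep(drop(Zc %*% v))
  })
  expect_gt(sep(proj[, 1]), max(rand_sep))
})

test_that("multi-class fits use K-1 directions and nearest-mean decisions", {
  set.seed(14)
  centers <- rbind(c(0, 0), c(3, 0), c(0, 3))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60, 0, 0.4), 30, 2), 2, -centers[k, ])))
  y <- rep(1:3, each = 30)
  m <- fit_kfd(x, y, kernel_spec(order = 1), 1e-3)
  expect_equal(m$gauss$ncol_decision, 2L)
  pr <- predict(m, x)
  expect_lt(mean(pr$class != y), 0.02)
  expect_equal(rowSums(pr$posterior), rep(1, nrow(x)))
})

test_that("cross-validation is trajectory-blocked, deterministic and symmetric", {
  ds <- tiny_stationary(D = 40, N = 30)
  tr <- get_trial(ds, 1)
  cv <- crossvalidate(tr, kernel_spec(order = 3), 1e-3, k_folds = 8, seed = 4)
  expect_equal(nrow(cv$folds), 8L)
  cv2 <- crossvalidate(tr, kernel_spec(order = 3), 1e-3, k_folds = 8, seed = 4)
  expect_identical(cv, cv2)
  expect_error(crossvalidate(tr, k_folds = 100), "exceeds")
  # mirror symmetry of the double well: negating states and flipping labels
  # gives identical CE fold by fold
  trm <- tr
  trm$x <- -tr$x; trm$y <- -tr$y; trm$class <- -tr$class
  cvm <- crossvalidate(trm, kernel_spec(order = 3), 1e-3, k_folds = 8, seed = 4)
  expect_equal(cv$folds$CE, cvm$folds$CE, tolerance = 1e-10)
  expect_equal(cv$folds$TI, cvm$folds$TI, tolerance = 1e-10)
})

test_that("penalty selection minimizes validation TI with larger-lambda ties", {
  ds <- tiny_stationary(D = 50, N = 30, seed = 2)
  va <- tiny_stationary(D = 50, N = 30, seed = 3)
  sel1 <- select_regularization(ds, va, kernel_spec(order = 3),
                                lam_grid = 0.5)
  expect_equal(sel1$lambda, 0.5)
  grid <- c(1e-4, 1e-2, 1)
  a <- select_regularization(ds, va, kernel_spec(order = 3), grid)
  b <- select_regularization(ds, va, kernel_spec(order = 3), rev(grid))
  expect_equal(a$lambda, b$lambda)   # invariant to grid order
  # linearly separable toy data reach validation TI = 0
  bd <- blob_data(n = 30, gap = 6, seed = 9)
  mk <- function(seed) {
    set.seed(seed)
    xs <- matrix(bd$x[, 1], 60, 1)[, rep(1, 10)] + matrix(rnorm(600, 0, 0.01), 60)
    ys <- matrix(bd$x[, 2], 60, 1)[, rep(1, 10)] + matrix(rnorm(600, 0, 0.01), 60)
    manual_trial_dataset(xs, ys, bd$y)
  }
  selb <- select_regularization(mk(1), mk(2), kernel_spec(order = 1),
                                lam_grid = c(1e-3, 1e-1))
  expect_equal(min(selb$ti), 0)
})

test_that("projected scores stay close to normal on the cubic expansion", {
  # normality in the discriminant subspace, as a tolerance-based smoke test:
  # subsampled per-fold projections fail the Lilliefors test in at most a
  # minority of folds
  ds <- tiny_stationary(D = 60, N = 40, seed = 13)
  tr <- get_trial(ds, 1)
  P <- patterns_of(tr)
  m <- fit_kfd(P, rep(tr$class, 40), kernel_spec(order = 3), 1e-3)
  proj <- discriminant_projection(m, P, n_dims = 1)[, 1]
  y <- rep(tr$class, 40)
  set.seed(77)
  rejections <- unlist(lapply(c(-1, 1), function(cl) {
    replicate(20, lilliefors_test(sample(proj[y == cl], 30))$p_value < 0.05)
  }))
  expect_lte(mean(rejections), 0.35)
})
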