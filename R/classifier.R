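#' Fit a regularized (kernel) Fisher discriminant
#'
#' Fits Fisher's discriminant in the polynomial feature space of a
#' [kernel_spec()], with a ridge term added to the within-class scatter. The
#' ridge is scale-relative: `lambda * mean(diag(Sw))` is added to the
#' diagonal, so `lambda` is dimensionless and comparable across expansion
#' orders.
#'
#' For two classes the discriminant direction is
#' \eqn{w = (S_w + r I)^{-1} (m_2 - m_1)} and patterns are scored by
#' projection onto `w`; class-conditional Gaussians (means, variances and
#' empirical priors of the projected training scores) provide posterior
#' scores, and the decision threshold is their equal-posterior point
#' (`threshold = "gaussian"`, the default) or the midpoint of the projected
#' class means (`"midpoint"`).
#'
#' For `K > 2` classes the top `K - 1` generalized eigendirections of the
#' between- versus regularized within-class scatter are used, orthonormalized
#' by Gram-Schmidt; decisions are by the nearest projected class mean
#' (equivalently, Gaussian posteriors with pooled variances).
#'
#' The representation follows `spec$representation`: the explicit feature map
#' (primal) when the expanded dimension is moderate, or the kernel dual form
#' (binary only), in which the discriminant is expressed as kernel
#' combinations of stored training patterns. Both representations solve the
#' same regularized problem and agree on predictions.
#'
#' @param x numeric matrix of patterns (rows) in the original coordinates.
#' @param labels per-pattern class labels (>= 2 classes, each >= 2 patterns).
#' @param spec a [kernel_spec()].
#' @param lambda ridge penalty (>= 0); singular scatter without
#'   regularization raises an error advising `lambda > 0`.
#' @param threshold binary decision rule, `"gaussian"` or `"midpoint"`.
#' @param n_projection number of orthonormal projection directions retained
#'   for [discriminant_projection()] (defaults to `max(K - 1, 3)`; directions
#'   beyond `K - 1` supplement the discriminant basis with principal
#'   directions of the class-centred data, for visualization only).
#' @return A `kfd_model`.
#' @export
fit_kfd <- function(x, labels, spec = kernel_spec(), lambda = 1e-3,
                    threshold = c("gaussian", "midpoint"),
                    n_projection = NULL) {
  threshold <- match.arg(threshold)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  labels <- as.vector(labels)
  if (nrow(x) != length(labels))
    stop("x and labels length mismatch", call. = FALSE)
  classes <- sort(unique(labels))
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 patterns", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  m <- expanded_dimension(ncol(x), spec)
  rep_used <- switch(spec$representation,
    auto = if (m <= spec$primal_limit) "primal" else "dual",
    spec$representation)
  if (rep_used == "dual" && K > 2L)
    stop("the kernel dual representation is implemented for binary problems; ",
         "use the primal representation for K > 2", call. = FALSE)
  if (is.null(n_projection)) n_projection <- max(K - 1L, 3L)

  fit <- if (rep_used == "primal")
    fit_kfd_primal(x, labels, classes, spec, lambda, n_projection)
  else
    fit_kfd_dual(x, labels, classes, spec, lambda)

  fit$spec <- spec
  fit$classes <- classes
  fit$lambda <- lambda
  fit$threshold <- threshold
  fit$d <- ncol(x)
  fit$representation <- rep_used
  class(fit) <- "kfd_model"
  fit
}

solve_ridge <- function(S, rhs, lambda) {
  ridge <- lambda * mean(diag(S))
  out <- tryCatch(solve(S + diag(ridge, nrow(S)), rhs),
                  error = function(e) NULL)
  if (is.null(out))
    stop("within-class scatter is singular; increase lambda (> 0)",
         call. = FALSE)
  out
}

fit_kfd_primal <- function(x, labels, classes, spec, lambda, n_projection) {
  Phi <- polynomial_feature_map(x, spec)
  n <- nrow(Phi); m <- ncol(Phi)
  K <- length(classes)
  grand <- colMeans(Phi)
  means <- t(vapply(classes, function(cl)
    colMeans(Phi[labels == cl, , drop = FALSE]), numeric(m)))
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  Sw <- matrix(0, m, m)
  for (ci in seq_len(K)) {
    Zc <- sweep(Phi[labels == classes[ci], , drop = FALSE], 2L, means[ci, ])
    Sw <- Sw + crossprod(Zc)
  }
  Sw <- Sw / n

  if (K == 2L) {
    w <- solve_ridge(Sw, means[2L, ] - means[1L, ], lambda)
    basis <- matrix(w / sqrt(sum(w^2)), ncol = 1L)
  } else {
    Sb <- matrix(0, m, m)
    for (ci in seq_len(K)) {
      dm <- means[ci, ] - grand
      Sb <- Sb + (counts[ci] / n) * tcrossprod(dm)
    }
    Mmat <- solve_ridge(Sw, Sb, lambda)
    ei <- eigen(Mmat)
    ord <- order(abs(Re(ei$values)), decreasing = TRUE)
    V <- Re(ei$vectors[, ord[seq_len(K - 1L)], drop = FALSE])
    basis <- gram_schmidt(V)
  }
  # supplement with principal directions of class-centred data (visualization)
  if (ncol(basis) < min(n_projection, m)) {
    Zc <- Phi
    for (ci in seq_len(K))
      Zc[labels == classes[ci], ] <-
        sweep(Phi[labels == classes[ci], , drop = FALSE], 2L, means[ci, ])
    pcs <- svd(Zc, nu = 0L, nv = min(n_projection, m))$v
    basis <- gram_schmidt(cbind(basis, pcs), keep = min(n_projection, m))
  }

  proj <- sweep(Phi, 2L, grand) %*% basis
  gauss <- projected_gaussians(proj, labels, classes, ncol_decision =
                                 if (K == 2L) 1L else K - 1L)
  list(grand_mean = grand, basis = basis, gauss = gauss,
       priors = counts / n)
}

# orthonormalize columns; drops near-dependent columns, keeps at most `keep`
gram_schmidt <- function(V, keep = ncol(V), tol = 1e-10) {
  out <- NULL
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    if (!is.null(out)) v <- v - out %*% crossprod(out, v)
    nv <- sqrt(sum(v^2))
    if (nv > tol) out <- cbind(out, v / nv)
    if (!is.null(out) && ncol(out) >= keep) break
  }
  unname(out)
}

# per-class means / variances of projected scores; only the first
# `ncol_decision` projection columns take part in classification
projected_gaussians <- function(proj, labels, classes, ncol_decision) {
  dec <- proj[, seq_len(ncol_decision), drop = FALSE]
  mu <- matrix(NA_real_, length(classes), ncol_decision)
  v <- matrix(NA_real_, length(classes), ncol_decision)
  for (ci in seq_along(classes)) {
    dc <- dec[labels == classes[ci], , drop = FALSE]
    mu[ci, ] <- colMeans(dc)
    v[ci, ] <- apply(dc, 2L, var)
  }
  if (any(!is.finite(v)) || any(v <= 0))
    stop("degenerate projected class distribution; increase lambda",
         call. = FALSE)
  list(mu = mu, var = v, ncol_decision = ncol_decision)
}

fit_kfd_dual <- function(x, labels, classes, spec, lambda) {
  n <- nrow(x)
  K <- poly_kernel(x, x, spec)
  ind1 <- labels == classes[1L]; ind2 <- labels == classes[2L]
  n1 <- sum(ind1); n2 <- sum(ind2)
  # class-centring operator C = I - sum_c J_c / n_c applied through K
  Cc <- diag(n)
  Cc[ind1, ind1] <- Cc[ind1, ind1] - 1 / n1
  Cc[ind2, ind2] <- Cc[ind2, ind2] - 1 / n2
  # ridge matched to the primal geometry: lambda * trace(Sw) / m
  m <- expanded_dimension(ncol(x), spec)
  ridge <- lambda * sum(diag(Cc %*% K)) / n / m
  dmc <- ifelse(ind2, 1 / n2, 0) - ifelse(ind1, 1 / n1, 0)
  a <- tryCatch(solve(Cc %*% K / n + diag(ridge, n), dmc),
                error = function(e) NULL)
  if (is.null(a))
    stop("dual system singular; increase lambda (> 0)", call. = FALSE)
  s <- drop(K %*% a)
  s0 <- mean(s)                      # grand-mean offset in score space
  nrm <- 1                           # dual scores are used unnormalized
  proj <- matrix(s - s0, ncol = 1L)
  gauss <- projected_gaussians(proj, labels, classes, 1L)
  list(train_x = x, dual_coef = a, score_offset = s0, scale = nrm,
       gauss = gauss, priors = c(n1, n2) / n)
}

# projection coordinates for new raw patterns (primal or dual)
kfd_project <- function(object, x, n_dims = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (ncol(x) != object$d)
    stop("pattern dimension ", ncol(x), " does not match model (",
         object$d, ")", call. = FALSE)
  if (object$representation == "primal") {
    Phi <- polynomial_feature_map(x, object$spec)
    proj <- sweep(Phi, 2L, object$grand_mean) %*% object$basis
  } else {
    s <- drop(poly_kernel(x, object$train_x, object$spec) %*% object$dual_coef)
    proj <- matrix(s - object$score_offset, ncol = 1L)
  }
  if (!is.null(n_dims)) {
    if (n_dims > ncol(proj))
      stop("n_dims = ", n_dims, " exceeds the ", ncol(proj),
           " stored projection directions", call. = FALSE)
    proj <- proj[, seq_len(n_dims), drop = FALSE]
  }
  proj
}

#' Predict classes and posterior scores from a fitted discriminant
#'
#' Labels are the posterior argmax; posteriors come from the per-class
#' Gaussian model of the projected training scores (normalized to sum to 1
#' per pattern). With `threshold = "midpoint"` (binary models) the decision
#' uses the midpoint of the projected class means instead.
#'
#' @param object a `kfd_model`.
#' @param x matrix of patterns in original coordinates.
#' @param ... unused.
#' @return A list with `class` (predicted labels) and `posterior`
#'   (patterns x classes matrix).
#' @export
predict.kfd_model <- function(object, x, ...) {
  g <- object$gauss
  proj <- kfd_project(object, x, n_dims = g$ncol_decision)
  K <- length(object$classes)
  logp <- matrix(0, nrow(proj), K)
  for (ci in seq_len(K)) {
    lp <- log(object$priors[ci])
    for (j in seq_len(g$ncol_decision))
      lp <- lp + dnorm(proj[, j], g$mu[ci, j], sqrt(g$var[ci, j]), log = TRUE)
    logp[, ci] <- lp
  }
  logp <- logp - apply(logp, 1L, max)
  post <- exp(logp)
  post <- post / rowSums(post)
  colnames(post) <- as.character(object$classes)
  if (object$threshold == "midpoint" && K == 2L) {
    mid <- mean(g$mu[, 1L])
    flip <- g$mu[2L, 1L] > g$mu[1L, 1L]
    cls_idx <- if (flip) (proj[, 1L] > mid) + 1L else (proj[, 1L] <= mid) + 1L
    cls <- object$classes[cls_idx]
  } else {
    cls <- object$classes[max.col(post, ties.method = "first")]
  }
  list(class = cls, posterior = post)
}

#' @export
print.kfd_model <- function(x, ...) {
  cat("Regularized kernel Fisher discriminant (", x$representation,
      " form)\n", sep = "")
  cat("  expansion order:", x$spec$order, " lambda:", x$lambda,
      " classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Project patterns onto the maximally discriminating directions
#'
#' Coordinates of patterns in the orthonormal discriminant basis fixed at fit
#' time (by default up to three directions, the usual low-dimensional view of
#' an expanded state space).
#'
#' @param model a `kfd_model` (primal representation).
#' @param x matrix of patterns.
#' @param n_dims number of directions (must not exceed the stored basis).
#' @return A `nrow(x)` x `n_dims` coordinate matrix.
#' @export
discriminant_projection <- function(model, x, n_dims = 3L) {
  kfd_project(model, x, n_dims = n_dims)
}

#' Trajectory-blocked k-fold cross-validation of TI and CE
#'
#' Splits whole trajectories of one trial into `k_folds` folds (seeded
#' shuffle; a trajectory is never split across folds), fits the discriminant
#' on the training folds and evaluates the trajectory incoherence and
#' classification error on the held-out fold.
#'
#' @param trial a trial record from [get_trial()], or a `trial_dataset`
#'   (its first trial is used).
#' @param spec a [kernel_spec()].
#' @param lambda ridge penalty.
#' @param k_folds number of folds (default 20; must not exceed the number of
#'   trajectories).
#' @param L convergence tail length (see [is_convergent()]); default
#'   `max(1, round(0.1 * N))`.
#' @param seed seed for the fold assignment.
#' @param threshold passed to [fit_kfd()].
#' @return A list with `folds` (data frame of per-fold `TI`, `CE`),
#'   `ti_mean`, `ti_sem`, `ce_mean`, `ce_sem`, `L`.
#' @export
crossvalidate <- function(trial, spec = kernel_spec(), lambda = 1e-3,
                          k_folds = 20L, L = NULL, seed = 1L,
                          threshold = "gaussian") {
  if (inherits(trial, "trial_dataset")) trial <- get_trial(trial, 1L)
  P <- trial_patterns(trial)
  D <- length(trial$class)
  N <- nrow(P) / D
  if (is.null(L)) L <- max(1L, round(0.1 * N))
  if (k_folds > D)
    stop("k_folds exceeds the number of trajectories", call. = FALSE)
  fold <- with_seed(derive_seed(seed, 0L, "folds"),
                    sample(rep(seq_len(k_folds), length.out = D)))
  res <- vapply(seq_len(k_folds), function(f) {
    tr_id <- which(fold != f); te_id <- which(fold == f)
    rows_tr <- rep(tr_id, N) + rep((seq_len(N) - 1L) * D, each = length(tr_id))
    rows_te <- rep(te_id, N) + rep((seq_len(N) - 1L) * D, each = length(te_id))
    ytr <- rep(trial$class[tr_id], N)
    model <- fit_kfd(P[rows_tr, , drop = FALSE], ytr, spec, lambda,
                     threshold = threshold,
                     n_projection = length(unique(ytr)) - 1L)
    pred <- predict(model, P[rows_te, , drop = FALSE])$class
    PR <- matrix(pred, length(te_id), N)
    truth <- trial$class[te_id]
    ti <- mean(rowSums(PR[, (N - L + 1L):N, drop = FALSE] != truth) > 0L)
    ce <- mean(PR != truth)
    c(ti, ce)
  }, numeric(2))
  folds <- data.frame(fold = seq_len(k_folds), TI = res[1L, ], CE = res[2L, ])
  list(folds = folds,
       ti_mean = mean(folds$TI), ti_sem = sd(folds$TI) / sqrt(k_folds),
       ce_mean = mean(folds$CE), ce_sem = sd(folds$CE) / sqrt(k_folds),
       L = L)
}

# fit on all patterns of a trial (optionally with reference-frame labels)
fit_trial <- function(trial, spec, lambda, threshold = "gaussian",
                      frame = "generation", n_projection = NULL) {
  P <- trial_patterns(trial)
  y <- trial_pattern_labels(trial, frame)
  if (is.null(n_projection)) n_projection <- length(unique(y)) - 1L
  fit_kfd(P, y, spec, lambda, threshold = threshold,
          n_projection = n_projection)
}

# TI and CE of a fitted model on one trial
evaluate_trial <- function(model, trial, L,
                           frame = c("generation", "reference")) {
  frame <- match.arg(frame)
  P <- trial_patterns(trial)
  D <- length(trial$class)
  N <- nrow(P) / D
  pred <- predict(model, P)$class
  PR <- matrix(pred, D, N)
  truth <- trial_labels(trial, frame)
  tail_err <- rowSums(PR[, (N - L + 1L):N, drop = FALSE] != truth)
  list(TI = mean(tail_err > 0L), CE = mean(PR != truth),
       divergent = which(tail_err > 0L))
}

#' Select the ridge penalty by minimum validation TI
#'
#' Fits the discriminant on the training trial for every value of
#' `lam_grid`, evaluates the trajectory incoherence on the validation trial,
#' and returns the grid value with minimum TI. Ties are broken toward the
#' larger penalty (stronger regularization).
#'
#' @param train,validation trial records (or `trial_dataset`s, first trial
#'   used).
#' @param spec a [kernel_spec()].
#' @param lam_grid candidate penalties (default logarithmic, 1e-6 .. 10,
#'   8 points).
#' @param L convergence tail length.
#' @param threshold passed to [fit_kfd()].
#' @return A list with `lambda` (selected), `ti` (validation TI per grid
#'   value), `grid`.
#' @export
select_regularization <- function(train, validation, spec = kernel_spec(),
                                  lam_grid = 10^seq(-6, 1, length.out = 8L),
                                  L = NULL, threshold = "gaussian") {
  if (inherits(train, "trial_dataset")) train <- get_trial(train, 1L)
  if (inherits(validation, "trial_dataset")) validation <- get_trial(validation, 1L)
  if (length(lam_grid) == 0L) stop("empty lambda grid", call. = FALSE)
  N <- n_patterns_per_traj(train)
  if (is.null(L)) L <- max(1L, round(0.1 * N))
  grid <- sort(lam_grid)
  tis <- vapply(grid, function(lam) {
    model <- tryCatch(fit_trial(train, spec, lam, threshold),
                      error = function(e) NULL)
    if (is.null(model)) return(Inf)
    evaluate_trial(model, validation, L)$TI
  }, numeric(1))
  if (all(!is.finite(tis)))
    stop("no lambda on the grid produced a valid fit", call. = FALSE)
  best <- max(which(tis == min(tis)))   # ties -> larger lambda
  list(lambda = grid[best], ti = tis, grid = grid)
}

n_patterns_per_traj <- function(trial) {
  if (!is.null(trial$x)) ncol(trial$x) else ncol(trial$states[[1L]])
}

#' Sweep the expansion order and select the most parsimonious optimum
#'
#' For each candidate order, tunes the ridge penalty on the validation trial
#' ([select_regularization()]) and runs trajectory-blocked k-fold
#' cross-validation of TI on the training trial. The selected order is, by
#' default, the smallest order whose mean CV TI lies within one standard
#' error of the overall minimum (`rule = "1se"`); this is the usual
#' parsimony rule for nested model families, here the space of lowest
#' dimensionality that already attains the optimal out-of-sample trajectory
#' coherence. `rule = "min"` takes the strict minimizer (ties toward the
#' smaller order).
#'
#' @param train,validation trial records or `trial_dataset`s.
#' @param orders candidate polynomial orders.
#' @param lam_grid ridge grid for [select_regularization()].
#' @param k_folds folds for [crossvalidate()].
#' @param L convergence tail length.
#' @param seed fold-assignment seed.
#' @param rule `"1se"` or `"min"`.
#' @return A list with `order` (selected), `table` (per-order mean CV TI,
#'   SEM, tuned lambda), `rule`.
#' @export
select_expansion_order <- function(train, validation, orders = 1:5,
                                   lam_grid = 10^seq(-6, 1, length.out = 8L),
                                   k_folds = 20L, L = NULL, seed = 1L,
                                   rule = c("1se", "min")) {
  rule <- match.arg(rule)
  if (inherits(train, "trial_dataset")) train <- get_trial(train, 1L)
  if (inherits(validation, "trial_dataset")) validation <- get_trial(validation, 1L)
  tab <- data.frame(order = orders, ti_mean = NA_real_, ti_sem = NA_real_,
                    lambda = NA_real_)
  for (i in seq_along(orders)) {
    spec <- kernel_spec(order = orders[i])
    sel <- select_regularization(train, validation, spec, lam_grid, L = L)
    cv <- crossvalidate(train, spec, sel$lambda, k_folds = k_folds, L = L,
                        seed = seed)
    tab$ti_mean[i] <- cv$ti_mean
    tab$ti_sem[i] <- cv$ti_sem
    tab$lambda[i] <- sel$lambda
  }
  imin <- which.min(tab$ti_mean)
  sel_order <- if (rule == "1se") {
    thr <- tab$ti_mean[imin] + tab$ti_sem[imin]
    orders[which(tab$ti_mean <= thr)[1L]]
  } else {
    orders[which(tab$ti_mean == tab$ti_mean[imin])[1L]]
  }
  list(order = sel_order, table = tab, rule = rule)
}
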