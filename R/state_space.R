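#' Polynomial kernel specification
#'
#' Describes the inhomogeneous polynomial kernel
#' \eqn{k(x, z) = (c + x \cdot z)^p} and its explicit feature space: all
#' monomials of total degree up to `p`, each scaled by the square root of its
#' multinomial coefficient so that the dot product of two mapped vectors
#' equals the kernel exactly. The expanded dimension is
#' \eqn{\binom{d + p}{p}} for `d` input coordinates.
#'
#' @param order polynomial degree `p` (>= 1).
#' @param offset additive constant `c` (>= 0; default 1, inhomogeneous).
#' @param representation `"auto"` chooses the explicit (primal) map whenever
#'   the expanded dimension does not exceed `primal_limit` and the kernel
#'   dual form otherwise; `"primal"`/`"dual"` force a representation.
#' @param primal_limit expanded-dimension threshold for `"auto"`.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(order = 3L, offset = 1,
                        representation = c("auto", "primal", "dual"),
                        primal_limit = 2000L) {
  stop_if_not_scalar_number(order, "order", positive = TRUE, integerish = TRUE)
  stop_if_not_scalar_number(offset, "offset")
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  representation <- match.arg(representation)
  structure(list(order = as.integer(order), offset = offset,
                 representation = representation,
                 primal_limit = as.integer(primal_limit)),
            class = "kernel_spec")
}

#' Expanded-space dimension of a polynomial kernel
#' @param d input dimension.
#' @param spec a [kernel_spec()].
#' @return `choose(d + p, p)`.
#' @export
expanded_dimension <- function(d, spec) choose(d + spec$order, spec$order)

# exponent table: one row per monomial, columns = exponent of each input
# coordinate; the implicit offset exponent is order - rowSums.
monomial_exponents <- function(d, p) {
  grid <- expand.grid(rep(list(0:p), d), KEEP.OUT.ATTRS = FALSE)
  as.matrix(grid[rowSums(grid) <= p, , drop = FALSE])
}

#' Explicit polynomial feature map
#'
#' Maps each row of `x` to the vector of all monomials of total degree up to
#' `spec$order`, scaled by square-root multinomial coefficients (the offset
#' contributes \eqn{\sqrt{c}} per unused degree), so that
#' `tcrossprod(polynomial_feature_map(x, spec))` reproduces
#' [poly_kernel()] exactly.
#'
#' @param x numeric matrix (rows = patterns) or vector (one pattern).
#' @param spec a [kernel_spec()].
#' @return Numeric matrix with `choose(d + p, p)` columns.
#' @examples
#' sp <- kernel_spec(order = 2)
#' phi <- polynomial_feature_map(rbind(c(1, 2), c(0, 1)), sp)
#' tcrossprod(phi)[1, 2] == (1 + sum(c(1, 2) * c(0, 1)))^2
#' @export
polynomial_feature_map <- function(x, spec) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (!all(is.finite(x))) stop("non-finite input to feature map", call. = FALSE)
  d <- ncol(x); p <- spec$order
  E <- monomial_exponents(d, p)
  k0 <- p - rowSums(E)
  coefs <- sqrt(factorial(p) /
                  (factorial(k0) * apply(factorial(E), 1L, prod))) *
    sqrt(spec$offset)^k0
  Phi <- matrix(NA_real_, nrow(x), nrow(E))
  for (j in seq_len(nrow(E))) {
    v <- rep(1, nrow(x))
    for (i in seq_len(d)) {
      e <- E[j, i]
      if (e > 0L) v <- v * x[, i]^e
    }
    Phi[, j] <- coefs[j] * v
  }
  if (!all(is.finite(Phi)))
    stop("feature map overflow for extreme inputs", call. = FALSE)
  Phi
}

#' Inhomogeneous polynomial kernel
#'
#' \eqn{k(x, z) = (c + x \cdot z)^p}, a Mercer kernel whose reproducing
#' feature space is spanned by the monomials of [polynomial_feature_map()].
#'
#' @param x,z numeric matrices (rows = patterns) or vectors; must share the
#'   input dimension.
#' @param spec a [kernel_spec()].
#' @return The Gram matrix `nrow(x)` x `nrow(z)` (a scalar for two vectors).
#' @export
poly_kernel <- function(x, z, spec) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (is.null(dim(z))) z <- matrix(z, 1L)
  if (ncol(x) != ncol(z))
    stop("dimension mismatch between x and z", call. = FALSE)
  (spec$offset + tcrossprod(x, z))^spec$order
}

#' Delay-coordinate embedding specification
#'
#' @param n_lags number of lagged copies appended to each sample (>= 0;
#'   0 means no embedding).
#' @param lag delay between copies, in samples (>= 1).
#' @return An `embedding_spec` object.
#' @export
embedding_spec <- function(n_lags = 1L, lag = 1L) {
  stop_if_not_scalar_number(n_lags, "n_lags", integerish = TRUE)
  if (n_lags < 0) stop("n_lags must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(lag, "lag", positive = TRUE, integerish = TRUE)
  structure(list(n_lags = as.integer(n_lags), lag = as.integer(lag)),
            class = "embedding_spec")
}

#' Delay-coordinate embedding of a multivariate series
#'
#' Each output vector concatenates the current sample with `n_lags` lagged
#' copies (`lag` samples apart), aligned to the most recent sample. For a
#' series of length `T` the output has `T - n_lags * lag` rows. When applied
#' to a [trial_dataset()], each trajectory is embedded separately so no
#' output vector ever spans a trajectory boundary.
#'
#' @param series numeric matrix (rows = time) or vector, or a
#'   `trial_dataset`.
#' @param spec an [embedding_spec()].
#' @return The embedded series (matrix), or an embedded `trial_dataset`.
#' @examples
#' delay_embed(1:4, embedding_spec(n_lags = 1, lag = 1))
#' @export
delay_embed <- function(series, spec) {
  UseMethod("delay_embed")
}

#' @export
delay_embed.default <- function(series, spec) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1L)
  span <- spec$n_lags * spec$lag
  if (nrow(series) <= span)
    stop("series too short for the requested embedding (need length > ",
         span, ")", call. = FALSE)
  if (spec$n_lags == 0L) return(series)
  t_out <- (span + 1L):nrow(series)
  blocks <- lapply(0:spec$n_lags, function(l)
    series[t_out - l * spec$lag, , drop = FALSE])
  do.call(cbind, blocks)
}

#' @export
delay_embed.trial_dataset <- function(series, spec) {
  trials <- lapply(series$trials, function(tr) {
    P <- trial_patterns(tr)
    D <- if (!is.null(tr$x)) nrow(tr$x) else nrow(tr$states[[1L]])
    N <- nrow(P) / D
    emb <- lapply(seq_len(D), function(j) {
      rows <- j + (seq_len(N) - 1L) * D
      delay_embed.default(P[rows, , drop = FALSE], spec)
    })
    Nn <- nrow(emb[[1L]]); dd <- ncol(emb[[1L]])
    states <- lapply(seq_len(dd), function(cc)
      t(vapply(emb, function(m) m[, cc], numeric(Nn))))
    list(trial = tr$trial, beta = tr$beta, states = states,
         class = tr$class, class_ref = tr$class_ref)
  })
  do.call(trial_dataset, c(list(trials = trials), series$meta))
}
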