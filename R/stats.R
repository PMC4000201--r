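#' Priestley-Subba Rao test of second-order stationarity
#'
#' The simplest form of the evolutionary-spectrum stationarity test: the
#' series is divided into `n_time_segments` contiguous segments, a
#' periodogram is computed per segment, and the log-periodogram ordinates
#' are averaged within `n_freq_bands` frequency bands, giving a
#' time-by-frequency table \eqn{Y(t, \omega)}. The logarithm stabilizes the
#' variance of the spectral estimates (a log chi-squared with two degrees of
#' freedom has variance \eqn{\pi^2/6} regardless of the spectral level), so
#' the table obeys a linear model with known error variance, and the two-way
#' decomposition yields chi-squared tests: the between-time main effect
#' (non-stationarity of the spectral level), the between-frequency effect,
#' and the interaction (time-varying spectral shape). Stationarity is
#' rejected when the between-time effect (or the interaction) is
#' significant.
#'
#' @param series univariate numeric time series.
#' @param n_time_segments number of time segments (>= 2).
#' @param n_freq_bands number of frequency bands (>= 2).
#' @param taper optional `"hann"` data taper per segment; the default
#'   `"none"` keeps the raw periodogram, whose ordinates are asymptotically
#'   independent, matching the known-variance chi-squared calibration.
#' @return A `psr_result`: list with the `Y` table, segment boundaries,
#'   band frequency centres, the chi-squared statistics and degrees of
#'   freedom, and `p_time`, `p_freq`, `p_interaction`.
#' @examples
#' set.seed(1)
#' psr_test(rnorm(1024))$p_time          # calibrated under stationarity
#' psr_test(c(rnorm(512), 3 * rnorm(512)))$p_time  # variance step: rejected
#' @export
psr_test <- function(series, n_time_segments = 6L, n_freq_bands = 6L,
                     taper = c("none", "hann")) {
  taper <- match.arg(taper)
  series <- as.numeric(series)
  stop_if_not_scalar_number(n_time_segments, "n_time_segments",
                            positive = TRUE, integerish = TRUE)
  stop_if_not_scalar_number(n_freq_bands, "n_freq_bands",
                            positive = TRUE, integerish = TRUE)
  if (anyNA(series)) stop("series contains NA", call. = FALSE)
  if (sd(series) == 0) stop("zero-variance series", call. = FALSE)
  n <- length(series)
  seg_len <- n %/% n_time_segments
  n_freq <- (seg_len - 1L) %/% 2L
  m_band <- n_freq %/% n_freq_bands
  if (seg_len < 8L || m_band < 1L)
    stop("series too short for ", n_time_segments, " segments x ",
         n_freq_bands, " bands", call. = FALSE)
  win <- if (taper == "hann")
    0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1))) else
      rep(1, seg_len)
  Y <- matrix(NA_real_, n_time_segments, n_freq_bands)
  for (t in seq_len(n_time_segments)) {
    x <- series[((t - 1L) * seg_len + 1L):(t * seg_len)]
    x <- (x - mean(x)) * win
    I <- Mod(fft(x))^2 / seg_len
    I <- I[2:(n_freq + 1L)]
    logI <- log(pmax(I, .Machine$double.xmin))
    for (b in seq_len(n_freq_bands))
      Y[t, b] <- mean(logI[((b - 1L) * m_band + 1L):(b * m_band)])
  }
  sigma2 <- (pi^2 / 6) / m_band   # variance of a band mean of log-chisq_2 ordinates
  Tn <- n_time_segments; B <- n_freq_bands
  rowm <- rowMeans(Y); colm <- colMeans(Y); g <- mean(Y)
  ss_time <- B * sum((rowm - g)^2)
  ss_freq <- Tn * sum((colm - g)^2)
  resid <- Y - outer(rowm, rep(1, B)) - outer(rep(1, Tn), colm) + g
  ss_int <- sum(resid^2)
  df_time <- Tn - 1L; df_freq <- B - 1L; df_int <- (Tn - 1L) * (B - 1L)
  stat_time <- ss_time / sigma2
  stat_freq <- ss_freq / sigma2
  stat_int <- ss_int / sigma2
  structure(list(
    Y = Y,
    segment_length = seg_len,
    band_centers = (seq_len(B) - 0.5) * m_band / n_freq * pi,
    statistics = c(time = stat_time, freq = stat_freq,
                   interaction = stat_int),
    df = c(time = df_time, freq = df_freq, interaction = df_int),
    p_time = pchisq(stat_time, df_time, lower.tail = FALSE),
    p_freq = pchisq(stat_freq, df_freq, lower.tail = FALSE),
    p_interaction = pchisq(stat_int, df_int, lower.tail = FALSE)
  ), class = "psr_result")
}

#' @export
print.psr_result <- function(x, ...) {
  cat("Priestley-Subba Rao stationarity test\n")
  cat(sprintf("  between-time:   chi2 = %.2f, df = %d, p = %.4g\n",
              x$statistics["time"], x$df["time"], x$p_time))
  cat(sprintf("  interaction:    chi2 = %.2f, df = %d, p = %.4g\n",
              x$statistics["interaction"], x$df["interaction"],
              x$p_interaction))
  invisible(x)
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' \eqn{JSD(p, q) = H(m) - (H(p) + H(q))/2} with \eqn{m = (p+q)/2}.
#' Symmetric, non-negative, and bounded by \eqn{\ln 2} nats (1 bit).
#'
#' @param p,q non-negative vectors on the same support, each summing to 1
#'   (tolerance 1e-9).
#' @param base `"nats"` (natural log, default) or `"bits"`.
#' @return The divergence (scalar).
#' @export
js_divergence <- function(p, q, base = c("nats", "bits")) {
  base <- match.arg(base)
  if (length(p) != length(q))
    stop("p and q must share support", call. = FALSE)
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("p and q must be probability distributions (sum 1, non-negative)",
         call. = FALSE)
  H <- function(w) { w <- w[w > 0]; -sum(w * log(w)) }
  m <- (p + q) / 2
  out <- H(m) - (H(p) + H(q)) / 2
  out <- max(out, 0)
  if (base == "bits") out / log(2) else out
}

#' Wilks' lambda for multivariate group separation
#'
#' \eqn{\Lambda = \det(W) / \det(W + B)} from the within- and between-group
#' scatter matrices, with the Bartlett chi-squared approximation for the
#' p-value. Values near 1 indicate indistinguishable group means.
#'
#' @param groups list of numeric matrices (rows = observations), one per
#'   group; each group needs more observations than variables.
#' @return A list with `lambda`, `chi_sq`, `df`, `p_value`.
#' @export
wilks_lambda <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups", call. = FALSE)
  groups <- lapply(groups, function(g) {
    if (is.null(dim(g))) matrix(g, ncol = 1L) else as.matrix(g)
  })
  d <- ncol(groups[[1L]])
  ns <- vapply(groups, nrow, integer(1))
  if (any(ns <= d))
    stop("each group needs more observations than dimensions", call. = FALSE)
  n <- sum(ns); g <- length(groups)
  grand <- colMeans(do.call(rbind, groups))
  W <- matrix(0, d, d); B <- matrix(0, d, d)
  for (gr in groups) {
    mu <- colMeans(gr)
    W <- W + crossprod(sweep(gr, 2L, mu))
    B <- B + nrow(gr) * tcrossprod(mu - grand)
  }
  detW <- det(W)
  if (detW <= 0)
    stop("singular within-group scatter", call. = FALSE)
  lambda <- detW / det(W + B)
  chi <- -(n - 1 - (d + g) / 2) * log(lambda)
  df <- d * (g - 1)
  list(lambda = lambda, chi_sq = chi, df = df,
       p_value = pchisq(chi, df, lower.tail = FALSE))
}

#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov statistic against a Gaussian with estimated mean and
#' variance, with the Dallal-Wilkinson-corrected p-value.
#'
#' @param sample numeric vector, `n >= 4`, non-constant.
#' @return A list with `statistic` and `p_value`.
#' @export
lilliefors_test <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 4L) stop("need n >= 4", call. = FALSE)
  if (sd(sample) == 0) stop("constant sample", call. = FALSE)
  ht <- nortest::lillie.test(sample)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Normality-gated two-sample comparison
#'
#' Applies the Lilliefors normality test to both samples; when normality is
#' accepted for both at `alpha_normality`, compares means with the
#' two-tailed Welch t-test, otherwise with the Mann-Whitney U test. Returns
#' which test ran.
#'
#' @param a,b numeric samples (each `n >= 4`, non-degenerate).
#' @param alpha_normality significance level of the normality gate.
#' @return A list with `test` (`"t"` or `"mann-whitney"`), `p_value`,
#'   `statistic`, and the two normality p-values.
#' @export
trial_comparison <- function(a, b, alpha_normality = 0.05) {
  if (length(a) < 4L || length(b) < 4L)
    stop("need at least 4 observations per sample", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("degenerate (constant) sample", call. = FALSE)
  pa <- lilliefors_test(a)$p_value
  pb <- lilliefors_test(b)$p_value
  if (pa > alpha_normality && pb > alpha_normality) {
    ht <- t.test(a, b)
    list(test = "t", p_value = ht$p.value,
         statistic = unname(ht$statistic),
         normality_p = c(a = pa, b = pb))
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    list(test = "mann-whitney", p_value = ht$p.value,
         statistic = unname(ht$statistic),
         normality_p = c(a = pa, b = pb))
  }
}

#' Classification-certainty margin
#'
#' Per-pattern certainty: largest posterior minus second largest (0 for a
#' uniform posterior, 1 for a one-hot posterior). Optionally averaged per
#' trial.
#'
#' @param posteriors matrix of per-pattern class posteriors (rows sum to 1).
#' @param trials optional per-pattern trial index for trial summaries.
#' @return A list with `certainty` (per pattern) and, when `trials` is
#'   given, `by_trial` (data frame of per-trial means).
#' @export
certainty_measure <- function(posteriors, trials = NULL) {
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, 1L)
  if (any(posteriors < -1e-12) ||
      any(abs(rowSums(posteriors) - 1) > 1e-6))
    stop("rows of posteriors must be probability distributions", call. = FALSE)
  cert <- apply(posteriors, 1L, function(p) {
    s <- sort(p, decreasing = TRUE)
    s[1L] - s[2L]
  })
  out <- list(certainty = cert)
  if (!is.null(trials)) {
    agg <- tapply(cert, trials, mean)
    out$by_trial <- data.frame(trial = as.integer(names(agg)),
                               certainty = as.numeric(agg))
  }
  out
}
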