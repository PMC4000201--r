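#' Gaussian spike-density estimation and binning
#'
#' Converts spike trains into per-unit rate signals: each unit's spikes are
#' convolved with a Gaussian kernel of that unit's bandwidth, and the
#' resulting intensity (spikes per second) is averaged within uniform bins
#' (100 ms by default). The bin value is the exact average of the Gaussian
#' mixture over the bin, so the integral of each unit's density over the
#' full range recovers its spike count up to edge truncation.
#'
#' @param spike_times list of numeric vectors of spike times in seconds,
#'   one per unit (names are kept as unit ids), or a two-column data frame
#'   `(unit, time)`.
#' @param bandwidths per-unit Gaussian bandwidths (seconds); recycled if
#'   scalar. See [select_bandwidths()].
#' @param bin_width bin width in seconds (default 0.1).
#' @param t_range length-2 numeric range covered by the bins; defaults to
#'   the span of all spikes, extended to whole bins.
#' @return A `rate_matrix`: list with `times` (bin centres), `rates`
#'   (bins x units matrix, spikes/s), `bin_width`, `bandwidths`.
#' @export
spike_density <- function(spike_times, bandwidths, bin_width = 0.1,
                          t_range = NULL) {
  spike_times <- as_unit_list(spike_times)
  n_units <- length(spike_times)
  if (length(bandwidths) == 1L) bandwidths <- rep(bandwidths, n_units)
  if (length(bandwidths) != n_units)
    stop("need one bandwidth per unit", call. = FALSE)
  if (any(bandwidths <= 0)) stop("bandwidths must be > 0", call. = FALSE)
  stop_if_not_scalar_number(bin_width, "bin_width", positive = TRUE)
  if (is.null(t_range)) {
    all_s <- unlist(spike_times)
    if (length(all_s) == 0L) stop("no spikes and no t_range", call. = FALSE)
    t_range <- range(all_s)
  }
  if (diff(t_range) <= 0) stop("empty t_range", call. = FALSE)
  n_bins <- ceiling(diff(t_range) / bin_width)
  edges <- t_range[1L] + (0:n_bins) * bin_width
  rates <- matrix(0, n_bins, n_units,
                  dimnames = list(NULL, names(spike_times)))
  for (u in seq_len(n_units)) {
    s <- spike_times[[u]]
    if (length(s) == 0L) next
    if (any(s < t_range[1L] - 1e-9 | s > t_range[2L] + 1e-9))
      stop("spike times outside t_range for unit ", u, call. = FALSE)
    bw <- bandwidths[u]
    # exact bin average of the Gaussian mixture:
    # (1/h) * sum_s [Phi((b - s)/bw) - Phi((a - s)/bw)]
    upper <- outer(edges[-1L], s, function(e, sp) pnorm((e - sp) / bw))
    lower <- outer(edges[-(n_bins + 1L)], s, function(e, sp) pnorm((e - sp) / bw))
    rates[, u] <- rowSums(upper - lower) / bin_width
  }
  structure(list(times = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                 rates = rates, bin_width = bin_width,
                 bandwidths = bandwidths),
            class = "rate_matrix")
}

as_unit_list <- function(spike_times) {
  if (is.data.frame(spike_times)) {
    split(spike_times[[2L]], spike_times[[1L]])
  } else if (is.list(spike_times)) {
    spike_times
  } else stop("spike_times must be a list or two-column data frame",
              call. = FALSE)
}

#' Per-unit kernel bandwidth selection
#'
#' Applies a plug-in bandwidth rule to each unit's spike times: the
#' Sheather-Jones plug-in (`"sj"`, default) or Silverman's rule of thumb
#' (`"silverman"`). Units with too few spikes (or where the plug-in rule
#' fails) fall back to Silverman's rule and ultimately to `fallback`.
#'
#' @param spike_times as in [spike_density()].
#' @param method `"sj"` or `"silverman"`.
#' @param fallback bandwidth (seconds) for degenerate units.
#' @return Named numeric vector of per-unit bandwidths.
#' @export
select_bandwidths <- function(spike_times, method = c("sj", "silverman"),
                              fallback = 0.05) {
  method <- match.arg(method)
  spike_times <- as_unit_list(spike_times)
  vapply(spike_times, function(s) {
    if (length(s) < 2L || sd(s) == 0) return(fallback)
    bw <- switch(method,
      sj = tryCatch(bw.SJ(s), error = function(e) bw.nrd0(s)),
      silverman = bw.nrd0(s))
    if (!is.finite(bw) || bw <= 0) fallback else bw
  }, numeric(1))
}

#' Read spike events from delimited text
#'
#' Expects two numeric columns (unit id, spike time in seconds), separated
#' by whitespace or commas. Events are grouped by unit and sorted in time;
#' negative times are rejected.
#'
#' @param path path to the event file.
#' @return Named list of sorted spike-time vectors, one per unit (empty
#'   list, with a warning, for an empty file).
#' @export
read_spike_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty spike-event file: ", path)
    return(list())
  }
  parts <- strsplit(lines, "[,[:space:]]+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop("malformed spike-event row(s): line ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  unit <- vapply(parts, function(p) p[1L], character(1))
  tm <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(tm))
    stop("non-numeric spike time at line ",
         paste(head(which(is.na(tm)), 5L), collapse = ", "), call. = FALSE)
  if (any(tm < 0))
    stop("negative spike time at line ",
         paste(head(which(tm < 0), 5L), collapse = ", "), call. = FALSE)
  out <- split(tm, unit)
  lapply(out, sort)
}
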