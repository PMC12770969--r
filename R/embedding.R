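## Delay selection and delay-coordinate construction.

#' Average mutual information of a series with its lagged copy
#'
#' Estimates `I(x(t); x(t + lag))` for `lag = 1, ..., max_lag` from a
#' two-dimensional equal-width histogram on the range of `x`, in natural
#' log units.  The first local minimum of this curve is the standard choice
#' of embedding delay.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag to evaluate.
#' @param n_bins Histogram bins per axis; default
#'   `ceiling(sqrt(length(x) / 5))` clamped to `[8, 32]`.
#' @return Numeric vector of length `max_lag` (nonnegative).  A constant
#'   series yields all zeros with a warning.
#' @export
average_mutual_information <- function(x, max_lag, n_bins = NULL) {
  x <- as.numeric(x)
  max_lag <- check_count(max_lag, "max_lag", 1L)
  if (length(x) <= max_lag + 1L)
    stop_param("series length must exceed max_lag + 1")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant series: AMI is identically zero")
    return(numeric(max_lag))
  }
  n_bins <- n_bins %||% min(32L, max(8L, ceiling(sqrt(length(x) / 5))))
  n_bins <- check_count(n_bins, "n_bins", 2L)
  ix <- bin_index(x, rng, n_bins)
  vapply(seq_len(max_lag), function(l)
    ami_from_bins(ix[seq_len(length(x) - l)], ix[(1 + l):length(x)], n_bins),
    0)
}

bin_index <- function(x, rng, n_bins) {
  ix <- findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1L),
                     rightmost.closed = TRUE)
  pmin.int(pmax.int(ix, 1L), n_bins)
}

ami_from_bins <- function(a, b, n_bins) {
  jt <- tabulate(a + n_bins * (b - 1L), n_bins * n_bins) / length(a)
  jm <- matrix(jt, n_bins)
  pa <- rowSums(jm); pb <- colSums(jm)
  m <- jm > 0
  sum(jm[m] * log(jm[m] / (pa[row(jm)[m]] * pb[col(jm)[m]])))
}

#' Choose an embedding delay from an AMI curve
#'
#' Returns the smallest lag that is a strict local minimum of the curve.
#' If no interior minimum exists, falls back to the first lag at which the
#' AMI has decayed to `1/e` of its value at lag 1; failing that, the last
#' lag is returned with a warning.
#'
#' @param ami Numeric AMI curve over lags `1, ..., length(ami)`.
#' @return The selected delay (integer lag).
#' @export
select_delay <- function(ami) {
  if (!length(ami)) stop_param("empty AMI curve")
  n <- length(ami)
  if (n >= 3L)
    for (l in 2:(n - 1L))
      if (ami[l - 1L] > ami[l] && ami[l] < ami[l + 1L]) return(l)
  below <- which(ami <= ami[1] / exp(1))
  if (length(below)) return(below[1])
  warning("no AMI minimum or 1/e decay found; using the maximum lag")
  n
}

#' Per-node embedding delays for a trajectory set
#'
#' For each node the AMI curve is estimated per segment and averaged across
#' segments (segments are independent runs and are never concatenated), and
#' the delay is the first strict local minimum of the averaged curve.
#'
#' @param ts A [trajectory_set()].
#' @param max_lag Largest lag considered.
#' @param n_bins Histogram bins (default as in
#'   [average_mutual_information()], based on the segment length).
#' @return Integer vector of per-node delays (in samples).
#' @export
select_delays <- function(ts, max_lag = 50, n_bins = NULL) {
  stopifnot(inherits(ts, "trajectory_set"))
  N <- n_nodes_ts(ts)
  vapply(seq_len(N), function(i) {
    curves <- vapply(ts$segments, function(seg)
      average_mutual_information(seg[, i], max_lag, n_bins),
      numeric(max_lag))
    select_delay(rowMeans(curves))
  }, 0L)
}

#' Delay-coordinate vectors of one node within one segment
#'
#' Builds the matrix whose row at time `t` is
#' `(x(t), x(t - tau), ..., x(t - (k-1) tau))` (newest first), for every `t`
#' in the segment at which the full delay window exists.  Rows never span
#' segment boundaries; callers aggregate across segments.
#'
#' @param x Numeric series of one node within one segment.
#' @param tau Delay in samples.
#' @param k Embedding dimension (number of delayed copies).
#' @return List with `rows` (matrix, possibly 0-row) and `row_times`
#'   (1-based time indices of the rows within the segment).
#' @export
delay_vectors <- function(x, tau, k) {
  x <- as.numeric(x)
  tau <- check_count(tau, "tau", 1L)
  k <- check_count(k, "k", 1L)
  w <- (k - 1L) * tau
  Tn <- length(x)
  if (Tn < w + 1L) {
    warning("segment too short for the delay window; returning no rows")
    return(list(rows = matrix(numeric(0), 0, k),
                row_times = integer(0)))
  }
  times <- (w + 1L):Tn
  rows <- vapply(0:(k - 1L), function(j) x[times - j * tau],
                 numeric(length(times)))
  if (!is.matrix(rows)) rows <- matrix(rows, nrow = 1L)
  list(rows = rows, row_times = times)
}

#' Embedding specification
#'
#' Bundles the per-node delays and the embedding dimension.
#'
#' @param taus Integer vector of per-node delays (recycled if scalar).
#' @param k Embedding dimension; the default choice for an `n`-dimensional
#'   node is `k = 2 n + 1`.
#' @export
embedding_spec <- function(taus, k) {
  k <- check_count(k, "k", 1L)
  taus <- vapply(taus, check_count, 0L, name = "taus", min = 1L)
  structure(list(taus = taus, k = k), class = "embedding_spec")
}
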