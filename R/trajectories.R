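## Observable time-series container.
##
## A trajectory_set holds one scalar observable per node, partitioned into
## independent simulation segments.  Segments are separate runs from
## independent initial conditions; they are never concatenated numerically,
## and every downstream operation (delay vectors, derivative targets) is
## applied strictly within a segment.

#' Construct a trajectory set
#'
#' @param segments List of numeric matrices, one per independent run, each
#'   with rows = time samples and columns = nodes.  All segments must share
#'   the node count.
#' @param dt Sampling interval in model time units.
#' @param node_ids Optional integer identities of the columns (defaults to
#'   `1:N`); kept so that sub-networks of partially observed systems stay
#'   addressable.
#' @param observable_name Name of the recorded observable.
#' @param model,params Optional provenance (model name and parameter list).
#' @return Object of class `trajectory_set`.
#' @export
trajectory_set <- function(segments, dt, node_ids = NULL,
                           observable_name = "x", model = NULL,
                           params = NULL) {
  if (!is.list(segments) || !length(segments))
    stop_param("segments must be a non-empty list of matrices")
  segments <- lapply(segments, as.matrix)
  ncols <- vapply(segments, ncol, 0L)
  if (length(unique(ncols)) != 1L)
    stop_param("all segments must have the same node count")
  if (any(vapply(segments, nrow, 0L) < 2L))
    stop_param("every segment needs at least 2 samples")
  if (any(!vapply(segments, function(m) all(is.finite(m)), TRUE)))
    stop_param("segments contain non-finite values")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop_param("dt must be a positive scalar")
  node_ids <- node_ids %||% seq_len(ncols[1])
  structure(
    list(segments = segments, dt = as.numeric(dt),
         node_ids = as.integer(node_ids),
         observable_name = as.character(observable_name),
         model = model, params = params),
    class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  ns <- vapply(x$segments, nrow, 0L)
  cat(sprintf(
    "trajectory_set: %d nodes, %d segment(s), %d samples total, dt = %g\n",
    ncol(x$segments[[1]]), length(x$segments), sum(ns), x$dt))
  cat(sprintf("observable: %s%s\n", x$observable_name,
              if (!is.null(x$model)) paste0("  (model: ", x$model, ")")
              else ""))
  invisible(x)
}

n_nodes_ts <- function(ts) ncol(ts$segments[[1]])

total_samples <- function(ts) sum(vapply(ts$segments, nrow, 0L))

#' Keep only the first `n` segments of a trajectory set
#'
#' Convenience for data-length sweeps where increasing measurement length
#' means pooling more independent runs.
#'
#' @param ts A [trajectory_set()].
#' @param n Number of leading segments to keep.
#' @export
head_segments <- function(ts, n) {
  n <- check_count(n, "n", 1L)
  ts$segments <- ts$segments[seq_len(min(n, length(ts$segments)))]
  ts
}

#' Pool the segments of several trajectory sets
#'
#' All inputs must agree in node count, sampling interval and observable.
#'
#' @param ... [trajectory_set()] objects.
#' @export
combine_trajectories <- function(...) {
  tss <- list(...)
  stopifnot(all(vapply(tss, inherits, TRUE, "trajectory_set")))
  if (length(unique(vapply(tss, function(t) t$dt, 0))) != 1L ||
      length(unique(vapply(tss, n_nodes_ts, 0L))) != 1L)
    stop_param("trajectory sets are not compatible")
  out <- tss[[1]]
  out$segments <- do.call(c, lapply(tss, function(t) t$segments))
  out
}

#' Add white Gaussian measurement noise
#'
#' @param ts A [trajectory_set()].
#' @param variance Noise variance (`0` returns the input unchanged).
#' @param seed RNG seed.
#' @return A new [trajectory_set()] with i.i.d. zero-mean Gaussian noise of
#'   the given variance added to every sample.
#' @export
add_measurement_noise <- function(ts, variance, seed) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (!is.numeric(variance) || variance < 0 || !is.finite(variance))
    stop_param("variance must be a nonnegative number")
  if (variance == 0) return(ts)
  sdv <- sqrt(variance)
  ts$segments <- with_seed(seed, lapply(ts$segments, function(m)
    m + matrix(stats::rnorm(length(m), sd = sdv), nrow(m))))
  ts
}

#' Apply a static observation function
#'
#' Models the case where the recorded signal is a memoryless function
#' `phi(x)` of the observable state rather than the state itself.
#'
#' @param ts A [trajectory_set()].
#' @param phi One of `"identity"`, `"square"`, `"logistic"`
#'   (`1 / (1 + exp(-x))`).
#' @export
observe <- function(ts, phi = c("identity", "square", "logistic")) {
  stopifnot(inherits(ts, "trajectory_set"))
  phi <- match.arg(phi)
  f <- switch(phi, identity = identity, square = function(x) x^2,
              logistic = function(x) 1 / (1 + exp(-x)))
  if (phi != "identity") {
    ts$segments <- lapply(ts$segments, f)
    ts$observable_name <- sprintf("%s(%s)", phi, ts$observable_name)
  }
  ts
}

#' Write / read a trajectory set as delimited text with a JSON manifest
#'
#' Values go to `path` as CSV with columns `segment,time,node_0,...`; the
#' sampling interval and provenance go to a sidecar manifest at
#' `paste0(path, ".json")`.  The round trip preserves values to full double
#' precision and keeps segment boundaries.
#'
#' @param ts A [trajectory_set()].
#' @param path CSV file path.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns a [trajectory_set()].
#' @export
write_trajectories <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  blocks <- lapply(seq_along(ts$segments), function(s) {
    m <- ts$segments[[s]]
    cbind(segment = s - 1L, time = (seq_len(nrow(m)) - 1L) * ts$dt, m)
  })
  tab <- do.call(rbind, blocks)
  colnames(tab) <- c("segment", "time",
                     paste0("node_", ts$node_ids - 1L))
  utils::write.table(format(as.data.frame(tab), digits = 17,
                            scientific = TRUE, trim = TRUE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  manifest <- list(dt = ts$dt, observable_name = ts$observable_name,
                   model = ts$model, params = ts$params,
                   n_segments = length(ts$segments),
                   node_ids = ts$node_ids - 1L)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  mpath <- paste0(path, ".json")
  if (!file.exists(mpath))
    stop_param("missing manifest '%s'", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L || !identical(names(df)[1:2], c("segment", "time")))
    stop_param("trajectory file must start with columns 'segment,time'")
  segs <- split(df, df$segment)
  segs <- segs[order(as.integer(names(segs)))]
  segments <- lapply(segs, function(b) {
    tt <- b$time
    if (any(diff(tt) <= 0)) {
      bad <- which(diff(tt) <= 0)[1] + 1L
      stop_param("non-monotone time within segment %s at row %d",
                 b$segment[1], bad)
    }
    as.matrix(b[, -(1:2), drop = FALSE])
  })
  trajectory_set(segments, dt = manifest$dt,
                 node_ids = (manifest$node_ids %||%
                               (seq_len(ncol(segments[[1]])) - 1L)) + 1L,
                 observable_name = manifest$observable_name %||% "x",
                 model = manifest$model,
                 params = manifest$params)
}
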