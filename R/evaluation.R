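## Scoring inferred couplings against ground truth, and synchronization.

get_khat <- function(object) {
  if (inherits(object, "nips")) object$khat
  else as.matrix(object)
}

#' ROC analysis of an inferred coupling matrix
#'
#' Scores the off-diagonal entries of the estimated coupling matrix against
#' the true adjacency.  The AUROC is computed as the rank statistic
#' P(score of a random true edge > score of a random non-edge), counting
#' ties one half; the curve is traced at every distinct score.  An Otsu
#' threshold on the scores gives a concrete binary network prediction.
#'
#' @param object A `nips` fit or a numeric score matrix (rows = targets).
#' @param truth A [directed_network()] with at least one edge and one
#'   non-edge off the diagonal.
#' @return Object of class `nips_roc`: `auroc`, `thresholds`, `fpr`, `tpr`,
#'   `otsu_threshold`, `binary_prediction`.
#' @export
auroc <- function(object, truth) {
  khat <- get_khat(object)
  stopifnot(inherits(truth, "directed_network"))
  if (!identical(dim(khat), dim(truth$adjacency)))
    stop_param("khat and truth have different node sets")
  off <- row(khat) != col(khat)
  scores <- khat[off]
  labels <- truth$adjacency[off]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_param("degenerate truth: need at least one edge and one non-edge")
  rk <- rank(scores)
  auc <- (sum(rk[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  lab_sorted <- labels[ord]
  tp_cum <- cumsum(lab_sorted)
  fp_cum <- cumsum(1 - lab_sorted)
  ## index of the last element of each threshold group in the sorted order
  grp <- match(scores[ord], thr)
  last <- which(diff(c(grp, Inf)) != 0)
  tpr <- c(0, tp_cum[last] / n_pos, 1)
  fpr <- c(0, fp_cum[last] / n_neg, 1)
  eps <- tryCatch(otsu_threshold(scores), error = function(e) NA_real_)
  pred <- matrix(0, nrow(khat), ncol(khat))
  if (is.finite(eps)) pred[off] <- as.numeric(scores > eps)
  structure(list(auroc = auc, thresholds = c(Inf, thr, -Inf),
                 fpr = fpr, tpr = tpr, otsu_threshold = eps,
                 binary_prediction = pred, n_pos = n_pos, n_neg = n_neg),
            class = "nips_roc")
}

#' @export
print.nips_roc <- function(x, ...) {
  cat(sprintf("ROC over %d edges / %d non-edges: AUROC = %.4f\n",
              x$n_pos, x$n_neg, x$auroc))
  if (is.finite(x$otsu_threshold))
    cat(sprintf("Otsu threshold %.4g -> %d predicted edges\n",
                x$otsu_threshold, sum(x$binary_prediction)))
  invisible(x)
}

#' @export
plot.nips_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("AUROC = %.3f", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Otsu's threshold of a score distribution
#'
#' The threshold maximizing the between-class variance of a 256-bin
#' equal-width histogram over the score range; ties are broken toward the
#' lower threshold.  Used to binarize the estimated coupling matrix into a
#' concrete network prediction.
#'
#' @param scores Numeric values with at least two distinct entries.
#' @param n_bins Histogram resolution.
#' @return The threshold (a score value strictly inside the range).
#' @export
otsu_threshold <- function(scores, n_bins = 256L) {
  scores <- as.numeric(scores)
  rng <- range(scores)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop_param("scores are constant; no threshold exists")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(bin_index(scores, rng, n_bins), n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  valid <- seq_len(n_bins - 1L)
  w0v <- w0[valid]; mu0v <- mu0[valid]
  between <- ifelse(w0v > 0 & w0v < 1,
                    (mu_t * w0v - mu0v)^2 / (w0v * (1 - w0v)), -Inf)
  t_idx <- which.max(between)  # first max = lower threshold on ties
  edges[t_idx + 1L]
}

#' Weight-recovery correlation
#'
#' Squared Pearson correlation between the estimated and true coupling
#' strengths over all off-diagonal pairs (true zeros included).  Because
#' the estimate is a sum of squared coefficients, the square-root transform
#' is also offered for comparison on the weight scale.
#'
#' @param object A `nips` fit or score matrix.
#' @param truth A [directed_network()] carrying the true weights.
#' @param transform `"raw"` correlates `khat` itself, `"sqrt"` its square
#'   root.
#' @return Squared Pearson correlation in `[0, 1]`.
#' @export
weight_recovery <- function(object, truth,
                            transform = c("raw", "sqrt")) {
  khat <- get_khat(object)
  stopifnot(inherits(truth, "directed_network"))
  transform <- match.arg(transform)
  if (!identical(dim(khat), dim(truth$weights)))
    stop_param("khat and truth have different node sets")
  off <- row(khat) != col(khat)
  x <- khat[off]
  if (transform == "sqrt") x <- sqrt(x)
  y <- truth$weights[off]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_param("zero variance; correlation undefined")
  stats::cor(x, y)^2
}

#' Kuramoto order parameter of a trajectory set
#'
#' Extracts a phase for every node by the analytic-signal (Hilbert)
#' method on the mean-removed series and returns
#' `R(t) = | mean_n exp(i theta_n(t)) |`, the standard synchronization
#' index: 1 for complete phase locking, near 0 for incoherent phases.
#'
#' @param ts A [trajectory_set()].
#' @param window Optional centred moving-average smoothing width (samples).
#' @return For a single segment a numeric vector over time; otherwise a
#'   list of such vectors.
#' @export
kuramoto_order <- function(ts, window = 0L) {
  stopifnot(inherits(ts, "trajectory_set"))
  res <- lapply(ts$segments, function(seg) {
    ph <- apply(seg, 2, function(x) Arg(analytic_signal(x - mean(x))))
    R <- Mod(rowMeans(exp(1i * ph)))
    if (window > 1L) {
      R <- stats::filter(R, rep(1 / window, window), sides = 2)
      R <- as.numeric(R)
    }
    R
  })
  if (length(res) == 1L) res[[1]] else res
}

## Analytic signal via the FFT (positive frequencies doubled).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Smallest data length reaching a target reconstruction accuracy
#'
#' Runs the full simulate-infer-score pipeline of a scenario at increasing
#' data lengths (pooling more independent runs) and returns the smallest
#' grid value whose mean AUROC over `n_seeds` replicate scenarios reaches
#' `auroc_target`.  Simulated runs are cached per seed and extended lazily,
#' so early stopping costs nothing.
#'
#' @param scenario A scenario list as accepted by [run_scenario()].
#' @param auroc_target Target mean AUROC.
#' @param grid Ascending total sample counts (multiples of the scenario's
#'   samples per run).
#' @param n_seeds Replicates to average over.
#' @param base_seed Seed from which replicate seeds are derived.
#' @return The smallest passing grid value, or `NA` if none passes; the
#'   mean AUROC per evaluated grid point is attached as attribute
#'   `"auroc"`.
#' @export
samples_to_target <- function(scenario, auroc_target, grid, n_seeds = 3L,
                              base_seed = 1L) {
  if (!length(grid)) stop_param("empty grid")
  if (is.unsorted(grid)) stop_param("grid must be ascending")
  n_seeds <- check_count(n_seeds, "n_seeds", 1L)
  cache <- vector("list", n_seeds)
  means <- numeric(0)
  for (g in seq_along(grid)) {
    aucs <- vapply(seq_len(n_seeds), function(s) {
      env <- scenario_realization(scenario, child_seed(base_seed, s),
                                  cache[[s]], grid[g])
      cache[[s]] <<- env
      env$auroc
    }, 0)
    means[g] <- mean(aucs)
    names(means)[g] <- as.character(grid[g])
    if (means[g] >= auroc_target) {
      out <- grid[g]
      attr(out, "auroc") <- means
      return(out)
    }
  }
  out <- NA_integer_
  attr(out, "auroc") <- means
  warning("target AUROC not reached on the grid")
  out
}
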