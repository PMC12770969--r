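## The model-fitting core: network inference from partial states.

#' Infer directed network coupling from scalar observables
#'
#' Fits, independently for every node, an additive model of the node's
#' observable dynamics: a polynomial of order `r` in the node's own `k`
#' delayed observations (the forced delay embedding of the node, coupling
#' inputs acting as external forcing) plus a univariate polynomial of order
#' `r1` in each other node's current observable.  The fitted coupling-block
#' coefficients, squared and summed per source, give a nonnegative estimated
#' coupling matrix `khat` whose entry `(i, j)` scores the directed edge from
#' `j` to `i`.
#'
#' With `embedding = "network"` the whole network is embedded instead: the
#' dynamics of each node are regressed on multivariate polynomials in the
#' delayed observations of *every* node (one shared intercept), which needs
#' far more data but remains applicable when nodes are coupled through
#' unobservable states.
#'
#' All regressions are plain least squares (Tikhonov-regularized when
#' `ridge > 0`).  Rows never span segment boundaries, and each node's
#' regression is independent of the others, so results do not depend on the
#' order in which nodes are processed.
#'
#' @param ts A [trajectory_set()].
#' @param k Embedding dimension (delayed copies per node); `2 n + 1`
#'   suffices for `n`-dimensional node dynamics.
#' @param r Polynomial order of the self (or, for network embedding, per
#'   node) block.
#' @param r1 Polynomial order of the coupling blocks (node embedding only).
#' @param mode `"continuous"` regresses the central-difference derivative;
#'   `"map"` regresses the next observation (discrete-time dynamics).
#' @param embedding `"node"` (default) or `"network"`.
#' @param taus Per-node delays in samples (scalar recycled).  Default: for
#'   `"continuous"` mode the delays are selected per node by the first
#'   local minimum of the average mutual information; for `"map"` mode the
#'   unit delay is used (delay coordinates of a map are successive
#'   iterates).
#' @param ridge Nonnegative Tikhonov weight, see [solve_least_squares()].
#' @param max_lag,n_bins Passed to [select_delays()] when `taus` is NULL.
#' @param nodes Optional subset of target nodes to fit (rows of `khat`);
#'   other rows are zero.
#' @param keep_fits Store per-node targets and residuals so that
#'   [fitted()], [residuals()] work (default: yes unless the stored values
#'   would exceed ~5e6 numbers).
#' @return An object of class `nips` with components `khat` (N x N,
#'   nonnegative, zero diagonal), `coefficients` (per-node list), `taus`,
#'   `k`, `r`, `r1`, `mode`, `embedding`, `ridge`, `n_rows`, `n_cols`,
#'   `residual_rms`, and (if kept) `Y` and `residuals` lists.
#' @seealso [auroc()], [weight_recovery()], [otsu_threshold()]
#' @export
nips <- function(ts, k, r = 3, r1 = 1, mode = c("continuous", "map"),
                 embedding = c("node", "network"), taus = NULL, ridge = 0,
                 max_lag = 50, n_bins = NULL, nodes = NULL,
                 keep_fits = NULL) {
  stopifnot(inherits(ts, "trajectory_set"))
  mode <- match.arg(mode)
  embedding <- match.arg(embedding)
  k <- check_count(k, "k", 1L)
  N <- n_nodes_ts(ts)
  nodes <- nodes %||% seq_len(N)
  if (is.null(taus)) {
    taus <- if (mode == "map") rep(1L, N)
    else select_delays(ts, max_lag = max_lag, n_bins = n_bins)
  }
  if (length(taus) == 1L) taus <- rep(as.integer(taus), N)
  spec <- embedding_spec(taus, k)
  basis <- basis_spec(r, r1)
  cl <- match.call()
  if (embedding == "node")
    fit_node_embedding(ts, spec, basis, mode, ridge, nodes, keep_fits, cl)
  else
    fit_network_embedding(ts, spec, basis, mode, ridge, nodes, keep_fits, cl)
}

fit_node_embedding <- function(ts, spec, basis, mode, ridge, nodes,
                               keep_fits, cl) {
  N <- n_nodes_ts(ts)
  khat <- matrix(0, N, N)
  coefs <- vector("list", N)
  resid <- vector("list", N)
  Ys <- vector("list", N)
  rms <- rep(NA_real_, N)
  n_rows <- rep(NA_integer_, N)
  n_cols <- count_coefficients(N, spec$k, basis$r, basis$r1,
                               "node_embedding")
  keep <- keep_fits %||% (total_samples(ts) * length(nodes) <= 5e6)
  for (i in nodes) {
    reg <- build_node_regression(i, ts, spec, basis, mode)
    Z <- solve_least_squares(reg$A, reg$Y, ridge)
    khat[i, ] <- coupling_row(Z, N, spec$k, basis, i)
    coefs[[i]] <- Z
    rr <- reg$Y - drop(reg$A %*% Z)
    rms[i] <- sqrt(mean(rr^2))
    n_rows[i] <- nrow(reg$A)
    if (keep) {
      resid[[i]] <- rr
      Ys[[i]] <- reg$Y
    }
  }
  new_nips(khat, coefs, spec, basis, mode, "node", ridge, n_rows, n_cols,
           rms, if (keep) Ys, if (keep) resid, nodes, ts, cl)
}

## Whole-network embedding: the design matrix is shared by all target
## nodes (it depends only on the data), so it is built and factorized once
## and solved against all targets simultaneously.
fit_network_embedding <- function(ts, spec, basis, mode, ridge, nodes,
                                  keep_fits, cl) {
  N <- n_nodes_ts(ts)
  k <- spec$k
  taus <- spec$taus
  expo <- monomial_exponents(k, basis$r)
  n_beta <- nrow(expo)
  w_max <- (k - 1L) * max(taus)
  blocks <- list(); targets <- list()
  for (s in seq_along(ts$segments)) {
    seg <- ts$segments[[s]]
    Tn <- nrow(seg)
    tg_times <- if (mode == "continuous") 2:(Tn - 1L) else 1:(Tn - 1L)
    times <- tg_times[tg_times >= w_max + 1L]
    if (!length(times)) next
    Ablk <- matrix(1, length(times), 1L + N * (n_beta - 1L))
    for (j in seq_len(N)) {
      dv <- vapply(0:(k - 1L), function(d) seg[times - d * taus[j], j],
                   numeric(length(times)))
      if (!is.matrix(dv)) dv <- matrix(dv, nrow = 1L)
      Q <- eval_monomials(dv, expo)
      Ablk[, 1L + (j - 1L) * (n_beta - 1L) + seq_len(n_beta - 1L)] <-
        Q[, -1L, drop = FALSE]
    }
    blocks[[s]] <- Ablk
    Ymat <- if (mode == "continuous")
      (seg[times + 1L, , drop = FALSE] - seg[times - 1L, , drop = FALSE]) /
        (2 * ts$dt)
    else seg[times + 1L, , drop = FALSE]
    targets[[s]] <- Ymat
  }
  if (!length(blocks)) stop_param("no usable rows for network embedding")
  A <- do.call(rbind, blocks)
  Ymat <- do.call(rbind, targets)
  n_cols <- ncol(A)
  if (nrow(A) <= n_cols)
    warning(sprintf("network embedding: %d rows for %d columns; %s",
                    nrow(A), n_cols, "system is underdetermined"))
  Zmat <- solve_ls_multi(A, Ymat[, nodes, drop = FALSE], ridge)
  khat <- matrix(0, N, N)
  coefs <- vector("list", N)
  resid <- vector("list", N)
  Ys <- vector("list", N)
  rms <- rep(NA_real_, N)
  keep <- keep_fits %||% (nrow(A) * length(nodes) <= 5e6)
  for (ii in seq_along(nodes)) {
    i <- nodes[ii]
    Z <- Zmat[, ii]
    ssq <- vapply(seq_len(N), function(j)
      sum(Z[1L + (j - 1L) * (n_beta - 1L) + seq_len(n_beta - 1L)]^2), 0)
    ssq[i] <- 0
    khat[i, ] <- ssq
    coefs[[i]] <- Z
    rr <- Ymat[, i] - drop(A %*% Z)
    rms[i] <- sqrt(mean(rr^2))
    if (keep) {
      resid[[i]] <- rr
      Ys[[i]] <- Ymat[, i]
    }
  }
  n_rows <- rep(NA_integer_, N); n_rows[nodes] <- nrow(A)
  new_nips(khat, coefs, spec, basis, mode, "network", ridge, n_rows,
           n_cols, rms, if (keep) Ys, if (keep) resid, nodes, ts, cl)
}

## Least squares with several right-hand sides (shared design).
solve_ls_multi <- function(A, Ymat, ridge) {
  if (ridge == 0 && nrow(A) >= ncol(A)) {
    qrA <- qr(A, LAPACK = TRUE)
    dR <- abs(diag(qr.R(qrA)))
    if (min(dR) > max(dR) * 1e-10)
      return(as.matrix(qr.coef(qrA, Ymat)))
  }
  sv <- svd(A)
  f <- if (ridge > 0) sv$d / (sv$d^2 + ridge * sv$d[1]^2) else {
    tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
    ifelse(sv$d > tol, 1 / sv$d, 0)
  }
  sv$v %*% (f * crossprod(sv$u, Ymat))
}

new_nips <- function(khat, coefs, spec, basis, mode, embedding, ridge,
                     n_rows, n_cols, rms, Ys, resid, nodes, ts, cl) {
  structure(
    list(khat = khat, coefficients = coefs, taus = spec$taus, k = spec$k,
         r = basis$r, r1 = basis$r1, mode = mode, embedding = embedding,
         ridge = ridge, n_rows = n_rows, n_cols = n_cols,
         residual_rms = rms, Y = Ys, residuals = resid, nodes = nodes,
         dt = ts$dt, node_ids = ts$node_ids, model = ts$model,
         call = cl),
    class = "nips")
}

#' @export
print.nips <- function(x, ...) {
  N <- nrow(x$khat)
  cat(sprintf("nips fit: %d nodes, %s embedding, %s mode\n", N,
              x$embedding, x$mode))
  cat(sprintf("  k = %d, r = %d, r1 = %d, delays in [%d, %d], ridge = %g\n",
              x$k, x$r, x$r1, min(x$taus), max(x$taus), x$ridge))
  cat(sprintf("  %s rows x %d columns per node; median residual RMS %.3g\n",
              paste(range(x$n_rows, na.rm = TRUE), collapse = "-"),
              x$n_cols, stats::median(x$residual_rms, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.nips <- function(object, ...) {
  off <- row(object$khat) != col(object$khat)
  scores <- object$khat[off]
  eps <- tryCatch(otsu_threshold(scores), error = function(e) NA_real_)
  out <- list(fit = object, otsu = eps,
              n_predicted_edges = if (is.na(eps)) NA_integer_ else
                sum(scores > eps),
              score_quantiles = stats::quantile(scores),
              residual_rms = summary(object$residual_rms),
              underdetermined = any(object$n_rows <= object$n_cols,
                                    na.rm = TRUE))
  class(out) <- "summary.nips"
  out
}

#' @export
print.summary.nips <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Otsu threshold %.3g -> %s predicted edges\n", x$otsu,
              format(x$n_predicted_edges)))
  if (x$underdetermined)
    cat("  warning: at least one node system was underdetermined\n")
  invisible(x)
}

#' @export
#' @rdname nips
#' @param object,x A `nips` fit.
#' @param type For `coef`: `"coupling"` returns the `khat` matrix,
#'   `"coefficients"` the per-node coefficient vectors.
#' @param ... Unused.
coef.nips <- function(object, type = c("coupling", "coefficients"), ...) {
  type <- match.arg(type)
  if (type == "coupling") object$khat else object$coefficients
}

#' @export
residuals.nips <- function(object, ...) {
  if (is.null(object$residuals))
    stop("fit was made with keep_fits = FALSE; refit to store residuals")
  object$residuals
}

#' @export
fitted.nips <- function(object, ...) {
  if (is.null(object$Y))
    stop("fit was made with keep_fits = FALSE; refit to store fits")
  Map(function(y, r) if (is.null(y)) NULL else y - r, object$Y,
      object$residuals)
}

#' Predict regression targets on (new) data
#'
#' Rebuilds each node's design matrix on `ts` with the stored embedding and
#' basis and applies the stored coefficients, giving the model's predicted
#' derivative (continuous mode) or next observation (map mode) at every
#' usable time.
#'
#' @param object A `nips` fit (node embedding).
#' @param ts A [trajectory_set()] with the same node count.
#' @param nodes Nodes to predict (default: the fitted ones).
#' @param ... Unused.
#' @return List (one entry per node) of lists with `segment`, `time`
#'   (1-based sample index) and `pred`.
#' @export
predict.nips <- function(object, ts, nodes = NULL, ...) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (object$embedding != "node")
    stop("predict is implemented for node-embedding fits")
  nodes <- nodes %||% object$nodes
  spec <- embedding_spec(object$taus, object$k)
  basis <- basis_spec(object$r, object$r1)
  out <- vector("list", nrow(object$khat))
  for (i in nodes) {
    reg <- build_node_regression(i, ts, spec, basis, object$mode)
    pred <- drop(reg$A %*% object$coefficients[[i]])
    nr <- reg$rows_per_segment
    out[[i]] <- list(
      segment = rep(seq_along(nr), nr),
      pred = pred)
  }
  out
}

#' @export
#' @rdname nips
#' @param truth Optional [directed_network()] ground truth; when supplied
#'   the ROC curve is drawn, otherwise a histogram of the off-diagonal
#'   scores with the Otsu threshold.
plot.nips <- function(x, truth = NULL, ...) {
  if (!is.null(truth)) {
    plot(auroc(x, truth), ...)
    return(invisible(x))
  }
  off <- row(x$khat) != col(x$khat)
  scores <- x$khat[off]
  graphics::hist(scores, breaks = 64,
                 main = "Inferred coupling strengths",
                 xlab = expression(hat(k)[ij]), ...)
  eps <- tryCatch(otsu_threshold(scores), error = function(e) NA_real_)
  if (is.finite(eps)) graphics::abline(v = eps, lty = 2)
  invisible(x)
}
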