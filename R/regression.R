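## Per-node regression assembly and the least-squares solve.

#' Regression targets from one node's series within one segment
#'
#' In `"continuous"` mode the target is the time derivative estimated by
#' central differences, defined at interior samples only (endpoints are
#' dropped).  In `"map"` mode the target is the next observation
#' `x(t + 1)`, the natural choice for discrete-time node dynamics.
#'
#' @param x Numeric series of one node within one segment.
#' @param dt Sampling interval.
#' @param mode `"continuous"` or `"map"`.
#' @return List with `Y` (targets) and `target_times` (1-based indices `t`
#'   at which each target is defined).
#' @export
derivative_targets <- function(x, dt, mode = c("continuous", "map")) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  Tn <- length(x)
  if ((mode == "continuous" && Tn < 3L) || Tn < 2L) {
    warning("segment too short for targets; returning none")
    return(list(Y = numeric(0), target_times = integer(0)))
  }
  if (mode == "continuous")
    list(Y = (x[3:Tn] - x[1:(Tn - 2L)]) / (2 * dt),
         target_times = 2:(Tn - 1L))
  else
    list(Y = x[2:Tn], target_times = 1:(Tn - 1L))
}

#' Assemble the regression system for one target node
#'
#' For every segment, usable rows are the times at which both the full
#' delay window of the target node and the regression target exist.  The
#' design matrix is `[Q | P_1 | ... | P_N]` (source blocks in ascending
#' node order, skipping the target): `Q` holds the multivariate monomials
#' of the target's delay vector and each `P_j` the univariate powers of
#' source `j` at the same times.  Rows from all segments are stacked.
#'
#' @param i Target node index.
#' @param ts A [trajectory_set()].
#' @param spec An [embedding_spec()].
#' @param basis A [basis_spec()].
#' @param mode Target mode, see [derivative_targets()].
#' @return Object of class `node_regression`: `A`, `Y`, `node`, `n_beta`,
#'   `alpha_sources`, `rows_per_segment`, plus the specs.
#' @export
build_node_regression <- function(i, ts, spec, basis,
                                  mode = c("continuous", "map")) {
  stopifnot(inherits(ts, "trajectory_set"),
            inherits(spec, "embedding_spec"),
            inherits(basis, "basis_spec"))
  mode <- match.arg(mode)
  N <- n_nodes_ts(ts)
  i <- check_count(i, "i", 1L)
  if (i > N) stop_param("node index out of range")
  taus <- if (length(spec$taus) == 1L) rep(spec$taus, N) else spec$taus
  if (length(taus) != N) stop_param("need one tau per node")
  tau <- taus[i]; k <- spec$k
  expo <- monomial_exponents(k, basis$r)
  others <- setdiff(seq_len(N), i)
  Alist <- list(); Ylist <- list(); nrows <- integer(length(ts$segments))
  for (s in seq_along(ts$segments)) {
    seg <- ts$segments[[s]]
    x <- seg[, i]
    dv <- suppressWarnings(delay_vectors(x, tau, k))
    tg <- suppressWarnings(derivative_targets(x, ts$dt, mode))
    times <- intersect(dv$row_times, tg$target_times)
    nrows[s] <- length(times)
    if (!length(times)) next
    Q <- eval_monomials(dv$rows[match(times, dv$row_times), , drop = FALSE],
                        expo)
    P <- seg[times, others, drop = FALSE]
    if (basis$r1 > 1L) {
      ## per-source blocks (x_j, x_j^2, ...): columns grouped by source
      P <- do.call(cbind, lapply(seq_along(others), function(jj)
        vapply(seq_len(basis$r1), function(l) P[, jj]^l,
               numeric(length(times)))))
    }
    Alist[[s]] <- cbind(Q, P)
    Ylist[[s]] <- tg$Y[match(times, tg$target_times)]
  }
  if (!sum(nrows))
    stop_param("no usable rows for node %d", i)
  A <- do.call(rbind, Alist[nrows > 0])
  Y <- unlist(Ylist[nrows > 0], use.names = FALSE)
  if (nrow(A) <= ncol(A))
    warning(sprintf(
      "node %d: %d rows for %d columns; system is underdetermined",
      i, nrow(A), ncol(A)))
  structure(list(A = A, Y = Y, node = i, n_beta = nrow(expo),
                 alpha_sources = others, rows_per_segment = nrows,
                 spec = spec, basis = basis, mode = mode),
            class = "node_regression")
}

#' Minimum-norm least squares with optional Tikhonov regularization
#'
#' Solves `min || Y - A Z ||^2` through an orthogonal decomposition: a
#' LAPACK QR factorization on well-conditioned systems, falling back to the
#' SVD-based minimum-norm solution when the triangular factor is (near)
#' singular.  With `ridge > 0` the Tikhonov-regularized problem is solved
#' through the SVD.
#'
#' @param A Design matrix.
#' @param Y Response vector, `length(Y) == nrow(A)`.
#' @param ridge Nonnegative regularization weight, on the scale of the
#'   squared largest singular value (i.e. `ridge * d_1^2` is added to every
#'   squared singular value).
#' @return Coefficient vector of length `ncol(A)`.
#' @export
solve_least_squares <- function(A, Y, ridge = 0) {
  A <- as.matrix(A)
  if (!nrow(A) || !ncol(A) || !length(Y))
    stop_param("empty least-squares system")
  if (length(Y) != nrow(A)) stop_param("A and Y are not row-aligned")
  if (ridge < 0) stop_param("ridge must be nonnegative")
  if (ridge == 0 && nrow(A) >= ncol(A)) {
    qrA <- qr(A, LAPACK = TRUE)
    dR <- abs(diag(qr.R(qrA)))
    if (min(dR) > max(dR) * 1e-10)
      return(drop(qr.coef(qrA, Y)))
  }
  sv <- svd(A)
  if (ridge > 0) {
    f <- sv$d / (sv$d^2 + ridge * sv$d[1]^2)
  } else {
    tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
    f <- ifelse(sv$d > tol, 1 / sv$d, 0)
  }
  drop(sv$v %*% (f * crossprod(sv$u, Y)))
}

#' Coupling strengths of one target node from its coefficient vector
#'
#' The estimated strength of the connection from source `j` to target `i`
#' is the sum of squares of the `r1` coefficients in source `j`'s coupling
#' block; the self entry is fixed at zero.
#'
#' @param Z Solved coefficient vector (self block first, then the coupling
#'   blocks in ascending source order skipping `i`).
#' @param N Network size.
#' @param k Embedding dimension (fixes the self-block length).
#' @param basis A [basis_spec()].
#' @param i Target node index.
#' @return Numeric vector of length `N`: row `i` of the estimated coupling
#'   matrix.
#' @export
coupling_row <- function(Z, N, k, basis, i) {
  stopifnot(inherits(basis, "basis_spec"))
  n_beta <- monomial_count(k, basis$r)
  if (length(Z) != n_beta + (N - 1L) * basis$r1)
    stop("coefficient vector does not match the (N, k, basis) partition")
  alph <- matrix(Z[-seq_len(n_beta)], nrow = basis$r1)
  out <- numeric(N)
  out[setdiff(seq_len(N), i)] <- colSums(alph^2)
  out
}
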