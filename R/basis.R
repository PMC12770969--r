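## Polynomial basis bookkeeping for the additive regression model.
##
## The self-dynamics block uses all multivariate monomials of total degree
## <= r in the k delayed observations of the target node (constant
## included); each candidate source node contributes the univariate powers
## x, x^2, ..., x^r1 (no constant).  Monomials are ordered graded-
## lexicographically, constant first, and that ordering is stable.

#' Number of multivariate monomials of total degree at most r in k variables
#'
#' `choose(k + r, r)`, the column count of one self-dynamics block.
#'
#' @param k Number of variables (delayed copies).
#' @param r Maximal total degree.
#' @export
monomial_count <- function(k, r) {
  k <- check_count(k, "k", 1L)
  r <- check_count(r, "r", 0L)
  as.integer(round(choose(k + r, r)))
}

#' Number of unknown regression coefficients per node
#'
#' For node-by-node embedding the per-node system has
#' `choose(k + r, r) + (N - 1) * r1` unknowns (one multivariate self block
#' plus `N - 1` univariate coupling blocks).  Embedding the whole network
#' instead requires `N * choose(k + r, r) - (N - 1)` unknowns (one
#' multivariate block per node, with the duplicate constants merged into a
#' single shared intercept).
#'
#' @param N Network size.
#' @param k Embedding dimension.
#' @param r Multivariate polynomial order.
#' @param r1 Univariate coupling order (node embedding only).
#' @param mode `"node_embedding"` or `"full_embedding"`.
#' @export
count_coefficients <- function(N, k, r, r1 = 1,
                               mode = c("node_embedding",
                                        "full_embedding")) {
  mode <- match.arg(mode)
  N <- check_count(N, "N", 1L)
  if (mode == "node_embedding") {
    r1 <- check_count(r1, "r1", 1L)
    as.integer(monomial_count(k, r) + (N - 1L) * r1)
  } else {
    as.integer(N * monomial_count(k, r) - (N - 1L))
  }
}

## Exponent matrix (n_monomials x k) in graded-lex order: degrees ascending,
## and within a degree the exponent of the first variable descending.
monomial_exponents <- function(k, r) {
  compositions <- function(d, parts) {
    if (parts == 1L) return(matrix(d, 1L, 1L))
    do.call(rbind, lapply(d:0, function(f)
      cbind(f, compositions(d - f, parts - 1L))))
  }
  out <- do.call(rbind, lapply(0:r, compositions, parts = k))
  dimnames(out) <- NULL
  out
}

## Evaluate all monomials for a matrix of points (rows x k) given an
## exponent matrix; returns rows x n_monomials.
eval_monomials <- function(X, expo) {
  out <- matrix(1, nrow(X), nrow(expo))
  for (m in seq_len(nrow(expo))) {
    nz <- which(expo[m, ] > 0L)
    for (j in nz) out[, m] <- out[, m] * X[, j]^expo[m, j]
  }
  out
}

#' Evaluate the multivariate monomial basis at a point
#'
#' All monomials of total degree at most `r` in the entries of `xd`, in
#' graded-lexicographic order with the constant first.
#'
#' @param xd Numeric vector (a delay vector).
#' @param r Maximal total degree.
#' @return Numeric vector of length `monomial_count(length(xd), r)`.
#' @export
multivariate_monomials <- function(xd, r) {
  xd <- as.numeric(xd)
  r <- check_count(r, "r", 0L)
  drop(eval_monomials(matrix(xd, 1L), monomial_exponents(length(xd), r)))
}

#' Evaluate the univariate coupling basis
#'
#' The powers `x, x^2, ..., x^r1` (no constant term, mirroring a coupling
#' function that vanishes nowhere by offset).
#'
#' @param x Numeric scalar or vector.
#' @param r1 Highest power, at least 1.
#' @return For scalar `x` a vector of length `r1`; for vector `x` a matrix
#'   with `r1` columns.
#' @export
univariate_powers <- function(x, r1) {
  r1 <- check_count(r1, "r1", 1L)
  out <- vapply(seq_len(r1), function(l) x^l, numeric(length(x)))
  if (length(x) == 1L) as.numeric(out) else out
}

#' Basis specification
#'
#' @param r Multivariate polynomial order of the self block.
#' @param r1 Univariate order of the coupling blocks.
#' @export
basis_spec <- function(r, r1 = 1) {
  structure(list(r = check_count(r, "r", 0L),
                 r1 = check_count(r1, "r1", 1L)),
            class = "basis_spec")
}
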