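# Squared Euclidean distances between columns of X (landmarks) and columns
# of Y, via the expanded inner-product form with a clamp at zero so
# round-off never produces a negative squared distance.
.pairwise_sqdist <- function(X, Y = X) {
  nx <- colSums(X^2)
  ny <- colSums(Y^2)
  d2 <- outer(nx, ny, "+") - 2 * crossprod(X, Y)
  pmax(d2, 0)
}

#' Full Gaussian similarity matrix
#'
#' Builds the n x n similarity matrix with
#' \eqn{s_{ij} = \exp(-\|x_i - x_j\|^2 / 2\sigma^2)} for \eqn{i \ne j} and a
#' zero diagonal (`self_similarity = 0`); columns of the expression matrix
#' are the points.  The zero self-similarity follows the printed algorithm;
#' set `self_similarity = 1` for the usual positive-semidefinite Gram
#' convention.
#'
#' @param x numeric genes x samples matrix (samples are the points).
#' @param sigma positive Gaussian bandwidth, on the scale of z-scored
#'   expression distances.
#' @param self_similarity value placed on the diagonal, 0 (default) or 1.
#' @return symmetric n x n matrix with entries in `[0, 1]`, sample ids as
#'   dimnames.
#' @export
gaussian_similarity_full <- function(x, sigma, self_similarity = 0) {
  .check_sigma(sigma)
  if (ncol(x) < 2L) .stop("need at least two samples")
  d2 <- .pairwise_sqdist(x)
  s <- exp(-d2 / (2 * sigma^2))
  diag(s) <- self_similarity
  dimnames(s) <- list(colnames(x), colnames(x))
  s
}

.check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    .stop("sigma must be a single positive number")
}

#' Sample a landmark set for the Nystrom approximation
#'
#' Draws `l` distinct sample positions uniformly without replacement,
#' deterministically for a given seed.  The complement (the remaining
#' n - l positions, in original order) is returned alongside.
#'
#' @param n number of samples.
#' @param l number of landmarks, `1 < l < n`.  The training protocol uses
#'   half the cohort, `l = floor(n / 2)`.
#' @param seed integer RNG seed.
#' @return list with integer vectors `landmarks` (length `l`) and
#'   `complement` (length `n - l`, increasing).
#' @export
sample_landmarks <- function(n, l, seed) {
  if (l <= 1L || l >= n) .stop("need 1 < l < n (got l = ", l, ", n = ", n, ")")
  idx <- .with_seed(seed, sample.int(n, l))
  list(landmarks = idx, complement = setdiff(seq_len(n), idx))
}

#' Gaussian similarity blocks over a landmark set
#'
#' Evaluates only the two blocks of the full similarity matrix that the
#' Nystrom approximation needs: `A` (l x l, landmark-landmark, zero
#' diagonal) and `B` (l x (n-l), landmark-remainder).  The
#' (n-l) x (n-l) remainder block is never materialized; it exists only
#' through its approximation \eqn{B^T A^{-1} B}.
#'
#' @inheritParams gaussian_similarity_full
#' @param landmarks integer vector of landmark positions (columns of `x`),
#'   or the list returned by [sample_landmarks()].
#' @return a `similarity_blocks` object; see [similarity_blocks()].
#' @export
gaussian_similarity_blocks <- function(x, landmarks, sigma,
                                       self_similarity = 0) {
  .check_sigma(sigma)
  if (is.list(landmarks)) landmarks <- landmarks$landmarks
  landmarks <- as.integer(landmarks)
  n <- ncol(x)
  if (anyDuplicated(landmarks) || any(landmarks < 1L | landmarks > n))
    .stop("landmarks must be distinct positions in 1..n")
  comp <- setdiff(seq_len(n), landmarks)
  XL <- x[, landmarks, drop = FALSE]
  A <- exp(-.pairwise_sqdist(XL) / (2 * sigma^2))
  diag(A) <- self_similarity
  B <- if (length(comp)) {
    exp(-.pairwise_sqdist(XL, x[, comp, drop = FALSE]) / (2 * sigma^2))
  } else {
    matrix(numeric(0), nrow = length(landmarks), ncol = 0L)
  }
  similarity_blocks(A, B, landmarks, sigma = sigma, n = n)
}

#' Construct a similarity-blocks object
#'
#' Container for the Nystrom view of a similarity matrix: the
#' landmark-landmark block `A`, the landmark-remainder block `B`, and the
#' landmark index set.  `A` must be symmetric; block entries must lie in
#' `[0, 1]` for kernel-built blocks but are not range-checked here so that
#' arbitrary (e.g. low-rank synthetic) similarity matrices can be wrapped.
#'
#' @param A numeric l x l symmetric matrix.
#' @param B numeric l x (n - l) matrix.
#' @param landmark_idx integer vector of l distinct sample positions.
#' @param sigma bandwidth used to build the blocks (NA if not kernel-built).
#' @param n total number of samples.
#' @return object of class `similarity_blocks` with fields `A`, `B`,
#'   `landmark_idx`, `complement_idx`, `sigma`, `n`.
#' @export
similarity_blocks <- function(A, B, landmark_idx, sigma = NA_real_, n) {
  l <- length(landmark_idx)
  if (!is.matrix(A) || nrow(A) != l || ncol(A) != l)
    .stop("A must be l x l with l = |landmark_idx|")
  if (max(abs(A - t(A))) > 1e-12 * max(1, max(abs(A))))
    .stop("A must be symmetric")
  if (!is.matrix(B) || nrow(B) != l || ncol(B) != n - l)
    .stop("B must be l x (n - l)")
  structure(
    list(A = (A + t(A)) / 2, B = B,
         landmark_idx = as.integer(landmark_idx),
         complement_idx = setdiff(seq_len(n), as.integer(landmark_idx)),
         sigma = sigma, n = as.integer(n)),
    class = "similarity_blocks")
}

#' @export
print.similarity_blocks <- function(x, ...) {
  cat(sprintf("similarity_blocks: n = %d, l = %d landmarks, sigma = %s\n",
              x$n, length(x$landmark_idx), format(x$sigma)))
  invisible(x)
}
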