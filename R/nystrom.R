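# --- symmetric pseudo-inverse machinery -----------------------------------
#
# The landmark block A has a zero diagonal, so it equals the PSD Gaussian
# Gram block minus the identity and can be indefinite.  All inversions
# therefore go through a symmetric eigendecomposition with small
# eigenvalues clipped, which reduces to the exact inverse when the block is
# well conditioned.

# Moore-Penrose pseudo-inverse of a symmetric matrix: eigenvalues with
# |lambda| <= tau_rel * max|lambda| are zeroed, the rest inverted (signs
# kept, so negative structural eigenvalues are honoured).
.sym_pinv <- function(M, tau_rel = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  amax <- max(abs(e$values))
  if (amax == 0) .stop("matrix numerically rank 0")
  inv <- ifelse(abs(e$values) > tau_rel * amax, 1 / e$values, 0)
  e$vectors %*% (inv * t(e$vectors))
}

# Pseudo inverse square root of a symmetric matrix: eigenvalues below
# tau_rel * (max eigenvalue) are clipped to zero (negative directions are
# dropped -- they have no real square root) and the positive part is
# pseudo-inverted.
.sym_pinv_sqrt <- function(M, tau_rel = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lmax <- max(e$values)
  if (lmax <= 0) .stop("matrix numerically rank 0 (no positive eigenvalue)")
  keep <- e$values > tau_rel * lmax
  inv <- ifelse(keep, 1 / sqrt(pmax(e$values, 0)), 0)
  e$vectors %*% (inv * t(e$vectors))
}

# Fix eigenvector sign so the largest-magnitude entry of each column is
# positive; makes embeddings reproducible across linear-algebra backends.
.sign_fix <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# --- Nystrom pipeline ------------------------------------------------------

#' Approximate degree vector from similarity blocks
#'
#' Row sums of the Nystrom-reconstructed similarity matrix
#' \eqn{\tilde S = W A^{-1} W^T}: the first l entries are
#' \eqn{A 1_l + B 1_{n-l}}, the remaining n - l entries
#' \eqn{B^T 1_l + B^T A^{-1} B 1_{n-l}}.  The product with
#' \eqn{A^{-1}} uses matrix-vector operations only, so the
#' (n-l) x (n-l) block is never formed.  `A^{-1}` is taken in the
#' clipped pseudo-inverse sense (see package vignette).
#'
#' @param blocks a [similarity_blocks()] object.
#' @return positive numeric vector of length n, in block order (landmarks
#'   first, then the complement in original order).
#' @export
approximate_degrees <- function(blocks) {
  stopifnot(inherits(blocks, "similarity_blocks"))
  A <- blocks$A
  B <- blocks$B
  l <- nrow(A)
  m <- ncol(B)
  ones_l <- rep(1, l)
  if (m == 0L) {
    d <- as.vector(A %*% ones_l)
  } else {
    b_row <- as.vector(B %*% rep(1, m))           # B 1_{n-l}
    d_top <- as.vector(A %*% ones_l) + b_row
    d_bot <- as.vector(crossprod(B, ones_l)) +
      as.vector(crossprod(B, .sym_pinv(A) %*% b_row))
    d <- c(d_top, d_bot)
  }
  if (any(d <= 0))
    .stop("degenerate degree; increase sigma or the landmark count l")
  d
}

#' Degree-normalize the similarity blocks
#'
#' Computes \eqn{\bar A = D_l^{-1/2} A D_l^{-1/2}} and
#' \eqn{\bar B = D_l^{-1/2} B D_{n-l}^{-1/2}}, where \eqn{D_l} and
#' \eqn{D_{n-l}} are the landmark and complement parts of the approximate
#' degree vector.
#'
#' @param blocks a [similarity_blocks()] object.
#' @param degrees positive degree vector in block order, as returned by
#'   [approximate_degrees()].
#' @return list with matrices `A_bar` (symmetric l x l) and `B_bar`
#'   (l x (n-l)).
#' @export
normalize_blocks <- function(blocks, degrees) {
  stopifnot(inherits(blocks, "similarity_blocks"))
  l <- nrow(blocks$A)
  if (length(degrees) != blocks$n || any(degrees <= 0))
    .stop("degrees must be positive and of length n")
  s_l <- 1 / sqrt(degrees[seq_len(l)])
  s_m <- 1 / sqrt(degrees[-seq_len(l)])
  A_bar <- blocks$A * tcrossprod(s_l)
  B_bar <- if (ncol(blocks$B)) {
    blocks$B * tcrossprod(s_l, s_m)
  } else {
    blocks$B
  }
  list(A_bar = (A_bar + t(A_bar)) / 2, B_bar = B_bar)
}

#' One-shot orthogonalization operator R
#'
#' \eqn{R = \bar A + \bar A^{-1/2} \bar B \bar B^T \bar A^{-1/2}}, whose
#' eigendecomposition yields orthogonal approximate eigenvectors of the
#' full degree-normalized similarity without ever forming it.
#'
#' @param A_bar,B_bar normalized blocks from [normalize_blocks()].
#' @return symmetric l x l matrix.
#' @export
orthogonalized_operator <- function(A_bar, B_bar) {
  Ais <- .sym_pinv_sqrt(A_bar)
  R <- if (ncol(B_bar)) {
    A_bar + Ais %*% tcrossprod(B_bar) %*% Ais
  } else {
    A_bar
  }
  (R + t(R)) / 2
}

#' Row-normalized Nystrom spectral embedding
#'
#' Runs the core of the approximation: approximate degrees, block
#' normalization, eigendecomposition of the orthogonalized operator `R`,
#' expansion to all n samples via
#' \eqn{\tilde V = [\bar A; \bar B^T] \bar A^{-1/2} U_{R,1:k}
#' \Lambda_{R,1:k}^{-1/2}}, and row normalization to unit Euclidean norm.
#' Rows are returned in the original sample order.  Rows whose
#' pre-normalization norm falls below `1e-12` (possible only for
#' pathological bandwidths) are recorded and mapped to the first standard
#' basis direction instead of producing NaN.
#'
#' @param blocks a [similarity_blocks()] object.
#' @param k number of clusters / embedding dimensions, `2 <= k < l`.
#' @return object of class `nystrom_embedding` with fields `U_tilde`
#'   (n x k, unit rows), `eigenvalues` (top k eigenvalues of `R`,
#'   decreasing), `row_order` (block-order positions of the original
#'   samples) and `degenerate_rows` (original sample positions whose
#'   embedding row was degenerate).
#' @export
nystrom_embedding <- function(blocks, k) {
  stopifnot(inherits(blocks, "similarity_blocks"))
  l <- nrow(blocks$A)
  n <- blocks$n
  if (k < 2L) .stop("k must be at least 2")
  if (k >= l && l < n) .stop("k must be smaller than the landmark count l")
  if (k >= n) .stop("k must be smaller than n")
  degrees <- approximate_degrees(blocks)
  nb <- normalize_blocks(blocks, degrees)
  R <- orthogonalized_operator(nb$A_bar, nb$B_bar)
  e <- eigen(R, symmetric = TRUE)           # values already decreasing
  lmax <- max(e$values)
  if (lmax <= 0) .stop("R numerically rank 0")
  usable <- sum(e$values > 1e-10 * lmax)
  if (usable < k)
    .stop("only ", usable, " positive eigenvalue(s) after clipping; ",
          "cannot extract k = ", k, " embedding dimensions")
  U_R <- .sign_fix(e$vectors[, seq_len(k), drop = FALSE])
  lam <- e$values[seq_len(k)]
  Ais <- .sym_pinv_sqrt(nb$A_bar)
  proj <- Ais %*% U_R %*% diag(1 / sqrt(lam), nrow = k)
  V <- rbind(nb$A_bar %*% proj, crossprod(nb$B_bar, proj))
  rn <- sqrt(rowSums(V^2))
  degen_block <- which(rn < 1e-12)
  rn[degen_block] <- 1
  U <- V / rn
  if (length(degen_block)) {
    U[degen_block, ] <- 0
    U[degen_block, 1L] <- 1
  }
  block_order <- c(blocks$landmark_idx, blocks$complement_idx)
  U_full <- matrix(0, nrow = n, ncol = k)
  U_full[block_order, ] <- U
  structure(
    list(U_tilde = U_full,
         eigenvalues = lam,
         row_order = block_order,
         degenerate_rows = sort(block_order[degen_block])),
    class = "nystrom_embedding")
}

#' Nystrom reconstruction of the held-out similarity block
#'
#' Returns \eqn{B^T A^{-1} B}, the approximation of the
#' (n-l) x (n-l) remainder block implied by the landmark blocks.  Exact
#' whenever the full similarity matrix has rank at most l and the landmarks
#' span its column space.  Exposed mainly for diagnostics and testing; the
#' clustering path never materializes this matrix.
#'
#' @param A symmetric l x l landmark block.
#' @param B l x (n - l) cross block.
#' @return (n - l) x (n - l) matrix.
#' @export
nystrom_reconstruct_block <- function(A, B) {
  crossprod(B, .sym_pinv(A) %*% B)
}

#' Normalized graph Laplacian of a dense similarity matrix
#'
#' Diagnostic helper: \eqn{L = I - D^{-1/2} S D^{-1/2}} with `D` the degree
#' (row-sum) matrix.  Its eigenvectors coincide with those of
#' \eqn{D^{-1/2} S D^{-1/2}} (eigenvalues `1 - lambda`), so the clustering
#' path works with the normalized similarity directly and this function is
#' never on it.
#'
#' @param S symmetric nonnegative similarity matrix.
#' @return symmetric matrix of the same dimension.
#' @export
laplacian_from_similarity <- function(S) {
  d <- rowSums(S)
  if (any(d <= 0)) .stop("zero degree in similarity matrix")
  s <- 1 / sqrt(d)
  diag(nrow(S)) - S * tcrossprod(s)
}

#' @export
print.nystrom_embedding <- function(x, ...) {
  cat(sprintf("nystrom_embedding: n = %d, k = %d, eigenvalues [%s]\n",
              nrow(x$U_tilde), ncol(x$U_tilde),
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  if (length(x$degenerate_rows))
    cat("degenerate rows:", paste(x$degenerate_rows, collapse = ", "), "\n")
  invisible(x)
}
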