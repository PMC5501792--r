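#' Lloyd k-means with a relative-objective stopping rule
#'
#' Plain Lloyd iterations on the rows of `U`: assign each row to the
#' nearest centroid in squared Euclidean distance, then recompute each
#' centroid as the mean of its members.  Iterations stop when the relative
#' change of the objective (sum of squared distances to assigned
#' centroids), measured against the previous value, falls below `rel_tol`
#' (default 0.001), or when the previous objective is exactly zero.  A
#' 300-iteration cap guards against cycling at the tolerance boundary.
#'
#' Centroids are initialized by sampling `k` distinct rows uniformly under
#' `seed`, so a run is fully determined by `(U, k, seed)`.  A cluster that
#' empties during the iterations is re-seeded with the point currently
#' farthest from its assigned centroid, so every cluster in the result is
#' nonempty (survival evaluation needs every subtype populated).
#'
#' @param U numeric n x d matrix of points in rows (here: the spectral
#'   embedding, d = k).
#' @param k number of clusters, `2 <= k <= n`.
#' @param seed integer seed for the initialization draw.
#' @param rel_tol relative objective tolerance for termination.
#' @param max_iter iteration cap.
#' @return object of class `cluster_assignment`: `labels` (1..k, named by
#'   rownames of `U` when present), `centroids` (k x d), `objective`,
#'   `objective_trace`, `n_iter`, `seed`.
#' @export
lloyd_kmeans <- function(U, k, seed, rel_tol = 0.001, max_iter = 300L) {
  if (!is.matrix(U)) U <- as.matrix(U)
  n <- nrow(U)
  if (k > n) .stop("k must not exceed the number of points")
  if (k < 2L) .stop("k must be at least 2")
  if (any(!is.finite(U))) .stop("non-finite values in clustering input")
  centroids <- U[.with_seed(seed, sample.int(n, k)), , drop = FALSE]
  labels <- integer(n)
  trace <- numeric(0)
  obj_prev <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- .rows_sqdist(U, centroids)
    labels <- max.col(-d2, ties.method = "first")
    # repair emptied clusters from the globally worst-fit point
    empty <- setdiff(seq_len(k), unique(labels))
    for (j in empty) {
      cur <- d2[cbind(seq_len(n), labels)]
      cur[tabulate(labels, k)[labels] <= 1L] <- -Inf  # keep donors nonempty
      far <- which.max(cur)
      labels[far] <- j
    }
    obj <- sum(d2[cbind(seq_len(n), labels)])
    trace <- c(trace, obj)
    centroids <- .centroid_means(U, labels, k)
    if (obj_prev == 0 ||
        (is.finite(obj_prev) && abs(obj - obj_prev) / obj_prev < rel_tol) ||
        obj == 0 || iter >= max_iter)
      break
    obj_prev <- obj
  }
  if (!is.null(rownames(U))) names(labels) <- rownames(U)
  structure(
    list(labels = labels, centroids = centroids, objective = obj,
         objective_trace = trace, n_iter = iter, seed = as.integer(seed)),
    class = "cluster_assignment")
}

.rows_sqdist <- function(U, C) {
  d2 <- outer(rowSums(U^2), rowSums(C^2), "+") - 2 * tcrossprod(U, C)
  pmax(d2, 0)
}

.centroid_means <- function(U, labels, k) {
  cnt <- tabulate(labels, k)
  sums <- rowsum(U, labels, reorder = TRUE)
  out <- matrix(0, nrow = k, ncol = ncol(U))
  out[as.integer(rownames(sums)), ] <- sums
  out / pmax(cnt, 1L)
}

#' Dense full spectral clustering (normalized-cuts comparator)
#'
#' The standard normalized spectral clustering pipeline without any
#' approximation: dense Gaussian similarity with zero diagonal, degree
#' normalization \eqn{D^{-1/2} S D^{-1/2}}, top-k eigenvectors, unit-norm
#' rows, then [lloyd_kmeans()].  Serves as the exact comparator for the
#' Nystrom pipeline (identical labels when the landmark set is the whole
#' cohort) and as the "standard spectral clustering" baseline.
#'
#' @inheritParams gaussian_similarity_full
#' @param k number of clusters.
#' @param seed k-means initialization seed.
#' @return a `cluster_assignment` (see [lloyd_kmeans()]) with an extra
#'   `embedding` field holding the row-normalized eigenvector matrix.
#' @export
full_spectral_clustering <- function(x, sigma, k, seed,
                                     self_similarity = 0) {
  n <- ncol(x)
  if (n < k + 1L) .stop("need n >= k + 1 samples")
  S <- gaussian_similarity_full(x, sigma, self_similarity)
  d <- rowSums(S)
  if (any(d <= 0)) .stop("zero degree; increase sigma")
  s <- 1 / sqrt(d)
  M <- S * tcrossprod(s)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- .sign_fix(e$vectors[, seq_len(k), drop = FALSE])
  rn <- sqrt(rowSums(V^2))
  degen <- rn < 1e-12
  rn[degen] <- 1
  V <- V / rn
  if (any(degen)) {
    V[degen, ] <- 0
    V[degen, 1L] <- 1
  }
  rownames(V) <- colnames(x)
  out <- lloyd_kmeans(V, k, seed)
  out$embedding <- V
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors via the standard
#' contingency-table closed form; 1 means identical partitions up to label
#' renaming, 0 is the expected agreement of independent random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in `[-1, 1]`.
#' @export
label_agreement <- function(a, b) {
  if (length(a) != length(b)) .stop("label vectors differ in length")
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical
  (sum_ij - expected) / denom
}

#' Export cluster labels as a two-column table
#'
#' @param assignment a `cluster_assignment`.
#' @param path output path for a tab-separated file with columns
#'   `sample_id`, `subtype`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ids <- names(assignment$labels)
  if (is.null(ids)) ids <- as.character(seq_along(assignment$labels))
  df <- data.frame(sample_id = ids, subtype = unname(assignment$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "cluster_assignment: n = %d, k = %d, objective = %.6g, %d iteration(s)\n",
    length(x$labels), nrow(x$centroids), x$objective, x$n_iter))
  print(table(subtype = x$labels))
  invisible(x)
}
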