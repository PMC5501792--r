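test_that("approximate degrees match the dense reconstruction oracle", {
  set.seed(21)
  for (rep in 1:20) {
    x <- matrix(rnorm(5 * 10), 5, dimnames = list(paste0("g", 1:5),
                                                  paste0("S", 1:10)))
    bl <- gaussian_similarity_blocks(x, sample_landmarks(10, 4, rep),
                                     sigma = runif(1, 2, 4))
    expect_equal(approximate_degrees(bl),
                 unname(degrees_dense_oracle(bl$A, bl$B)),
                 tolerance = 1e-10)
  }
})

test_that("degrees with l = n equal exact row sums of S", {
  set.seed(2)
  x <- matrix(rnorm(4 * 7), 4, dimnames = list(paste0("g", 1:4),
                                               paste0("S", 1:7)))
  S <- gaussian_similarity_full(x, 2)
  bl <- gaussian_similarity_blocks(x, 1:7, 2)
  expect_equal(approximate_degrees(bl), unname(rowSums(S)),
               tolerance = 1e-12)
})

test_that("duplicated landmark columns still give finite degrees", {
  x <- cbind(S1 = c(0, 0), S2 = c(0, 0), S3 = c(1, 2), S4 = c(2, 1),
             S5 = c(1, 1))
  rownames(x) <- c("g1", "g2")
  bl <- gaussian_similarity_blocks(x, 1:3, sigma = 2)   # A singular-ish
  d <- approximate_degrees(bl)
  expect_true(all(is.finite(d)))
  expect_true(all(d > 0))
})

test_that("block normalization matches the identity and dense cases", {
  set.seed(3)
  x <- matrix(rnorm(4 * 6), 4, dimnames = list(paste0("g", 1:4),
                                               paste0("S", 1:6)))
  bl <- gaussian_similarity_blocks(x, 1:4, 2)
  nb <- normalize_blocks(bl, rep(1, 6))
  expect_equal(nb$A_bar, bl$A, tolerance = 1e-14)
  expect_equal(nb$B_bar, bl$B, tolerance = 1e-14)

  # l = n reproduces the dense normalized similarity
  bl_full <- gaussian_similarity_blocks(x, 1:6, 2)
  d <- approximate_degrees(bl_full)
  nb_full <- normalize_blocks(bl_full, d)
  S <- gaussian_similarity_full(x, 2)
  ds <- rowSums(S)
  expect_equal(nb_full$A_bar, unname(S / sqrt(ds %o% ds)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(max(abs(nb_full$A_bar - t(nb_full$A_bar))), 1e-12)
})

test_that("orthogonalized operator matches the dense formula and is symmetric", {
  # hand-sized 3-landmark toy built from a positive-definite Gram block so
  # the plain (unclipped) dense eigendecomposition is a valid oracle
  set.seed(13)
  Z <- matrix(rnorm(5 * 3), 5, 3)
  G <- tcrossprod(Z) + diag(0.5, 5)
  bl <- similarity_blocks(G[1:3, 1:3], G[1:3, 4:5], 1:3, n = 5)
  nb <- normalize_blocks(bl, abs(rowSums(G)))
  R <- orthogonalized_operator(nb$A_bar, nb$B_bar)
  e <- eigen(nb$A_bar, symmetric = TRUE)
  inv_sqrt <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  R_dense <- nb$A_bar + inv_sqrt %*% nb$B_bar %*% t(nb$B_bar) %*% inv_sqrt
  expect_equal(R, (R_dense + t(R_dense)) / 2, tolerance = 1e-8)
  expect_lt(max(abs(R - t(R))), 1e-10)

  # B_bar empty: R reduces to A_bar
  x <- matrix(rnorm(3 * 5), 3, dimnames = list(paste0("g", 1:3),
                                               paste0("S", 1:5)))
  bl_full <- gaussian_similarity_blocks(x, 1:5, 1.5)
  nb_full <- normalize_blocks(bl_full, approximate_degrees(bl_full))
  expect_equal(orthogonalized_operator(nb_full$A_bar, nb_full$B_bar),
               nb_full$A_bar, tolerance = 1e-12)
})

test_that("R has real eigenvalues for random PSD-perturbed inputs", {
  set.seed(71)
  for (rep in 1:5) {
    Z <- matrix(rnorm(8 * 4), 8, 4)
    G <- tcrossprod(Z) + diag(runif(1, 0.1, 1), 8)
    bl <- similarity_blocks(G[1:4, 1:4], G[1:4, 5:8], 1:4, n = 8)
    nb <- normalize_blocks(bl, abs(rowSums(G)))
    R <- orthogonalized_operator(nb$A_bar, nb$B_bar)
    expect_lt(max(abs(R - t(R))), 1e-10)
    expect_true(all(abs(Im(eigen(R)$values)) < 1e-12))
  }
})

test_that("low-rank similarity is reconstructed exactly from spanning landmarks", {
  set.seed(31)
  n <- 30; r <- 6; l <- 10
  Z <- matrix(rnorm(n * r), n, r)
  G <- tcrossprod(Z)                       # PSD, rank r
  A <- G[1:l, 1:l]                         # landmarks span the range
  B <- G[1:l, (l + 1):n]
  expect_lt(max(abs(nystrom_reconstruct_block(A, B) -
                    G[(l + 1):n, (l + 1):n])), 1e-8)
})

test_that("embedding rows are unit norm and free of NaN/Inf", {
  co <- blob_cohort(n = 40, k = 3)
  bl <- gaussian_similarity_blocks(co$expression,
                                   sample_landmarks(40, 20, 1), sigma = 10)
  emb <- nystrom_embedding(bl, 3)
  expect_true(all(is.finite(emb$U_tilde)))
  expect_equal(unname(sqrt(rowSums(emb$U_tilde^2))), rep(1, 40),
               tolerance = 1e-8)
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
})

test_that("with l = n the embedding spans the dense top-k eigenspace", {
  co <- blob_cohort(n = 20, k = 3, p = 100)
  x <- co$expression
  bl <- gaussian_similarity_blocks(x, 1:20, sigma = 10)
  emb <- nystrom_embedding(bl, 3)
  S <- gaussian_similarity_full(x, 10)
  d <- rowSums(S)
  M <- S / sqrt(d %o% d)
  V <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, 1:3]
  # principal angles between the two 3-dim subspaces
  q1 <- qr.Q(qr(emb$U_tilde))
  q2 <- qr.Q(qr(V / sqrt(rowSums(V^2))))
  angles <- acos(pmin(1, svd(crossprod(q1, q2))$d))
  expect_lt(max(angles), 1e-6)
})

test_that("well-separated components collapse to near-orthogonal directions", {
  # three tight point clouds far apart: S is block-diagonal to numerical
  # precision, so embedding rows must collapse to k directions
  set.seed(8)
  centers <- rbind(c(0, 0), c(40, 0), c(0, 40))
  labels <- rep(1:3, each = 12)
  x <- t(centers[labels, ] + matrix(rnorm(72, sd = 0.05), 36, 2))
  dimnames(x) <- list(c("g1", "g2"), sprintf("S%02d", 1:36))
  bl <- gaussian_similarity_blocks(x, sample_landmarks(36, 18, 2),
                                   sigma = 1)
  emb <- nystrom_embedding(bl, 3)
  U <- emb$U_tilde
  for (cl in 1:3) {
    rows <- U[labels == cl, , drop = FALSE]
    cosines <- tcrossprod(rows)     # unit rows: inner product = cosine
    expect_gt(min(cosines), 0.99)
  }
  # different components land on near-orthogonal directions
  m1 <- colMeans(U[labels == 1, ]); m2 <- colMeans(U[labels == 2, ])
  expect_lt(abs(sum(m1 * m2)), 0.1)
})

test_that("permuting sample order permutes the embedding rows accordingly", {
  co <- blob_cohort(n = 24, k = 2, p = 80)
  x <- co$expression
  set.seed(99)
  perm <- sample(24)
  bl1 <- gaussian_similarity_blocks(x, 1:12, 8)
  # same landmark *set*, expressed in the permuted column positions
  bl2 <- gaussian_similarity_blocks(x[, perm], match(1:12, perm), 8)
  e1 <- nystrom_embedding(bl1, 2)$U_tilde
  e2 <- nystrom_embedding(bl2, 2)$U_tilde
  expect_equal(e1, e2[match(seq_len(24), perm), , drop = FALSE],
               tolerance = 1e-9)
})

test_that("embedding dimension bounds are enforced", {
  co <- blob_cohort(n = 20, k = 2, p = 50)
  bl <- gaussian_similarity_blocks(co$expression, 1:8, 8)
  expect_error(nystrom_embedding(bl, 1), "at least 2")
  expect_error(nystrom_embedding(bl, 8), "landmark count")
})

test_that("the normalized Laplacian diagnostic mirrors the similarity spectrum", {
  set.seed(4)
  x <- matrix(rnorm(5 * 8), 5, dimnames = list(paste0("g", 1:5),
                                               paste0("S", 1:8)))
  S <- gaussian_similarity_full(x, 2)
  L <- laplacian_from_similarity(S)
  d <- rowSums(S)
  M <- S / sqrt(d %o% d)
  expect_equal(sort(eigen(L, symmetric = TRUE)$values),
               sort(1 - eigen((M + t(M)) / 2, symmetric = TRUE)$values),
               tolerance = 1e-10)
})
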