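test_that("scaled_distance matches closed forms and compensates masking", {
  T_ <- 30
  a <- rep(0.5, T_)
  m <- rbind(a, a, a + 0.1)
  rownames(m) <- c("x", "y", "z")
  d <- scaled_distance(quantile_matrix(pmin(m, 1)), overlap_min = 5)
  expect_equal(d$d["x", "y"], 0)
  expect_equal(d$d["x", "z"], 0.1 * sqrt(T_))
  expect_equal(d$d, t(d$d))
  expect_equal(unname(diag(d$d)), rep(0, 3))
  # masking half the days of a constant-difference pair leaves d unchanged
  m2 <- m
  m2[1, seq(1, T_, 2)] <- NA
  m2[3, seq(1, T_, 2)] <- NA
  d2 <- scaled_distance(quantile_matrix(pmin(m2, 1)), overlap_min = 5)
  expect_equal(d2$d["x", "z"], d$d["x", "z"], tolerance = 1e-12)
})

test_that("scaled_distance refuses pairs with insufficient overlap", {
  m <- matrix(0.5, 2, 12)
  m[1, 1:8] <- NA
  m[2, 5:12] <- NA   # overlap = 0
  expect_error(scaled_distance(quantile_matrix(m), overlap_min = 3),
               "insufficient overlap")
})

test_that("PCA recovers a planted 1-D latent structure in its first component", {
  set.seed(41)
  n <- 60; T_ <- 50
  mu <- runif(n, 0.05, 0.95)
  m <- pmin(pmax(outer(mu, rep(1, T_)) + rnorm(n * T_, 0, 0.02), 1e-6), 1)
  qm <- quantile_matrix(m)
  emb <- pca_correlation(qm)
  expect_gte(abs(cor(emb$coordinates[, 1], mu, method = "spearman")), 0.95)
  # duplicated cows receive identical scores
  m2 <- rbind(m, m[1, ])
  emb2 <- pca_correlation(quantile_matrix(m2))
  expect_equal(emb2$coordinates[n + 1, ], emb2$coordinates[1, ],
               ignore_attr = TRUE)
})

test_that("PCA on pure noise shows no dominant component", {
  set.seed(42)
  m <- matrix(runif(50 * 200, 0.01, 1), 50, 200)
  emb <- pca_correlation(quantile_matrix(m))
  expect_lt(max(emb$eigenvalues) / sum(emb$eigenvalues), 0.1)
})

test_that("similarity inversion is monotone and caps zero distances", {
  d <- matrix(c(0, 2, 4, 2, 0, 1, 4, 1, 0), 3)
  s <- similarity_invert(d)
  expect_equal(s[1, 2], 0.5)
  expect_equal(s[2, 3], 1)
  expect_true(all(diag(s) == 0))
  # ordering reversal: d12 < d13 => s12 > s13
  expect_gt(s[1, 2], s[1, 3])
  # zero distance between distinct points -> 10x the largest finite s
  d0 <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2, 0), 3)
  s0 <- similarity_invert(d0)
  expect_equal(s0[1, 2], 10 * 0.5)
  # all-equal distances -> all-equal similarities
  de <- matrix(1, 4, 4); diag(de) <- 0
  se <- similarity_invert(de)
  expect_true(all(se[upper.tri(se)] == 1))
})

test_that("knn graph is symmetric with degree >= k and links nearest pairs", {
  set.seed(43)
  x <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(x))
  s <- similarity_invert(d)
  adj <- knn_graph(s, k = 3)
  expect_equal(adj, t(adj))
  expect_true(all(colSums(adj > 0) >= 3))
  # 3 points, k = 1: brute force says the two closest pairs get linked
  p3 <- matrix(c(0, 0, 1, 0, 5, 0), 3, 2, byrow = TRUE)
  d3 <- as.matrix(dist(p3))
  a3 <- knn_graph(similarity_invert(d3), k = 1)
  pairs <- which(a3 > 0 & upper.tri(a3), arr.ind = TRUE)
  offd <- d3[upper.tri(d3)]
  keep <- sort(offd)[1:2]
  got <- sort(d3[pairs])
  expect_equal(got, keep)
})

test_that("laplacian embedding is spectrally bounded and recovers a chain", {
  set.seed(44)
  n <- 80
  mu <- sort(runif(n, 0.02, 0.98))
  m <- pmin(pmax(outer(mu, rep(1, 60)) + rnorm(n * 60, 0, 0.03), 1e-6), 1)
  qm <- quantile_matrix(m)
  emb <- diffusion_map(qm, k = 10)
  expect_true(all(emb$spectrum > -1e-10 & emb$spectrum < 2 + 1e-10))
  expect_gte(abs(cor(emb$coordinates[, 1], mu, method = "spearman")), 0.9)
  expect_error(laplacian_embedding(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("the recovered geometry is robust to the Laplacian normalization", {
  set.seed(45)
  n <- 60
  mu <- runif(n, 0.02, 0.98)
  m <- pmin(pmax(outer(mu, rep(1, 50)) + rnorm(n * 50, 0, 0.03), 1e-6), 1)
  adj <- knn_graph(similarity_invert(scaled_distance(quantile_matrix(m))), k = 10)
  for (norm in c("symmetric", "unnormalized", "randomwalk")) {
    emb <- laplacian_embedding(adj, normalization = norm, orient_by = mu)
    expect_gte(abs(cor(emb$coordinates[, 1], mu, method = "spearman")), 0.85)
  }
})

test_that("embedding coordinates are invariant to cow ordering", {
  qm <- sim_qm(seed = 46, n_cows = 60, n_days = 40, pen_days = 15)
  mu <- qm_mu(qm)
  emb1 <- diffusion_map(qm, k = 8)
  set.seed(1)
  perm <- sample(nrow(qm))
  qm2 <- qm[perm, ]
  attr(qm2, "profiles") <- attr(qm, "profiles")
  emb2 <- diffusion_map(qm2, k = 8)
  # align rows back; coordinates agree up to sign within eigenspaces
  back <- order(perm)
  c1 <- emb1$coordinates[, 1:3]
  c2 <- emb2$coordinates[back, 1:3]
  for (j in 1:3) {
    expect_lt(min(max(abs(c1[, j] - c2[, j])), max(abs(c1[, j] + c2[, j]))),
              1e-6)
  }
})

test_that("harmonic reference curves are orthonormal path-Laplacian eigenvectors", {
  n <- 50
  H <- harmonic_reference(n, 4)
  expect_lt(max(abs(crossprod(H) - diag(4))), 1e-10)
  # v1 monotone; v_k has exactly k sign changes
  expect_true(all(diff(H[, 1]) < 0) || all(diff(H[, 1]) > 0))
  for (k in 1:4) expect_equal(sum(diff(sign(H[, k])) != 0), k)
  # matches direct eigendecomposition of the path-graph Laplacian
  L <- diag(c(1, rep(2, n - 2), 1))
  for (i in seq_len(n - 1)) { L[i, i + 1] <- -1; L[i + 1, i] <- -1 }
  eig <- eigen(L, symmetric = TRUE)
  vecs <- eig$vectors[, order(eig$values)][, 2:5]
  for (k in 1:4) {
    align <- abs(sum(vecs[, k] * H[, k]))
    expect_equal(align, 1, tolerance = 1e-8)
  }
})

test_that("a rope-like herd inherits harmonic curvature; permuted data has no geometry", {
  qm <- sim_qm(seed = 47, n_cows = 120, n_days = 60, pen_days = 20,
               shift_fraction = 0, missing_rate = 0)
  emb <- diffusion_map(qm, k = 10)
  ord <- order(emb$coordinates[, 1])
  H <- harmonic_reference(nrow(qm), 2)
  expect_gte(abs(cor(emb$coordinates[ord, 1], H[, 1])), 0.8)
  expect_gte(abs(cor(emb$coordinates[ord, 2], H[, 2])), 0.8)
  # within-day-permuted control: flat spectrum, no dominant relative gap,
  # and no recovered latent order
  perm <- permute_within_days(qm, seed = 9)
  embp <- diffusion_map(perm, k = 10)
  expect_lt(max(embp$eigengaps), 2)
  mu <- qm_mu(qm)
  expect_lt(abs(cor(embp$coordinates[, 1], mu, method = "spearman")), 0.3)
})

test_that("no clusters emerge from a cohesion-free herd", {
  qm <- sim_qm(seed = 48, n_cows = 80, n_days = 40, pen_days = 15,
               shift_fraction = 0)
  emb <- diffusion_map(qm, k = 10)
  # cluster along the recovered 1-D geometry (higher axes carry the
  # harmonic embedding artifact, not structure)
  co <- emb$coordinates[, 1, drop = FALSE]
  set.seed(1)
  gap <- cluster::clusGap(co, kmeans, K.max = 6, B = 30, nstart = 10,
                          iter.max = 30)
  k_hat <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                          method = "firstSEmax")
  expect_equal(k_hat, 1)
})
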