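test_that("segment_labels uses half-open bins covering (0, 1]", {
  m <- quantile_matrix(matrix(c(0.03, 0.05, 0.051, 1.0, 0.5, NA), 1))
  lab <- segment_labels(m, 20)
  expect_equal(as.integer(lab[1, 1:5]), c(1L, 1L, 2L, 20L, 10L))
  expect_true(is.na(lab[1, 6]))
  expect_error(segment_labels(matrix(0, 1, 1), 20), "\\(0, 1\\]")
  # float-noise at bin edges: position/N ratios land in the right bin
  q <- matrix((1:20) / 20, 1)
  expect_equal(as.integer(segment_labels(q, 20)), 1:20)
})

test_that("segment entropy attains its analytic extremes", {
  # 114 cows each observed once in a segment -> log2(114) = 6.83
  lab <- matrix(1L, nrow = 114, ncol = 1,
                dimnames = list(paste0("c", 1:114), "1"))
  expect_equal(segment_entropy(lab, 1)[["seg1"]], log2(114))
  expect_equal(round(segment_entropy(lab, 1)[["seg1"]], 2), 6.83)
  # one cow observed 50 times, no others -> 0
  lab2 <- matrix(c(rep(1L, 50), rep(NA, 50)), nrow = 2, byrow = TRUE)
  expect_equal(unname(suppressWarnings(segment_entropy(lab2, 1))[1]), 0)
  # counts {2, 2} over two cows -> 1 bit
  lab3 <- matrix(1L, 2, 2)
  expect_equal(unname(segment_entropy(lab3, 1)[1]), 1)
})

test_that("cow entropy attains its analytic extremes", {
  # equally often in all 20 segments -> log2(20) = 4.32
  lab <- matrix(rep(1:20, 3), 1)
  expect_equal(unname(cow_entropy(lab, 20)), log2(20))
  expect_equal(round(unname(cow_entropy(lab, 20)), 2), 4.32)
  # always one segment -> 0
  expect_equal(unname(cow_entropy(matrix(7L, 1, 30), 20)), 0)
  # 50/50 between first and last segment -> 1 bit (multimodality seen as
  # consistency, where variance would be maximal)
  bimodal <- matrix(rep(c(1L, 20L), 25), 1)
  expect_equal(unname(cow_entropy(bimodal, 20)), 1)
})

test_that("entropy is invariant to segment relabeling; variance is not", {
  set.seed(31)
  lab <- matrix(sample(1:20, 200, replace = TRUE), 4)
  perm <- sample(20)
  relab <- matrix(perm[lab], 4)
  expect_equal(cow_entropy(relab, 20), cow_entropy(lab, 20))
  q <- quantile_matrix(matrix(lab / 20, 4))
  q2 <- quantile_matrix(matrix(relab / 20, 4))
  expect_false(isTRUE(all.equal(cow_variance(q), cow_variance(q2))))
})

test_that("cow_variance matches a brute-force two-pass oracle", {
  expect_equal(unname(cow_variance(quantile_matrix(matrix(0.4, 1, 10)))), 0)
  # values {eps, 1} equally -> ~ 0.25 * n/(n-1)
  v <- rep(c(1e-12, 1), 10)
  expect_equal(unname(cow_variance(quantile_matrix(matrix(v, 1)))),
               0.25 * 20 / 19, tolerance = 1e-9)
  set.seed(32)
  m <- matrix(runif(200, 0.01, 1), 10)
  m[sample(200, 40)] <- NA
  got <- cow_variance(quantile_matrix(m))
  oracle <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    mu <- sum(x) / length(x)
    sum((x - mu)^2) / (length(x) - 1)
  })
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
})

test_that("permute_within_days preserves day multisets and missingness", {
  qm <- sim_qm(seed = 33, n_cows = 30, n_days = 10, pen_days = 4,
               missing_rate = 0.2)
  p1 <- permute_within_days(qm, seed = 7)
  p2 <- permute_within_days(qm, seed = 7)
  expect_identical(unclass(p1), unclass(p2))   # deterministic under seed
  expect_identical(is.na(unclass(p1)), is.na(unclass(qm)))
  for (j in seq_len(ncol(qm))) {
    expect_equal(sort(unname(unclass(p1)[, j])), sort(unname(unclass(qm)[, j])))
  }
})

test_that("permutation p-values hit the extreme cases and stay in (0, 1]", {
  # a perfectly consistent cow in a noisy herd: observed entropy below
  # every permuted draw -> p = 1/(B+1)
  qm <- sim_qm(seed = 34, n_cows = 40, n_days = 40, pen_days = 15,
               missing_rate = 0, sigma_min = 1e-6, sigma_max = 0.5)
  mu <- qm_mu(qm)
  B <- 59
  p <- permutation_pvalues(qm, "entropy", B = B, seed = 1)
  most_consistent <- which.min(pmin(mu, 1 - mu))
  expect_equal(unname(p[most_consistent]), 1 / (B + 1))
  expect_true(all(p > 0 & p <= 1))
  # identical seeds give identical p-values
  p2 <- permutation_pvalues(qm, "entropy", B = B, seed = 1)
  expect_identical(p, p2)
})

test_that("entropy flags planted bimodal cows as consistent where variance cannot", {
  # herd of uniform-noise cows plus one cow alternating front/back
  set.seed(35)
  n_days <- 60
  m <- matrix(runif(19 * n_days, 0.01, 1), 19)
  m <- rbind(matrix(rep(c(0.02, 0.99), n_days / 2), 1), m)
  m[] <- apply(m, 2, function(x) rank(x) / length(x))
  qm <- quantile_matrix(m)
  pe <- permutation_pvalues(qm, "entropy", B = 200, seed = 2)
  pv <- permutation_pvalues(qm, "variance", B = 200, seed = 2)
  expect_lte(pe[1], 0.05)     # entropy: strongly non-random
  expect_gt(pv[1], 0.5)       # variance: indistinguishable from random
})

test_that("queue_stochasticity assembles bounded summaries", {
  qm <- sim_qm(seed = 36, n_cows = 40, n_days = 25, pen_days = 10)
  st <- queue_stochasticity(qm, B = 50, seed = 3)
  expect_s3_class(st, "stochasticity")
  expect_true(all(st$per_cow$H_c >= 0 & st$per_cow$H_c <= log2(20) + 1e-12))
  expect_true(all(st$per_segment$H_q <= log2(nrow(qm)) + 1e-12, na.rm = TRUE))
  expect_true(all(st$per_cow$p_entropy > 0 & st$per_cow$p_entropy <= 1))
  expect_output(print(st), "stochasticity")
})
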