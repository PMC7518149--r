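test_that("tree_discretize separates obvious groups and handles edge k", {
  x <- c(1, 1, 1, 10, 10, 10)
  lab <- tree_discretize(x, 2)
  expect_equal(unname(lab[1:3]), rep(lab[[1]], 3))
  expect_equal(unname(lab[4:6]), rep(lab[[4]], 3))
  expect_true(lab[[1]] != lab[[4]])
  # k = n gives singletons
  y <- c(3, 1, 4, 1.5, 9)
  expect_equal(sort(unname(tree_discretize(y, 5))), 1:5)
  expect_error(tree_discretize(c(1, 1, 2), 3), "distinct")
  # planted 3-group attribute recovered
  set.seed(61)
  z <- c(rnorm(30, 0, 0.3), rnorm(30, 5, 0.3), rnorm(30, 10, 0.3))
  expect_gte(adjusted_rand(tree_discretize(z, 3), rep(1:3, each = 30)), 0.9)
})

test_that("mce_value matches the term-by-term oracle on contingency tables", {
  # printed toy tables, checked cell by cell against the defining sum
  tabs <- list(matrix(c(20, 5, 3, 22), 2),
               matrix(c(10, 0, 0, 10), 2),
               matrix(c(7, 7, 7, 7), 2),
               matrix(c(12, 1, 2, 9, 3, 8), 2))
  for (tab in tabs) {
    lab <- labels_from_table(tab)
    expect_equal(mce_value(lab$a, lab$b), mce_oracle(tab), tolerance = 1e-12)
  }
  set.seed(62)
  for (i in 1:100) {
    tab <- matrix(rpois(6, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    lab <- labels_from_table(tab)
    expect_equal(mce_value(lab$a, lab$b), mce_oracle(tab), tolerance = 1e-12)
  }
})

test_that("mce_value is symmetric, relabeling-invariant, and hits its limits", {
  set.seed(63)
  a <- sample(1:3, 120, replace = TRUE)
  b <- sample(1:4, 120, replace = TRUE)
  expect_equal(mce_value(a, b), mce_value(b, a))
  expect_equal(mce_value(c(4, 5, 6)[a], b), mce_value(a, b))
  # identical labelings -> 0
  expect_equal(mce_value(a, a), 0)
  # independence limit for two uniform binary labels: 1 bit
  big_a <- rep(1:2, each = 5000)
  big_b <- rep(rep(1:2, 2), each = 2500)
  expect_equal(mce_value(big_a, big_b), 1)
  expect_error(mce_value(1:3, 1:4), "equal length")
})

test_that("MCE weakly decreases as association strengthens", {
  set.seed(64)
  n <- 400
  a <- sample(1:3, n, replace = TRUE)
  vals <- sapply(seq(0, 1, 0.25), function(mix) {
    keep <- runif(n) < mix
    b <- ifelse(keep, a, sample(a))
    mce_value(a, b)
  })
  expect_true(all(diff(vals) <= 0.05))      # monotone up to sampling noise
  expect_lt(vals[5], vals[1] - 0.5)         # and clearly decreasing overall
})

test_that("mce_test: identical labels beat all permutations; seeds reproduce", {
  la <- rep(1:4, each = 25)
  res <- mce_test(la, la, B = 400, seed = 1)
  expect_equal(res$mce, 0)
  expect_equal(res$p_value, 1 / 401)
  expect_lte(res$p_value, 0.005)
  res2 <- mce_test(la, la, B = 400, seed = 1)
  expect_identical(res, res2)
})

test_that("mce_test p-values are calibrated under independent labels", {
  set.seed(65)
  rej <- 0
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    a <- sample(1:3, 80, replace = TRUE)
    b <- sample(1:3, 80, replace = TRUE)
    if (mce_test(a, b, B = 99, seed = i)$p_value <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.03)
})

test_that("grid selection picks the dominant cell and tie-breaks to (2,2)", {
  # planted association: bimodal attribute aligned with queue medians
  set.seed(66)
  n <- 80
  grp <- rep(1:2, each = n / 2)
  queue <- ifelse(grp == 1, runif(n, 0.05, 0.45), runif(n, 0.55, 0.95))
  attrib <- rnorm(n, mean = c(0, 8)[grp])
  res <- mce_grid_select(queue, attrib, ka_range = 2:4, kb_range = 2:4,
                         B = 200, seed = 1)
  expect_s3_class(res, "mce_result")
  expect_lte(res$p_value, 0.05)
  expect_equal(nrow(res$grid), 9)
  expect_match(res$label, "^0\\.[0-9]+_\\{[0-9]+,[0-9]+\\}$")
  # a flat grid (all p equal) falls back to the smallest model
  with_flat <- res
  with_flat$grid$p <- 0.5
  g <- with_flat$grid
  crit <- g$p
  rr <- stats::ave(crit, g$k_a, FUN = function(z) rank(z, ties.method = "average"))
  rc <- stats::ave(crit, g$k_b, FUN = function(z) rank(z, ties.method = "average"))
  avg <- (rr + rc) / 2
  ord <- order(avg, g$k_a + g$k_b, g$k_a)
  expect_equal(unlist(g[ord[1], c("k_a", "k_b")], use.names = FALSE), c(2, 2))
})

test_that("sensor_subsets extracts exact windows and disjoint columns", {
  cfg <- sim_config(n_cows = 4, n_days = 2, pen_days = 1, seed = 67)
  pr <- draw_herd(cfg)
  sl <- simulate_sensor(pr, cfg)
  ss <- sensor_subsets(sl)
  # a window covering all 24 h equals the full record
  all24 <- sensor_subsets(sl, windows = list(all = 0L:23L))
  expect_equal(dim(all24$all$active), c(4, 48))
  got <- all24$all$active["cow001", "d1h5"]
  expect_equal(got, sl$active[sl$cow_id == "cow001" & sl$day == 1 & sl$hour == 5])
  # disjoint windows give disjoint column sets
  expect_length(intersect(colnames(ss$morning$active),
                          colnames(ss$night$active)), 0)
  expect_error(sensor_subsets(sl, windows = list(a = 1:25)), "0\\.\\.23")
  expect_error(sensor_subsets(sl, windows = list(a = 1:3, b = 3:5)), "overlap")
})

test_that("a planted rear-activity offset is detected by the sensor MCE test", {
  cfg <- sim_config(n_cows = 120, n_days = 15, pen_days = 5, seed = 68,
                    outlier_days = integer(0))
  pr <- draw_herd(cfg)
  qm <- filter_cows(filter_days(to_quantiles(simulate_milkings(pr, cfg)),
                                0, NULL), 0.5)
  sl <- simulate_sensor(pr, cfg)
  sl <- sl[sl$cow_id %in% rownames(qm), ]
  ss <- sensor_subsets(sl)
  qlab <- tree_discretize(unclass(qm), 2)
  slab <- tree_discretize(ss$morning$active, 2)
  res <- mce_test(qlab, slab, B = 300, seed = 2)
  expect_lte(res$p_value, 0.05)
})
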