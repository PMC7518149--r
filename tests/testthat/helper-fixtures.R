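# Shared fixture builders. Everything is generated in code; no data files.

# a tiny hand-specified milk log: 3 days, up to 4 cows
toy_log <- function() {
  records <- data.frame(
    day = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3, 3),
    subperiod = c(rep("pen", 7), rep("pasture", 4)),
    cow_id = c("a", "b", "c", "d", "a", "b", "d", "a", "b", "c", "d"),
    position = c(1, 2, 3, 4, 2, 1, 3, 2, 1, 3, 4),
    stringsAsFactors = FALSE)
  structure(list(records = records,
                 enrolled = stats::setNames(c(4L, 4L, 4L), 1:3),
                 subperiod = stats::setNames(c("pen", "pen", "pasture"), 1:3)),
            class = "milk_log")
}

# a filtered quantile matrix from a simulated herd (shared across tests)
sim_qm <- function(seed = 5, n_cows = 200, n_days = 80, pen_days = 26,
                   outlier_days = integer(0), ...) {
  cfg <- sim_config(seed = seed, n_cows = n_cows, n_days = n_days,
                    pen_days = pen_days, outlier_days = outlier_days, ...)
  profiles <- draw_herd(cfg)
  qm <- to_quantiles(simulate_milkings(profiles, cfg))
  qm <- filter_days(qm, warmup = 0, drop_windows = NULL, min_coverage = 0.75)
  qm <- filter_cows(qm, 0.5)
  attr(qm, "profiles") <- profiles
  qm
}

# latent preference of the surviving cows, aligned to qm rows
qm_mu <- function(qm) {
  pr <- attr(qm, "profiles")
  pr$mu[match(rownames(qm), pr$cow_id)]
}

# block-constant cows x days matrix with planted (row, col) partitions
planted_blocks <- function(n_row = 60, n_col = 40, r = 3, c = 2,
                           noise = 0.02, seed = 1) {
  set.seed(seed)
  row_lab <- sort(rep_len(seq_len(r), n_row))
  col_lab <- sort(rep_len(seq_len(c), n_col))
  means <- matrix(seq(0.1, 0.9, length.out = r * c), r, c)
  vals <- means[cbind(rep(row_lab, n_col), rep(col_lab, each = n_row))]
  m <- matrix(vals + stats::rnorm(n_row * n_col, 0, noise), n_row, n_col)
  m <- pmin(pmax(m, 1e-6), 1)
  list(qm = quantile_matrix(m), row_lab = row_lab, col_lab = col_lab)
}

# brute-force Kendall tau-b via explicit pair counting
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# term-by-term MCE oracle from a contingency table of counts
mce_oracle <- function(tab) {
  N <- sum(tab)
  h_dir <- function(tb) {
    total <- 0
    for (j in seq_len(ncol(tb))) {
      nb <- sum(tb[, j])
      if (nb == 0) next
      h <- 0
      for (i in seq_len(nrow(tb))) {
        p <- tb[i, j] / nb
        if (p > 0) h <- h - p * log2(p)
      }
      total <- total + (nb / N) * h
    }
    total
  }
  (h_dir(tab) + h_dir(t(tab))) / 2
}

# labels realizing a given contingency table
labels_from_table <- function(tab) {
  a <- b <- integer(0)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    a <- c(a, rep(i, tab[i, j])); b <- c(b, rep(j, tab[i, j]))
  }
  list(a = a, b = b)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
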