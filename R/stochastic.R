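#' Discretize entry quantiles into queue segments
#'
#' The queue is divided into `n_segments` equal-width bins of the quantile
#' scale. Bins are half-open on the left, `((j-1)/K, j/K]`: entry quantiles
#' are strictly positive and reach exactly 1, so this convention covers the
#' whole range with no empty edge bin (0.05 falls in segment 1 with K = 20;
#' 1.0 falls in segment K).
#'
#' @param qm a [quantile_matrix()] (or plain numeric matrix in (0, 1]).
#' @param n_segments number of segments K (default 20).
#' @return an integer matrix of segment labels (1..K) with `NA` preserved.
#' @export
segment_labels <- function(qm, n_segments = 20L) {
  v <- unclass(qm)
  ok <- !is.na(v)
  if (any(v[ok] <= 0 | v[ok] > 1)) stop("entry quantiles must lie in (0, 1]")
  # guard against binary-float noise in position/N ratios at bin edges
  lab <- ceiling(v * n_segments - 1e-9)
  lab[ok] <- pmin(pmax(lab[ok], 1L), n_segments)
  storage.mode(lab) <- "integer"
  dimnames(lab) <- dimnames(v)
  lab
}

# per-row entropy of a label matrix: counts of each of 1..K per row
row_label_entropy <- function(labels, K) {
  n <- nrow(labels)
  ok <- !is.na(labels)
  idx <- (row(labels)[ok] - 1L) * K + labels[ok]
  counts <- matrix(tabulate(idx, nbins = n * K), nrow = n, byrow = TRUE)
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, 1)
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  h[tot == 0] <- NA_real_
  stats::setNames(h, rownames(labels))
}

#' Entropy of cow identity conditional on queue segment
#'
#' For each queue segment q, counts how often each cow was observed in that
#' segment (pooled over all days) and returns the Shannon entropy
#' `H_q = -sum_c (n_c|q / N_q) log2(n_c|q / N_q)`. Low `H_q` means the same
#' small set of cows occupies that section of the queue across milkings;
#' the maximum, attained when every cow is equally likely, is log2 of the
#' number of cows.
#'
#' @param labels integer segment-label matrix from [segment_labels()]
#'   (cows x days).
#' @param n_segments number of segments K.
#' @return named numeric vector of `H_q` (bits), one per segment; segments
#'   with no observations are `NA` with a warning.
#' @export
segment_entropy <- function(labels, n_segments = max(labels, na.rm = TRUE)) {
  K <- as.integer(n_segments)
  ok <- !is.na(labels)
  seg <- labels[ok]
  cow <- row(labels)[ok]
  counts <- matrix(tabulate((seg - 1L) * nrow(labels) + cow,
                            nbins = K * nrow(labels)),
                   nrow = K, byrow = TRUE)
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, 1)
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  h[tot == 0] <- NA_real_
  if (anyNA(h)) warning("segments with no observations reported as NA: ",
                        paste(which(is.na(h)), collapse = ", "))
  stats::setNames(h, paste0("seg", seq_len(K)))
}

#' Entropy of queue-segment membership conditional on cow
#'
#' For each cow c, the Shannon entropy of its distribution over queue
#' segments, `H_c = -sum_q (n_q|c / N_c) log2(n_q|c / N_c)`. Low `H_c` means
#' the cow repeatedly occupies the same few segments. Unlike variance, this
#' treats a cow that enters either first or last as highly consistent
#' (1 bit) rather than maximally variable.
#'
#' @inheritParams segment_entropy
#' @return named numeric vector of `H_c` (bits), one per cow; cows with no
#'   observations are `NA` with a warning.
#' @export
cow_entropy <- function(labels, n_segments = max(labels, na.rm = TRUE)) {
  h <- row_label_entropy(labels, as.integer(n_segments))
  if (anyNA(h)) warning("cows with no observations reported as NA: ",
                        paste(names(h)[is.na(h)], collapse = ", "))
  h
}

#' Per-cow variance of entry quantiles
#'
#' Unbiased sample variance over each cow's non-missing entry quantiles; the
#' conventional (continuous-scale) stochasticity measure that entropy is
#' contrasted against. Cows with fewer than 2 observations are `NA`.
#'
#' @param qm a [quantile_matrix()].
#' @return named numeric vector of variances.
#' @export
cow_variance <- function(qm) {
  apply(unclass(qm), 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else stats::var(x)
  })
}

#' Permute entry quantiles within each observation day
#'
#' The permutation null of a purely random queueing process: each day's
#' recorded quantile values are shuffled among the cows present that day,
#' preserving the missingness pattern and each day's quantile multiset
#' exactly.
#'
#' @param qm a [quantile_matrix()].
#' @param seed optional integer seed for reproducibility.
#' @return a `quantile_matrix` of the same shape.
#' @export
permute_within_days <- function(qm, seed = NULL) {
  if (!is.null(seed)) set.seed(check_seed(seed))
  v <- unclass(qm)
  for (j in seq_len(ncol(v))) {
    ok <- which(!is.na(v[, j]))
    if (length(ok) > 1L) v[ok, j] <- v[sample(ok), j]
  }
  quantile_matrix(v, subperiod = day_subperiod(qm), enrolled = day_enrolled(qm))
}

#' Permutation p-values for per-cow stochasticity statistics
#'
#' Tests, cow by cow, whether the observed entropy (or variance) of entry
#' quantiles is smaller than expected under a purely random queueing
#' process. The null is generated by repeatedly permuting quantiles within
#' each day; each cow is compared against its own null distribution (cows
#' differ in attendance patterns, so nulls are not shared). One-sided
#' p-values use the add-one correction `p = (1 + #{null <= obs}) / (B + 1)`,
#' so p is never exactly 0.
#'
#' @param qm a [quantile_matrix()].
#' @param statistic `"entropy"` (default) or `"variance"`.
#' @param B number of permutations (default 5000).
#' @param seed integer seed.
#' @param n_segments segments used for the entropy statistic.
#' @return named numeric vector of per-cow p-values in (0, 1].
#' @export
permutation_pvalues <- function(qm, statistic = c("entropy", "variance"),
                                B = 5000L, seed = 1L, n_segments = 20L) {
  statistic <- match.arg(statistic)
  stopifnot(B >= 1L)
  stat_fun <- if (statistic == "entropy") {
    function(m) row_label_entropy(segment_labels(m, n_segments), n_segments)
  } else {
    function(m) cow_variance(m)
  }
  obs <- stat_fun(qm)
  set.seed(check_seed(seed))
  leq <- numeric(length(obs))
  for (b in seq_len(B)) {
    nullstat <- stat_fun(permute_within_days(qm))
    leq <- leq + as.numeric(!is.na(nullstat) & !is.na(obs) & nullstat <= obs)
  }
  p <- (1 + leq) / (B + 1)
  p[is.na(obs)] <- NA_real_
  stats::setNames(p, names(obs))
}

#' Full stochasticity analysis of a quantile matrix
#'
#' Runs the segment-level and cow-level entropy analyses, per-cow variance,
#' and both permutation tests, and assembles the per-segment and per-cow
#' summary tables used for the stochasticity scatter plots.
#'
#' @inheritParams permutation_pvalues
#' @return an object of class `stochasticity`: a list with `per_segment`
#'   (data frame: segment, median quantile, `H_q`, null mean), `per_cow`
#'   (data frame: cow, median quantile, `H_c`, variance, both p-values),
#'   `n_segments`, `B`, and the analytic entropy maxima for reference lines.
#' @export
queue_stochasticity <- function(qm, n_segments = 20L, B = 5000L, seed = 1L) {
  labels <- segment_labels(qm, n_segments)
  H_q <- segment_entropy(labels, n_segments)
  H_c <- cow_entropy(labels, n_segments)
  v <- cow_variance(qm)
  med <- apply(unclass(qm), 1L, stats::median, na.rm = TRUE)

  # segment medians: median of observed quantiles mapped into each segment
  seg_med <- vapply(seq_len(n_segments), function(k) {
    stats::median(unclass(qm)[!is.na(labels) & labels == k])
  }, numeric(1))

  # one shared permutation stream feeds the per-segment null reference and
  # both per-cow tests
  set.seed(check_seed(seed))
  null_seg <- matrix(NA_real_, B, n_segments)
  leq_h <- numeric(length(H_c))
  leq_v <- numeric(length(v))
  for (b in seq_len(B)) {
    pm <- permute_within_days(qm)
    pl <- segment_labels(pm, n_segments)
    null_seg[b, ] <- segment_entropy(pl, n_segments)
    nh <- row_label_entropy(pl, n_segments)
    nv <- cow_variance(pm)
    leq_h <- leq_h + as.numeric(!is.na(nh) & !is.na(H_c) & nh <= H_c)
    leq_v <- leq_v + as.numeric(!is.na(nv) & !is.na(v) & nv <= v)
  }
  p_h <- (1 + leq_h) / (B + 1); p_h[is.na(H_c)] <- NA_real_
  p_v <- (1 + leq_v) / (B + 1); p_v[is.na(v)] <- NA_real_

  out <- list(
    per_segment = data.frame(segment = seq_len(n_segments),
                             median_quantile = seg_med, H_q = H_q,
                             H_q_null = colMeans(null_seg), row.names = NULL),
    per_cow = data.frame(cow_id = rownames(qm), median_quantile = med,
                         H_c = H_c, variance = v,
                         p_entropy = p_h, p_variance = p_v, row.names = NULL),
    n_segments = n_segments, B = B,
    max_H_q = log2(nrow(qm)), max_H_c = log2(n_segments))
  class(out) <- "stochasticity"
  out
}

#' @export
print.stochasticity <- function(x, ...) {
  cat(sprintf("<stochasticity> %d cows, %d segments, B = %d permutations\n",
              nrow(x$per_cow), x$n_segments, x$B))
  cat(sprintf("  cows rejecting randomness at alpha = 0.05: %d/%d (entropy), %d/%d (variance)\n",
              sum(x$per_cow$p_entropy <= 0.05, na.rm = TRUE), nrow(x$per_cow),
              sum(x$per_cow$p_variance <= 0.05, na.rm = TRUE), nrow(x$per_cow)))
  invisible(x)
}

#' @describeIn queue_stochasticity scatter of per-segment and per-cow
#'   entropy against median entry quantile, with the analytic maxima as
#'   horizontal reference lines.
#' @param x a `stochasticity` object.
#' @param which `"segment"`, `"cow"`, or `"variance"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stochasticity <- function(x, which = c("segment", "cow", "variance"), ...) {
  which <- match.arg(which)
  if (which == "segment") {
    graphics::plot(x$per_segment$median_quantile, x$per_segment$H_q,
                   xlab = "median segment quantile", ylab = expression(H[q]),
                   ylim = c(0, x$max_H_q * 1.05), col = "red3", pch = 19, ...)
    graphics::points(x$per_segment$median_quantile, x$per_segment$H_q_null,
                     col = "steelblue", pch = 19)
    graphics::abline(h = x$max_H_q, lty = 2)
  } else if (which == "cow") {
    graphics::plot(x$per_cow$median_quantile, x$per_cow$H_c,
                   xlab = "median entry quantile", ylab = expression(H[c]),
                   ylim = c(0, x$max_H_c * 1.05), pch = 19, ...)
    graphics::abline(h = x$max_H_c, lty = 2)
  } else {
    graphics::plot(x$per_cow$median_quantile, x$per_cow$variance,
                   xlab = "median entry quantile", ylab = "variance",
                   pch = 19, ...)
  }
  invisible(x)
}
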