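#' Ward (D2) hierarchical clustering tree
#'
#' Agglomerative merge tree under Ward's minimum-variance criterion in the
#' `ward.D2` convention: the criterion operates on squared dissimilarities
#' while merge heights stay on the distance scale. Thin wrapper over
#' [stats::hclust()] that validates its input; the result is deterministic
#' given the distance matrix.
#'
#' @param distances a symmetric distance matrix, `dist` object, or
#'   `scaled_distance`.
#' @return an `hclust` tree.
#' @export
ward_tree <- function(distances) {
  if (inherits(distances, "scaled_distance")) distances <- distances$d
  d <- if (inherits(distances, "dist")) distances else stats::as.dist(as.matrix(distances))
  if (any(!is.finite(d))) stop("distances must be finite")
  stats::hclust(d, method = "ward.D2")
}

# within-cell energy: sum over the r x c cells of the within-cell variance
# of the (non-missing) quantile entries; empty/singleton cells contribute 0
cocluster_energy <- function(X, row_labels, col_labels) {
  r <- max(row_labels); cc <- max(col_labels)
  energy <- 0
  empty <- 0L
  for (a in seq_len(r)) {
    xa <- X[row_labels == a, , drop = FALSE]
    for (b in seq_len(cc)) {
      v <- xa[, col_labels == b, drop = FALSE]
      v <- v[!is.na(v)]
      if (!length(v)) empty <- empty + 1L
      else if (length(v) > 1L) energy <- energy + stats::var(v)
    }
  }
  if (empty > 0L) warning(empty, " empty co-cluster cell(s) contribute zero energy")
  energy
}

# mean-quantile representation of each column within each row cluster:
# returns (n_col x r) matrix; NA where a (col, row-cluster) cell is empty
cluster_mean_repr <- function(X, labels, margin) {
  if (margin == 1L) {                       # rows clustered; represent columns
    t(vapply(seq_len(max(labels)), function(a) {
      colMeans(X[labels == a, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(X))))                  # r x n_col
  } else {                                  # columns clustered; represent rows
    t(vapply(seq_len(max(labels)), function(b) {
      rowMeans(X[, labels == b, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(X))))                  # c x n_row
  }
}

# scaled Euclidean distance between the ROWS of a (possibly NA-holed) matrix,
# without an overlap floor (reduced representations can be short)
repr_distance <- function(R) {
  M <- !is.na(R)
  R0 <- ifelse(M, R, 0)
  Tn <- ncol(R)
  overlap <- M %*% t(M)
  sq <- R0^2 %*% t(M) + M %*% t(R0^2) - 2 * R0 %*% t(R0)
  sq[sq < 0] <- 0
  d <- sqrt(Tn / pmax(overlap, 1L) * sq)
  d[overlap == 0] <- max(d[overlap > 0], 0) * 2 + 1  # no shared support: far
  diag(d) <- 0
  d
}

#' Data Mechanics co-clustering of a quantile matrix
#'
#' Iterative co-clustering that alternately clusters cows (rows) and days
#' (columns), each axis informing the other's distance metric, converging
#' toward a contingency partition whose cells are as homogeneous in entry
#' quantile as possible. Each iteration: (1) compute missingness-scaled
#' Euclidean distances between cows and between days in the current
#' representations; (2) build Ward D2 trees and cut at `r` and `c`;
#' (3) re-represent each day by its vector of within-cow-cluster mean
#' quantiles and each cow by its vector of within-day-cluster means. The
#' cross-axis update is realized as distance in cluster-mean space — the
#' module's central interpretation of "weighted distance", isolated here so
#' alternates can be swapped in. Iteration stops when both label vectors
#' repeat or `max_iter` is reached; with no randomness anywhere, results
#' are fully deterministic. The first iteration uses the raw matrix for
#' both axes, so `max_iter = 1` reduces exactly to two independent Ward
#' clusterings.
#'
#' Energy — the sum of within-cell variances over the `r x c` cells,
#' missing entries excluded — is recorded each iteration; if labels
#' oscillate without repeating convergence, the minimum-energy iterate is
#' returned with `converged = FALSE`.
#'
#' @param qm a [quantile_matrix()] (or numeric matrix).
#' @param r,c number of row (cow) and column (day) clusters.
#' @param max_iter iteration cap (default 20).
#' @return an object of class `co_clustering`: `row_labels`, `col_labels`
#'   (named integer vectors), `energy_trace`, `converged`, `iterations`,
#'   `row_tree`, `col_tree` (final Ward trees), and `r`, `c`.
#' @export
dm_cocluster <- function(qm, r, c, max_iter = 20L) {
  X <- unclass(qm)
  if (r < 1L || r > nrow(X)) stop("r must lie in [1, n_cows]")
  if (c < 1L || c > ncol(X)) stop("c must lie in [1, n_days]")

  row_repr <- X                     # cows described by days
  col_repr <- t(X)                  # days described by cows
  seen <- character(0)
  prev_key <- NULL
  best <- NULL
  energy_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    rd <- repr_distance(row_repr)
    cd <- repr_distance(col_repr)
    rt <- ward_tree(rd)
    ct <- ward_tree(cd)
    rl <- if (r == 1L) rep(1L, nrow(X)) else stats::cutree(rt, k = r)
    cl <- if (c == 1L) rep(1L, ncol(X)) else stats::cutree(ct, k = c)
    en <- suppressWarnings(cocluster_energy(X, rl, cl))
    energy_trace <- c(energy_trace, en)
    state <- list(row_labels = stats::setNames(as.integer(rl), rownames(X)),
                  col_labels = stats::setNames(as.integer(cl), colnames(X)),
                  row_tree = rt, col_tree = ct, energy = en)
    if (is.null(best) || en < best$energy) best <- state
    key <- paste(c(rl, -1L, cl), collapse = ",")
    if (identical(key, prev_key)) { converged <- TRUE; best <- state; break }
    if (key %in% seen) break        # label cycle: return min-energy iterate
    seen <- c(seen, key)
    prev_key <- key
    if (iter >= max_iter) break
    # cross-axis update: each axis re-represented by the other's cluster means
    col_repr <- t(cluster_mean_repr(X, rl, margin = 1L))  # days x r
    row_repr <- t(cluster_mean_repr(X, cl, margin = 2L))  # cows x c
  }

  structure(list(row_labels = best$row_labels, col_labels = best$col_labels,
                 energy_trace = energy_trace, converged = converged,
                 iterations = iter, row_tree = best$row_tree,
                 col_tree = best$col_tree, r = as.integer(r), c = as.integer(c)),
            class = "co_clustering")
}

#' @export
print.co_clustering <- function(x, ...) {
  cat(sprintf("<co_clustering> r = %d, c = %d; %d iterations (%sconverged); final energy %.4g\n",
              x$r, x$c, x$iterations, if (x$converged) "" else "not ",
              x$energy_trace[length(x$energy_trace)]))
  invisible(x)
}

#' Grid of Data Mechanics co-clusterings
#'
#' Runs [dm_cocluster()] on the full `r = 1..r_max`, `c = 1..c_max` grid and
#' tabulates, per cell, the final energy, the smallest column-cluster size,
#' and the subperiod purity of the column clusters (mean, over clusters, of
#' the majority subperiod fraction). The grid is the input to the visual
#' scan that chooses display granularity — the package supplies the scan
#' summary, not the decision — and to [flag_outlier_days()].
#'
#' @param qm a [quantile_matrix()].
#' @param r_max,c_max grid bounds (default 10).
#' @param max_iter per-fit iteration cap.
#' @return an object of class `dm_grid`: `fits` (list indexed
#'   `[[r]][[c]]`) and `summary` (data frame with one row per grid cell).
#' @export
dm_grid <- function(qm, r_max = 10L, c_max = 10L, max_iter = 20L) {
  stopifnot(r_max <= nrow(qm), c_max <= ncol(qm))
  sub <- day_subperiod(qm)
  fits <- vector("list", r_max)
  rows <- list()
  for (r in seq_len(r_max)) {
    fits[[r]] <- vector("list", c_max)
    for (cc in seq_len(c_max)) {
      fit <- dm_cocluster(qm, r, cc, max_iter = max_iter)
      fits[[r]][[cc]] <- fit
      sizes <- table(fit$col_labels)
      purity <- mean(vapply(split(sub, fit$col_labels),
                            function(s) max(table(s)) / length(s), numeric(1)))
      rows[[length(rows) + 1L]] <-
        data.frame(r = r, c = cc,
                   energy = fit$energy_trace[length(fit$energy_trace)],
                   converged = fit$converged,
                   min_col_cluster = as.integer(min(sizes)),
                   subperiod_purity = purity)
    }
  }
  structure(list(fits = fits, summary = do.call(rbind, rows)),
            class = "dm_grid")
}

#' @export
print.dm_grid <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<dm_grid> %d x %d co-clusterings; energy range [%.3g, %.3g]\n",
              max(s$r), max(s$c), min(s$energy), max(s$energy)))
  invisible(x)
}

#' Flag whole-herd outlier days from a co-clustering grid
#'
#' A day is flagged as an outlier if it persistently lands in tiny column
#' clusters once the temporal axis is finely stratified: across all grid
#' cells with at least `min_c` column clusters (all row granularities), the
#' day must fall in a column cluster of size `<= max_size` in at least
#' `min_persistence` of those cells. Persistence across row granularities
#' is what separates herd-level anomalies from ordinary cluster-boundary
#' days.
#'
#' Anomalous days that share a common signature (e.g. one disruptive event
#' spanning several milkings) tend to co-cluster with each other rather
#' than split into singletons, so `max_size` should be at least the number
#' of simultaneously anomalous days one wants to catch; the default of 4
#' matches a "handful" of outlier days.
#'
#' @param ensemble a `dm_grid`.
#' @param max_size largest column-cluster size that counts as "isolated"
#'   (default 4).
#' @param min_persistence fraction of qualifying grid cells in which the
#'   day must be isolated (default 0.8).
#' @param min_c minimum number of column clusters for a grid cell to count
#'   as fine temporal granularity (default 6).
#' @return character vector of flagged day names (possibly empty).
#' @export
flag_outlier_days <- function(ensemble, max_size = 4L, min_persistence = 0.8,
                              min_c = 6L) {
  stopifnot(inherits(ensemble, "dm_grid"))
  if (max_size < 1L) return(character(0))
  hits <- NULL
  n_cells <- 0L
  for (r in seq_along(ensemble$fits)) {
    for (cc in seq_along(ensemble$fits[[r]])) {
      if (cc < min_c) next
      fit <- ensemble$fits[[r]][[cc]]
      if (is.null(fit)) next
      n_cells <- n_cells + 1L
      sizes <- table(fit$col_labels)
      small <- fit$col_labels %in% as.integer(names(sizes)[sizes <= max_size])
      if (is.null(hits)) hits <- stats::setNames(numeric(length(small)),
                                                 names(fit$col_labels))
      hits <- hits + as.numeric(small)
    }
  }
  if (n_cells == 0L) return(character(0))
  names(hits)[hits / n_cells >= min_persistence]
}

#' Heatmap of a co-clustered quantile matrix
#'
#' Renders the quantile matrix with rows and columns ordered by dendrogram
#' leaf order within clusters, with gaps at cluster boundaries, subperiod
#' column annotations and optional attribute/health row annotations.
#' Requires the `pheatmap` package.
#'
#' @param x a `co_clustering`.
#' @param qm the [quantile_matrix()] it was fitted to.
#' @param row_annotations optional data frame of per-cow annotations
#'   (row names = cow ids).
#' @param filename optional path; if given the heatmap is written to file.
#' @param ... passed to [pheatmap::pheatmap()].
#' @export
plot_cocluster_heatmap <- function(x, qm, row_annotations = NULL,
                                   filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_cocluster_heatmap requires the pheatmap package")
  }
  ro <- x$row_tree$order
  co <- x$col_tree$order
  ro <- ro[order(x$row_labels[ro])]       # cluster blocks, leaf order within
  co <- co[order(x$col_labels[co])]
  M <- unclass(qm)[ro, co, drop = FALSE]
  ann_col <- data.frame(subperiod = day_subperiod(qm)[co],
                        row.names = colnames(M))
  gaps_r <- cumsum(table(x$row_labels))[-x$r]
  gaps_c <- cumsum(table(x$col_labels))[-x$c]
  pheatmap::pheatmap(M, cluster_rows = FALSE, cluster_cols = FALSE,
                     annotation_col = ann_col,
                     annotation_row = row_annotations[rownames(M), , drop = FALSE],
                     gaps_row = unname(gaps_r), gaps_col = unname(gaps_c),
                     filename = filename, silent = !is.na(filename), ...)
}
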