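#' Missingness-scaled Euclidean distance between cows
#'
#' Euclidean distance between temporally aligned entry-quantile vectors,
#' rescaled for missing records: with `S_ij` the set of days on which both
#' cows were observed and `T` the total number of days,
#' `d_ij = sqrt((T / |S_ij|) * sum_{t in S_ij} (q_it - q_jt)^2)`.
#' The `T/|S|` factor makes distances comparable across pairs with different
#' overlap — masking half the days of two rows with a constant difference
#' leaves the distance unchanged.
#'
#' @param qm a [quantile_matrix()] or numeric matrix with `NA` for missing.
#' @param overlap_min minimum number of shared observed days per pair
#'   (default 10); pairs below it raise an error listing the offenders.
#' @return a list of class `scaled_distance`: `d` (symmetric distance
#'   matrix, zero diagonal) and `overlap` (matrix of `|S_ij|`).
#' @export
scaled_distance <- function(qm, overlap_min = 10L) {
  X <- unclass(qm)
  M <- !is.na(X)
  X0 <- ifelse(M, X, 0)
  Tn <- ncol(X)
  overlap <- M %*% t(M)                        # |S_ij|
  sq <- X0^2 %*% t(M) + M %*% t(X0^2) - 2 * X0 %*% t(X0)
  sq[sq < 0] <- 0                              # numeric noise
  low <- overlap < overlap_min
  diag(low) <- FALSE
  if (any(low)) {
    idx <- which(low & upper.tri(low), arr.ind = TRUE)
    stop("insufficient overlap (< ", overlap_min, " shared days) for pairs: ",
         paste(sprintf("(%s, %s)", rownames(X)[idx[, 1]], rownames(X)[idx[, 2]]),
               collapse = ", "))
  }
  d <- sqrt(Tn / pmax(overlap, 1L) * sq)
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  structure(list(d = d, overlap = overlap), class = "scaled_distance")
}

#' PCA of entry-quantile records on a pairwise-complete correlation matrix
#'
#' Days are the variables and cows the observations. The day-by-day
#' correlation matrix is computed from all pairwise-complete cow pairs and
#' eigendecomposed; cow scores are obtained after standardizing each day
#' column and setting missing entries to the (post-standardization) day
#' mean of 0. The number of "significant" dimensions is counted by the
#' Kaiser rule (eigenvalues > 1), with the full scree exported so the rule
#' can be overridden by eye.
#'
#' @param qm a [quantile_matrix()].
#' @return an object of class `queue_embedding` with fields `eigenvalues`
#'   (decreasing), `coordinates` (cows x dims of retained scores),
#'   `n_significant`, `scree` (data frame), and `method = "pca"`.
#' @export
pca_correlation <- function(qm) {
  X <- unclass(qm)
  if (nrow(X) < 3L || ncol(X) < 3L) stop("need at least 3 cows and 3 days")
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  flat <- !is.na(sds) & sds == 0
  if (any(flat)) {
    warning("dropping zero-variance days: ",
            paste(colnames(X)[flat], collapse = ", "))
    X <- X[, !flat, drop = FALSE]
  }
  C <- stats::cor(X, use = "pairwise.complete.obs")
  C[is.na(C)] <- 0
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  Z <- scale(X)
  Z[is.na(Z)] <- 0
  scores <- Z %*% eig$vectors
  ev <- pmax(eig$values, 0)
  nsig <- sum(ev > 1)
  med <- apply(unclass(qm), 1L, stats::median, na.rm = TRUE)
  scores <- orient_columns(scores, med)
  keep <- seq_len(max(nsig, 3L))
  structure(list(eigenvalues = ev,
                 coordinates = scores[, keep, drop = FALSE],
                 n_significant = nsig,
                 scree = data.frame(component = seq_along(ev), eigenvalue = ev,
                                    prop_var = ev / sum(ev)),
                 method = "pca"),
            class = "queue_embedding")
}

# orient each column so its correlation with `ref` is non-negative
# (plot-stable sign convention for eigenvectors)
orient_columns <- function(m, ref) {
  for (j in seq_len(ncol(m))) {
    r <- suppressWarnings(stats::cor(m[, j], ref))
    if (!is.na(r) && r < 0) m[, j] <- -m[, j]
  }
  m
}

#' Invert distances into similarities
#'
#' `s_ij = 1 / d_ij`. Zero distances between distinct cows (identical
#' records) would be infinite; they are capped at 10 times the largest
#' finite similarity in the matrix. The diagonal is set to 0 and plays no
#' role in graph construction.
#'
#' @param dm a `scaled_distance` (or plain symmetric distance matrix).
#' @return a symmetric similarity matrix with zero diagonal.
#' @export
similarity_invert <- function(dm) {
  d <- if (inherits(dm, "scaled_distance")) dm$d else as.matrix(dm)
  s <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  off <- row(d) != col(d)
  pos <- off & d > 0
  s[pos] <- 1 / d[pos]
  zero <- off & d == 0
  if (any(zero)) s[zero] <- if (any(pos)) 10 * max(s[pos]) else 1
  s
}

#' k-nearest-neighbor similarity graph
#'
#' Builds a weighted undirected graph by linking each cow to its `k` most
#' similar neighbors; the edge set is the union over both endpoints, so the
#' adjacency is symmetric and every node has degree at least `k`. Edge
#' weights are the similarities. A disconnected graph triggers a warning
#' with component sizes (the spectral embedding still proceeds; each
#' component contributes one trivial eigenpair).
#'
#' @param similarity symmetric similarity matrix with zero diagonal.
#' @param k neighbors per node (default 10).
#' @return symmetric weighted adjacency matrix.
#' @export
knn_graph <- function(similarity, k = 10L) {
  n <- nrow(similarity)
  if (k >= n) stop("k must be smaller than the number of cows")
  adj <- matrix(0, n, n, dimnames = dimnames(similarity))
  for (i in seq_len(n)) {
    s <- similarity[i, ]
    s[i] <- -Inf
    nb <- order(s, decreasing = TRUE)[seq_len(k)]
    adj[i, nb] <- similarity[i, nb]
  }
  adj <- pmax(adj, t(adj))                     # union symmetrization
  comp <- graph_components(adj)
  if (max(comp) > 1L) {
    warning("kNN graph is disconnected; component sizes: ",
            paste(table(comp), collapse = ", "))
  }
  adj
}

#' Diffusion-map embedding from a graph Laplacian
#'
#' Eigendecomposes the Laplacian of the weighted kNN graph and uses the
#' eigenvectors of the smallest non-trivial eigenvalues as embedding
#' coordinates. The default is the symmetric normalized Laplacian
#' `L = I - D^{-1/2} W D^{-1/2}`; unnormalized (`D - W`) and random-walk
#' (`I - D^{-1} W`, computed from the symmetric form) variants are exposed
#' because the qualitative geometry recovered should not depend on the
#' normalization. Trivial eigenpairs (eigenvalue numerically 0, one per
#' connected component) are excluded. The number of significant dimensions
#' is chosen by the largest eigengap among the first `n_dims_max`
#' non-trivial eigenvalues — a reproducible stand-in for reading the
#' spectrum by eye — and the full spectrum is returned for audit.
#'
#' @param adjacency symmetric non-negative weighted adjacency matrix.
#' @param n_dims_max maximum dimensions retained/considered (default 10).
#' @param normalization `"symmetric"` (default), `"unnormalized"`, or
#'   `"randomwalk"`.
#' @param orient_by optional numeric vector (e.g. median entry quantile);
#'   each coordinate is sign-flipped to correlate non-negatively with it.
#' @return a `queue_embedding` with `eigenvalues` (non-trivial, increasing),
#'   `coordinates`, `n_significant`, `eigengaps` (relative gaps
#'   `lambda[i+1] / lambda[i]`), `spectrum` (all eigenvalues), and
#'   `method = "diffusion"`.
#' @export
laplacian_embedding <- function(adjacency, n_dims_max = 10L,
                                normalization = c("symmetric", "unnormalized",
                                                  "randomwalk"),
                                orient_by = NULL) {
  normalization <- match.arg(normalization)
  W <- as.matrix(adjacency)
  if (any(W < 0)) stop("adjacency must be non-negative")
  if (max(abs(W - t(W))) > 1e-8) stop("adjacency must be symmetric")
  n <- nrow(W)
  deg <- rowSums(W)
  deg[deg == 0] <- 1e-12
  if (normalization == "unnormalized") {
    L <- diag(deg) - W
  } else {
    Dhalf <- 1 / sqrt(deg)
    L <- diag(n) - (Dhalf * W) * rep(Dhalf, each = n)  # D^-1/2 W D^-1/2
    L <- (L + t(L)) / 2
  }
  eig <- eigen(L, symmetric = TRUE)
  vals <- rev(eig$values)                       # increasing
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  trivial <- vals < 1e-8
  nt <- which(!trivial)
  if (!length(nt)) stop("no non-trivial eigenpairs")
  keep <- nt[seq_len(min(n_dims_max, length(nt)))]
  vals_k <- vals[keep]
  vecs_k <- vecs[, keep, drop = FALSE]
  if (normalization == "randomwalk") {
    vecs_k <- vecs_k / sqrt(deg)                # phi = D^-1/2 u
    vecs_k <- scale(vecs_k, center = FALSE,
                    scale = sqrt(colSums(vecs_k^2)))
  }
  rownames(vecs_k) <- rownames(W)
  if (!is.null(orient_by)) vecs_k <- orient_columns(vecs_k, orient_by)
  # relative gaps lambda_{i+1} / lambda_i; a flat (structureless) spectrum
  # has ratios near 1, a dominant gap shows as a large ratio
  gaps <- vals_k[-1L] / pmax(vals_k[-length(vals_k)], 1e-12)
  nsig <- if (length(gaps)) which.max(gaps) else 1L
  structure(list(eigenvalues = vals_k, coordinates = vecs_k,
                 n_significant = as.integer(nsig), eigengaps = gaps,
                 spectrum = vals, method = "diffusion",
                 normalization = normalization),
            class = "queue_embedding")
}

#' @export
print.queue_embedding <- function(x, ...) {
  cat(sprintf("<queue_embedding> method = %s, %d cows, %d dims retained, %d significant\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates), x$n_significant))
  invisible(x)
}

#' @export
plot.queue_embedding <- function(x, dims = c(1L, 2L), color_by = NULL, ...) {
  co <- x$coordinates
  col <- if (is.null(color_by)) "black" else
    grDevices::hcl.colors(64, "viridis")[cut(color_by, 64, labels = FALSE)]
  graphics::plot(co[, dims[1]], co[, dims[2]],
                 xlab = paste0("dim ", dims[1]), ylab = paste0("dim ", dims[2]),
                 col = col, pch = 19, ...)
  invisible(x)
}

#' Convenience wrapper: diffusion map of a quantile matrix
#'
#' Chains [scaled_distance()], [similarity_invert()], [knn_graph()] and
#' [laplacian_embedding()] with the package defaults (k = 10 neighbors).
#'
#' @inheritParams scaled_distance
#' @inheritParams knn_graph
#' @inheritParams laplacian_embedding
#' @return a `queue_embedding`.
#' @export
diffusion_map <- function(qm, k = 10L, n_dims_max = 10L, overlap_min = 10L,
                          normalization = "symmetric") {
  med <- apply(unclass(qm), 1L, stats::median, na.rm = TRUE)
  dm <- scaled_distance(qm, overlap_min = overlap_min)
  adj <- knn_graph(similarity_invert(dm), k = k)
  laplacian_embedding(adj, n_dims_max = n_dims_max,
                      normalization = normalization, orient_by = med)
}

#' Harmonic-series reference curves for chain-like embeddings
#'
#' Spectral embeddings of "rope-like" (chain-structured) data imprint a
#' cosine harmonic series on each axis: the k-th non-trivial eigenvector of
#' the path-graph Laplacian on n nodes is
#' `v_k(j) = cos(pi * k * (j + 0.5) / n), j = 0..n-1`. These unit-normalized
#' curves can be overlaid on embedding coordinates (sorted by the first
#' coordinate) to distinguish genuine geometry from the embedding artifact.
#'
#' @param n_points number of nodes along the chain.
#' @param n_dims number of harmonic curves (must be < `n_points`).
#' @return matrix `n_points` x `n_dims`, columns unit-normalized.
#' @export
harmonic_reference <- function(n_points, n_dims) {
  stopifnot(n_dims < n_points)
  j <- seq_len(n_points) - 1L
  v <- sapply(seq_len(n_dims), function(k) cos(pi * k * (j + 0.5) / n_points))
  v <- matrix(v, ncol = n_dims)
  scale(v, center = FALSE, scale = sqrt(colSums(v^2)))[, , drop = FALSE]
}
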