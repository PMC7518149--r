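# Shannon entropy (bits) of a count vector, with 0 * log2(0) == 0.
shannon_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(NA_real_)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Connected components of a symmetric adjacency matrix (positive = edge).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Interpret `x` as a seed: integer scalar, checked.
check_seed <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    stop("seed must be a single integer")
  }
  as.integer(x)
}
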