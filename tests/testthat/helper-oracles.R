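# Brute-force oracles, independent of the igraph-backed implementations.
# All operate on a habitat_network via its plain node/edge data frames.

oracle_adjacency <- function(net) {
  n <- nrow(net$nodes)
  A <- matrix(0, n, n)
  P <- matrix(0, n, n)
  e <- net$edges
  for (k in seq_len(nrow(e))) {
    i <- match(e$from[k], net$nodes$patch_id)
    j <- match(e$to[k], net$nodes$patch_id)
    A[i, j] <- A[j, i] <- 1
    P[i, j] <- P[j, i] <- e$probability[k]
  }
  list(A = A, P = P)
}

oracle_degree <- function(net) rowSums(oracle_adjacency(net)$A)

oracle_strength <- function(net) rowSums(oracle_adjacency(net)$P)

oracle_neigh3 <- function(net) {
  A <- oracle_adjacency(net)$A
  n <- nrow(A)
  B <- diag(n) + A
  R <- (B %*% B %*% B) > 0   # reachable within 3 steps
  rowSums(R) - 1
}

# All simple paths between s and t as lists of node index vectors.
oracle_simple_paths <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (w in seq_len(n)) {
      if (A[v, w] > 0 && !(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

oracle_betweenness <- function(net) {
  A <- oracle_adjacency(net)$A
  n <- nrow(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_simple_paths(A, s, t)
    if (!length(paths)) next
    lens <- lengths(paths)
    L <- min(lens)
    sp <- paths[lens == L]
    sigma <- length(sp)
    for (p in sp) {
      inner <- p[-c(1, length(p))]
      b[inner] <- b[inner] + 1 / sigma
    }
  }
  b
}

oracle_habav <- function(net, include_self = TRUE) {
  adj <- oracle_adjacency(net)
  P <- adj$P
  a <- net$nodes$area_m2
  n <- nrow(P)
  ha <- numeric(n)
  for (i in seq_len(n)) {
    tot <- if (include_self) a[i] else 0
    for (j in seq_len(n)) {
      if (j == i) next
      paths <- oracle_simple_paths(adj$A, i, j)
      if (!length(paths)) next
      best <- max(vapply(paths, function(p) {
        prod(P[cbind(p[-length(p)], p[-1])])
      }, numeric(1)))
      tot <- tot + a[j] * best
    }
    ha[i] <- tot
  }
  ha
}

oracle_components <- function(net) {
  A <- oracle_adjacency(net)$A
  n <- nrow(A)
  seen <- rep(FALSE, n)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE; comp[v] <- k
      queue <- c(queue, which(A[v, ] > 0 & !seen))
    }
  }
  comp
}

# Exhaustive ROC-balance scan (mirrors the spec definition, written
# independently of the implementation).
oracle_roc_balance <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  best_t <- NA; best_gap <- Inf
  for (t in cand) {
    gap <- abs(mean(pres >= t) - mean(bg < t))
    if (gap < best_gap) { best_gap <- gap; best_t <- t }
  }
  best_t
}
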