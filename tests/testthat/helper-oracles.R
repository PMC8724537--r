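# Independent oracles used against the package implementations. Each is
# written from the definition of the quantity, by a different algorithm
# than the implementation it checks.

# TOM by literal triple loop over the adjacency definition.
tomOracle <- function(X, beta) {
  r <- abs(cor(t(X)))
  a <- r^beta
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- list(rownames(X), rownames(X))
  tom
}

# HITS hub vector by power iteration on A %*% t(A) (hub update),
# normalized to max 1.
hitsOracle <- function(A, tol = 1e-12, maxIter = 10000) {
  h <- rep(1, nrow(A))
  M <- A %*% t(A)
  for (i in seq_len(maxIter)) {
    h2 <- as.numeric(M %*% h)
    h2 <- h2 / max(h2)
    if (max(abs(h2 - h)) < tol) break
    h <- h2
  }
  h
}

# All shortest paths between s and t by recursive enumeration over BFS
# distance layers; returns list of node sequences.
allShortestPaths <- function(adj, dist, s, t) {
  if (!is.finite(dist[s, t])) return(list())
  walkBack <- function(v) {
    if (v == s) return(list(s))
    preds <- adj[[v]][dist[s, adj[[v]]] == dist[s, v] - 1]
    out <- list()
    for (p in preds)
      for (path in walkBack(p)) out[[length(out) + 1]] <- c(path, v)
    out
  }
  walkBack(t)
}

# Betweenness (normalized), stress, eccentricity and per-node mean path
# length by exhaustive shortest-path enumeration on an undirected simple
# graph given as an adjacency matrix.
topologyOracle <- function(am) {
  n <- nrow(am)
  adj <- lapply(seq_len(n), function(i) which(am[i, ] > 0))
  # BFS distances
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]])
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- dist[s, v] + 1
          nxt <- c(nxt, w)
        }
      frontier <- unique(nxt)
    }
  }
  stress <- numeric(n)
  btwRaw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- allShortestPaths(adj, dist, s, t)
    if (!length(paths)) next
    through <- table(factor(unlist(lapply(paths, function(p)
      setdiff(p, c(s, t)))), levels = seq_len(n)))
    stress <- stress + as.numeric(through)
    btwRaw <- btwRaw + as.numeric(through) / length(paths)
  }
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  fd <- dist; diag(fd) <- NA; fd[is.infinite(fd)] <- NA
  ecc <- apply(fd, 1, function(z) if (all(is.na(z))) 0 else
    max(z, na.rm = TRUE))
  apl <- apply(fd, 1, function(z) if (all(is.na(z))) NA_real_ else
    mean(z, na.rm = TRUE))
  list(betweenness = btwRaw / norm, stress = stress,
       eccentricity = ecc, avg.path.length = apl)
}

# snpsLD by brute-force double loop over all (hit, marker) pairs.
snpsLdOracle <- function(d, hits, minR2 = 0.7) {
  out <- character()
  for (h in hits) for (m in colnames(d)) {
    if (m %in% hits) next
    if (sd(d[, h]) == 0 || sd(d[, m]) == 0) next
    if (cor(d[, h], d[, m])^2 >= minR2) out <- c(out, m)
  }
  sort(unique(out))
}

# Adjusted Rand index (contingency-table formula), independent of any
# clustering package.
ariOracle <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(choose(x, 2))
  sumIj <- ch2(tab)
  sumI <- ch2(rowSums(tab))
  sumJ <- ch2(colSums(tab))
  nC2 <- choose(sum(tab), 2)
  exp <- sumI * sumJ / nC2
  (sumIj - exp) / ((sumI + sumJ) / 2 - exp)
}
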