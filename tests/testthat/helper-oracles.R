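# Independent oracles used by the suite. These re-derive quantities by brute
# force (enumeration, closed forms) and never call the code paths they check.

# Brute-force betweenness: BFS distances, then DFS enumeration of every
# shortest path between each unordered pair, counting interior visits.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      nb <- which(adj[v, ] > 0)
      for (w in nb) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  bc <- rep(0, n)
  for (s in seq_len(n - 1)) {
    ds <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (!is.finite(ds[t])) next
      # enumerate all shortest s->t paths by walking down the BFS gradient
      dt <- bfs_dist(t)
      paths <- list(s)
      complete <- list()
      while (length(paths) > 0) {
        path <- paths[[1]]; paths <- paths[-1]
        v <- path[length(path)]
        if (v == t) { complete[[length(complete) + 1]] <- path; next }
        nb <- which(adj[v, ] > 0 & ds == ds[v] + 1 & dt == ds[t] - ds[v] - 1)
        for (w in nb) paths[[length(paths) + 1]] <- c(path, w)
      }
      sigma <- length(complete)
      if (sigma == 0) next
      interior <- unlist(lapply(complete, function(p) p[-c(1, length(p))]))
      if (length(interior) > 0) {
        tab <- table(interior)
        idx <- as.integer(names(tab))
        bc[idx] <- bc[idx] + as.numeric(tab) / sigma
      }
    }
  }
  bc
}

# Exhaustive two-group PERMANOVA p-value: every assignment of m samples to
# group 1, F recomputed from the raw within/between decomposition.
exhaustive_permanova_p <- function(d, labels) {
  n <- nrow(d)
  d2 <- d^2
  g1 <- unique(labels)[1]
  m <- sum(labels == g1)
  sst <- sum(d2) / (2 * n)
  f_of <- function(idx) {
    in1 <- seq_len(n) %in% idx
    ssw <- sum(d2[in1, in1]) / (2 * m) + sum(d2[!in1, !in1]) / (2 * (n - m))
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  f_obs <- f_of(which(labels == g1))
  f_all <- apply(combn(n, m), 2, f_of)
  mean(f_all >= f_obs - 1e-12)
}

# Spearman rho closed form without ties: 1 - 6 sum(d^2) / (n (n^2 - 1))
spearman_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x) * (length(x)^2 - 1))
}

# Kruskal-Wallis H from first principles (no ties assumed)
kw_by_hand <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  N <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, idx, sum)
  ns <- lengths(groups)
  12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
}
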