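# Independent brute-force oracles. Each deliberately uses a different
# algorithm than the implementation it checks.

# Floyd–Warshall all-pairs distances from the raw adjacency matrix
# (implementation uses breadth-first search).
oracle_floyd_warshall <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  dimnames(d) <- list(igraph::V(net)$name, igraph::V(net)$name)
  d
}

# Betweenness by explicit enumeration of every shortest path (DFS over the
# distance levels of the Floyd–Warshall oracle), pair-normalized.
oracle_betweenness <- function(net) {
  d <- oracle_floyd_warshall(net)
  n <- nrow(d)
  adj <- lapply(seq_len(n), function(i) {
    which(as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))[i, ] > 0)
  })
  paths_between <- function(s, t) {
    # all shortest s->t paths as lists of interior vertices
    res <- list()
    walk <- function(v, interior) {
      if (v == t) {
        res[[length(res) + 1L]] <<- interior
        return(invisible(NULL))
      }
      for (w in adj[[v]]) {
        if (is.finite(d[v, t]) && d[s, w] == d[s, v] + 1 &&
            d[w, t] == d[v, t] - 1) {
          walk(w, if (w == t) interior else c(interior, w))
        }
      }
    }
    walk(s, integer(0))
    res
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      paths <- paths_between(s, t)
      if (length(paths) == 0L) next
      for (pth in paths) {
        for (v in pth) b[v] <- b[v] + 1 / length(paths)
      }
    }
  }
  if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  stats::setNames(b, igraph::V(net)$name)
}

# K-shell by literal recursive pruning: repeatedly delete all nodes of
# degree <= k within the surviving subgraph.
oracle_kshell <- function(net) {
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  n <- nrow(A)
  shell <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    deg <- rowSums(A[, alive, drop = FALSE])[alive]
    if (all(deg > k)) {
      k <- k + 1L
      next
    }
    repeat {
      idx <- which(alive)
      deg_alive <- rowSums(A[alive, alive, drop = FALSE])
      peel <- idx[deg_alive <= k]
      if (length(peel) == 0L) break
      shell[peel] <- k
      alive[peel] <- FALSE
    }
  }
  stats::setNames(as.numeric(shell), igraph::V(net)$name)
}

# Kendall pair counts by an explicit double loop.
oracle_kendall <- function(x, y, variant = "a") {
  y <- y[names(x)]
  n <- length(x)
  nc <- 0L; nd <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) nc <- nc + 1L
      if (s < 0) nd <- nd + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  if (variant == "a") return(2 * (nc - nd) / (n * (n - 1)))
  ties <- function(v) { t <- table(v); sum(t * (t - 1) / 2) }
  denom <- sqrt((n0 - ties(x)) * (n0 - ties(y)))
  if (denom == 0) 0 else (nc - nd) / denom
}

# Monte-Carlo standard error of a mean.
mc_se <- function(x) stats::sd(x) / sqrt(length(x))
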