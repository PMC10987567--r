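# Exact bond-percolation quantities by exhaustive edge-subset enumeration.
#
# With recovery probability 1, the SIR final-size distribution from a seed
# set equals the distribution of the set of nodes reachable from the seeds
# when each edge is kept independently with the infection probability; the
# independent cascade induces the same distribution. On graphs with few
# edges the expectation can therefore be computed exactly by summing over
# all 2^M edge subsets, which gives a simulation-free oracle for the
# Monte-Carlo spreaders.

# Enumerate all edge subsets; call visit(component_membership, weight) for
# each. Union-find with path halving keeps the inner loop cheap.
percolation_enumerate <- function(net, p, visit) {
  validate_network(net)
  if (!is.numeric(p) || p < 0 || p > 1) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  m <- igraph::gsize(net)
  n <- igraph::gorder(net)
  if (m > 20L) {
    stop(sprintf(
      "exact percolation enumerates 2^M edge subsets; M = %d exceeds the limit of 20", m),
      call. = FALSE)
  }
  el <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(el) <- "integer"
  ea <- el[, 1L]; eb <- el[, 2L]
  pow <- bitwShiftL(1L, seq_len(m) - 1L)
  # log-space subset weights avoid underflow at extreme p
  for (s in 0:(2^m - 1)) {
    parent <- seq_len(n)
    k_on <- 0L
    for (k in seq_len(m)) {
      if (bitwAnd(s, pow[k]) != 0L) {
        k_on <- k_on + 1L
        a <- ea[k]
        while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
        b <- eb[k]
        while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
        if (a != b) parent[a] <- b
      }
    }
    comp <- integer(n)
    for (i in seq_len(n)) {
      a <- i
      while (parent[a] != a) a <- parent[a]
      comp[i] <- a
    }
    w <- p^k_on * (1 - p)^(m - k_on)
    if (w > 0) visit(comp, w)
  }
  invisible(NULL)
}

#' Exact bond-percolation spreading influence
#'
#' For every node, the exact expected number of other nodes reached when
#' each edge is kept independently with probability `p` — the closed-form
#' value that [sir_influence()] with `beta = 1, alpha = p` and single-seed
#' IC cascades estimate by Monte Carlo. Computed by exhaustive enumeration
#' of all `2^M` edge subsets, so it is restricted to graphs with at most 20
#' edges.
#'
#' @param net A network graph with at most 20 edges.
#' @param p Edge retention probability, in `[0, 1]`.
#' @return A named numeric score vector of exact expected spread sizes
#'   (seed excluded).
#' @examples
#' round(exact_percolation_influence(example_network(), 0.5), 3)
#' @export
exact_percolation_influence <- function(net, p) {
  n <- igraph::gorder(net)
  infl <- numeric(n)
  percolation_enumerate(net, p, function(comp, w) {
    sz <- tabulate(comp, n)
    infl <<- infl + w * (sz[comp] - 1)
  })
  stats::setNames(infl, igraph::V(net)$name)
}

#' Exact bond-percolation multi-seed spread
#'
#' Exact expected number of nodes (seeds included, by default) reachable
#' from a seed set under independent edge retention with probability `p`;
#' the simulation-free counterpart of [sir_spread()] / [ic_spread()] with
#' recovery probability 1.
#'
#' @inheritParams exact_percolation_influence
#' @param seeds Seed nodes (labels or indices), non-empty.
#' @param include_seeds Count the seeds in the total (default `TRUE`).
#' @return The exact expected spread size (a single number).
#' @export
exact_percolation_spread <- function(net, seeds, p, include_seeds = TRUE) {
  idx <- resolve_seeds(net, seeds)
  n <- igraph::gorder(net)
  total <- 0
  percolation_enumerate(net, p, function(comp, w) {
    sz <- tabulate(comp, n)
    reached <- sum(sz[unique(comp[idx])])
    total <<- total + w * reached
  })
  if (include_seeds) total else total - length(idx)
}
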