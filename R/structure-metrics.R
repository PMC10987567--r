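# Structural node metrics: the quantities the heat-conduction score composes
# (degree, eigenvector centrality, distances, closeness, network density,
# degree density) plus the k-shell and betweenness baselines.
#
# All score functions return a "score vector": a numeric vector named by node
# label, defined for every node of the input graph, all values finite.

#' Node degrees
#'
#' Integer degree of every node. The degree sum always equals twice the edge
#' count.
#'
#' @param net A network graph (see [validate_network()]).
#' @return A named numeric score vector.
#' @export
degree_vector <- function(net) {
  validate_network(net)
  d <- igraph::degree(net)
  stats::setNames(as.numeric(d), igraph::V(net)$name)
}

#' Degree centrality
#'
#' Degree normalized by the maximum possible degree, `D(v) / (N - 1)`,
#' in `[0, 1]`.
#'
#' @inheritParams degree_vector
#' @return A named numeric score vector.
#' @export
degree_centrality <- function(net) {
  validate_network(net)
  n <- igraph::gorder(net)
  if (n < 2L) stop("degree centrality needs at least 2 nodes", call. = FALSE)
  degree_vector(net) / (n - 1)
}

#' Eigenvector centrality (unit Euclidean norm)
#'
#' Principal-eigenvector scores of the adjacency matrix, computed by power
#' iteration and scaled to unit L2 norm with non-negative orientation, the
#' convention under which \eqn{\sum_i EC(v_i)^2 = 1}. Iteration is on
#' \eqn{A + I}, which has the same principal eigenvector as \eqn{A} but
#' converges on bipartite graphs too, where iterating \eqn{A} alone
#' oscillates between the two dominant eigendirections.
#'
#' @inheritParams degree_vector
#' @param tol Convergence threshold on the max-norm difference between
#'   successive normalized iterates.
#' @param max_iter Maximum number of power-iteration steps.
#' @return A named numeric score vector with non-negative entries and unit
#'   Euclidean norm.
#' @examples
#' ec <- eigenvector_centrality(example_network())
#' sum(ec^2)
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 1000L) {
  validate_network(net)
  if (igraph::gsize(net) < 1L) {
    stop("eigenvector centrality needs at least one edge", call. = FALSE)
  }
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  resid <- NA_real_
  for (it in seq_len(max_iter)) {
    y <- as.vector(A %*% x) + x   # (A + I) x
    y <- y / sqrt(sum(y^2))
    resid <- max(abs(y - x))
    x <- y
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "power iteration did not converge in %d iterations (residual %.3e)",
      max_iter, resid), call. = FALSE)
  }
  if (sum(x) < 0) x <- -x
  x[abs(x) < .Machine$double.eps] <- 0
  stats::setNames(x, igraph::V(net)$name)
}

#' All-pairs shortest-path distances
#'
#' Hop counts between every pair of nodes (breadth-first search). Unreachable
#' pairs carry `Inf` as the unreachable marker; the diagonal is zero.
#'
#' @inheritParams degree_vector
#' @return A symmetric numeric matrix with node labels as dimnames.
#' @export
all_pairs_distances <- function(net) {
  validate_network(net)
  igraph::distances(net, algorithm = "unweighted")
}

#' Closeness centrality
#'
#' `CC(v) = (N - 1) / sum_j R(v, j)` on a connected graph. On a disconnected
#' graph closeness is undefined across components, so it is computed within
#' each node's connected component, using that component's size in place of
#' `N`; nodes in singleton components score 0.
#'
#' @inheritParams degree_vector
#' @param dist Optional precomputed distance matrix from
#'   [all_pairs_distances()]; recomputed if `NULL`.
#' @return A named numeric score vector.
#' @export
closeness_centrality <- function(net, dist = NULL) {
  validate_network(net)
  n <- igraph::gorder(net)
  if (n < 2L) stop("closeness centrality needs at least 2 nodes", call. = FALSE)
  if (is.null(dist)) dist <- all_pairs_distances(net)
  comp <- igraph::components(net)$membership
  cc <- numeric(n)
  for (i in seq_len(n)) {
    members <- comp == comp[i]
    size <- sum(members)
    cc[i] <- if (size < 2L) 0 else (size - 1) / sum(dist[i, members])
  }
  stats::setNames(cc, igraph::V(net)$name)
}

#' Network density
#'
#' Fraction of realized edges among all node pairs,
#' `2 * M / (N * (N - 1))`; the thermal-conductivity term of the
#' heat-conduction score.
#'
#' @inheritParams degree_vector
#' @return A number in `[0, 1]`.
#' @examples
#' network_density(example_network())  # 0.29091
#' @export
network_density <- function(net) {
  validate_network(net)
  n <- igraph::gorder(net)
  if (n < 2L) stop("network density needs at least 2 nodes", call. = FALSE)
  2 * igraph::gsize(net) / (n * (n - 1))
}

#' Degree density of a receiving node
#'
#' The "contact area" term of the heat-conduction score: the receiver's
#' degree spread over a disc whose radius is the hop distance. Two area
#' conventions are supported (see [hcm_config()]):
#' `quadratic` uses the literal disc area `D / (pi * R^2)`;
#' `exponential` uses `D / pi^R`, the convention that reproduces the
#' reference example's output values. The two coincide at distance 1.
#'
#' @param receiver_degree Degree of the receiving node (>= 0). Vectorized.
#' @param distance Hop distance (>= 1, finite). Vectorized.
#' @param mode Area convention, `"quadratic"` or `"exponential"`.
#' @return Numeric degree-density value(s), strictly decreasing in distance
#'   and increasing in degree.
#' @examples
#' degree_density(4, 1, "quadratic")  # 1.27324
#' degree_density(4, 2, "quadratic")  # 0.31831
#' @export
degree_density <- function(receiver_degree, distance,
                           mode = c("quadratic", "exponential")) {
  mode <- match.arg(mode)
  if (any(!is.finite(distance)) || any(distance < 1)) {
    stop("`distance` must be finite and >= 1 (exclude unreachable pairs)",
         call. = FALSE)
  }
  if (any(receiver_degree < 0)) {
    stop("`receiver_degree` must be >= 0", call. = FALSE)
  }
  switch(mode,
         quadratic = receiver_degree / (pi * distance^2),
         exponential = receiver_degree / pi^distance)
}

#' K-shell (coreness) decomposition
#'
#' Shell index of every node from recursive removal of nodes by increasing
#' degree; a classical coarse importance baseline.
#'
#' @inheritParams degree_vector
#' @return A named numeric score vector of shell indices.
#' @export
k_shell <- function(net) {
  validate_network(net)
  stats::setNames(as.numeric(igraph::coreness(net)), igraph::V(net)$name)
}

#' Shortest-path betweenness centrality
#'
#' Fraction of shortest paths passing through each node (endpoints excluded),
#' normalized by the number of node pairs `(N - 1)(N - 2) / 2`, so a node
#' mediating every pair scores 1. Graphs with fewer than 3 nodes score 0.
#'
#' @inheritParams degree_vector
#' @return A named numeric score vector.
#' @export
betweenness_centrality <- function(net) {
  validate_network(net)
  n <- igraph::gorder(net)
  b <- igraph::betweenness(net, directed = FALSE, weights = NULL)
  if (n > 2L) b <- b / ((n - 1) * (n - 2) / 2)
  stats::setNames(as.numeric(b), igraph::V(net)$name)
}

#' Tabulate and write score vectors
#'
#' `score_table()` turns a named score vector into a data frame with columns
#' `node`, `score`, `rank` (rank 1 = highest score; ties keep input node
#' order, see [rank_nodes()]). `write_scores()` writes it as CSV;
#' `read_scores()` reads such a CSV back into a named score vector.
#'
#' @param scores A named numeric score vector.
#' @param path File path for CSV input/output.
#' @return `score_table()`: a data frame; `read_scores()`: a named numeric
#'   vector; `write_scores()`: `path`, invisibly.
#' @export
score_table <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  ord <- rank_nodes(scores)
  rank <- match(names(scores), ord)
  data.frame(node = names(scores), score = unname(scores), rank = rank,
             stringsAsFactors = FALSE)
}

#' @rdname score_table
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(score_table(scores), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname score_table
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("node", "score") %in% names(df))) {
    stop("scores CSV must have columns 'node' and 'score'", call. = FALSE)
  }
  stats::setNames(as.numeric(df$score), as.character(df$node))
}
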