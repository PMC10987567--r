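#' @importFrom igraph V E vcount ecount degree distances graph_from_data_frame
#'   as_edgelist simplify components induced_subgraph sample_gnp sample_pa
#'   coreness betweenness is_igraph is_directed vertex_attr vertex_attr<-
#'   make_empty_graph
#'   add_vertices add_edges as_adjacency_matrix gorder gsize
NULL

# Run code with a temporarily fixed RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a counter.
# Linear congruential mixing; keeps every derived seed in [1, 2^31 - 2].
substream_seed <- function(master, index) {
  s <- (abs(as.numeric(master)) * 48271 + 104729 * as.numeric(index)) %%
    2147483646
  as.integer(s) + 1L
}

#' Validate a network object
#'
#' All functions in this package operate on undirected, unweighted, simple
#' graphs represented as named [igraph][igraph::igraph-package] graphs, with
#' vertex names assigned in first-appearance order. `validate_network()`
#' checks those invariants and returns the graph invisibly, so it can be used
#' as an assertion at module boundaries.
#'
#' @param net An `igraph` graph.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  if (!is_igraph(net)) stop("`net` must be an igraph graph", call. = FALSE)
  if (is_directed(net)) stop("`net` must be undirected", call. = FALSE)
  if (gorder(net) < 1L) stop("`net` must have at least one node", call. = FALSE)
  if (igraph::any_loop(net)) stop("`net` must not contain self-loops", call. = FALSE)
  if (igraph::any_multiple(net)) stop("`net` must not contain multi-edges", call. = FALSE)
  if (is.null(vertex_attr(net, "name"))) {
    stop("`net` must have vertex names", call. = FALSE)
  }
  invisible(net)
}

# Build a simple undirected named graph from character endpoint vectors,
# keeping first-appearance label order and dropping loops/duplicates with a
# warning (public edge lists are messy; the model assumes a simple graph).
build_network <- function(from, to, context = "edge list") {
  labels <- unique(as.vector(rbind(from, to)))
  g <- make_empty_graph(n = 0, directed = FALSE)
  g <- add_vertices(g, length(labels), name = labels)
  if (length(from) > 0L) {
    idx <- rbind(match(from, labels), match(to, labels))
    g <- add_edges(g, as.vector(idx))
  }
  m0 <- gsize(g)
  g <- simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- m0 - gsize(g)
  if (dropped > 0L) {
    warning(sprintf("%s: dropped %d self-loop/duplicate edge(s)",
                    context, dropped), call. = FALSE)
  }
  g
}

#' Read an undirected network from a plain-text edge list
#'
#' Parses a two-column edge list (one edge per line, whitespace- or
#' comma-separated node labels, `#`-prefixed comment lines ignored) into a
#' simple undirected graph. Node labels are opaque strings; vertices are
#' ordered by first appearance in the file. Self-loops and duplicate edges
#' are dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter. `NULL` (default) auto-detects: comma if
#'   the first data line contains one, otherwise any whitespace.
#' @param comment_prefix Lines starting with this prefix are skipped.
#' @return An undirected simple `igraph` graph with named vertices.
#' @seealso [write_edge_list()], [example_network()]
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "a b", "b c"), f)
#' g <- read_edge_list(f)
#' igraph::gorder(g)
#' @export
read_edge_list <- function(path, delimiter = NULL, comment_prefix = "#") {
  if (!file.exists(path)) {
    stop(sprintf("edge list file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_prefix) & nzchar(trimws(lines))
  data_idx <- which(keep)
  if (length(data_idx) == 0L) {
    stop(sprintf("edge list '%s' contains no edges", path), call. = FALSE)
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl(",", lines[data_idx[1L]], fixed = TRUE)) "," else ""
  }
  from <- character(length(data_idx))
  to <- character(length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    fields <- if (identical(delimiter, "")) {
      strsplit(trimws(lines[i]), "\\s+")[[1L]]
    } else {
      trimws(strsplit(lines[i], delimiter, fixed = TRUE)[[1L]])
    }
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L) {
      stop(sprintf("malformed edge list line %d in '%s': '%s'",
                   i, path, lines[i]), call. = FALSE)
    }
    from[k] <- fields[1L]
    to[k] <- fields[2L]
  }
  build_network(from, to, context = sprintf("'%s'", path))
}

#' Write a network as a plain-text edge list
#'
#' Writes one `u<TAB>v` line per edge, each unordered pair once. Reading the
#' file back with [read_edge_list()] recovers the same edge set (isolated
#' vertices are not representable in an edge list and are lost).
#'
#' @param net A network graph (see [validate_network()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  validate_network(net)
  el <- as_edgelist(net, names = TRUE)
  lines <- if (nrow(el) == 0L) character(0) else paste(el[, 1L], el[, 2L], sep = "\t")
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("cannot write edge list to '%s': %s",
                                            path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' The 11-node worked-example network
#'
#' A small connected graph of 11 nodes (`v1`..`v11`) and 16 edges used
#' throughout the documentation and tests as the reference example for the
#' heat-conduction ranking. Node `v1` is a cut vertex: removing it splits the
#' graph into two components. Reference values for its structural metrics and
#' heat-conduction scores are available from [example_reference()].
#'
#' @return An undirected simple `igraph` graph with 11 vertices and 16 edges.
#' @examples
#' g <- example_network()
#' igraph::gsize(g)
#' @export
example_network <- function() {
  from <- c("v1", "v1", "v1", "v1", "v2", "v2", "v3", "v4",
            "v4", "v4", "v6", "v8", "v8", "v9", "v9", "v10")
  to <- c("v2", "v3", "v8", "v9", "v3", "v7", "v4", "v5",
          "v6", "v7", "v7", "v9", "v11", "v10", "v11", "v11")
  # force the canonical v1..v11 vertex order
  labels <- paste0("v", 1:11)
  g <- make_empty_graph(n = 0, directed = FALSE)
  g <- add_vertices(g, 11L, name = labels)
  add_edges(g, as.vector(rbind(match(from, labels), match(to, labels))))
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest connected node set. Ties are
#' broken in favour of the component containing the earliest vertex in
#' first-appearance order, so the result is deterministic.
#'
#' @param net A network graph.
#' @return An `igraph` graph; vertex order follows the input graph.
#' @export
largest_component <- function(net) {
  validate_network(net)
  comp <- components(net)
  best_size <- max(comp$csize)
  candidates <- which(comp$csize == best_size)
  # earliest first-appearance vertex decides among equally large components
  first_vertex <- vapply(candidates,
                         function(cc) min(which(comp$membership == cc)), 1L)
  chosen <- candidates[which.min(first_vertex)]
  induced_subgraph(net, which(comp$membership == chosen))
}

#' Generate random benchmark graphs
#'
#' Reproducible Erdős–Rényi \eqn{G(n,p)} and Barabási–Albert preferential-
#' attachment graphs used as synthetic stand-ins for real networks in tests
#' and experiments. Vertices are named `v1`..`vn`.
#'
#' @param n Number of nodes.
#' @param p Edge probability (ER), in `[0, 1]`.
#' @param m Edges attached per new node (BA), `1 <= m < n`.
#' @param seed Integer seed; the same seed always yields the same graph.
#' @return An undirected simple named `igraph` graph.
#' @examples
#' g <- generate_er(20, 0.2, seed = 1)
#' identical(igraph::as_edgelist(g), igraph::as_edgelist(generate_er(20, 0.2, seed = 1)))
#' @export
generate_er <- function(n, p, seed) {
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (!is.numeric(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  g <- with_local_seed(seed, sample_gnp(n, p, directed = FALSE))
  vertex_attr(g, "name") <- paste0("v", seq_len(n))
  g
}

#' @rdname generate_er
#' @export
generate_ba <- function(n, m, seed) {
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (m < 1L || m >= n) stop("`m` must satisfy 1 <= m < n", call. = FALSE)
  g <- with_local_seed(seed, sample_pa(n, m = m, directed = FALSE))
  g <- simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  vertex_attr(g, "name") <- paste0("v", seq_len(n))
  g
}
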