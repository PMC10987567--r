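# The heat-conduction importance score.
#
# The physical analogy: heat conducted between two bodies is
# Q = dT * K * A / dL. Mapped onto a network, the "temperature difference"
# is the eigenvector-centrality gap between sender and receiver, the
# conductivity is the network density, the contact area is the receiver's
# degree density, and the distance is the shortest-path hop count. A node's
# importance is its mean output value over all other nodes.

#' Configuration of the heat-conduction score
#'
#' The one genuinely open knob is the degree-density area convention inside
#' the pairwise output value:
#' \describe{
#'   \item{`exponential`}{`Q = D_i * exp(EC_i - EC_j) * density * D_j / (R * pi^R)`.
#'     The default: it reproduces the reference example's published output
#'     values (see [example_reference()]) to the printed precision.}
#'   \item{`quadratic`}{`Q = D_i * exp(EC_i - EC_j) * density * D_j / (pi * R^3)`,
#'     i.e. the literal disc-area degree density divided by the distance.}
#' }
#' The two conventions coincide for every pair at distance 1 and diverge
#' beyond it (at `R = 2` their ratio is already `pi^2 / (2 pi) != 1`).
#' Unreachable pairs contribute zero to a node's output sum while the
#' normalizer stays `N - 1`, so capacities remain well defined on
#' disconnected graphs.
#'
#' @param area_mode Degree-density convention, `"exponential"` or
#'   `"quadratic"`.
#' @return An object of class `hcm_config`.
#' @seealso [output_value()], [output_capacity()]
#' @export
hcm_config <- function(area_mode = c("exponential", "quadratic")) {
  structure(list(area_mode = match.arg(area_mode),
                 unreachable_policy = "skip"),
            class = "hcm_config")
}

#' @export
print.hcm_config <- function(x, ...) {
  cat("Heat-conduction score configuration\n")
  cat("  area_mode:          ", x$area_mode, "\n", sep = "")
  cat("  unreachable_policy: ", x$unreachable_policy, "\n", sep = "")
  invisible(x)
}

#' Pairwise heat-conduction output value
#'
#' The heat `Q(v_i, v_j)` that node `i` exports to node `j`: the product of
#' the sender's degree, the exponential of the eigenvector-centrality gap,
#' the network density, and the receiver's degree density, divided by the
#' hop distance. Vectorized over all arguments.
#'
#' @param D_i Sender degree.
#' @param EC_i,EC_j Sender and receiver eigenvector centralities (unit-L2
#'   convention, see [eigenvector_centrality()]).
#' @param density Network density (see [network_density()]).
#' @param D_j Receiver degree.
#' @param R_ij Hop distance, finite and >= 1 (apply the unreachable policy
#'   before calling).
#' @param config An [hcm_config()].
#' @return Non-negative numeric value(s); zero iff either degree is zero.
#' @examples
#' # v1 -> v2 on the example network:
#' output_value(4, 0.44507, 0.29872, 0.29091, 3, 1)  # 1.28632
#' @export
output_value <- function(D_i, EC_i, EC_j, density, D_j, R_ij,
                         config = hcm_config()) {
  stopifnot(inherits(config, "hcm_config"))
  if (any(!is.finite(R_ij)) || any(R_ij < 1)) {
    stop("`R_ij` must be finite and >= 1: unreachable pairs must be excluded",
         call. = FALSE)
  }
  if (any(density < 0) || any(density > 1)) {
    stop("`density` must lie in [0, 1]", call. = FALSE)
  }
  dd <- degree_density(D_j, R_ij,
                       mode = if (config$area_mode == "exponential")
                         "exponential" else "quadratic")
  D_i * exp(EC_i - EC_j) * density * dd / R_ij
}

#' Heat-conduction output capacity of every node
#'
#' The importance score: `I(v_i) = (1 / (N - 1)) * sum_{j != i} Q(v_i, v_j)`,
#' with unreachable pairs contributing zero while the normalizer stays
#' `N - 1`. All structural inputs (degrees, eigenvector centrality, distance
#' matrix, density) are computed once and reused for every pair; pass
#' `metrics` to reuse values you already have.
#'
#' @param net A network graph (see [validate_network()]).
#' @param config An [hcm_config()].
#' @param metrics Optional precomputed list with elements `degree`, `ec`,
#'   `dist`, `density` (as returned by [degree_vector()],
#'   [eigenvector_centrality()], [all_pairs_distances()],
#'   [network_density()]). Any missing element is computed.
#' @return A named numeric score vector of output capacities.
#' @examples
#' ic <- output_capacity(example_network())
#' round(ic["v1"], 6)  # 0.615762
#' @export
output_capacity <- function(net, config = hcm_config(), metrics = NULL) {
  validate_network(net)
  stopifnot(inherits(config, "hcm_config"))
  n <- igraph::gorder(net)
  if (n < 2L) stop("output capacity needs at least 2 nodes", call. = FALSE)
  deg <- if (!is.null(metrics$degree)) metrics$degree else degree_vector(net)
  ec <- if (!is.null(metrics$ec)) metrics$ec else eigenvector_centrality(net)
  dist <- if (!is.null(metrics$dist)) metrics$dist else all_pairs_distances(net)
  density <- if (!is.null(metrics$density)) metrics$density else network_density(net)

  gap <- exp(outer(ec, ec, "-"))          # e^(EC_i - EC_j)
  dd <- outer(rep(1, n), deg)             # receiver degree D_j per column
  area <- if (config$area_mode == "exponential") {
    dist * pi^dist
  } else {
    pi * dist^3
  }
  q <- deg * gap * density * dd / area
  q[!is.finite(dist) | dist == 0] <- 0    # skip unreachable pairs + diagonal
  stats::setNames(rowSums(q) / (n - 1), igraph::V(net)$name)
}

#' Rank nodes by score
#'
#' Nodes in non-increasing score order; equal scores keep first-appearance
#' (input) order, so rankings are deterministic.
#'
#' @param scores A named numeric score vector with finite values.
#' @return A character vector of node labels, best first.
#' @examples
#' rank_nodes(c(a = 1, b = 3, c = 2))  # "b" "c" "a"
#' @export
rank_nodes <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  names(scores)[order(-scores)]   # order() is stable: ties keep input order
}
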