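#' Frozen reference values for the worked-example network
#'
#' The published reference tables for [example_network()], frozen at their
#' printed precision (5 decimals): degrees, eigenvector and closeness
#' centralities, the full hop-distance block, the quadratic degree densities
#' towards `v1`, the exponential-convention output values of `v1`, and the
#' output capacities with their descending ranking. [run_example()] and the
#' test-suite compare fresh computations against these values.
#'
#' @return A list with elements `density`, `degree`, `ec`, `cc` (named
#'   vectors over `v1`..`v11`), `dist` (11 x 11 matrix), `dd_quadratic_to_v1`
#'   (degree density from each other node to `v1`, quadratic convention),
#'   `q_v1` (output value of `v1` for each other node, exponential
#'   convention), `capacity` (output capacities in ranked order),
#'   `ranking` (node labels, best first), `i_v1` (the capacity of `v1` at
#'   6-decimal precision).
#' @export
example_reference <- function() {
  nodes <- paste0("v", 1:11)
  dist <- matrix(c(
    0, 1, 1, 2, 3, 3, 2, 1, 1, 2, 2,
    1, 0, 1, 2, 3, 2, 1, 2, 2, 3, 3,
    1, 1, 0, 1, 2, 2, 2, 2, 2, 3, 3,
    2, 2, 1, 0, 1, 1, 1, 3, 3, 4, 4,
    3, 3, 2, 1, 0, 2, 2, 4, 4, 5, 5,
    3, 2, 2, 1, 2, 0, 1, 4, 4, 5, 5,
    2, 1, 2, 1, 2, 1, 0, 3, 3, 4, 4,
    1, 2, 2, 3, 4, 4, 3, 0, 1, 2, 1,
    1, 2, 2, 3, 4, 4, 3, 1, 0, 1, 1,
    2, 3, 3, 4, 5, 5, 4, 2, 1, 0, 1,
    2, 3, 3, 4, 5, 5, 4, 1, 1, 1, 0),
    nrow = 11, byrow = TRUE, dimnames = list(nodes, nodes))
  list(
    density = 0.29091,
    degree = stats::setNames(c(4, 3, 3, 4, 1, 2, 3, 3, 4, 2, 3), nodes),
    ec = stats::setNames(c(0.44507, 0.29872, 0.30294, 0.22330, 0.06995,
                           0.13435, 0.20561, 0.38080, 0.43838, 0.24139,
                           0.33222), nodes),
    cc = stats::setNames(c(0.55556, 0.50000, 0.52632, 0.45455, 0.32258,
                           0.34483, 0.43478, 0.43478, 0.45455, 0.33333,
                           0.34483), nodes),
    dist = dist,
    dd_quadratic_to_v1 = stats::setNames(
      c(0.95493, 0.95493, 0.31831, 0.03537, 0.07074, 0.23873, 0.95493,
        1.27324, 0.15915, 0.23873), paste0("v", 2:11)),
    q_v1 = stats::setNames(
      c(1.28632, 1.28091, 0.29435, 0.01820, 0.03414, 0.22470, 1.18495,
        1.49154, 0.14454, 0.19798), paste0("v", 2:11)),
    capacity = stats::setNames(
      c(0.61576, 0.53142, 0.38379, 0.36353, 0.34412, 0.33343, 0.28214,
        0.26374, 0.14042, 0.13362, 0.04395),
      c("v1", "v9", "v4", "v3", "v8", "v2", "v7", "v11", "v6", "v10", "v5")),
    ranking = c("v1", "v9", "v4", "v3", "v8", "v2", "v7", "v11", "v6",
                "v10", "v5"),
    i_v1 = 0.615762
  )
}
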