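# Agreement between a ranking and simulated spreading influence: Kendall
# rank correlation, tau-versus-alpha curves, top-k extraction, and the
# re-sorted infection-value curve.

#' Kendall rank correlation between two score vectors
#'
#' Counts concordant and discordant node pairs between two score vectors
#' aligned by node identity. Variant `"a"` is the plain formula
#' `tau = 2 (n_c - n_d) / (n (n - 1))`, which counts tied pairs in neither
#' `n_c` nor `n_d` and therefore deflates towards zero when ties are common.
#' Variant `"b"` (the default) applies the standard tie correction
#' `tau = (n_c - n_d) / sqrt((n_0 - n_1)(n_0 - n_2))`; when one vector is
#' entirely tied the correction's denominator vanishes and the statistic is
#' reported as 0 (no ordering information). Monte-Carlo influence scores tie
#' heavily at modest run counts, which is why `"b"` is the default.
#'
#' @param x,y Named numeric score vectors over the same node set (order may
#'   differ; values are aligned by name).
#' @param variant `"b"` (tie-corrected, default) or `"a"` (plain).
#' @return An object of class `tau_result`: a list with `tau`,
#'   `n_concordant`, `n_discordant`, `n`, `variant`.
#' @examples
#' kendall_tau(c(a = 1, b = 2, c = 3, d = 4),
#'             c(a = 1, b = 3, c = 2, d = 4), variant = "a")$tau  # 0.667
#' @export
kendall_tau <- function(x, y, variant = c("b", "a")) {
  variant <- match.arg(variant)
  if (is.null(names(x)) || is.null(names(y))) {
    stop("`x` and `y` must be named score vectors", call. = FALSE)
  }
  if (length(x) != length(y) || !setequal(names(x), names(y)) ||
      anyDuplicated(names(x)) || anyDuplicated(names(y))) {
    stop("`x` and `y` must be defined on the same node set", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  y <- y[names(x)]
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  prod_sign <- dx * dy
  upper <- upper.tri(prod_sign)
  nc <- sum(prod_sign[upper] > 0)
  nd <- sum(prod_sign[upper] < 0)
  n0 <- n * (n - 1) / 2
  tau <- if (variant == "a") {
    2 * (nc - nd) / (n * (n - 1))
  } else {
    tie_pairs <- function(v) {
      t <- table(v)
      sum(t * (t - 1) / 2)
    }
    denom <- sqrt((n0 - tie_pairs(x)) * (n0 - tie_pairs(y)))
    if (denom == 0) 0 else (nc - nd) / denom
  }
  structure(list(tau = tau, n_concordant = nc, n_discordant = nd,
                 n = n, variant = variant),
            class = "tau_result")
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf("Kendall tau-%s = %.4f  (n = %d, concordant %d, discordant %d)\n",
              x$variant, x$tau, x$n, x$n_concordant, x$n_discordant))
  invisible(x)
}

#' Kendall tau against SIR influence across infection probabilities
#'
#' For each infection probability in `alphas`, simulates single-seed SIR
#' influence ([sir_influence()]) and computes its Kendall tau against a
#' candidate score vector; the mean tau across probabilities summarizes a
#' method's overall agreement with spreading ground truth. The default
#' probability grid is ten values on `[0.01, 0.1]` in steps of `0.01`.
#'
#' @param net A network graph.
#' @param scores Candidate score vector (e.g. from [output_capacity()]).
#' @param alphas Infection probabilities to sweep.
#' @param beta Recovery probability (default 1).
#' @param runs SIR repetitions per node per probability.
#' @param seed Master RNG seed; each probability gets its own substream.
#' @param variant Kendall variant, see [kendall_tau()].
#' @return A list of class `tau_curve`: `table` (data frame with columns
#'   `alpha`, `tau`, `n_concordant`, `n_discordant`), `mean_tau`, `variant`,
#'   `runs`, `seed`.
#' @export
tau_curve <- function(net, scores, alphas = seq(0.01, 0.1, by = 0.01),
                      beta = 1, runs = 1000L, seed = 1L,
                      variant = c("b", "a")) {
  variant <- match.arg(variant)
  validate_network(net)
  rows <- lapply(seq_along(alphas), function(k) {
    cfg <- sir_config(alpha = alphas[k], beta = beta, runs = runs,
                      seed = substream_seed(seed, k))
    infl <- sir_influence(net, cfg)
    tr <- kendall_tau(scores, infl, variant = variant)
    data.frame(alpha = alphas[k], tau = tr$tau,
               n_concordant = tr$n_concordant,
               n_discordant = tr$n_discordant)
  })
  table <- do.call(rbind, rows)
  structure(list(table = table, mean_tau = mean(table$tau),
                 variant = variant, runs = as.integer(runs),
                 seed = as.integer(seed)),
            class = "tau_curve")
}

#' @export
print.tau_curve <- function(x, ...) {
  cat(sprintf("Kendall tau-%s vs SIR influence (%d runs, seed %d)\n",
              x$variant, x$runs, x$seed))
  print(x$table, row.names = FALSE)
  cat(sprintf("mean tau = %.4f\n", x$mean_tau))
  invisible(x)
}

#' Top-k nodes of a score vector
#'
#' The first `k` nodes of [rank_nodes()] (descending score, stable ties).
#'
#' @param scores A named numeric score vector.
#' @param k How many nodes, `0 <= k <= length(scores)`.
#' @return A character vector of `k` node labels.
#' @export
top_k <- function(scores, k) {
  if (k < 0 || k > length(scores)) {
    stop(sprintf("`k` must lie in [0, %d]", length(scores)), call. = FALSE)
  }
  utils::head(rank_nodes(scores), k)
}

#' Infection values re-sorted by a candidate ranking
#'
#' Lists ground-truth infection values in the order a candidate ranking
#' places the nodes. Perfect agreement yields a non-increasing sequence; any
#' ascent marks a node the candidate ranked above a stronger spreader. The
#' number of ascents is returned as a scalar summary.
#'
#' @param scores Candidate score vector.
#' @param infection_values Ground-truth score vector on the same node set.
#' @return A list: `values` (infection values in candidate rank order,
#'   named), `violations` (count of strict ascents).
#' @export
resort_curve <- function(scores, infection_values) {
  if (length(scores) != length(infection_values) ||
      !setequal(names(scores), names(infection_values))) {
    stop("score vectors must be defined on the same node set", call. = FALSE)
  }
  ord <- rank_nodes(scores)
  values <- infection_values[ord]
  violations <- if (length(values) < 2L) 0L else sum(diff(values) > 0)
  list(values = values, violations = as.integer(violations))
}
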