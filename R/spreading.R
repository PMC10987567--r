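# Stochastic spreading processes used as ground truth for node influence:
# a synchronous discrete-time network SIR model and the independent cascade
# (IC) model. With beta = 1 the SIR final-size distribution coincides with
# bond percolation at the infection probability, which is also what IC
# induces — the basis for the exact small-graph oracle in percolation.R.

# Neighbor index lists; the simulators run on integer indices.
adjacency_list <- function(net) {
  lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
}

#' SIR simulation settings
#'
#' @param alpha Per-contact infection probability per step, in `[0, 1]`.
#' @param beta Per-step recovery probability of an infective node, in
#'   `(0, 1]`. Default 1: an infective node gets exactly one infection round,
#'   which makes the final-size distribution identical to bond percolation at
#'   `alpha` (and to the IC model).
#' @param t_max Maximum number of steps; with `beta = 1` epidemics die out
#'   within the graph diameter, so the default 30 rarely truncates.
#' @param runs Monte-Carlo repetitions for averaged quantities.
#' @param seed Master RNG seed; per-node/per-run substreams are derived from
#'   it deterministically.
#' @return An object of class `sir_config`.
#' @export
sir_config <- function(alpha, beta = 1, t_max = 30L, runs = 1000L, seed = 1L) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(beta) || beta <= 0 || beta > 1) {
    stop("`beta` must lie in (0, 1]", call. = FALSE)
  }
  if (t_max < 1L) stop("`t_max` must be >= 1", call. = FALSE)
  if (runs < 1L) stop("`runs` must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, t_max = as.integer(t_max),
                 runs = as.integer(runs), seed = as.integer(seed)),
            class = "sir_config")
}

resolve_seeds <- function(net, seeds) {
  if (length(seeds) == 0L) stop("seed set must be non-empty", call. = FALSE)
  idx <- if (is.character(seeds)) {
    match(seeds, igraph::V(net)$name)
  } else {
    as.integer(seeds)
  }
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > igraph::gorder(net))) {
    stop("seed nodes must belong to the network", call. = FALSE)
  }
  unique(idx)
}

# Core synchronous SIR step loop on an adjacency list. States: 0 = S, 1 = I,
# 2 = R. Each step every infective node exposes each susceptible neighbor
# with probability alpha (a susceptible with k infective neighbors is
# infected with probability 1 - (1 - alpha)^k, drawn as one Bernoulli —
# distributionally identical to independent per-contact draws), then each
# infective node recovers with probability beta. Uses the current RNG state.
sir_engine <- function(adj, n, seed_idx, alpha, beta, t_max) {
  state <- integer(n)
  state[seed_idx] <- 1L
  ever <- state == 1L
  trajectory <- integer(0)
  infective <- seed_idx
  steps <- 0L
  while (length(infective) > 0L && steps < t_max) {
    steps <- steps + 1L
    exposures <- tabulate(unlist(adj[infective], use.names = FALSE), nbins = n)
    cand <- which(exposures > 0L & state == 0L)
    newly <- cand[stats::runif(length(cand)) < 1 - (1 - alpha)^exposures[cand]]
    recovering <- infective[stats::runif(length(infective)) < beta]
    state[recovering] <- 2L
    state[newly] <- 1L
    ever[newly] <- TRUE
    infective <- c(infective[!infective %in% recovering], newly)
    trajectory[steps] <- length(infective)
  }
  list(ever = ever, trajectory = trajectory, steps = steps)
}

#' Run a single SIR epidemic
#'
#' Synchronous discrete-time SIR on the network: per step, every infective
#' node independently infects each susceptible neighbor with probability
#' `alpha`, then recovers with probability `beta` (infection before recovery,
#' so with `beta = 1` every infective gets exactly one round). Stops when no
#' infectives remain or `t_max` is reached. Consumes the current RNG stream;
#' call `set.seed()` first for a reproducible single run (the averaged
#' wrappers seed themselves).
#'
#' @param net A network graph.
#' @param seeds Initial infective nodes (labels or indices), non-empty.
#' @param config An [sir_config()].
#' @return A list: `infected` (number of non-seed nodes ever infected — the
#'   infection value), `trajectory` (currently-infective count after each
#'   step), `steps`.
#' @export
sir_run <- function(net, seeds, config) {
  validate_network(net)
  stopifnot(inherits(config, "sir_config"))
  idx <- resolve_seeds(net, seeds)
  n <- igraph::gorder(net)
  res <- sir_engine(adjacency_list(net), n, idx,
                    config$alpha, config$beta, config$t_max)
  list(infected = sum(res$ever) - length(idx),
       trajectory = res$trajectory,
       steps = res$steps)
}

#' Single-seed SIR spreading influence of every node
#'
#' For each node, the mean infection value (non-seed nodes ever infected)
#' over `config$runs` independent epidemics started from that node alone.
#' This is the ground-truth influence score that rankings are benchmarked
#' against. Per-node RNG substreams are derived from `config$seed`, so
#' results are reproducible and independent of node processing order.
#'
#' @param net A network graph.
#' @param config An [sir_config()].
#' @return A named numeric score vector of mean infection values.
#' @export
sir_influence <- function(net, config) {
  validate_network(net)
  stopifnot(inherits(config, "sir_config"))
  adj <- adjacency_list(net)
  n <- igraph::gorder(net)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    scores[i] <- with_local_seed(substream_seed(config$seed, i), {
      total <- 0
      for (r in seq_len(config$runs)) {
        res <- sir_engine(adj, n, i, config$alpha, config$beta, config$t_max)
        total <- total + sum(res$ever) - 1L
      }
      total / config$runs
    })
  }
  stats::setNames(scores, igraph::V(net)$name)
}

#' Multi-seed SIR spread summary
#'
#' Repeats [sir_run()] from a fixed seed set and averages: the mean final
#' infection value and the mean per-step infective count (trajectories
#' zero-padded to the longest run).
#'
#' @inheritParams sir_run
#' @return A `spread_result` list: `final_counts` (per run), `mean_final`,
#'   `trajectory_mean`, `runs`, `seed`.
#' @export
sir_spread <- function(net, seeds, config) {
  validate_network(net)
  stopifnot(inherits(config, "sir_config"))
  idx <- resolve_seeds(net, seeds)
  adj <- adjacency_list(net)
  n <- igraph::gorder(net)
  with_local_seed(substream_seed(config$seed, 0L), {
    finals <- numeric(config$runs)
    trajs <- vector("list", config$runs)
    for (r in seq_len(config$runs)) {
      res <- sir_engine(adj, n, idx, config$alpha, config$beta, config$t_max)
      finals[r] <- sum(res$ever) - length(idx)
      trajs[[r]] <- res$trajectory
    }
    tmax <- max(lengths(trajs), 1L)
    traj_mat <- vapply(trajs, function(tr) c(tr, rep(0L, tmax - length(tr))),
                       numeric(tmax))
    structure(list(final_counts = finals,
                   mean_final = mean(finals),
                   trajectory_mean = rowMeans(matrix(traj_mat, nrow = tmax)),
                   runs = config$runs, seed = config$seed),
              class = "spread_result")
  })
}

#' @export
print.spread_result <- function(x, ...) {
  cat("Spread result over", x$runs, "runs (seed", x$seed, ")\n")
  cat("  mean final size:", format(x$mean_final), "\n")
  cat("  trajectory mean:", paste(format(round(x$trajectory_mean, 2)),
                                  collapse = " "), "\n")
  invisible(x)
}

#' Run a single independent cascade
#'
#' Newly activated nodes get exactly one attempt, with probability `p`, to
#' activate each inactive neighbor; the cascade iterates until no activations
#' occur. Consumes the current RNG stream.
#'
#' @param net A network graph.
#' @param seeds Initially active nodes (labels or indices), non-empty.
#' @param p Activation probability, in `[0, 1]`.
#' @param include_seeds Count the seeds in the activated total (default
#'   `TRUE`, matching "number of activated nodes").
#' @return A list: `activated` (total count), `trajectory` (newly activated
#'   per step), `steps`.
#' @export
ic_run <- function(net, seeds, p, include_seeds = TRUE) {
  validate_network(net)
  if (!is.numeric(p) || p < 0 || p > 1) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  idx <- resolve_seeds(net, seeds)
  adj <- adjacency_list(net)
  n <- igraph::gorder(net)
  active <- logical(n)
  active[idx] <- TRUE
  frontier <- idx
  trajectory <- integer(0)
  steps <- 0L
  while (length(frontier) > 0L) {
    steps <- steps + 1L
    attempts <- tabulate(unlist(adj[frontier], use.names = FALSE), nbins = n)
    cand <- which(attempts > 0L & !active)
    newly <- cand[stats::runif(length(cand)) < 1 - (1 - p)^attempts[cand]]
    active[newly] <- TRUE
    frontier <- newly
    trajectory[steps] <- length(newly)
  }
  total <- sum(active)
  list(activated = if (include_seeds) total else total - length(idx),
       trajectory = trajectory, steps = steps)
}

#' Averaged independent-cascade spread
#'
#' Mean activated count over `runs` independent cascades from a fixed seed
#' set, with a reproducible RNG substream per call.
#'
#' @inheritParams ic_run
#' @param runs Monte-Carlo repetitions.
#' @param seed Master RNG seed.
#' @return A `spread_result` list as in [sir_spread()] (trajectories are
#'   newly-activated counts per step).
#' @export
ic_spread <- function(net, seeds, p, runs = 1000L, seed = 1L,
                      include_seeds = TRUE) {
  validate_network(net)
  if (runs < 1L) stop("`runs` must be >= 1", call. = FALSE)
  with_local_seed(substream_seed(seed, 0L), {
    finals <- numeric(runs)
    trajs <- vector("list", runs)
    for (r in seq_len(runs)) {
      res <- ic_run(net, seeds, p, include_seeds = include_seeds)
      finals[r] <- res$activated
      trajs[[r]] <- res$trajectory
    }
    tmax <- max(lengths(trajs), 1L)
    traj_mat <- vapply(trajs, function(tr) c(tr, rep(0L, tmax - length(tr))),
                       numeric(tmax))
    structure(list(final_counts = finals,
                   mean_final = mean(finals),
                   trajectory_mean = rowMeans(matrix(traj_mat, nrow = tmax)),
                   runs = as.integer(runs), seed = as.integer(seed)),
              class = "spread_result")
  })
}
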