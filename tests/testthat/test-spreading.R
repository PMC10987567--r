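fixture <- example_network()

path3 <- local({
  f <- tempfile()
  writeLines(c("a b", "b c"), f)
  read_edge_list(f)
})

test_that("deterministic SIR limits: alpha 0 spreads nothing, alpha 1 percolates fully", {
  set.seed(1)
  r0 <- sir_run(fixture, "v1", sir_config(alpha = 0, beta = 1))
  expect_equal(r0$infected, 0)

  # alpha = beta = 1: BFS percolation, finished within the seed's eccentricity
  set.seed(1)
  r1 <- sir_run(fixture, "v1", sir_config(alpha = 1, beta = 1))
  expect_equal(r1$infected, 10)
  expect_true(all(r1$trajectory[1:3] > 0))
  expect_equal(sum(r1$trajectory[1:3]), 10)  # everyone within 3 hops of v1
  expect_lte(r1$steps, 30)

  expect_error(sir_run(fixture, character(0), sir_config(0.5)), "non-empty")
  expect_error(sir_run(fixture, "nope", sir_config(0.5)), "belong")
})

test_that("SIR means on the 3-path match exact branch enumeration", {
  # alpha = 0.5, beta = 1. Seed b: each leaf infected independently, E = 1.
  # Seed a: E = P(b) + P(b)P(c|b) = 0.5 + 0.25 = 0.75.
  cfg <- sir_config(alpha = 0.5, beta = 1, runs = 4000, seed = 11)
  runs_mean <- function(seeds) {
    with_seed_vals <- numeric(cfg$runs)
    set.seed(101)
    for (r in seq_len(cfg$runs)) {
      with_seed_vals[r] <- sir_run(path3, seeds, cfg)$infected
    }
    with_seed_vals
  }
  vb <- runs_mean("b")
  expect_lt(abs(mean(vb) - 1), 3 * mc_se(vb) + 1e-9)
  va <- runs_mean("a")
  expect_lt(abs(mean(va) - 0.75), 3 * mc_se(va) + 1e-9)
})

test_that("sir_influence is exact at full percolation and symmetric under symmetry", {
  infl <- sir_influence(fixture, sir_config(alpha = 1, beta = 1, runs = 3))
  expect_equal(unname(infl), rep(10, 11))

  f <- tempfile()
  writeLines(c("a b", "b c", "c a", "x y", "y z", "z x"), f)
  two_tri <- read_edge_list(f)
  infl2 <- sir_influence(two_tri, sir_config(alpha = 1, beta = 1, runs = 2))
  expect_true(all(infl2 == 2))

  # stronger spreader ranks above the leaf, and reruns are bit-identical
  cfg <- sir_config(alpha = 0.04, beta = 1, runs = 2000, seed = 5)
  s1 <- sir_influence(fixture, cfg)
  s2 <- sir_influence(fixture, cfg)
  expect_identical(s1, s2)
  expect_gt(s1["v1"], s1["v5"])
})

test_that("IC limits and the 3-path closed form hold", {
  set.seed(2)
  expect_equal(ic_run(fixture, "v3", 1)$activated, 11)
  set.seed(2)
  expect_equal(ic_run(fixture, c("v1", "v9"), 0)$activated, 2)
  set.seed(2)
  expect_equal(ic_run(fixture, "v3", 0, include_seeds = FALSE)$activated, 0)

  # seed a, p = 0.5: E[total] = 1 + 0.5 + 0.25 = 1.75
  set.seed(31)
  vals <- replicate(4000, ic_run(path3, "a", 0.5)$activated)
  expect_lt(abs(mean(vals) - 1.75), 3 * mc_se(vals) + 1e-9)

  sp <- ic_spread(fixture, "v2", 1, runs = 50, seed = 1)
  expect_equal(sp$mean_final, 11)
  expect_equal(stats::sd(sp$final_counts), 0)
  sp_all <- ic_spread(fixture, paste0("v", 1:11), 0.3, runs = 20, seed = 1)
  expect_equal(sp_all$mean_final, 11)
})

test_that("SIR with beta = 1 and IC share the bond-percolation final size", {
  p <- 0.3
  exact <- exact_percolation_spread(fixture, c("v1", "v9"), p) - 2
  sir <- sir_spread(fixture, c("v1", "v9"),
                    sir_config(alpha = p, beta = 1, runs = 4000, seed = 21))
  ic <- ic_spread(fixture, c("v1", "v9"), p, runs = 4000, seed = 22,
                  include_seeds = FALSE)
  expect_lt(abs(sir$mean_final - exact), 3 * mc_se(sir$final_counts))
  expect_lt(abs(ic$mean_final - exact), 3 * mc_se(ic$final_counts))
  # and the two simulators agree with each other
  se <- sqrt(mc_se(sir$final_counts)^2 + mc_se(ic$final_counts)^2)
  expect_lt(abs(sir$mean_final - ic$mean_final), 3 * se)
})

test_that("mean final size grows with the infection probability", {
  means <- vapply(c(0.1, 0.3, 0.6, 0.9), function(a) {
    sir_spread(fixture, "v1",
               sir_config(alpha = a, beta = 1, runs = 1500, seed = 77))$mean_final
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("final size never exceeds the seed's component", {
  f <- tempfile()
  writeLines(c("a b", "b c", "x y"), f)
  g <- read_edge_list(f)
  set.seed(9)
  for (r in 1:50) {
    expect_lte(sir_run(g, "x", sir_config(alpha = 1, beta = 0.3))$infected, 1)
    expect_lte(ic_run(g, "a", 0.9)$activated, 3)
  }
})

test_that("the exact percolation oracle matches closed forms on tiny graphs", {
  # path a-b-c: infl(a) = p + p^2, infl(b) = 2p
  for (p in c(0.2, 0.5, 0.8)) {
    infl <- exact_percolation_influence(path3, p)
    expect_equal(unname(infl["a"]), p + p^2, tolerance = 1e-12)
    expect_equal(unname(infl["b"]), 2 * p, tolerance = 1e-12)
    expect_equal(exact_percolation_spread(path3, "a", p), 1 + p + p^2,
                 tolerance = 1e-12)
  }
  # degenerate probabilities
  expect_equal(unname(exact_percolation_influence(fixture, 0)), rep(0, 11))
  expect_equal(unname(exact_percolation_influence(fixture, 1)), rep(10, 11))
  big <- generate_er(30, 0.3, seed = 1)
  expect_error(exact_percolation_influence(big, 0.5), "exceeds")
})
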