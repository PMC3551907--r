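test_that("degenerate transmission probabilities behave exactly", {
  p4 <- path_graph(c("a", "b", "c", "d"))
  # beta = 0: only the seed is ever infected
  tr0 <- simulate_spread(p4, "a", beta = 0, max_steps = 20, rng_seed = 1)
  expect_equal(sum(is.finite(tr0$infection_time)), 1)
  # beta = 1: deterministic BFS wavefront, node at hop h infected at h + 1
  tr1 <- simulate_spread(p4, "a", beta = 1, max_steps = 20)
  expect_equal(unname(tr1$infection_time), c(1, 2, 3, 4))
})

test_that("spread runs are reproducible and structurally consistent", {
  set.seed(81)
  g <- giant_component(named_gnp(60, 0.06))
  sn <- igraph::V(g)$name[1]
  t1 <- simulate_spread(g, sn, 0.35, 50, rng_seed = 9)
  t2 <- simulate_spread(g, sn, 0.35, 50, rng_seed = 9)
  expect_identical(t1$infection_time, t2$infection_time)
  expect_identical(t1$states_by_step, t2$states_by_step)

  for (k in 1:5) {
    tr <- simulate_spread(g, sn, 0.3, 50, rng_seed = 100 + k)
    it <- tr$infection_time
    expect_equal(unname(it[tr$seed_node]), 1)
    # every later infection had an infected neighbour at an earlier step
    for (v in names(it)[is.finite(it) & it > 1]) {
      nb <- igraph::neighbors(g, v)$name
      expect_true(any(it[nb] < it[v]))
    }
    # states are monotone: 0 before infection, 1 from it onward
    counts <- vapply(seq_len(tr$n_steps), function(s) count_percolated(tr, s),
                     integer(1))
    expect_true(all(diff(counts) >= 0))
    expect_equal(count_percolated(tr, 1), 1L)
  }
})

test_that("beta = 1 infection times equal 1 + hop distance from the seed", {
  set.seed(82)
  for (k in 1:5) {
    g <- named_gnp(sample(10:40, 1), 0.12)
    sn <- igraph::V(g)$name[1]
    tr <- simulate_spread(g, sn, 1, max_steps = 100)
    st <- percolation_states(g, stats::setNames(
      as.numeric(igraph::V(g)$name == sn), igraph::V(g)$name))
    h <- as.numeric(hop_distance(g, st))
    expect_equal(unname(tr$infection_time), unname(1 + h))
  }
})

test_that("immune nodes block and never acquire infection", {
  p4 <- path_graph(c("a", "b", "c", "d"))
  tr <- simulate_spread(p4, "a", beta = 1, max_steps = 20, immune = "b")
  expect_equal(unname(tr$infection_time), c(1, Inf, Inf, Inf))
  expect_true(all(tr$states_by_step[, "b"] == 0))
  expect_error(simulate_spread(p4, "a", 0.5, immune = "a"), "immune")
})

test_that("star seeding matches the binomial expectation at step two", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", paste0("l", 1:4))
  set.seed(83)
  counts <- vapply(1:3000, function(k) {
    count_percolated(simulate_spread(star, "c", 0.5, max_steps = 2), 2)
  }, integer(1))
  se <- sqrt(4 * 0.5 * 0.5 / 3000)
  expect_lt(abs(mean(counts) - 3.0), 3 * se)
})

test_that("the PC/BC ratio hits its closed-form anchors", {
  g <- connected_gnp(25, 0.2)
  expect_equal(pc_bc_ratio(g, percolation_states(g, 1)), 1, tolerance = 1e-12)
  expect_equal(pc_bc_ratio(g, percolation_states(g, 0)), 0)
  # averaging the single-source scenarios recovers ratio 1 as well
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  tot <- numeric(n)
  for (a in seq_len(n)) {
    x <- stats::setNames(numeric(n), nodes); x[a] <- 1
    tot <- tot + scores_of(percolation_centrality(g, percolation_states(g, x)))
  }
  bc <- scores_of(betweenness_centrality(g))
  idx <- bc > 0
  expect_equal(sum(tot[idx] / (n - 1)) / sum(bc[idx]), 1, tolerance = 1e-12)
  # undefined when no node has positive betweenness
  empty <- igraph::make_graph(c("a", "b"), directed = FALSE)
  expect_warning(r <- pc_bc_ratio(empty, percolation_states(empty, 1)), "undefined")
  expect_true(is.na(r))
})
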