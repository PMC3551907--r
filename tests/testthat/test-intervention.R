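test_that("immunization ranking follows each strategy's ordering rules", {
  p4 <- path_graph(c("a", "b", "c", "d"))
  st <- percolation_states(p4, c(a = 1, b = 0, c = 0, d = 0))
  # ring vaccination: ascending hop distance from the percolated set
  expect_equal(rank_for_immunization(p4, st, "hop"), c("b", "c", "d"))
  # everybody percolated: nothing to immunize
  expect_equal(rank_for_immunization(p4, percolation_states(p4, 1), "pc"),
               character(0))
  # pc strategy equals a full sort of PC restricted to candidates
  set.seed(91)
  g <- giant_component(named_gnp(40, 0.1))
  x <- stats::setNames(as.numeric(seq_len(igraph::vcount(g)) <= 4),
                       igraph::V(g)$name)
  stg <- percolation_states(g, x)
  got <- rank_for_immunization(g, stg, "pc")
  pc <- as.numeric(percolation_centrality(g, stg))
  cand <- which(x < 1)
  expect_equal(got, igraph::V(g)$name[cand[order(-pc[cand], cand)]])
  # bc strategy ignores states in the scores but still excludes percolated
  gotb <- rank_for_immunization(g, stg, "bc")
  expect_false(any(igraph::V(g)$name[x >= 1] %in% gotb))
})

test_that("a zero-size intervention reproduces the plain trajectory seed-for-seed", {
  sf <- giant_component(generate_scale_free(250, seed = 17))
  sn <- igraph::V(sf)$name[1]
  ri <- run_intervention(sf, rho = 5, i_percent = 0, strategy = "bc",
                         beta = 0.4, seed_node = sn, replicates = 2,
                         rng_seed = 5, keep_traces = TRUE)
  for (k in 1:2) {
    seed_k <- attr(ri, "replicate_seeds")[k]
    t_end <- ri$t_intervention[k] + ri$time[k]
    tr <- simulate_spread(sf, sn, 0.4, max_steps = t_end, rng_seed = seed_k)
    got <- attr(ri, "traces")[[k]]$infection_time
    got[got > t_end] <- Inf
    expect_identical(unname(got), unname(tr$infection_time))
  }
})

test_that("immunized nodes are absorbing-susceptible in every replicate", {
  sf <- giant_component(generate_scale_free(150, seed = 23))
  for (st in c("pc", "bc", "hop")) {
    r <- run_intervention(sf, rho = 10, i_percent = 15, strategy = st,
                          beta = 0.5, replicates = 3, rng_seed = 7,
                          keep_traces = TRUE)
    for (trc in attr(r, "traces")) {
      expect_gt(length(trc$immune), 0)
      expect_true(all(is.infinite(trc$infection_time[trc$immune])))
    }
  }
})

test_that("a blocked spread is censored at exactly the cutoff", {
  # beta = 1 path seeded at one end; immunizing the single node adjacent
  # to the infected prefix cuts the graph
  p6 <- path_graph(letters[1:6])
  r <- run_intervention(p6, rho = 16, i_percent = 17, strategy = "hop",
                        beta = 1, seed_node = "a", replicates = 1,
                        rng_seed = 1, keep_traces = TRUE)
  expect_true(r$censored)
  expect_equal(r$time, 30)
  expect_identical(attr(r, "traces")[[1]]$immune, "b")
  expect_equal(sum(is.finite(attr(r, "traces")[[1]]$infection_time)), 1)
})

test_that("the saturation grid aggregates cells, ties, and pairing correctly", {
  p5 <- path_graph(letters[1:5])
  tab <- experiment_grid(p5, rho = 20, i_percent = 0, strategies = "bc",
                         beta = 1, seed_node = "a", replicates = 1, rng_seed = 2)
  expect_s3_class(tab, "saturation_table")
  expect_equal(nrow(tab$cells), 1)
  expect_equal(tab$cells$n, 1)

  # deterministic spread: i = 0 strategies tie, and the winner map says so
  tab2 <- experiment_grid(p5, rho = 20, i_percent = 0,
                          strategies = c("bc", "hop"), beta = 1,
                          seed_node = "a", replicates = 2, rng_seed = 2)
  expect_equal(tab2$winners$winner, "tie:bc+hop")

  # monotonicity in i under paired seeds with deterministic spread
  sf <- giant_component(generate_scale_free(150, seed = 29))
  tab3 <- experiment_grid(sf, rho = 10, i_percent = c(0, 5, 20),
                          strategies = "hop", beta = 1, replicates = 4,
                          rng_seed = 11)
  m <- tab3$cells[order(tab3$cells$i_percent), "mean_time"]
  expect_true(all(diff(m) >= 0))
})

test_that("grid runs reproduce under a fixed master seed", {
  sf <- giant_component(generate_scale_free(100, seed = 31))
  a <- experiment_grid(sf, rho = c(5, 15), i_percent = 5,
                       strategies = c("bc", "hop"), beta = 0.5,
                       replicates = 3, rng_seed = 42)
  b <- experiment_grid(sf, rho = c(5, 15), i_percent = 5,
                       strategies = c("bc", "hop"), beta = 0.5,
                       replicates = 3, rng_seed = 42)
  expect_identical(a$cells, b$cells)
  expect_identical(a$winners, b$winners)
})
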