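test_that("normalized betweenness matches hand-derived values", {
  p3 <- path_graph(c("a", "b", "c"))
  expect_equal(scores_of(betweenness_centrality(p3)), c(0, 1, 0))

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", "l1", "l2", "l3")
  expect_equal((betweenness_centrality(star))[["c"]], 1)

  # path of five: 8 ordered pairs cross the midpoint, (N-1)(N-2) = 12
  p5 <- path_graph(letters[1:5])
  expect_equal((betweenness_centrality(p5))[["c"]], 8 / 12)

  # fewer than three nodes: no interior triples
  expect_equal(scores_of(betweenness_centrality(path_graph(c("a", "b")))), c(0, 0))
})

test_that("betweenness agrees with igraph on random graphs, both modes", {
  set.seed(21)
  for (k in 1:10) {
    n <- sample(5:25, 1)
    g <- named_gnp(n, runif(1, 0.1, 0.5))
    raw <- as.numeric(betweenness_centrality(g)) * (n - 1) * (n - 2)
    expect_equal(raw, 2 * unname(igraph::betweenness(g)), tolerance = 1e-12)
    gd <- igraph::sample_gnp(n, 0.3, directed = TRUE)
    igraph::V(gd)$name <- paste0("d", seq_len(n))
    rawd <- as.numeric(betweenness_centrality(gd)) * (n - 1) * (n - 2)
    expect_equal(rawd, unname(igraph::betweenness(gd)), tolerance = 1e-12)
  }
})

test_that("percolation centrality worked examples and degenerate conventions", {
  p3 <- path_graph(c("a", "b", "c"))
  # nobody percolated: trivially zero
  expect_equal(scores_of(percolation_centrality(p3, percolation_states(p3, 0))),
               c(0, 0, 0))
  # everyone percolated: reduces to betweenness
  expect_equal(scores_of(percolation_centrality(p3, percolation_states(p3, 1))),
               c(0, 1, 0))
  # star with one percolated leaf: all spread potential crosses the hub
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", "l1", "l2", "l3")
  st <- percolation_states(star, c(c = 0, l1 = 1, l2 = 0, l3 = 0))
  expect_equal((percolation_centrality(star, st))[["c"]], 1)
  # only v percolated: no valid source for v, PC(v) = 0 by convention
  st2 <- percolation_states(star, c(c = 1, l1 = 0, l2 = 0, l3 = 0))
  expect_equal((percolation_centrality(star, st2))[["c"]], 0)
})

test_that("uniform states reduce percolation centrality to betweenness", {
  set.seed(31)
  for (k in 1:20) {
    g <- connected_gnp(sample(4:30, 1), runif(1, 0.15, 0.5))
    bc <- scores_of(betweenness_centrality(g))
    for (alpha in c(0.1, 1.0)) {
      pc <- scores_of(percolation_centrality(g, percolation_states(g, alpha)))
      expect_lt(max(abs(pc - bc)), 1e-12)
    }
  }
})

test_that("single-source scenarios average to betweenness, independent of level", {
  set.seed(32)
  for (k in 1:8) {
    g <- named_gnp(sample(5:20, 1), runif(1, 0.15, 0.5))
    n <- igraph::vcount(g)
    nodes <- igraph::V(g)$name
    bc <- scores_of(betweenness_centrality(g))
    for (alpha in c(0.3, 1.0)) {
      tot <- numeric(n)
      for (a in seq_len(n)) {
        x <- stats::setNames(numeric(n), nodes)
        x[a] <- alpha
        tot <- tot + scores_of(percolation_centrality(g, percolation_states(g, x)))
      }
      expect_lt(max(abs(tot / (n - 1) - bc)), 1e-12)
    }
    # scale invariance: a single source's PC does not depend on its level
    x1 <- stats::setNames(numeric(n), nodes); x1[1] <- 0.05
    x2 <- stats::setNames(numeric(n), nodes); x2[1] <- 1.0
    expect_lt(max(abs(scores_of(percolation_centrality(g, percolation_states(g, x1))) -
                      scores_of(percolation_centrality(g, percolation_states(g, x2))))),
              1e-12)
  }
})

test_that("weight matrix columns are normalized source distributions", {
  g <- path_graph(c("a", "b", "c"))
  W <- weight_matrix(percolation_states(g, c(a = 1, b = 0, c = 0)))
  expect_equal(unname(W[c("a", "c"), "b"]), c(1, 0))
  # uniform positive states: every off-diagonal entry 1/(N-1)
  W2 <- weight_matrix(percolation_states(g, 0.4))
  expect_true(all(abs(W2[row(W2) != col(W2)] - 0.5) < 1e-15))
  expect_true(all(diag(W2) == 0))
  # all-zero states give the zero matrix
  expect_true(all(weight_matrix(percolation_states(g, 0)) == 0))
  set.seed(33)
  for (k in 1:10) {
    g <- named_gnp(sample(3:12, 1), 0.3)
    W <- weight_matrix(random_states(g))
    x <- 1  # column sums over s != v must be 1 where S - x_v > 0
    cs <- colSums(W)
    expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
  }
})

test_that("ramp pair weights vanish unless the source is more percolated", {
  g <- path_graph(c("a", "b", "c"))
  st <- percolation_states(g, c(a = 1, b = 0, c = 0))
  W <- pair_weight_matrix(st)
  expect_equal(sum(W), 1)
  expect_equal(unname(W["a", "b"]), 0.5)
  expect_equal(unname(W["b", "a"]), 0)
  # uniform states: all weights zero, and PC_st all zero at any level
  for (alpha in c(0, 0.5, 1)) {
    stu <- percolation_states(g, alpha)
    expect_true(all(pair_weight_matrix(stu) == 0))
    expect_equal(scores_of(percolation_centrality_st(g, stu)), c(0, 0, 0))
  }
  set.seed(34)
  for (k in 1:10) {
    g <- named_gnp(sample(3:12, 1), 0.4)
    st <- random_states(g)
    W <- pair_weight_matrix(st)
    x <- as.numeric(st)
    expect_true(all(W[outer(x, x, `<=`)] == 0))
    if (sum(W) > 0) expect_equal(sum(W), 1, tolerance = 1e-12)
  }
})

test_that("source-target percolation centrality matches its worked example", {
  g <- path_graph(c("a", "b", "c"))
  st <- percolation_states(g, c(a = 1, b = 0, c = 0))
  expect_equal(scores_of(percolation_centrality_st(g, st)), c(0, 0.5, 0))
})

test_that("fast measures match the brute-force oracles on random instances", {
  set.seed(35)
  for (k in 1:30) {
    g <- named_gnp(sample(4:12, 1), runif(1, 0.2, 0.6))
    st <- random_states(g)
    expect_lt(max(abs(scores_of(betweenness_centrality(g)) -
                      scores_of(oracle_betweenness(g)))), 1e-10)
    expect_lt(max(abs(scores_of(percolation_centrality(g, st)) -
                      scores_of(oracle_percolation_centrality(g, st, "source")))), 1e-10)
    expect_lt(max(abs(scores_of(percolation_centrality_st(g, st)) -
                      scores_of(oracle_percolation_centrality(g, st, "source-target")))), 1e-10)
  }
})

test_that("scores stay in range and respect the zero-betweenness bound", {
  set.seed(36)
  for (k in 1:10) {
    g <- named_gnp(sample(4:20, 1), runif(1, 0.1, 0.5))
    st <- random_states(g)
    bc <- scores_of(betweenness_centrality(g))
    pc <- scores_of(percolation_centrality(g, st))
    pcst <- scores_of(percolation_centrality_st(g, st))
    expect_true(all(bc >= 0 & bc <= 1))
    expect_true(all(pc >= 0 & pc <= 1 + 1e-12))
    expect_true(all(pcst >= 0 & pcst <= 1 + 1e-12))
    expect_true(all(pc[bc == 0] == 0))
  }
})
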