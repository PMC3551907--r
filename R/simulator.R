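# Discrete-time susceptible-infected (SI) contagion spread.
#
# Synchronous updates with one-step latency: at every step each
# susceptible, non-immune node is exposed through each edge to a
# currently infected neighbour by an independent Bernoulli(beta) trial,
# and becomes infected at the next step if any trial succeeds (so a node
# with k infected neighbours is infected with probability 1-(1-beta)^k).
# Contagion spreads through links only; newly infected nodes transmit
# from the following step; infected nodes never recover.  States in the
# simulator are binary; partial states are the business of the centrality
# functions.

# One synchronous update.  tA is the transposed adjacency matrix (so
# tA %*% infected counts infected in-neighbours); returns the indices of
# newly infected nodes.  Consumes one runif() draw per exposed candidate.
#' @noRd
si_step <- function(tA, infected, immune, beta) {
  k <- as.numeric(tA %*% infected)
  cand <- which(!infected & !immune & k > 0)
  if (!length(cand)) return(integer(0))
  p <- 1 - (1 - beta)^k[cand]
  cand[stats::runif(length(cand)) < p]
}

#' @noRd
spread_matrix <- function(graph) {
  Matrix::t(igraph::as_adjacency_matrix(graph, sparse = TRUE))
}

#' Simulate SI contagion spread
#'
#' Runs the discrete-time susceptible-infected model from a single fully
#' percolated seed node (infection time 1).  The run stops at `max_steps`
#' or as soon as no susceptible node has an infected neighbour (nothing
#' further can happen).  With `beta = 1` the infection front is exactly
#' the BFS wavefront: a node at hop distance \eqn{h} from the seed is
#' infected at step \eqn{h + 1}; with `beta = 0` only the seed is ever
#' infected.
#'
#' @param graph A simple `igraph` graph.
#' @param seed_node Node name where the contagion starts (percolated at
#'   step 1).  Must not be immune.
#' @param beta Per-contact, per-timestep transmission probability in
#'   \eqn{[0,1]}.
#' @param max_steps Maximum number of timesteps (including step 1).
#' @param immune Character vector of immunized nodes: state permanently
#'   0, never infected, never transmit.
#' @param rng_seed Optional integer seed; fixing it makes the run
#'   reproducible (the caller's RNG state is preserved).
#' @return A `spread_trace`: list with `infection_time` (named, `Inf` if
#'   never infected), `states_by_step` (steps x nodes binary matrix),
#'   `immune`, `beta`, `seed_node`, `n_steps`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - d)
#' tr <- simulate_spread(g, "a", beta = 1, max_steps = 10)
#' tr$infection_time  # 1, 2, 3, 4
#' @export
simulate_spread <- function(graph, seed_node, beta, max_steps = 100L,
                            immune = character(), rng_seed = NULL) {
  graph <- check_graph(graph)
  assert_scalar_number(beta, "beta", lo = 0, hi = 1)
  nodes <- node_names(graph)
  if (!seed_node %in% nodes) stop("seed_node is not in the graph", call. = FALSE)
  if (seed_node %in% immune) stop("seed_node must not be immune", call. = FALSE)
  if (!all(immune %in% nodes)) stop("immune nodes must be in the graph", call. = FALSE)
  max_steps <- as.integer(max_steps)
  if (is.na(max_steps) || max_steps < 1L) stop("max_steps must be >= 1", call. = FALSE)
  run <- function() {
    tA <- spread_matrix(graph)
    n <- length(nodes)
    immune_mask <- nodes %in% immune
    infected <- logical(n)
    infected[match(seed_node, nodes)] <- TRUE
    inf_time <- rep(Inf, n)
    inf_time[infected] <- 1
    states <- matrix(0, max_steps, n, dimnames = list(NULL, nodes))
    states[1L, ] <- as.numeric(infected)
    steps <- 1L
    while (steps < max_steps) {
      if (!any(!infected & !immune_mask & as.numeric(tA %*% infected) > 0)) break
      new <- si_step(tA, infected, immune_mask, beta)
      steps <- steps + 1L
      infected[new] <- TRUE
      inf_time[new] <- steps
      states[steps, ] <- as.numeric(infected)
    }
    structure(list(infection_time = stats::setNames(inf_time, nodes),
                   states_by_step = states[seq_len(steps), , drop = FALSE],
                   immune = nodes[immune_mask],
                   beta = beta, seed_node = seed_node, n_steps = steps),
              class = "spread_trace")
  }
  if (is.null(rng_seed)) run() else withr::with_seed(as.integer(rng_seed), run())
}

#' @exportS3Method base::print
print.spread_trace <- function(x, ...) {
  cat(sprintf("<spread_trace> seed %s, beta %.3g: %d/%d infected in %d steps (%d immune)\n",
              x$seed_node, x$beta, sum(is.finite(x$infection_time)),
              length(x$infection_time), x$n_steps, length(x$immune)))
  invisible(x)
}

#' Number of percolated nodes at a timestep
#'
#' @param trace A `spread_trace` from [simulate_spread()].
#' @param t Timestep, `1 <= t <= trace$n_steps`.
#' @return Integer count of nodes with state 1 at step `t`
#'   (non-decreasing in `t`).
#' @export
count_percolated <- function(trace, t) {
  stopifnot(inherits(trace, "spread_trace"))
  t <- as.integer(t)
  if (is.na(t) || t < 1L || t > trace$n_steps) {
    stop("t must be within the recorded steps (1..", trace$n_steps, ")",
         call. = FALSE)
  }
  as.integer(sum(trace$states_by_step[t, ]))
}

#' Ratio of average percolation to betweenness centrality
#'
#' The diagnostic tracked over a spread: the ratio of the averages of PC
#' and BC over nodes with nonzero betweenness (the node count divides
#' numerator and denominator and cancels, so it is computed as a ratio of
#' sums).  While the contagion is localized the ratio differs markedly
#' from 1; as percolation becomes universal PC converges to BC node by
#' node and the ratio settles at unity.  It is exactly 0 when no node is
#' percolated, and exactly 1 under uniform full percolation.
#'
#' @param graph A simple `igraph` graph.
#' @param states Node states.
#' @return A single number, or `NA` (with a warning) if every node has
#'   zero betweenness.
#' @export
pc_bc_ratio <- function(graph, states) {
  graph <- check_graph(graph)
  bc <- betweenness_centrality(graph)
  idx <- which(as.numeric(bc) > 0)
  if (!length(idx)) {
    warning("PC/BC ratio undefined: all betweenness values are zero")
    return(NA_real_)
  }
  pc <- percolation_centrality(graph, states)
  sum(as.numeric(pc)[idx]) / sum(as.numeric(bc)[idx])
}
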