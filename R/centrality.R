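# Shortest-path centrality measures: normalized betweenness, percolation
# centrality (source-weighted, fast Brandes-style accumulation), and the
# ramp-weighted source-target variant.
#
# Conventions shared by all measures:
#   * pairs (s, r) are ordered, s != r, and the evaluated node v is never
#     counted as source or target (endpoints excluded);
#   * disconnected pairs (sigma_sr = 0) contribute nothing;
#   * with fewer than 3 nodes there are no valid (s, v, r) triples and the
#     normalized scores are all zero.

#' Normalized betweenness centrality
#'
#' \deqn{BC(v) = \frac{1}{(N-1)(N-2)} \sum_{s \ne v \ne r}
#'   \frac{\sigma_{sr}(v)}{\sigma_{sr}}}
#' over ordered pairs, endpoints excluded, so scores lie in \eqn{[0,1]}.
#'
#' @param graph A simple `igraph` graph (directed supported).
#' @return A `centrality_scores` vector (measure `"bc"`).
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' betweenness_centrality(g)  # b scores 1
#' @export
betweenness_centrality <- function(graph) {
  graph <- check_graph(graph)
  nodes <- node_names(graph)
  n <- length(nodes)
  if (n < 3L) return(new_scores(numeric(n), nodes, "bc"))
  al <- adj_lists(graph)
  ones <- rep(1, n)
  raw <- numeric(n)
  for (s in seq_len(n)) {
    b <- bfs_count(al$out, s, n)
    d <- accumulate_dependencies(b, al$rin, ones)
    d[s] <- 0
    raw <- raw + d
  }
  new_scores(raw / ((n - 1) * (n - 2)), nodes, "bc")
}

#' Percolation centrality
#'
#' The proportion of percolated paths through a node: geodesics whose
#' source is (partially) percolated, weighted by the source's state.
#' \deqn{PC^t(v) = \frac{1}{N-2} \sum_{s \ne v \ne r}
#'   \frac{\sigma_{sr}(v)}{\sigma_{sr}} \frac{x_s}{S - x_v}}
#' where \eqn{S = \sum_i x_i}.  Subtracting \eqn{x_v} from \eqn{S}
#' normalizes each evaluation node's source weights to sum to 1, so that
#' with uniform states \eqn{x_v = \alpha > 0} the measure reduces exactly
#' to [betweenness_centrality()], and averaging the single-source
#' scenarios over all possible contagion origins likewise recovers it.
#'
#' Computed in \eqn{O(NM)} by Brandes-style accumulation of
#' \eqn{\sum_s x_s \delta_s(v)} followed by the per-node division.
#' Degenerate denominators are conventions, not errors: all scores are 0
#' when \eqn{S = 0}, and \eqn{PC(v) = 0} when \eqn{S - x_v = 0} (the only
#' percolated node is \eqn{v} itself, so no valid source exists).
#'
#' @param graph A simple `igraph` graph.
#' @param states Node states (see [percolation_states()]).
#' @return A `centrality_scores` vector (measure `"pc"`), values in
#'   \eqn{[0,1]}.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)
#' percolation_centrality(g, percolation_states(g, 1))  # equals BC
#' @export
percolation_centrality <- function(graph, states) {
  graph <- check_graph(graph)
  x <- check_states(graph, states)
  nodes <- node_names(graph)
  n <- length(nodes)
  tm <- attr(states, "time")
  S <- sum(x)
  if (n < 3L || S <= 0) return(new_scores(numeric(n), nodes, "pc", tm))
  al <- adj_lists(graph)
  ones <- rep(1, n)
  raw <- numeric(n)
  for (s in which(x > 0)) {
    b <- bfs_count(al$out, s, n)
    d <- accumulate_dependencies(b, al$rin, ones)
    d[s] <- 0
    raw <- raw + x[s] * d
  }
  den <- S - x
  pc <- numeric(n)
  ok <- den > 0
  pc[ok] <- raw[ok] / den[ok] / (n - 2)
  new_scores(pc, nodes, "pc", tm)
}

#' Source weight matrix
#'
#' The matrix of percolated-path weights \eqn{w_{s,v} = x_s / (S - x_v)}
#' for \eqn{s \ne v} (diagonal 0), rows indexed by source nodes, columns
#' by the node whose percolation centrality is being evaluated.  Whenever
#' \eqn{S - x_v > 0} column \eqn{v} sums to 1 over sources; all entries
#' are 0 when \eqn{S = 0}, and a column with \eqn{S - x_v = 0} is 0.
#'
#' @param states Node states (named; see [percolation_states()]).
#' @return A square numeric matrix with node dimnames.
#' @export
weight_matrix <- function(states) {
  x <- as.numeric(states)
  nodes <- names(states)
  if (is.null(nodes)) stop("states must be named by node", call. = FALSE)
  n <- length(x)
  S <- sum(x)
  W <- matrix(0, n, n, dimnames = list(source = nodes, node = nodes))
  if (S > 0) {
    den <- S - x
    ok <- den > 0
    W[, ok] <- outer(x, den[ok], `/`)
  }
  diag(W) <- 0
  W
}

#' Source-target pair weight matrix
#'
#' Ramp-weighted pair weights for the source-target percolation variant:
#' \deqn{w_{s,r} = \frac{R(x_s - x_r)}{\sum_{s' \ne r'} R(x_{s'} - x_{r'})}}
#' with \eqn{R(y) = y} for \eqn{y > 0} and 0 otherwise, so a pair only
#' counts when the source is more percolated than the target.  Entries sum
#' to 1 over ordered pairs whenever any raw weight is positive (the
#' measure's leading scale factor is absorbed into the weights); the
#' matrix is all zero under uniform states.
#'
#' @inheritParams weight_matrix
#' @return A square numeric matrix (rows sources, columns targets).
#' @export
pair_weight_matrix <- function(states) {
  x <- as.numeric(states)
  nodes <- names(states)
  if (is.null(nodes)) stop("states must be named by node", call. = FALSE)
  W <- outer(x, x, `-`)
  W[W < 0] <- 0
  diag(W) <- 0
  tot <- sum(W)
  if (tot > 0) W <- W / tot
  dimnames(W) <- list(source = nodes, target = nodes)
  W
}

#' Source-target percolation centrality
#'
#' Extends [percolation_centrality()] to weight each ordered pair by the
#' positive part of the source-target state difference
#' (see [pair_weight_matrix()]):
#' \deqn{PC_{st}(v) = \sum_{s \ne v \ne r}
#'   \frac{\sigma_{sr}(v)}{\sigma_{sr}}\, w_{s,r}.}
#' Under uniform states every ramp weight vanishes and all scores are 0:
#' paths between equally percolated nodes carry no potential spread.
#' Values lie in \eqn{[0,1]} and read as the weighted fraction of
#' percolated paths through \eqn{v}.
#'
#' @inheritParams percolation_centrality
#' @return A `centrality_scores` vector (measure `"pc_st"`).
#' @export
percolation_centrality_st <- function(graph, states) {
  graph <- check_graph(graph)
  x <- check_states(graph, states)
  nodes <- node_names(graph)
  n <- length(nodes)
  tm <- attr(states, "time")
  W <- pair_weight_matrix(stats::setNames(x, nodes))
  if (n < 3L || sum(W) == 0) return(new_scores(numeric(n), nodes, "pc_st", tm))
  al <- adj_lists(graph)
  res <- numeric(n)
  for (s in seq_len(n)) {
    coef <- W[s, ]
    if (all(coef == 0)) next
    b <- bfs_count(al$out, s, n)
    d <- accumulate_dependencies(b, al$rin, coef)
    d[s] <- 0
    res <- res + d
  }
  new_scores(res, nodes, "pc_st", tm)
}
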