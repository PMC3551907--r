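# Breadth-first geodesic counting (the BFS stage of Brandes' algorithm)
# and dependency accumulation.  All centrality code in the package runs on
# these primitives; the brute-force oracles deliberately do not.

#' @noRd
adj_lists <- function(graph) {
  out <- lapply(igraph::as_adj_list(graph, mode = "out"), as.integer)
  rin <- if (igraph::is_directed(graph)) {
    lapply(igraph::as_adj_list(graph, mode = "in"), as.integer)
  } else {
    out
  }
  list(out = out, rin = rin)
}

# Single-source BFS with geodesic counting.  Returns hop distances
# (-1L = unreachable), geodesic counts sigma, and the BFS visit order.
#' @noRd
bfs_count <- function(adj, s, n) {
  dist <- rep.int(-1L, n)
  sigma <- numeric(n)
  dist[s] <- 0L
  sigma[s] <- 1
  q <- integer(n)
  q[1L] <- s
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    u <- q[head]
    head <- head + 1L
    nb <- adj[[u]]
    if (length(nb)) {
      fresh <- nb[dist[nb] < 0L]
      if (length(fresh)) {
        dist[fresh] <- dist[u] + 1L
        q[(tail + 1L):(tail + length(fresh))] <- fresh
        tail <- tail + length(fresh)
      }
      nxt <- nb[dist[nb] == dist[u] + 1L]
      if (length(nxt)) sigma[nxt] <- sigma[nxt] + sigma[u]
    }
  }
  list(dist = dist, sigma = sigma, order = q[seq_len(tail)])
}

# Reverse-order dependency accumulation with per-target coefficients:
#   delta(v) = sum over targets r of coef[r] * sigma_sr(v) / sigma_sr.
# coef = 1 gives Brandes' betweenness dependency; per-target pair weights
# give the source-target percolation variant.  delta[s] is meaningless to
# callers (the endpoint convention excludes it) and must be dropped.
#' @noRd
accumulate_dependencies <- function(bfs, rin, coef) {
  n <- length(bfs$dist)
  delta <- numeric(n)
  ord <- bfs$order
  dist <- bfs$dist
  sigma <- bfs$sigma
  if (length(ord) >= 2L) {
    for (idx in length(ord):2L) {
      w <- ord[idx]
      pr <- rin[[w]]
      pr <- pr[dist[pr] == dist[w] - 1L]
      if (length(pr)) {
        delta[pr] <- delta[pr] + (sigma[pr] / sigma[w]) * (coef[w] + delta[w])
      }
    }
  }
  delta
}

#' All-pairs shortest-path data
#'
#' Runs the geodesic-counting BFS from every source and returns, per
#' source, hop distances, geodesic counts \eqn{\sigma(s,\cdot)}
#' (\eqn{\sigma(s,s) = 1}), and predecessor lists on the shortest-path
#' DAG.  The count of geodesics from `s` to `r` through interior node `v`
#' is \eqn{\sigma(s,v)\,\sigma(v,r)} whenever
#' \eqn{d(s,v) + d(v,r) = d(s,r)}, else 0.
#'
#' @param graph A simple `igraph` graph (directed supported).
#' @return An object of class `sp_data`: list with `dist` (numeric matrix,
#'   `Inf` for unreachable), `sigma` (numeric matrix), `preds` (nested
#'   list: `preds[[s]][[v]]` is the character vector of predecessors of
#'   `v` on geodesics from `s`), and `nodes`.
#' @export
all_pairs_shortest_paths <- function(graph) {
  graph <- check_graph(graph)
  nodes <- node_names(graph)
  n <- length(nodes)
  al <- adj_lists(graph)
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  preds <- vector("list", n)
  names(preds) <- nodes
  for (s in seq_len(n)) {
    b <- bfs_count(al$out, s, n)
    reach <- b$dist >= 0L
    dist[s, reach] <- b$dist[reach]
    sigma[s, ] <- b$sigma
    ps <- vector("list", n)
    names(ps) <- nodes
    for (v in seq_len(n)) {
      if (!reach[v] || v == s) {
        ps[[v]] <- character(0)
      } else {
        pr <- al$rin[[v]]
        pr <- pr[b$dist[pr] == b$dist[v] - 1L & b$dist[pr] >= 0L]
        ps[[v]] <- nodes[pr]
      }
    }
    preds[[s]] <- ps
  }
  structure(list(dist = dist, sigma = sigma, preds = preds, nodes = nodes),
            class = "sp_data")
}

#' @exportS3Method base::print
print.sp_data <- function(x, ...) {
  cat(sprintf("<sp_data> %d nodes; finite pairs: %d\n",
              length(x$nodes), sum(is.finite(x$dist))))
  invisible(x)
}

#' Hop distance to the percolated set
#'
#' The hop distance of node \eqn{v} is the smallest number of hops from
#' \eqn{v} to any node whose state satisfies \eqn{x \ge \theta}.  Nodes
#' that themselves satisfy the predicate have hop distance 0; nodes whose
#' component contains no such node get `Inf`.
#'
#' @param graph A simple `igraph` graph.
#' @param states Node states (see [percolation_states()]).
#' @param threshold State threshold \eqn{\theta \in (0, 1]}; default 1
#'   (fully percolated).
#' @return A `centrality_scores` vector (measure `"hop"`).  If no node
#'   satisfies the predicate all values are `Inf` and the attribute
#'   `no_sources` is `TRUE`.
#' @export
hop_distance <- function(graph, states, threshold = 1) {
  graph <- check_graph(graph)
  x <- check_states(graph, states)
  assert_scalar_number(threshold, "threshold", lo = .Machine$double.xmin, hi = 1)
  nodes <- node_names(graph)
  src <- which(x >= threshold)
  if (!length(src)) {
    out <- new_scores(rep(Inf, length(nodes)), nodes, "hop",
                      attr(states, "time"))
    attr(out, "no_sources") <- TRUE
    return(out)
  }
  d <- igraph::distances(graph, v = igraph::V(graph), to = src, mode = "out")
  h <- apply(d, 1L, min)
  new_scores(h, nodes, "hop", attr(states, "time"))
}
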