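# Brute-force reference implementations.  These enumerate geodesics
# explicitly (guided by igraph::distances(), not by the package's own BFS
# machinery) or solve the full electrical problem with a Laplacian
# pseudoinverse, and are used as independent oracles in the test suite.
# They are exponential-time in the worst case and guarded by a path-count
# cap; intended for graphs of up to ~15 nodes.

# All geodesics s -> r as lists of integer node indices, by depth-first
# extension along neighbours that strictly decrease the remaining
# distance to r.  d_to_r is the vector of hop distances to r.
#' @noRd
geodesics_idx <- function(adjout, d_to_r, s, r, max_paths) {
  if (!is.finite(d_to_r[s])) return(list())
  paths <- list()
  extend <- function(path) {
    c0 <- path[length(path)]
    if (c0 == r) {
      if (length(paths) >= max_paths) {
        stop("geodesic enumeration exceeded max_paths cap", call. = FALSE)
      }
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (u in adjout[[c0]]) {
      if (is.finite(d_to_r[u]) && d_to_r[u] == d_to_r[c0] - 1) extend(c(path, u))
    }
  }
  extend(s)
  paths
}

#' Enumerate all geodesics between two nodes
#'
#' Exhaustively lists the shortest paths from `s` to `r` by backtracking
#' over the distance-layered neighbourhood structure.  The list length
#' equals \eqn{\sigma(s,r)}; an unreachable pair yields an empty list.
#'
#' @param graph A simple `igraph` graph.
#' @param s,r Node names (or indices).
#' @param max_paths Safety cap on the number of geodesics (default 1e6);
#'   exceeding it is an error.
#' @return A list of character vectors, each a node sequence from `s` to
#'   `r` of length \eqn{d(s,r) + 1}.
#' @export
oracle_geodesics <- function(graph, s, r, max_paths = 1e6) {
  graph <- check_graph(graph)
  nodes <- node_names(graph)
  si <- if (is.character(s)) match(s, nodes) else as.integer(s)
  ri <- if (is.character(r)) match(r, nodes) else as.integer(r)
  if (is.na(si) || is.na(ri)) stop("unknown node", call. = FALSE)
  adjout <- lapply(igraph::as_adj_list(graph, mode = "out"), as.integer)
  d_to_r <- igraph::distances(graph, to = ri, mode = "out")[, 1L]
  lapply(geodesics_idx(adjout, d_to_r, si, ri, max_paths),
         function(p) nodes[p])
}

# Shared driver: for every ordered pair (s, r) with positive pair weight,
# enumerate geodesics and add weight * (fraction through v as interior)
# to each node's total.
#' @noRd
oracle_pair_sum <- function(graph, pair_weight, max_paths) {
  nodes <- node_names(graph)
  n <- length(nodes)
  adjout <- lapply(igraph::as_adj_list(graph, mode = "out"), as.integer)
  D <- igraph::distances(graph, mode = "out")
  tot <- numeric(n)
  for (r in seq_len(n)) {
    d_to_r <- D[, r]
    for (s in seq_len(n)) {
      if (s == r || pair_weight[s, r] == 0 || !is.finite(d_to_r[s])) next
      paths <- geodesics_idx(adjout, d_to_r, s, r, max_paths)
      m <- length(paths)
      if (!m) next
      cnt <- numeric(n)
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        cnt[interior] <- cnt[interior] + 1
      }
      tot <- tot + pair_weight[s, r] * cnt / m
    }
  }
  stats::setNames(tot, nodes)
}

#' Brute-force betweenness centrality
#'
#' Literal evaluation of normalized betweenness by geodesic enumeration.
#' Test oracle for [betweenness_centrality()]; exponential worst case.
#'
#' @inheritParams oracle_geodesics
#' @return A `centrality_scores` vector (measure `"bc"`).
#' @export
oracle_betweenness <- function(graph, max_paths = 1e6) {
  graph <- check_graph(graph)
  n <- igraph::vcount(graph)
  if (n < 3L) return(new_scores(numeric(n), node_names(graph), "bc"))
  pw <- matrix(1, n, n); diag(pw) <- 0
  tot <- oracle_pair_sum(graph, pw, max_paths)
  new_scores(tot / ((n - 1) * (n - 2)), node_names(graph), "bc")
}

#' Brute-force percolation centrality
#'
#' Literal evaluation of percolation centrality from enumerated geodesics:
#' each ordered pair's path fraction through `v` is weighted by the
#' source state (variant `"source"`, oracle for
#' [percolation_centrality()]) or by the normalized ramp of the
#' source-target state difference (variant `"source-target"`, oracle for
#' [percolation_centrality_st()]).
#'
#' @inheritParams oracle_geodesics
#' @param states Node states.
#' @param variant `"source"` or `"source-target"`.
#' @return A `centrality_scores` vector.
#' @export
oracle_percolation_centrality <- function(graph, states,
                                          variant = c("source", "source-target"),
                                          max_paths = 1e6) {
  variant <- match.arg(variant)
  graph <- check_graph(graph)
  x <- check_states(graph, states)
  nodes <- node_names(graph)
  n <- length(nodes)
  if (variant == "source") {
    S <- sum(x)
    if (n < 3L || S <= 0) return(new_scores(numeric(n), nodes, "pc"))
    pw <- matrix(x, n, n)          # weight x_s on every pair (s, r)
    diag(pw) <- 0
    tot <- oracle_pair_sum(graph, pw, max_paths)
    den <- S - x
    out <- numeric(n)
    ok <- den > 0
    out[ok] <- tot[ok] / den[ok] / (n - 2)
    new_scores(out, nodes, "pc")
  } else {
    W <- pair_weight_matrix(stats::setNames(x, nodes))
    if (n < 3L || sum(W) == 0) return(new_scores(numeric(n), nodes, "pc_st"))
    new_scores(oracle_pair_sum(graph, W, max_paths), nodes, "pc_st")
  }
}

#' Brute-force current-flow measures via Laplacian pseudoinverse
#'
#' Solves the whole electrical network with `MASS::ginv()` on the full
#' combinatorial Laplacian and sums node throughputs pair by pair in
#' plain loops.  Independent oracle for the current-flow measures.
#'
#' @inheritParams oracle_percolation_centrality
#' @param variant `"betweenness"`, `"source"`, or `"source-target"`.
#' @return A `centrality_scores` vector.
#' @export
oracle_current_flow <- function(graph, states = NULL,
                                variant = c("betweenness", "source", "source-target")) {
  variant <- match.arg(variant)
  graph <- check_graph(graph)
  nodes <- node_names(graph)
  n <- length(nodes)
  if (igraph::is_directed(graph)) stop("undirected graphs only", call. = FALSE)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  L <- diag(rowSums(A)) - A
  G <- MASS::ginv(L)
  el <- igraph::as_edgelist(graph, names = FALSE)
  memb <- igraph::components(graph)$membership
  throughput <- function(s, r) {
    p <- G[, s] - G[, r]
    thr <- numeric(n)
    if (nrow(el)) {
      for (e in seq_len(nrow(el))) {
        u <- el[e, 1L]; v <- el[e, 2L]
        f <- abs(p[u] - p[v])
        thr[u] <- thr[u] + f / 2
        thr[v] <- thr[v] + f / 2
      }
    }
    thr[c(s, r)] <- 0
    thr
  }
  x <- if (is.null(states)) NULL else check_states(graph, states)
  tot <- numeric(n)
  if (variant == "betweenness") {
    for (ci in unique(memb)) {
      idx <- which(memb == ci)
      nc <- length(idx)
      if (nc < 3L) next
      sub <- numeric(n)
      for (s in idx) for (r in idx) {
        if (s != r) sub <- sub + throughput(s, r)
      }
      tot[idx] <- sub[idx] / ((nc - 1) * (nc - 2))
    }
    return(new_scores(tot, nodes, "bc_rw"))
  }
  if (is.null(x)) stop("states required for percolation variants", call. = FALSE)
  if (variant == "source") {
    S <- sum(x)
    if (n < 3L || S <= 0) return(new_scores(numeric(n), nodes, "pc_rw"))
    for (s in seq_len(n)) for (r in seq_len(n)) {
      if (s == r || memb[s] != memb[r] || x[s] == 0) next
      tot <- tot + x[s] * throughput(s, r)
    }
    den <- S - x
    out <- numeric(n)
    ok <- den > 0
    out[ok] <- tot[ok] / den[ok] / (n - 2)
    new_scores(out, nodes, "pc_rw")
  } else {
    W <- pair_weight_matrix(stats::setNames(x, nodes))
    if (n < 3L || sum(W) == 0) return(new_scores(numeric(n), nodes, "pc_rw_st"))
    for (s in seq_len(n)) for (r in seq_len(n)) {
      if (s == r || memb[s] != memb[r] || W[s, r] == 0) next
      tot <- tot + W[s, r] * throughput(s, r)
    }
    new_scores(tot, nodes, "pc_rw_st")
  }
}
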