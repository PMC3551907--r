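# Current-flow (random-walk) betweenness and its percolation-weighted
# analogues.  The network is treated as an electric circuit with unit
# resistance on every link; I_sr(v) is the current through node v when a
# unit current is pumped from s to r, computed from node potentials
# obtained by solving the graph Laplacian with one grounded node per
# connected component (dense solve; intended for graphs up to a few
# thousand nodes).  Pairs spanning different components contribute 0 --
# the electrical problem is undefined across components.

# Per-component potential matrices: for component with member indices
# `idx`, Tmat[i, j] is the potential at idx[i] when unit current enters at
# idx[j] and leaves via the grounded (last) member.  Potentials for a pair
# (s, r) are then Tmat[, s] - Tmat[, r], independent of the ground choice.
#' @noRd
cf_solver <- function(graph) {
  graph <- check_graph(graph)
  if (igraph::is_directed(graph)) {
    stop("current-flow measures are defined for undirected graphs", call. = FALSE)
  }
  comp <- igraph::components(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  lapply(seq_len(comp$no), function(ci) {
    idx <- which(comp$membership == ci)
    nc <- length(idx)
    Tmat <- matrix(0, nc, nc)
    if (nc >= 2L) {
      Ac <- A[idx, idx, drop = FALSE]
      L <- diag(rowSums(Ac)) - Ac
      keep <- seq_len(nc - 1L)   # ground the last member
      Tmat[keep, keep] <- solve(L[keep, keep, drop = FALSE])
    }
    el <- igraph::as_edgelist(igraph::induced_subgraph(graph, idx), names = TRUE)
    # edge endpoints as positions within the component
    pos <- match(node_names(graph)[idx], node_names(graph))
    local <- stats::setNames(seq_len(nc), node_names(graph)[idx])
    list(idx = idx, n = nc, Tmat = Tmat,
         eu = unname(local[el[, 1L]]), ev = unname(local[el[, 2L]]))
  })
}

# Node throughputs I_sr(.) for one pair (s, r), local component indices.
# Throughput of v is half the summed absolute currents on its incident
# edges; the terminals' own throughputs are zeroed (endpoint convention).
#' @noRd
cf_throughput <- function(sol, s, r) {
  p <- sol$Tmat[, s] - sol$Tmat[, r]
  thr <- numeric(sol$n)
  if (length(sol$eu)) {
    f <- abs(p[sol$eu] - p[sol$ev])
    acc <- rowsum(c(f, f), c(sol$eu, sol$ev))
    thr[as.integer(rownames(acc))] <- acc[, 1L] / 2
  }
  thr[c(s, r)] <- 0
  thr
}

#' Current-flow (random-walk) betweenness centrality
#'
#' Average over ordered pairs \eqn{(s, r)} in the same component,
#' endpoints excluded, of the current through \eqn{v} when a unit current
#' is pumped from \eqn{s} to \eqn{r}; normalized by
#' \eqn{(N_c - 1)(N_c - 2)} per component.  Components with fewer than 3
#' nodes score 0.  On trees every unit current follows the unique path,
#' so the measure coincides with [betweenness_centrality()].
#'
#' @param graph A simple undirected `igraph` graph.
#' @return A `centrality_scores` vector (measure `"bc_rw"`).
#' @export
current_flow_betweenness <- function(graph) {
  graph <- check_graph(graph)
  nodes <- node_names(graph)
  out <- numeric(length(nodes))
  for (sol in cf_solver(graph)) {
    nc <- sol$n
    if (nc < 3L) next
    tot <- numeric(nc)
    for (s in seq_len(nc - 1L)) {
      for (r in seq.int(s + 1L, nc)) {
        tot <- tot + 2 * cf_throughput(sol, s, r)  # ordered pairs: x2
      }
    }
    out[sol$idx] <- tot / ((nc - 1) * (nc - 2))
  }
  new_scores(out, nodes, "bc_rw")
}

#' Current-flow percolation centrality
#'
#' Percolation centrality with geodesic fractions replaced by electrical
#' throughput:
#' \deqn{PC_{rw}(v) = \frac{1}{N-2} \sum_{s \ne v \ne r}
#'   \frac{x_s}{S - x_v}\, I_{sr}(v)}
#' with the same source weights as [weight_matrix()] and pairs restricted
#' to \eqn{v}'s component.  On a connected graph, uniform states reduce
#' it to [current_flow_betweenness()]; all scores are 0 when \eqn{S = 0}.
#'
#' @param graph A simple undirected `igraph` graph.
#' @param states Node states (see [percolation_states()]).
#' @return A `centrality_scores` vector (measure `"pc_rw"`).
#' @export
current_flow_percolation_centrality <- function(graph, states) {
  graph <- check_graph(graph)
  x <- check_states(graph, states)
  nodes <- node_names(graph)
  n <- length(nodes)
  tm <- attr(states, "time")
  S <- sum(x)
  if (n < 3L || S <= 0) return(new_scores(numeric(n), nodes, "pc_rw", tm))
  out <- numeric(n)
  for (sol in cf_solver(graph)) {
    nc <- sol$n
    if (nc < 3L) next
    xs <- x[sol$idx]
    raw <- numeric(nc)
    for (s in seq_len(nc - 1L)) {
      for (r in seq.int(s + 1L, nc)) {
        if (xs[s] == 0 && xs[r] == 0) next
        raw <- raw + (xs[s] + xs[r]) * cf_throughput(sol, s, r)
      }
    }
    den <- S - xs
    ok <- den > 0
    raw[ok] <- raw[ok] / den[ok]
    raw[!ok] <- 0
    out[sol$idx] <- raw / (n - 2)
  }
  new_scores(out, nodes, "pc_rw", tm)
}

#' Current-flow source-target percolation centrality
#'
#' The electrical analogue of [percolation_centrality_st()]:
#' \deqn{PC_{rw,st}(v) = \sum_{s \ne v \ne r} w_{s,r}\, I_{sr}(v)}
#' with ramp pair weights from [pair_weight_matrix()] and pairs restricted
#' to \eqn{v}'s component.  Uniform states give all-zero scores.
#'
#' @inheritParams current_flow_percolation_centrality
#' @return A `centrality_scores` vector (measure `"pc_rw_st"`).
#' @export
current_flow_percolation_centrality_st <- function(graph, states) {
  graph <- check_graph(graph)
  x <- check_states(graph, states)
  nodes <- node_names(graph)
  n <- length(nodes)
  tm <- attr(states, "time")
  W <- pair_weight_matrix(stats::setNames(x, nodes))
  if (n < 3L || sum(W) == 0) return(new_scores(numeric(n), nodes, "pc_rw_st", tm))
  out <- numeric(n)
  for (sol in cf_solver(graph)) {
    nc <- sol$n
    if (nc < 3L) next
    Wc <- W[sol$idx, sol$idx, drop = FALSE]
    raw <- numeric(nc)
    for (s in seq_len(nc - 1L)) {
      for (r in seq.int(s + 1L, nc)) {
        wpair <- Wc[s, r] + Wc[r, s]   # I_sr is symmetric in (s, r)
        if (wpair == 0) next
        raw <- raw + wpair * cf_throughput(sol, s, r)
      }
    }
    out[sol$idx] <- raw
  }
  new_scores(out, nodes, "pc_rw_st", tm)
}
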