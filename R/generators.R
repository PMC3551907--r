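# Synthetic network generators: truncated power-law (scale-free)
# configuration model and Erdos-Renyi graphs.

#' Generate a scale-free network from a truncated power law
#'
#' Draws a degree sequence from \eqn{p(k) \propto k^{-\gamma}} for
#' \eqn{k = 1, \dots, k_{max}} (hard cutoff), repairs parity, checks the
#' Erdos-Gallai condition, and realizes the sequence as a simple
#' undirected graph: a Havel-Hakimi construction randomized by
#' degree-preserving edge switching, the rewiring form of the
#' configuration model that keeps the graph simple by construction.  The distribution, not a growth process,
#' is the input: \eqn{\gamma} and \eqn{k_{max}} are honoured directly,
#' and the realized maximum degree never exceeds the cutoff.
#'
#' @param n Number of nodes.
#' @param gamma Scale-free exponent \eqn{\gamma > 1} (default 2.5).
#' @param k_max Maximum degree cutoff in \eqn{[1, n-1]}; default
#'   \eqn{\min(n - 1, \lceil n^{1/(\gamma-1)} \rceil)}, the natural
#'   cutoff of a power-law sample of size \eqn{n}.
#' @param outlier_fraction Accepted for degree-distribution
#'   parameterizations that designate a proportion of out-lier nodes;
#'   validated (in \eqn{[0,1]}) and recorded as a graph attribute but not
#'   interpreted by this generator (default 0).
#' @param seed Optional integer RNG seed; fixing it makes the edge set
#'   reproducible.
#' @param max_tries Redraw budget for infeasible degree sequences.
#' @return A simple undirected `igraph` graph with `n` named nodes.
#' @examples
#' g <- generate_scale_free(200, gamma = 2.5, seed = 1)
#' max(igraph::degree(g))
#' @export
generate_scale_free <- function(n, gamma = 2.5, k_max = NULL,
                                outlier_fraction = 0, seed = NULL,
                                max_tries = 100L) {
  assert_scalar_number(n, "n", lo = 2)
  assert_scalar_number(gamma, "gamma", lo = 1 + 1e-9)
  assert_scalar_number(outlier_fraction, "outlier_fraction", lo = 0, hi = 1)
  n <- as.integer(n)
  if (is.null(k_max)) k_max <- min(n - 1L, as.integer(ceiling(n^(1 / (gamma - 1)))))
  assert_scalar_number(k_max, "k_max", lo = 1, hi = n - 1)
  k_max <- as.integer(k_max)
  build <- function() {
    prob <- (seq_len(k_max))^(-gamma)
    for (try in seq_len(max_tries)) {
      degs <- sample.int(k_max, n, replace = TRUE, prob = prob)
      while (sum(degs) %% 2L == 1L) {
        i <- sample.int(n, 1L)
        degs[i] <- sample.int(k_max, 1L, prob = prob)
      }
      if (!igraph::is_graphical(degs)) next
      # Havel-Hakimi realization, then degree-preserving edge switching
      # (10 M proposed swaps) to randomize while staying simple
      g <- tryCatch({
        g0 <- igraph::realize_degseq(degs, method = "smallest")
        igraph::rewire(g0, igraph::keeping_degseq(niter = 10L * igraph::ecount(g0)))
      }, error = function(e) NULL)
      if (!is.null(g)) {
        igraph::V(g)$name <- paste0("n", seq_len(n))
        g <- igraph::set_graph_attr(g, "outlier_fraction", outlier_fraction)
        return(check_graph(g))
      }
    }
    stop("no feasible degree sequence realized within max_tries redraws",
         call. = FALSE)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate an Erdos-Renyi random graph
#'
#' Either the \eqn{G(N, M)} model (exactly `m` edges) or the
#' \eqn{G(N, p)} model (each pair independently with probability `p`);
#' exactly one of `m` and `p` must be given.
#'
#' @param n Number of nodes.
#' @param m Number of edges (\eqn{G(N,M)}); at most \eqn{n(n-1)/2}.
#' @param p Edge probability (\eqn{G(N,p)}).
#' @param seed Optional integer RNG seed.
#' @return A simple undirected `igraph` graph with named nodes.
#' @export
generate_er <- function(n, m = NULL, p = NULL, seed = NULL) {
  assert_scalar_number(n, "n", lo = 1)
  n <- as.integer(n)
  if (is.null(m) == is.null(p)) {
    stop("supply exactly one of `m` (edge count) or `p` (edge probability)",
         call. = FALSE)
  }
  if (!is.null(m)) {
    assert_scalar_number(m, "m", lo = 0, hi = n * (n - 1) / 2)
  } else {
    assert_scalar_number(p, "p", lo = 0, hi = 1)
  }
  build <- function() {
    g <- if (!is.null(m)) {
      igraph::sample_gnm(n, as.integer(m))
    } else {
      igraph::sample_gnp(n, p)
    }
    igraph::V(g)$name <- paste0("n", seq_len(n))
    check_graph(g)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Largest connected component
#'
#' Convenience for spread experiments, which operate on the dominant
#' component (percolation saturation is unreachable across components).
#'
#' @param graph A simple `igraph` graph.
#' @return The induced subgraph on the largest component (ties broken by
#'   lowest component id), node names preserved.
#' @export
giant_component <- function(graph) {
  graph <- check_graph(graph)
  comp <- igraph::components(graph)
  keep <- which(comp$membership == which.max(comp$csize))
  check_graph(igraph::induced_subgraph(graph, keep))
}
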