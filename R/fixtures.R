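# Canonical small fixtures: an 8-node two-hub demonstration network and a
# synthetic 39-node contact-style network.  Both are constants built in
# code, identical across runs.

# Synthetic 39-node sparse contact-style network (an emulation of a small
# real-world sexual-contact outbreak network: one dominant 33-node
# component of diameter 9, a few satellite dyads/triads, many degree-1
# nodes).  It does not reproduce any published topology.
.alberta_like_edges <- c(
  "p1 p13",  "p1 p24",  "p1 p31",  "p2 p17",  "p2 p21",  "p2 p26",
  "p2 p39",  "p3 p19",  "p4 p23",  "p4 p38",  "p5 p35",  "p6 p10",
  "p7 p16",  "p7 p18",  "p8 p14",  "p9 p17",  "p10 p23", "p11 p36",
  "p12 p20", "p12 p21", "p13 p22", "p13 p23", "p13 p30", "p15 p28",
  "p16 p24", "p16 p33", "p16 p34", "p17 p21", "p17 p23", "p17 p30",
  "p17 p32", "p23 p25", "p23 p27", "p23 p39", "p24 p36", "p24 p39",
  "p28 p31", "p28 p37", "p29 p32"
)

#' Canonical fixture networks
#'
#' Fixed small networks used throughout the documentation and tests.
#'
#' `"two-hub-8"` is an 8-node network of two adjacent bridge hubs, `h1`
#' and `h2`, each attached to a group of three peripheral nodes (left
#' group `l1..l3`, right group `r1..r3`).  It ships with two partial
#' state vectors, `right_heavy` and `left_heavy`, mirror images of each
#' other: under right-heavy states the hub adjacent to the heavily
#' percolated right group takes the higher percolation centrality, and
#' the relation reverses under left-heavy states, while betweenness is
#' symmetric between the hubs throughout.
#'
#' `"alberta-like-39"` is a fixed synthetic 39-node sparse contact-style
#' network (one dominant 33-node component, small satellites) with a
#' labeled peripheral seed node (graph attribute `seed_node`, a degree-1
#' node of maximal eccentricity).  Its state vector percolates the seed
#' fully and nothing else -- the starting condition of a spread
#' simulation.
#'
#' @param name `"two-hub-8"` or `"alberta-like-39"`.
#' @return A list with elements `graph` (an `igraph`) and `states`
#'   (for `"two-hub-8"`, a list of two [percolation_states()] vectors
#'   named `right_heavy` and `left_heavy`; for `"alberta-like-39"`, a
#'   single state vector).
#' @examples
#' fx <- canonical_fixture("two-hub-8")
#' percolation_centrality(fx$graph, fx$states$right_heavy)
#' @export
canonical_fixture <- function(name = c("two-hub-8", "alberta-like-39")) {
  name <- match.arg(name)
  if (name == "two-hub-8") {
    nodes <- c("l1", "l2", "l3", "h1", "h2", "r1", "r2", "r3")
    edges <- c("h1", "h2",
               "h1", "l1", "h1", "l2", "h1", "l3",
               "h2", "r1", "h2", "r2", "h2", "r3")
    g <- igraph::make_graph(edges, directed = FALSE)
    g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
    g <- check_graph(g)
    right <- c(l1 = 0.1, l2 = 0.1, l3 = 0.1, h1 = 0.3, h2 = 0.3,
               r1 = 0.9, r2 = 0.8, r3 = 0.7)
    left <- c(l1 = 0.9, l2 = 0.8, l3 = 0.7, h1 = 0.3, h2 = 0.3,
              r1 = 0.1, r2 = 0.1, r3 = 0.1)
    list(graph = g,
         states = list(right_heavy = percolation_states(g, right),
                       left_heavy = percolation_states(g, left)))
  } else {
    parts <- strsplit(.alberta_like_edges, " ")
    from <- vapply(parts, `[[`, character(1), 1L)
    to <- vapply(parts, `[[`, character(1), 2L)
    nodes <- paste0("p", 1:39)
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
    )
    g <- igraph::set_graph_attr(g, "seed_node", "p15")
    g <- check_graph(g)
    x <- stats::setNames(numeric(39), nodes)
    x["p15"] <- 1
    list(graph = g, states = percolation_states(g, x, time = 1L))
  }
}
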