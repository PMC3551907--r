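# Shared fixture builders.  All randomness is local to the calling test's
# set.seed(); graphs come out simple and named.

named_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

connected_gnp <- function(n, p) {
  repeat {
    g <- named_gnp(n, p)
    if (igraph::is_connected(g)) return(g)
  }
}

random_states <- function(g, binary = FALSE) {
  n <- igraph::vcount(g)
  x <- if (binary) sample(0:1, n, replace = TRUE) else round(runif(n), 3)
  percolation_states(g, stats::setNames(x, igraph::V(g)$name))
}

path_graph <- function(nodes) {
  n <- length(nodes)
  igraph::graph_from_data_frame(
    data.frame(from = nodes[-n], to = nodes[-1]),
    directed = FALSE,
    vertices = data.frame(name = nodes))
}

scores_of <- function(x) unname(as.numeric(x))
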