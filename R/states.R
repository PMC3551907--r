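# Per-node percolation state vectors.

#' Construct a percolation state vector
#'
#' A percolation state \eqn{x_v \in [0,1]} describes how percolated
#' (infected) node \eqn{v} is at a given timestep: 0 is non-percolated,
#' 1 fully percolated, intermediate values partially percolated (for a
#' network of towns, the fraction of the town infected).  The vector is
#' named by node, covers exactly the graph's node set in graph order, and
#' carries the timestep as an attribute.
#'
#' @param graph The graph whose node set the states cover.
#' @param x Numeric states in \eqn{[0,1]}: either named by node (any
#'   order, must cover the node set), an unnamed vector in graph node
#'   order, or a single value recycled to all nodes.
#' @param time Nonnegative integer timestep (default 0).
#' @return A named numeric vector of class `perc_states`.
#' @examples
#' g <- igraph::make_ring(4)
#' percolation_states(g, c(1, 0, 0, 0))
#' @export
percolation_states <- function(graph, x, time = 0L) {
  graph <- check_graph(graph)
  nodes <- node_names(graph)
  n <- length(nodes)
  if (!is.numeric(x)) stop("states must be numeric", call. = FALSE)
  if (length(x) == 1L && is.null(names(x))) x <- rep(x, n)
  if (is.null(names(x))) {
    if (length(x) != n) stop("unnamed states must have one value per node", call. = FALSE)
    names(x) <- nodes
  } else {
    if (!setequal(names(x), nodes)) {
      stop("state names must match the graph's node set exactly", call. = FALSE)
    }
    x <- x[nodes]
  }
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("states must lie in [0, 1]", call. = FALSE)
  }
  time <- as.integer(time)
  if (is.na(time) || time < 0L) stop("time must be a nonnegative integer", call. = FALSE)
  structure(stats::setNames(as.numeric(x), nodes), time = time, class = "perc_states")
}

# Coerce states supplied as perc_states or plain (named) numeric into a
# plain numeric vector aligned with graph node order.
#' @noRd
check_states <- function(graph, states) {
  if (!inherits(states, "perc_states")) states <- percolation_states(graph, states)
  nodes <- node_names(graph)
  if (!identical(names(states), nodes)) {
    if (!setequal(names(states), nodes)) {
      stop("states do not cover the graph's node set", call. = FALSE)
    }
    states <- states[nodes]
  }
  as.numeric(stats::setNames(unclass(states), nodes))
}

#' Total extent of percolation
#'
#' @param states A state vector.
#' @return \eqn{S = \sum_v x_v}, between 0 and the node count.
#' @export
total_percolation <- function(states) sum(as.numeric(states))

#' @exportS3Method base::print
print.perc_states <- function(x, ...) {
  cat(sprintf("<perc_states> %d nodes, t = %d, S = %.4g\n",
              length(x), attr(x, "time") %||% 0L, sum(as.numeric(x))))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' @noRd
new_scores <- function(values, nodes, measure, time = NULL) {
  structure(stats::setNames(as.numeric(values), nodes),
            measure = measure, time = time, class = "centrality_scores")
}

#' @exportS3Method base::print
print.centrality_scores <- function(x, ...) {
  cat(sprintf("<centrality_scores> measure = %s%s\n",
              attr(x, "measure") %||% "score",
              if (!is.null(attr(x, "time"))) sprintf(", t = %d", attr(x, "time")) else ""))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' @export
as.data.frame.centrality_scores <- function(x, ...) {
  data.frame(node = names(x),
             score = as.numeric(x),
             measure = attr(x, "measure") %||% "score",
             time = attr(x, "time") %||% NA_integer_,
             stringsAsFactors = FALSE,
             row.names = NULL)
}
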