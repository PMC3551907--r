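# Graph model and plain-text readers/writers.
#
# Graphs are igraph objects restricted to the simple case: no self-loops,
# no duplicate edges, every vertex named.  All percnet functions call
# check_graph() on entry so downstream code can assume these invariants.

#' @noRd
check_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("`graph` must be an igraph object", call. = FALSE)
  if (igraph::vcount(graph) < 1L) stop("graph must have at least one node", call. = FALSE)
  if (any(igraph::which_loop(graph))) stop("graph must not contain self-loops", call. = FALSE)
  if (any(igraph::which_multiple(graph))) stop("graph must not contain duplicate edges", call. = FALSE)
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  graph
}

#' @noRd
node_names <- function(graph) igraph::V(graph)$name

#' Read a two-column edge list
#'
#' Reads a plain-text edge list with two whitespace-separated node
#' identifiers per line.  Lines starting with `#` (and trailing `#`
#' comments) are ignored.  Duplicate edges are removed; for undirected
#' graphs the pair order is irrelevant.  Node order in the resulting graph
#' is first-appearance order in the file.
#'
#' @param path Path to the edge-list file.
#' @param directed Logical; read edges as directed pairs.
#' @return A simple, named `igraph` graph.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c", "# comment", "b a"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g)  # 2: "b a" duplicates "a b"
#' @export
read_edge_list <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("edge list is empty: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge list line %d in %s: expected two node identifiers",
                 keep[bad[1L]], path), call. = FALSE)
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  self <- which(from == to)
  if (length(self)) {
    stop(sprintf("self-loop '%s %s' at line %d is not allowed",
                 from[self[1L]], to[self[1L]], keep[self[1L]]), call. = FALSE)
  }
  key <- if (directed) paste(from, to) else paste(pmin(from, to), pmax(from, to))
  dup <- duplicated(key)
  from <- from[!dup]; to <- to[!dup]
  nodes <- unique(as.vector(rbind(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = directed,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  check_graph(g)
}

#' Write a graph as a two-column edge list
#'
#' @param graph An `igraph` graph.
#' @param path Output path.
#' @param header Optional character vector written as leading `#` comment
#'   lines (provenance).
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path, header = NULL) {
  graph <- check_graph(graph)
  el <- igraph::as_edgelist(graph, names = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(el)) writeLines(paste(el[, 1L], el[, 2L]), con)
  invisible(path)
}

#' Write centrality scores as CSV
#'
#' Writes `node,score,measure,time` with full double precision so that
#' [read_scores()] round-trips bit-exactly.  Row order follows the score
#' vector (i.e. graph node order).
#'
#' @param scores A `centrality_scores` vector (named numeric with
#'   `measure`/`time` attributes) or plain named numeric vector.
#' @param path Output path.
#' @param header Optional character vector written as leading `#` comment
#'   lines.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path, header = NULL) {
  measure <- attr(scores, "measure") %||% "score"
  time <- attr(scores, "time") %||% NA_integer_
  df <- data.frame(
    node = if (length(scores)) names(scores) else character(0),
    score = if (length(scores)) sprintf("%.17g", as.numeric(scores)) else character(0),
    measure = rep_len(measure, length(scores)),
    time = rep_len(time, length(scores)),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read centrality scores written by [write_scores()]
#'
#' @param path Path to a scores CSV.
#' @return A `centrality_scores` named numeric vector.
#' @export
read_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("node", "score") %in% names(df))) {
    stop("scores file must have columns node,score", call. = FALSE)
  }
  out <- as.numeric(df$score)
  names(out) <- as.character(df$node)
  structure(out,
            measure = if (nrow(df)) df$measure[1L] else "score",
            time = if (nrow(df) && !is.na(df$time[1L])) df$time[1L] else NULL,
            class = "centrality_scores")
}

#' Read per-node percolation states from CSV
#'
#' The file holds columns `node,state` and optionally `time` (a header row
#' is detected automatically).  States must lie in \eqn{[0,1]}.  Nodes of
#' the graph absent from the file default to state 0 when
#' `default_missing = TRUE`, otherwise raise an error; nodes in the file
#' that are not in the graph always raise an error.
#'
#' @param path Path to the CSV file.
#' @param graph The graph whose node set the states must cover.
#' @param default_missing Logical; allow absent nodes to default to 0.
#' @return A [percolation_states()] vector in graph node order.
#' @export
read_states <- function(path, graph, default_missing = FALSE) {
  graph <- check_graph(graph)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("^\\s*node\\s*,", first, ignore.case = TRUE)
  df <- read.csv(path, header = has_header, stringsAsFactors = FALSE,
                 comment.char = "#")
  if (!has_header) {
    names(df)[1:2] <- c("node", "state")
    if (ncol(df) >= 3L) names(df)[3L] <- "time"
  }
  df$node <- as.character(df$node)
  nodes <- node_names(graph)
  unknown <- setdiff(df$node, nodes)
  if (length(unknown)) {
    stop("states file names nodes not in the graph: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$node)) stop("duplicate node in states file", call. = FALSE)
  st <- as.numeric(df$state)
  if (anyNA(st) || any(st < 0) || any(st > 1)) {
    stop("states must be numbers in [0, 1]", call. = FALSE)
  }
  missing <- setdiff(nodes, df$node)
  if (length(missing) && !default_missing) {
    stop("states file is missing nodes (set default_missing = TRUE to default them to 0): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  x <- stats::setNames(numeric(length(nodes)), nodes)
  x[df$node] <- st
  time <- if ("time" %in% names(df) && nrow(df)) as.integer(df$time[1L]) else 0L
  percolation_states(graph, x, time = time)
}
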