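#' Compute node- and graph-level network measures
#'
#' For a raw directed network: per-node in-degree, out-degree and total
#' degree, counted over *mentions* — arcs with weight 2 or more. In a
#' roster design every ordered pair carries a rating, and the floor
#' response ("We never spend time together.", weight 1) is the absence of
#' a nomination, so degree measures that counted it would be constant at
#' n-1. "Named by four or more peers" is therefore mention in-degree
#' >= 4. Per-graph: node count, arc count (all ratings), mention count,
#' density (arcs over n(n-1)) and the reciprocity rate (fraction of
#' mention arcs whose reverse arc is also a mention; 1 on a symmetric
#' ratings table). For a derived undirected network: per-node degree,
#' normalised shortest-path betweenness, normalised closeness and
#' component id; per-graph node count, edge count, density (edges over
#' n(n-1)/2) and component count. Betweenness and closeness are also
#' reported for raw networks, computed on the underlying undirected
#' contact structure.
#'
#' Conventions: betweenness is divided by the number of ordered/unordered
#' pairs excluding the node ((n-1)(n-2)/2 for undirected graphs), and
#' closeness follows the Wasserman–Faust normalisation for disconnected
#' graphs — `((r-1)/(n-1)) * ((r-1) / sum(d))` over the `r` reachable
#' nodes — so an isolate has closeness 0 rather than an undefined value.
#'
#' @param net A `raw_network` or `derived_network`.
#' @return An object of class `metric_table`: list with data frames
#'   `nodes` and `graph`.
#' @export
compute_metrics <- function(net) {
  if (inherits(net, "raw_network")) {
    g <- net$graph
    directed <- TRUE
  } else if (inherits(net, "derived_network")) {
    g <- net$graph
    directed <- FALSE
  } else {
    ts_validation_error("compute_metrics needs a raw_network or derived_network")
  }
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  if (directed) {
    # path-based measures and degrees on the mention structure only
    gm <- igraph::subgraph_from_edges(
      g, igraph::E(g)[igraph::E(g)$weight >= 2], delete.vertices = FALSE)
    gu <- igraph::as_undirected(gm, mode = "collapse")
  } else {
    gm <- g
    gu <- g
  }
  comp <- igraph::components(gu)
  btw <- if (n > 2) {
    igraph::betweenness(gu, directed = FALSE, weights = NA, normalized = TRUE)
  } else {
    rep(0, n)
  }
  D <- igraph::distances(gu, weights = NA)
  clo <- closeness_from_distances(D)
  nodes <- data.frame(
    id = ids,
    gender = igraph::V(g)$gender,
    classroom = igraph::V(g)$classroom,
    stringsAsFactors = FALSE
  )
  if (directed) {
    nodes$in_degree <- as.numeric(igraph::degree(gm, mode = "in"))
    nodes$out_degree <- as.numeric(igraph::degree(gm, mode = "out"))
    nodes$degree <- as.numeric(igraph::degree(gu))
  } else {
    nodes$degree <- as.numeric(igraph::degree(g))
  }
  nodes$betweenness <- as.numeric(btw)
  nodes$closeness <- as.numeric(clo)
  nodes$component <- as.integer(comp$membership)

  m <- igraph::ecount(g)
  density <- if (n < 2) 0 else if (directed) m / (n * (n - 1)) else
    m / (n * (n - 1) / 2)
  graph <- data.frame(
    n_nodes = as.integer(n),
    n_edges = as.integer(m),
    n_mentions = if (directed) as.integer(igraph::ecount(gm)) else NA_integer_,
    density = density,
    reciprocity = if (directed) arc_reciprocity(net) else NA_real_,
    n_components = as.integer(comp$no)
  )
  structure(list(nodes = nodes, graph = graph), class = "metric_table")
}

# Fraction of mention arcs (weight >= 2) whose reverse arc is also a
# mention; 1 on a symmetric ratings table, NA when there are no mentions.
arc_reciprocity <- function(raw) {
  arcs <- raw$arcs[raw$arcs$weight >= 2, , drop = FALSE]
  if (nrow(arcs) == 0) return(NA_real_)
  fwd <- paste(arcs$rater_id, arcs$ratee_id, sep = "\r")
  rev <- paste(arcs$ratee_id, arcs$rater_id, sep = "\r")
  mean(rev %in% fwd)
}

# Wasserman-Faust normalised closeness from a shortest-path distance
# matrix (Inf = unreachable). Isolates get 0.
closeness_from_distances <- function(D) {
  n <- nrow(D)
  if (n <= 1) return(rep(0, n))
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0) return(0)
    ((r / (n - 1)) * r) / sum(d[reach])
  }, numeric(1))
}

#' @export
print.metric_table <- function(x, ...) {
  cat("<metric_table>\n graph:\n")
  print(x$graph, row.names = FALSE)
  cat(sprintf(" nodes: %d rows x %d measures\n", nrow(x$nodes),
              ncol(x$nodes) - 3L))
  invisible(x)
}

#' Write a metric table to CSV
#'
#' Writes the per-node measures (one row per node) with the graph-level
#' measures appended as a second file or, with `graph_path = NULL`,
#' omitted.
#'
#' @param metrics A `metric_table`.
#' @param nodes_path Output CSV for node measures.
#' @param graph_path Optional output CSV for graph measures.
#' @return Invisibly, `metrics`.
#' @export
write_metrics <- function(metrics, nodes_path, graph_path = NULL) {
  stopifnot(inherits(metrics, "metric_table"))
  utils::write.csv(metrics$nodes, nodes_path, row.names = FALSE)
  if (!is.null(graph_path)) {
    utils::write.csv(metrics$graph, graph_path, row.names = FALSE)
  }
  invisible(metrics)
}
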