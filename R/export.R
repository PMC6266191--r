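#' Export networks to standard graph formats
#'
#' `write_graphml()` writes GraphML (node attributes: gender, classroom,
#' plus any characteristic labels attached by [run_scenario()]; edge
#' attribute: weight). `write_gexf()` writes GEXF 1.2. `write_edge_list()`
#' writes a plain CSV edge list.
#'
#' @param net A `raw_network` or `derived_network`.
#' @param path Output file path.
#' @param labels Optional data frame of per-node labels (column `id` plus
#'   one logical column per label) to attach as node attributes.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, path, labels = NULL) {
  g <- network_with_labels(net, labels)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_list <- function(net, path, labels = NULL) {
  df <- if (inherits(net, "raw_network")) {
    data.frame(from = net$arcs$rater_id, to = net$arcs$ratee_id,
               weight = net$arcs$weight, stringsAsFactors = FALSE)
  } else {
    stats::setNames(net$edges, c("from", "to", "weight"))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_gexf <- function(net, path, labels = NULL) {
  g <- network_with_labels(net, labels)
  directed <- igraph::is_directed(g)
  ids <- igraph::V(g)$name
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")

  doc <- xml2::xml_new_root(
    "gexf",
    xmlns = "http://www.gexf.net/1.2draft",
    version = "1.2"
  )
  graph_node <- xml2::xml_add_child(
    doc, "graph",
    mode = "static",
    defaultedgetype = if (directed) "directed" else "undirected"
  )
  attrs_node <- xml2::xml_add_child(graph_node, "attributes", class = "node")
  for (i in seq_along(vattrs)) {
    v <- igraph::vertex_attr(g, vattrs[i])
    type <- if (is.logical(v)) "boolean" else if (is.numeric(v)) "double" else "string"
    xml2::xml_add_child(attrs_node, "attribute",
                        id = as.character(i - 1L), title = vattrs[i],
                        type = type)
  }
  nodes_node <- xml2::xml_add_child(graph_node, "nodes")
  for (vi in seq_along(ids)) {
    nd <- xml2::xml_add_child(nodes_node, "node",
                              id = ids[vi], label = ids[vi])
    if (length(vattrs)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (i in seq_along(vattrs)) {
        val <- igraph::vertex_attr(g, vattrs[i])[vi]
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                            value = tolower(as.character(val)))
      }
    }
  }
  edges_node <- xml2::xml_add_child(graph_node, "edges")
  el <- igraph::as_data_frame(g, what = "edges")
  ew <- if (is.null(el$weight)) rep(1, nrow(el)) else el$weight
  for (ei in seq_len(nrow(el))) {
    xml2::xml_add_child(edges_node, "edge",
                        id = as.character(ei - 1L),
                        source = el$from[ei], target = el$to[ei],
                        weight = as.character(ew[ei]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# Attach label columns (and for derived networks the rule name) to the
# igraph object before export.
network_with_labels <- function(net, labels = NULL) {
  if (!inherits(net, c("raw_network", "derived_network"))) {
    ts_validation_error("expected a raw_network or derived_network")
  }
  g <- net$graph
  if (inherits(net, "derived_network")) {
    g <- igraph::set_graph_attr(g, "tie_rule", net$name)
  }
  if (!is.null(labels)) {
    if (!"id" %in% names(labels)) {
      ts_validation_error("labels data frame needs an 'id' column")
    }
    idx <- match(igraph::V(g)$name, labels$id)
    for (nm in setdiff(names(labels), "id")) {
      g <- igraph::set_vertex_attr(g, nm, value = labels[[nm]][idx])
    }
  }
  g
}
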