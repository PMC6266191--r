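#' Build the raw directed rating network
#'
#' Turns a validated [response_set()] into a directed, weighted network:
#' one node per individual (carrying gender and classroom attributes), one
#' arc per roster rating with its 1-5 contact weight. Ratings never cross
#' classrooms in a roster design, so the whole-study graph is the disjoint
#' union of the classroom networks; pass `classroom` to restrict to one.
#'
#' @param responses A `response_set`.
#' @param classroom Optional classroom id to restrict the network to.
#' @return An object of class `raw_network` wrapping an igraph graph.
#' @export
build_raw_network <- function(responses, classroom = NULL) {
  stopifnot(inherits(responses, "response_set"))
  ind <- responses$individuals
  rat <- responses$ratings
  if (!is.null(classroom)) {
    if (!classroom %in% ind$classroom_id) {
      ts_validation_error(sprintf("unknown classroom '%s'", classroom))
    }
    ind <- ind[ind$classroom_id == classroom, , drop = FALSE]
    rat <- rat[rat$rater_id %in% ind$id & rat$ratee_id %in% ind$id, ,
               drop = FALSE]
  }
  vertices <- data.frame(name = ind$id, gender = ind$gender,
                         classroom = ind$classroom_id,
                         stringsAsFactors = FALSE)
  edges <- data.frame(from = rat$rater_id, to = rat$ratee_id,
                      weight = rat$weight, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  structure(list(graph = g, nodes = vertices, arcs = rat),
            class = "raw_network")
}

#' @export
print.raw_network <- function(x, ...) {
  cat(sprintf("<raw_network> %d nodes, %d directed arcs (weights 1-5)\n",
              nrow(x$nodes), nrow(x$arcs)))
  invisible(x)
}

# Weight lookup matrix: W[a, b] = weight of arc a -> b, NA if absent.
weight_matrix <- function(raw) {
  ids <- raw$nodes$name
  n <- length(ids)
  W <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  W[cbind(match(raw$arcs$rater_id, ids), match(raw$arcs$ratee_id, ids))] <-
    raw$arcs$weight
  W
}

#' Derive a dichotomised network under a tie rule
#'
#' Applies a [tie_rule()] to every unordered pair of the raw network: an
#' undirected edge exists exactly when [evaluate_tie()] holds for the
#' dyad's two directed weights. Isolates are retained — the node set of
#' the derived network always equals the raw node set. Each edge carries
#' the weight prescribed by the rule's `output_weighting` and an
#' explanation trace of the decision; explanations for rejected dyads can
#' be recomputed on demand with [explain_tie()].
#'
#' @param raw A `raw_network`.
#' @param rule A `tie_rule`.
#' @return An object of class `derived_network`.
#' @export
derive_network <- function(raw, rule) {
  stopifnot(inherits(raw, "raw_network"), inherits(rule, "tie_rule"))
  ids <- raw$nodes$name
  n <- length(ids)
  W <- weight_matrix(raw)
  if (n >= 2) {
    pair_idx <- which(upper.tri(W), arr.ind = TRUE)
    wab <- W[pair_idx]
    wba <- t(W)[pair_idx]
    keep <- evaluate_tie_many(rule, wab, wba)
    a <- ids[pair_idx[keep, 1]]
    b <- ids[pair_idx[keep, 2]]
    wa <- ifelse(is.na(wab[keep]), 0, wab[keep])
    wb <- ifelse(is.na(wba[keep]), 0, wba[keep])
    ew <- switch(rule$output_weighting,
                 dichotomous = rep(1, length(a)),
                 min = pmin(wa, wb),
                 mean = (wa + wb) / 2,
                 sum = wa + wb)
    edges <- data.frame(a = a, b = b, weight = ew, stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$a, to = edges$b, weight = edges$weight,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = raw$nodes)
  explanations <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    explanations[[i]] <- evaluate_tie(
      rule, W[edges$a[i], edges$b[i]], W[edges$b[i], edges$a[i]],
      subject = c(edges$a[i], edges$b[i]))$explanation
  }
  out <- structure(list(
    name = rule$name, graph = g, nodes = raw$nodes, edges = edges,
    rule = rule, edge_explanations = explanations
  ), class = "derived_network")
  attr(out, "weight_matrix") <- W
  out
}

#' @export
print.derived_network <- function(x, ...) {
  cat(sprintf("<derived_network> '%s': %d nodes, %d undirected edges\n",
              x$name, nrow(x$nodes), nrow(x$edges)))
  print(x$rule)
  invisible(x)
}

#' Explain a tie decision for any dyad
#'
#' Recomputes the explanation trace for an arbitrary pair of individuals
#' under a derived network's rule — including dyads that did not become
#' edges, so "why is there no tie?" is answerable.
#'
#' @param net A `derived_network`.
#' @param a,b Individual ids.
#' @return An `explanation`.
#' @export
explain_tie <- function(net, a, b) {
  stopifnot(inherits(net, "derived_network"))
  ids <- net$nodes$name
  if (!(a %in% ids) || !(b %in% ids)) {
    ts_validation_error("both ids must be nodes of the network")
  }
  W <- attr(net, "weight_matrix")
  evaluate_tie(net$rule, W[a, b], W[b, a], subject = c(a, b))$explanation
}

#' Edge set of a derived network
#'
#' @param net A `derived_network`.
#' @return Character vector of canonical `"min|max"` edge keys.
#' @export
edge_set <- function(net) {
  stopifnot(inherits(net, "derived_network"))
  if (nrow(net$edges) == 0) return(character(0))
  sort(edge_keys(net$edges$a, net$edges$b))
}
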