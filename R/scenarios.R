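#' Enumerate the cross-product of tie and characteristic definitions
#'
#' Combining n tie definitions with m characteristic-rule sets yields
#' n x m analysis scenarios, which is exactly what this returns:
#' deterministically ordered tie-rule major, then rule-set declaration
#' order. Each scenario pairs one tie rule with one set of characteristic
#' rules and carries the label `"<tie>__<set>"`.
#'
#' @param tie_rules Named or unnamed list of [tie_rule()] objects with
#'   unique names.
#' @param characteristic_rule_sets Named list of characteristic-rule
#'   lists (see [scenario_rule_sets()]); a single flat list of
#'   `characteristic_rule` objects is also accepted and treated as
#'   singleton sets.
#' @return List of `scenario` objects, length n x m.
#' @export
enumerate_scenarios <- function(tie_rules, characteristic_rule_sets) {
  if (length(tie_rules) == 0 || length(characteristic_rule_sets) == 0) {
    ts_schema_error("need at least one tie rule and one characteristic-rule set")
  }
  if (all(vapply(characteristic_rule_sets, inherits, logical(1),
                 "characteristic_rule"))) {
    nm <- names(characteristic_rule_sets) %||%
      vapply(characteristic_rule_sets, function(r) r$name, character(1))
    characteristic_rule_sets <- stats::setNames(
      lapply(characteristic_rule_sets, list), nm)
  }
  tie_names <- vapply(tie_rules, function(r) r$name, character(1))
  if (anyDuplicated(tie_names)) {
    ts_schema_error("duplicate tie-rule names")
  }
  set_names <- names(characteristic_rule_sets)
  if (is.null(set_names) || any(!nzchar(set_names)) ||
      anyDuplicated(set_names)) {
    ts_schema_error("characteristic-rule sets must have unique non-empty names")
  }
  out <- list()
  for (ti in seq_along(tie_rules)) {
    for (si in seq_along(characteristic_rule_sets)) {
      label <- paste(tie_names[ti], set_names[si], sep = "__")
      out[[length(out) + 1L]] <- structure(list(
        label = label,
        tie_rule = tie_rules[[ti]],
        characteristic_rules = characteristic_rule_sets[[si]],
        rule_set = set_names[si]
      ), class = "scenario")
    }
  }
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: tie rule '%s' + %d characteristic rule(s)\n",
              x$label, x$tie_rule$name, length(x$characteristic_rules)))
  invisible(x)
}

#' Run one analysis scenario
#'
#' Executes the full pipeline for one scenario: derives the network under
#' the scenario's tie rule, computes node and graph measures (raw
#' in/out-degree plus derived degree, betweenness, closeness, component),
#' then classifies every individual under each characteristic rule with
#' those measures available to `metric:` conditions — so a label like
#' "popular" or "bad_influence" is, by construction, relative to this
#' scenario's own network. The result is fully reproducible from the
#' inputs and rules.
#'
#' @param responses A `response_set`.
#' @param scenario A `scenario` (or a [tie_rule()], for a network-only run
#'   with no characteristic rules).
#' @param classroom Optional classroom restriction, passed to
#'   [build_raw_network()].
#' @return An object of class `scenario_result`: the derived network, its
#'   `metric_table`, a `labels` data frame (id, gender, classroom, one
#'   logical column per label), per-individual `explanations`, and
#'   `summary` counts per label overall and by gender.
#' @export
run_scenario <- function(responses, scenario, classroom = NULL) {
  if (inherits(scenario, "tie_rule")) {
    scenario <- structure(list(label = scenario$name, tie_rule = scenario,
                               characteristic_rules = list(),
                               rule_set = NA_character_),
                          class = "scenario")
  }
  stopifnot(inherits(scenario, "scenario"))
  raw <- build_raw_network(responses, classroom = classroom)
  net <- derive_network(raw, scenario$tie_rule)
  raw_metrics <- compute_metrics(raw)
  net_metrics <- compute_metrics(net)

  node_metrics <- merge(
    raw_metrics$nodes[, c("id", "in_degree", "out_degree")],
    net_metrics$nodes[, c("id", "degree", "betweenness", "closeness",
                          "component")],
    by = "id", sort = FALSE)
  node_metrics <- node_metrics[match(net$nodes$name, node_metrics$id), ,
                               drop = FALSE]

  ind <- responses$individuals
  ind <- ind[match(net$nodes$name, ind$id), , drop = FALSE]
  scores <- individual_scores(responses)

  labels <- data.frame(id = ind$id, gender = ind$gender,
                       classroom = ind$classroom_id,
                       stringsAsFactors = FALSE)
  explanations <- list()
  for (rule in scenario$characteristic_rules) {
    verdicts <- logical(nrow(ind))
    expl <- vector("list", nrow(ind))
    for (i in seq_len(nrow(ind))) {
      mrow <- as.list(node_metrics[i, setdiff(names(node_metrics), "id")])
      res <- classify_with_scores(rule, ind$gender[i],
                                  scores[[ind$id[i]]] %||% list(), mrow,
                                  subject = ind$id[i])
      verdicts[i] <- res$verdict
      expl[[i]] <- res$explanation
    }
    labels[[rule$name]] <- verdicts
    names(expl) <- ind$id
    explanations[[rule$name]] <- expl
  }

  label_names <- vapply(scenario$characteristic_rules, function(r) r$name,
                        character(1))
  summary <- do.call(rbind, lapply(label_names, function(nm) {
    v <- labels[[nm]]
    data.frame(label = nm,
               n = sum(v),
               n_male = sum(v & labels$gender == "male"),
               n_female = sum(v & labels$gender == "female"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary)) {
    summary <- data.frame(label = character(0), n = integer(0),
                          n_male = integer(0), n_female = integer(0))
  }

  structure(list(
    label = scenario$label,
    scenario = scenario,
    network = net,
    metrics = net_metrics,
    node_metrics = node_metrics,
    labels = labels,
    explanations = explanations,
    summary = summary
  ), class = "scenario_result")
}

#' Run every scenario of a cross-product
#'
#' @param responses A `response_set`.
#' @param scenarios List of `scenario` objects from
#'   [enumerate_scenarios()].
#' @param classroom Optional classroom restriction.
#' @return Named list of `scenario_result` objects (names = labels).
#' @export
run_scenarios <- function(responses, scenarios, classroom = NULL) {
  labels <- vapply(scenarios, function(s) s$label, character(1))
  if (anyDuplicated(labels)) ts_schema_error("duplicate scenario labels")
  stats::setNames(
    lapply(scenarios, function(s) run_scenario(responses, s, classroom)),
    labels)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s\n", x$label))
  cat(sprintf("  network '%s': %d nodes, %d edges, %d component(s)\n",
              x$network$name, x$metrics$graph$n_nodes,
              x$metrics$graph$n_edges, x$metrics$graph$n_components))
  if (nrow(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      cat(sprintf("  label '%s': %d individual(s) (%d male, %d female)\n",
                  x$summary$label[i], x$summary$n[i], x$summary$n_male[i],
                  x$summary$n_female[i]))
    }
  }
  invisible(x)
}
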