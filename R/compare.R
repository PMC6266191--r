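#' Compare two scenario results
#'
#' Quantifies how much two definitions disagree on the same study: the
#' edge Jaccard index of the two derived networks (1 when both are empty),
#' and per shared label a 2x2 confusion count (both / only-A / only-B /
#' neither), the observed agreement proportion and Cohen's kappa. When
#' both scenarios assign the identical degenerate labelling (everyone the
#' same), chance agreement equals 1 and kappa is 0/0; it is reported as 1
#' with `kappa_degenerate = TRUE`, preserving the perfect-agreement
#' signal. Per-node metric deltas (B minus A) are included for degree,
#' betweenness and closeness.
#'
#' @param a,b `scenario_result` objects over the same node set.
#' @return An object of class `scenario_comparison`.
#' @export
compare_scenarios <- function(a, b) {
  stopifnot(inherits(a, "scenario_result"), inherits(b, "scenario_result"))
  ids_a <- sort(a$network$nodes$name)
  ids_b <- sort(b$network$nodes$name)
  if (!identical(ids_a, ids_b)) {
    ts_validation_error("scenario results cover different node sets")
  }
  ea <- edge_set(a$network)
  eb <- edge_set(b$network)
  uni <- union(ea, eb)
  jaccard <- if (length(uni) == 0) 1 else length(intersect(ea, eb)) / length(uni)

  shared <- intersect(setdiff(names(a$labels), c("id", "gender", "classroom")),
                      setdiff(names(b$labels), c("id", "gender", "classroom")))
  label_stats <- lapply(shared, function(nm) {
    la <- a$labels[[nm]][match(ids_a, a$labels$id)]
    lb <- b$labels[[nm]][match(ids_a, b$labels$id)]
    label_agreement(nm, la, lb)
  })
  label_stats <- if (length(label_stats)) {
    do.call(rbind, label_stats)
  } else {
    data.frame(label = character(0), both = integer(0), only_a = integer(0),
               only_b = integer(0), neither = integer(0),
               agreement = numeric(0), kappa = numeric(0),
               kappa_degenerate = logical(0))
  }

  ma <- a$node_metrics[match(ids_a, a$node_metrics$id), ]
  mb <- b$node_metrics[match(ids_a, b$node_metrics$id), ]
  deltas <- data.frame(id = ids_a,
                       d_degree = mb$degree - ma$degree,
                       d_betweenness = mb$betweenness - ma$betweenness,
                       d_closeness = mb$closeness - ma$closeness,
                       stringsAsFactors = FALSE)

  structure(list(
    a = a$label, b = b$label,
    edge_jaccard = jaccard,
    n_edges_a = length(ea), n_edges_b = length(eb),
    labels = label_stats,
    metric_deltas = deltas
  ), class = "scenario_comparison")
}

# Confusion counts, observed agreement and Cohen's kappa for one label.
label_agreement <- function(name, la, lb) {
  n <- length(la)
  both <- sum(la & lb)
  only_a <- sum(la & !lb)
  only_b <- sum(!la & lb)
  neither <- sum(!la & !lb)
  po <- (both + neither) / n
  pe <- (sum(la) / n) * (sum(lb) / n) +
    (sum(!la) / n) * (sum(!lb) / n)
  degenerate <- abs(1 - pe) < .Machine$double.eps^0.5
  kappa <- if (degenerate) 1 else (po - pe) / (1 - pe)
  data.frame(label = name, both = both, only_a = only_a, only_b = only_b,
             neither = neither, agreement = po, kappa = kappa,
             kappa_degenerate = degenerate, stringsAsFactors = FALSE)
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> %s vs %s\n", x$a, x$b))
  cat(sprintf("  edge Jaccard %.3f (%d vs %d edges)\n", x$edge_jaccard,
              x$n_edges_a, x$n_edges_b))
  if (nrow(x$labels)) print(x$labels, row.names = FALSE)
  invisible(x)
}

#' Build the sensitivity report over all scenarios
#'
#' Collates per-scenario summaries (network size, density, label counts)
#' and pairwise [compare_scenarios()] statistics — all C(k,2) pairs by
#' default, or only pairs against `reference` to curb quadratic output.
#'
#' @param results Named list of `scenario_result` objects.
#' @param reference Optional scenario label; compare only against it.
#' @return An object of class `sensitivity_report` with data frames
#'   `scenarios` and `comparisons` plus the underlying comparison objects.
#' @export
sensitivity_report <- function(results, reference = NULL) {
  if (length(results) == 0) ts_validation_error("need at least one scenario result")
  labels <- vapply(results, function(r) r$label, character(1))
  summaries <- do.call(rbind, lapply(results, function(r) {
    base <- data.frame(
      scenario = r$label,
      tie_rule = r$network$name,
      rule_set = r$scenario$rule_set,
      n_nodes = r$metrics$graph$n_nodes,
      n_edges = r$metrics$graph$n_edges,
      density = r$metrics$graph$density,
      n_components = r$metrics$graph$n_components,
      stringsAsFactors = FALSE)
    if (nrow(r$summary)) {
      base <- merge(base, data.frame(
        scenario = r$label,
        label_counts = paste(sprintf("%s=%d", r$summary$label, r$summary$n),
                             collapse = "; "),
        stringsAsFactors = FALSE), by = "scenario")
    } else {
      base$label_counts <- ""
    }
    base
  }))
  rownames(summaries) <- NULL

  pairs <- if (is.null(reference)) {
    if (length(results) < 2) {
      matrix(integer(0), ncol = 2)
    } else {
      t(utils::combn(seq_along(results), 2))
    }
  } else {
    ri <- match(reference, labels)
    if (is.na(ri)) ts_validation_error(sprintf("unknown reference scenario '%s'",
                                               reference))
    cbind(ri, setdiff(seq_along(results), ri))
  }
  comparisons <- lapply(seq_len(nrow(pairs)), function(k) {
    compare_scenarios(results[[pairs[k, 1]]], results[[pairs[k, 2]]])
  })

  comp_df <- do.call(rbind, lapply(comparisons, function(cmp) {
    base <- data.frame(a = cmp$a, b = cmp$b, edge_jaccard = cmp$edge_jaccard,
                       n_edges_a = cmp$n_edges_a, n_edges_b = cmp$n_edges_b,
                       stringsAsFactors = FALSE)
    if (nrow(cmp$labels)) {
      merge(base, cbind(a = cmp$a, b = cmp$b, cmp$labels),
            by = c("a", "b"))
    } else {
      cbind(base, label = NA_character_, both = NA_integer_,
            only_a = NA_integer_, only_b = NA_integer_,
            neither = NA_integer_, agreement = NA_real_, kappa = NA_real_,
            kappa_degenerate = NA)
    }
  }))
  if (is.null(comp_df)) {
    comp_df <- data.frame(a = character(0), b = character(0),
                          edge_jaccard = numeric(0))
  }
  rownames(comp_df) <- NULL

  structure(list(
    scenarios = summaries,
    comparisons = comp_df,
    comparison_objects = comparisons
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d scenario(s), %d pairwise comparison(s)\n",
              nrow(x$scenarios), length(x$comparison_objects)))
  print(x$scenarios[, c("scenario", "n_nodes", "n_edges", "density",
                        "label_counts")], row.names = FALSE)
  invisible(x)
}

#' Write a sensitivity report to disk
#'
#' Emits the machine-readable report as JSON plus flat CSV tables
#' (`scenarios.csv`, `comparisons.csv`) under `dir`.
#'
#' @param report A `sensitivity_report`.
#' @param dir Output directory (created if needed).
#' @param provenance Optional named list recorded verbatim in the JSON
#'   (e.g. seed, rule digests, tool version).
#' @return Invisibly, the path of the JSON file.
#' @export
write_sensitivity_report <- function(report, dir, provenance = list()) {
  stopifnot(inherits(report, "sensitivity_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$scenarios, file.path(dir, "scenarios.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  payload <- list(
    tool = list(package = "tiescope",
                version = as.character(utils::packageVersion("tiescope"))),
    provenance = provenance,
    scenarios = report$scenarios,
    comparisons = report$comparisons
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}
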