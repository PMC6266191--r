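#' Parse rule definitions from structured config
#'
#' Rule files are YAML documents with two optional top-level keys,
#' `tie_rules` and `characteristic_rules`, each a list of named rule
#' fragments. Unknown keys anywhere are errors, not silently ignored, so a
#' typo cannot quietly change a definition.
#'
#' Tie-rule fragment keys: `name`, `reciprocity`, `min_each_weight`,
#' `min_sum_weight`, `min_mean_weight`, `output_weighting`.
#' Characteristic-rule fragment keys: `name`, optional `set` (a grouping
#' label used by [scenario_rule_sets()]), and `clauses`: a list of clauses,
#' each clause a list of conditions with keys `source`, `comparator`,
#' `threshold`, optional `gender`.
#'
#' @param fragment A named list (one already-parsed rule fragment).
#' @return A [tie_rule()] / [characteristic_rule()].
#' @export
parse_tie_rule <- function(fragment) {
  known <- c("name", "reciprocity", "min_each_weight", "min_sum_weight",
             "min_mean_weight", "output_weighting")
  unknown <- setdiff(names(fragment), known)
  if (length(unknown)) {
    ts_schema_error(sprintf("unknown tie-rule key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  if (is.null(fragment$name)) ts_schema_error("tie rule fragment lacks a name")
  tie_rule(
    name = fragment$name,
    reciprocity = fragment$reciprocity %||% TRUE,
    min_each_weight = fragment$min_each_weight,
    min_sum_weight = fragment$min_sum_weight,
    min_mean_weight = fragment$min_mean_weight,
    output_weighting = fragment$output_weighting %||% "dichotomous"
  )
}

#' @rdname parse_tie_rule
#' @export
parse_characteristic_rule <- function(fragment) {
  known <- c("name", "set", "clauses")
  unknown <- setdiff(names(fragment), known)
  if (length(unknown)) {
    ts_schema_error(sprintf("unknown characteristic-rule key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  if (is.null(fragment$name)) {
    ts_schema_error("characteristic rule fragment lacks a name")
  }
  if (is.null(fragment$clauses)) {
    ts_schema_error(sprintf("rule '%s' lacks clauses", fragment$name))
  }
  clauses <- lapply(fragment$clauses, function(clause) {
    if (!is.list(clause)) {
      ts_schema_error("each clause must be a list of conditions")
    }
    # YAML gives a bare condition map when a clause has one condition
    if (!is.null(names(clause)) && "source" %in% names(clause)) {
      clause <- list(clause)
    }
    lapply(clause, function(cond) {
      known_c <- c("source", "comparator", "threshold", "gender")
      unknown_c <- setdiff(names(cond), known_c)
      if (length(unknown_c)) {
        ts_schema_error(sprintf("unknown condition key(s): %s",
                                paste(unknown_c, collapse = ", ")))
      }
      score_condition(
        source = cond$source %||% ts_schema_error("condition lacks a source"),
        comparator = cond$comparator %||% "ge",
        threshold = cond$threshold %||% ts_schema_error("condition lacks a threshold"),
        gender = cond$gender %||% "any"
      )
    })
  })
  rule <- characteristic_rule(fragment$name, clauses)
  attr(rule, "set") <- fragment$set
  rule
}

#' Read a rule file
#'
#' Reads a YAML rule document (see [parse_tie_rule()] for the schema) and
#' returns both rule families.
#'
#' @param path Path to the YAML file.
#' @return List with `tie_rules` (named by rule name) and
#'   `characteristic_rules` (named list, names from the optional `set`
#'   key falling back to the rule name).
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) ts_schema_error(sprintf("rule file not found: %s", path))
  doc <- yaml::read_yaml(path)
  unknown <- setdiff(names(doc), c("tie_rules", "characteristic_rules"))
  if (length(unknown)) {
    ts_schema_error(sprintf("unknown top-level key(s) in rule file: %s",
                            paste(unknown, collapse = ", ")))
  }
  ties <- lapply(doc$tie_rules %||% list(), parse_tie_rule)
  names(ties) <- vapply(ties, function(r) r$name, character(1))
  if (anyDuplicated(names(ties))) {
    ts_schema_error("duplicate tie-rule names in rule file")
  }
  chars <- lapply(doc$characteristic_rules %||% list(), parse_characteristic_rule)
  if (length(chars)) {
    names(chars) <- vapply(chars, function(r) attr(r, "set") %||% r$name,
                           character(1))
  }
  list(tie_rules = ties, characteristic_rules = chars)
}

#' Group characteristic rules into scenario rule sets
#'
#' A scenario pairs one tie rule with one *set* of characteristic rules
#' (for instance, one binge-drinker definition together with the
#' network-conditioned labels that depend on it). Rules carrying the same
#' `set` attribute are grouped; rules without one form singleton sets.
#'
#' @param characteristic_rules Named list of `characteristic_rule` objects;
#'   names are the set labels.
#' @return Named list of characteristic-rule lists.
#' @export
scenario_rule_sets <- function(characteristic_rules) {
  if (length(characteristic_rules) == 0) return(list())
  labels <- names(characteristic_rules)
  if (is.null(labels) || any(!nzchar(labels))) {
    ts_schema_error("characteristic rules must be a named list")
  }
  sets <- split(unname(characteristic_rules), labels)
  sets[unique(labels)]
}
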