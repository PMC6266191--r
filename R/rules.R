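#' Declare a tie rule
#'
#' A tie rule states when a social tie exists between two individuals given
#' the two directed roster ratings of their dyad (each on the 1-5 contact
#' scale). All set conditions are conjunctive: reciprocity (both directions
#' mentioned), a minimum for each direction's weight, a minimum for the sum
#' of the two weights, and/or a minimum for their mean. At least one of the
#' three weight conditions must be set.
#'
#' `output_weighting` controls the weight attached to derived edges:
#' `"dichotomous"` (1 for every tie, the usual choice for analysis),
#' or the `"min"`, `"mean"` or `"sum"` of the two directed weights.
#'
#' @param name Rule name; becomes the derived network's name.
#' @param reciprocity Require both directions to be present (`TRUE` by
#'   default: friendship needs reciprocity).
#' @param min_each_weight Minimum weight required of each direction (1-5),
#'   or `NULL`.
#' @param min_sum_weight Minimum for the sum of the two weights (2-10),
#'   or `NULL`.
#' @param min_mean_weight Minimum for the mean of the two weights (1-5,
#'   may be fractional), or `NULL`.
#' @param output_weighting Edge-weight scheme for derived networks.
#' @return An object of class `tie_rule`.
#' @examples
#' # "strong relationship": reciprocal, both directions rated 4 or 5
#' tie_rule("strong", reciprocity = TRUE, min_each_weight = 4)
#' @export
tie_rule <- function(name,
                     reciprocity = TRUE,
                     min_each_weight = NULL,
                     min_sum_weight = NULL,
                     min_mean_weight = NULL,
                     output_weighting = c("dichotomous", "min", "mean", "sum")) {
  output_weighting <- match.arg(output_weighting)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    ts_schema_error("tie rule needs a non-empty name")
  }
  if (!is_flag(reciprocity)) ts_schema_error("reciprocity must be TRUE or FALSE")
  if (is.null(min_each_weight) && is.null(min_sum_weight) &&
      is.null(min_mean_weight)) {
    ts_schema_error(sprintf(
      "empty rule '%s': at least one of min_each_weight, min_sum_weight, min_mean_weight must be set",
      name))
  }
  chk <- function(x, what, lo, hi) {
    if (is.null(x)) return(NULL)
    if (!is_scalar_number(x) || x < lo || x > hi) {
      ts_schema_error(sprintf("%s must be a number in [%s, %s], got %s",
                              what, lo, hi, deparse(x)))
    }
    x
  }
  structure(list(
    name = name,
    reciprocity = reciprocity,
    min_each_weight = chk(min_each_weight, "min_each_weight", 1, 5),
    min_sum_weight = chk(min_sum_weight, "min_sum_weight", 2, 10),
    min_mean_weight = chk(min_mean_weight, "min_mean_weight", 1, 5),
    output_weighting = output_weighting
  ), class = "tie_rule")
}

#' @export
print.tie_rule <- function(x, ...) {
  conds <- c(
    if (x$reciprocity) "reciprocal",
    if (!is.null(x$min_each_weight)) sprintf("each weight >= %s", x$min_each_weight),
    if (!is.null(x$min_sum_weight)) sprintf("weight sum >= %s", x$min_sum_weight),
    if (!is.null(x$min_mean_weight)) sprintf("weight mean >= %s", x$min_mean_weight)
  )
  cat(sprintf("<tie_rule> %s: %s (edges: %s)\n", x$name,
              paste(conds, collapse = " AND "), x$output_weighting))
  invisible(x)
}

#' Evaluate a tie rule on one dyad
#'
#' Applies a [tie_rule()] to the two directed weights of a dyad and returns
#' the verdict together with an explanation trace recording every condition
#' evaluated, its observed value, threshold and outcome.
#'
#' A missing direction (`NA`) fails reciprocity; under a non-reciprocal
#' rule it contributes 0 to the each/sum/mean conditions, and a dyad with
#' both directions missing is never a tie.
#'
#' @param rule A `tie_rule`.
#' @param weight_ab,weight_ba The two directed weights (1-5) or `NA`.
#' @param subject Optional pair of ids for the explanation trace.
#' @return List with elements `verdict` (logical) and `explanation`
#'   (class `explanation`).
#' @examples
#' strong <- tie_rule("strong", min_each_weight = 4)
#' evaluate_tie(strong, 4, 5)$verdict   # TRUE
#' evaluate_tie(strong, 4, 3)$verdict   # FALSE: one direction below 4
#' evaluate_tie(strong, 5, NA)$verdict  # FALSE: reciprocity fails
#' @export
evaluate_tie <- function(rule, weight_ab, weight_ba, subject = c("a", "b")) {
  stopifnot(inherits(rule, "tie_rule"))
  for (w in c(weight_ab, weight_ba)[!is.na(c(weight_ab, weight_ba))]) {
    if (!(w %in% 1:5)) ts_validation_error(sprintf("weight %s outside 1-5", w))
  }
  wa <- ifelse(is.na(weight_ab), 0, weight_ab)
  wb <- ifelse(is.na(weight_ba), 0, weight_ba)
  checks <- list()
  add <- function(condition, observed, threshold, satisfied) {
    checks[[length(checks) + 1L]] <<- data.frame(
      condition = condition,
      observed = as.numeric(observed),
      threshold = as.numeric(threshold),
      satisfied = satisfied,
      stringsAsFactors = FALSE)
  }
  if (rule$reciprocity) {
    both <- !is.na(weight_ab) && !is.na(weight_ba)
    add("reciprocity: both directions mentioned",
        sum(!is.na(c(weight_ab, weight_ba))), 2, both)
  } else {
    add("mention: at least one direction present",
        sum(!is.na(c(weight_ab, weight_ba))), 1,
        !is.na(weight_ab) || !is.na(weight_ba))
  }
  if (!is.null(rule$min_each_weight)) {
    add(sprintf("each weight >= %s", rule$min_each_weight),
        min(wa, wb), rule$min_each_weight,
        min(wa, wb) >= rule$min_each_weight)
  }
  if (!is.null(rule$min_sum_weight)) {
    add(sprintf("weight sum >= %s", rule$min_sum_weight),
        wa + wb, rule$min_sum_weight, wa + wb >= rule$min_sum_weight)
  }
  if (!is.null(rule$min_mean_weight)) {
    add(sprintf("weight mean >= %s", rule$min_mean_weight),
        (wa + wb) / 2, rule$min_mean_weight,
        (wa + wb) / 2 >= rule$min_mean_weight)
  }
  checks <- do.call(rbind, checks)
  verdict <- all(checks$satisfied)
  expl <- structure(list(
    subject = subject,
    rule = rule$name,
    structure = "all",    # tie-rule conditions are conjunctive
    checks = checks,
    verdict = verdict
  ), class = "explanation")
  list(verdict = verdict, explanation = expl)
}

# Vectorised core used by derive_network: same semantics as evaluate_tie
# without building explanation objects.
evaluate_tie_many <- function(rule, weight_ab, weight_ba) {
  wa <- ifelse(is.na(weight_ab), 0, weight_ab)
  wb <- ifelse(is.na(weight_ba), 0, weight_ba)
  ok <- if (rule$reciprocity) {
    !is.na(weight_ab) & !is.na(weight_ba)
  } else {
    !is.na(weight_ab) | !is.na(weight_ba)
  }
  if (!is.null(rule$min_each_weight)) {
    ok <- ok & pmin(wa, wb) >= rule$min_each_weight
  }
  if (!is.null(rule$min_sum_weight)) {
    ok <- ok & (wa + wb) >= rule$min_sum_weight
  }
  if (!is.null(rule$min_mean_weight)) {
    ok <- ok & (wa + wb) / 2 >= rule$min_mean_weight
  }
  ok
}

#' Declare a score condition
#'
#' One atomic condition of a characteristic rule: compare a score source
#' against a threshold, optionally restricted to one gender. Score sources
#' are `"audit_total"` (AUDIT sum, 0-40), `"audit_c"` (items 1-3, 0-12),
#' `extra:<name>` for an extra attribute column, or `metric:<name>` for a
#' node-level network measure (`in_degree`, `out_degree`, `degree`,
#' `betweenness`, `closeness`) of the scenario's own derived network.
#'
#' @param source Score source string as above.
#' @param comparator One of `"ge"`, `"gt"`, `"le"`, `"lt"`.
#' @param threshold Finite numeric threshold.
#' @param gender `"any"` (default), `"male"` or `"female"`: the condition
#'   (and with it its clause) only applies to matching individuals; it does
#'   not change the truth value for others.
#' @return An object of class `score_condition`.
#' @export
score_condition <- function(source, comparator = "ge",
                            threshold, gender = "any") {
  if (!is.character(comparator) || length(comparator) != 1L ||
      !(comparator %in% c("ge", "gt", "le", "lt"))) {
    ts_schema_error(sprintf(
      "comparator must be one of ge, gt, le, lt (got '%s')",
      paste(comparator, collapse = ", ")))
  }
  if (!is.character(gender) || length(gender) != 1L ||
      !(gender %in% c("any", "male", "female"))) {
    ts_schema_error("gender scope must be one of any, male, female")
  }
  if (!is.character(source) || length(source) != 1L || !nzchar(source)) {
    ts_schema_error("score source must be a non-empty string")
  }
  plain <- c("audit_total", "audit_c")
  if (!(source %in% plain) && !grepl("^(extra|metric):.+", source)) {
    ts_schema_error(sprintf(
      "unknown score source '%s' (use audit_total, audit_c, extra:<name> or metric:<name>)",
      source))
  }
  if (!is_scalar_number(threshold)) {
    ts_schema_error("threshold must be a finite number")
  }
  structure(list(source = source, comparator = comparator,
                 threshold = threshold, gender = gender),
            class = "score_condition")
}

#' Declare a characteristic rule
#'
#' A characteristic rule assigns a derived label (such as "binge_drinker",
#' "popular" or "bad_influence") to individuals. Its semantics are a
#' disjunction of conjunctions: the label applies if and only if at least
#' one clause applies, where a clause applies when its gender scope matches
#' the individual and all its conditions are satisfied. Richer boolean
#' nesting is deliberately rejected: OR-of-ANDs covers published cut-off
#' definitions while keeping explanations readable.
#'
#' @param name The label this rule derives.
#' @param clauses A list of clauses; each clause is a list of
#'   [score_condition()] objects (a conjunction).
#' @return An object of class `characteristic_rule`.
#' @examples
#' # Finnish gender-stratified binge-drinker cut-offs on AUDIT-C
#' characteristic_rule("binge_drinker", list(
#'   list(score_condition("audit_c", "gt", 7, gender = "male")),
#'   list(score_condition("audit_c", "gt", 4, gender = "female"))
#' ))
#' @export
characteristic_rule <- function(name, clauses) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    ts_schema_error("characteristic rule needs a non-empty name")
  }
  if (!is.list(clauses) || length(clauses) == 0) {
    ts_schema_error(sprintf("rule '%s' needs at least one clause", name))
  }
  for (cl in clauses) {
    if (!is.list(cl) || length(cl) == 0 ||
        !all(vapply(cl, inherits, logical(1), "score_condition"))) {
      ts_schema_error(sprintf(
        "rule '%s': each clause must be a non-empty list of score conditions",
        name))
    }
  }
  structure(list(name = name, clauses = clauses),
            class = "characteristic_rule")
}

#' @export
print.characteristic_rule <- function(x, ...) {
  cat(sprintf("<characteristic_rule> %s\n", x$name))
  for (i in seq_along(x$clauses)) {
    conds <- vapply(x$clauses[[i]], function(co) {
      g <- if (co$gender == "any") "" else sprintf(" [%s]", co$gender)
      sprintf("%s %s %s%s", co$source, comparator_symbol(co$comparator),
              co$threshold, g)
    }, character(1))
    cat(sprintf("  clause %d: %s\n", i, paste(conds, collapse = " AND ")))
  }
  invisible(x)
}

# Resolve one score source for one individual. `scores` is the named list
# from individual_scores(); `metrics` a named list/row of node metrics.
resolve_source <- function(source, scores, metrics) {
  if (source %in% c("audit_total", "audit_c")) {
    v <- scores[[source]]
  } else if (startsWith(source, "extra:")) {
    v <- scores[[sub("^extra:", "", source)]]
  } else if (startsWith(source, "metric:")) {
    v <- metrics[[sub("^metric:", "", source)]]
  } else {
    v <- NULL
  }
  if (is.null(v) || length(v) != 1L || is.na(v)) {
    ts_eval_error(sprintf("score source '%s' cannot be resolved for this individual",
                          source))
  }
  as.numeric(v)
}

#' Classify one individual under a characteristic rule
#'
#' Evaluates a [characteristic_rule()] for a single individual, resolving
#' score sources against the individual's instrument scores and, for
#' `metric:` sources, against a caller-supplied map of node-level network
#' measures. Returns the verdict with a full explanation trace: every
#' evaluated clause and condition, the observed value, the threshold and
#' the outcome. Clauses whose gender scope does not match the individual
#' are recorded as not applicable.
#'
#' @param rule A `characteristic_rule`.
#' @param individual A list or one-row data frame with at least `id` and
#'   `gender`, plus `audit_q1`..`audit_q10` and/or extra attribute entries.
#' @param metrics Optional named list of node metrics for this individual
#'   (e.g. `list(in_degree = 5, degree = 3)`).
#' @return List with `verdict` and `explanation`.
#' @export
classify_individual <- function(rule, individual, metrics = list()) {
  stopifnot(inherits(rule, "characteristic_rule"))
  individual <- as.list(individual)
  scores <- list()
  audit_cols <- paste0("audit_q", 1:10)
  if (all(audit_cols %in% names(individual))) {
    items <- as.integer(unlist(individual[audit_cols]))
    if (!anyNA(items)) {
      scores$audit_total <- sum(items)
      scores$audit_c <- sum(items[1:3])
    }
  }
  for (nm in setdiff(names(individual), c(audit_cols, "id", "classroom_id", "gender"))) {
    v <- individual[[nm]]
    if (is.numeric(v) && length(v) == 1L) scores[[nm]] <- v
  }
  classify_with_scores(rule, individual$gender %||% "unknown",
                       scores, metrics, subject = individual$id %||% "?")
}

classify_with_scores <- function(rule, gender, scores, metrics, subject = "?") {
  rows <- list()
  verdict <- FALSE
  for (ci in seq_along(rule$clauses)) {
    clause <- rule$clauses[[ci]]
    scopes <- vapply(clause, function(co) co$gender, character(1))
    applicable <- all(scopes == "any" | scopes == gender)
    clause_true <- applicable
    for (co in clause) {
      if (!applicable) {
        rows[[length(rows) + 1L]] <- data.frame(
          clause = ci,
          condition = sprintf("%s %s %s%s", co$source,
                              comparator_symbol(co$comparator), co$threshold,
                              if (co$gender == "any") "" else sprintf(" [%s]", co$gender)),
          observed = NA_real_, threshold = co$threshold,
          applicable = FALSE, satisfied = NA,
          stringsAsFactors = FALSE)
        next
      }
      obs <- resolve_source(co$source, scores, metrics)
      sat <- apply_comparator(co$comparator, obs, co$threshold)
      clause_true <- clause_true && sat
      rows[[length(rows) + 1L]] <- data.frame(
        clause = ci,
        condition = sprintf("%s %s %s%s", co$source,
                            comparator_symbol(co$comparator), co$threshold,
                            if (co$gender == "any") "" else sprintf(" [%s]", co$gender)),
        observed = obs, threshold = co$threshold,
        applicable = TRUE, satisfied = sat,
        stringsAsFactors = FALSE)
    }
    verdict <- verdict || clause_true
  }
  checks <- do.call(rbind, rows)
  expl <- structure(list(
    subject = subject,
    rule = rule$name,
    structure = "any_clause_all_conditions",
    checks = checks,
    verdict = verdict
  ), class = "explanation")
  list(verdict = verdict, explanation = expl)
}

#' Re-evaluate an explanation trace
#'
#' Recomputes a verdict purely from the observations recorded in an
#' explanation, without consulting the original data. Used to audit that
#' every stored verdict follows from its own trace.
#'
#' @param x An `explanation`.
#' @return Logical verdict implied by the recorded checks.
#' @export
reevaluate_explanation <- function(x) {
  stopifnot(inherits(x, "explanation"))
  ch <- x$checks
  if (identical(x$structure, "all")) {
    all(ch$satisfied)
  } else {
    any(vapply(split(ch, ch$clause), function(cl) {
      all(cl$applicable) && all(cl$satisfied)
    }, logical(1)))
  }
}

#' @export
print.explanation <- function(x, ...) {
  cat(sprintf("<explanation> rule '%s' on %s -> %s\n", x$rule,
              paste(x$subject, collapse = "--"),
              if (x$verdict) "TRUE" else "FALSE"))
  print(x$checks, row.names = FALSE)
  invisible(x)
}
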