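#' Preset tie rules
#'
#' The named tie definitions used throughout the package's examples:
#' the reciprocal threshold family on the 1-5 contact scale ("any contact"
#' weights >1, "some contact" >2, "strong friendship" >3, "best friends"
#' >4; with integer weights >k is written as each weight >= k+1), all
#' dichotomised.
#'
#' @return Named list of [tie_rule()] objects, laxest first.
#' @export
preset_tie_rules <- function() {
  list(
    any_contact = tie_rule("any_contact", reciprocity = TRUE, min_each_weight = 2),
    some_contact = tie_rule("some_contact", reciprocity = TRUE, min_each_weight = 3),
    strong_friendship = tie_rule("strong_friendship", reciprocity = TRUE,
                                 min_each_weight = 4),
    best_friends = tie_rule("best_friends", reciprocity = TRUE, min_each_weight = 5)
  )
}

#' Preset characteristic rules
#'
#' Published binge-drinker cut-offs on the AUDIT-C consumption subscore
#' (AUDIT items 1-3), plus network-conditioned labels:
#'
#' * `binge_finnish`: gender-stratified — AUDIT-C > 7 for males,
#'   > 4 for females (equivalently >= 8 and >= 5 on integer scores).
#' * `binge_finnish_alt`: the ">= 7 or 8" male variant written with
#'   >= 7 (and >= 5 for females).
#' * `binge_spanish`: AUDIT-C > 4 regardless of gender.
#' * `binge_spanish_ge`: the ">= 4" reading of the Spanish cut-off.
#' * `popular`: named by four or more peers — raw in-degree >= 4.
#' * `bad_influence`: a binge drinker (Spanish cut-off) with many friends
#'   in the scenario's derived network (degree >= 4).
#'
#' Comparators are kept exactly as published; nothing is silently
#' normalised, so competing phrasings of the "same" cut-off can be run
#' side by side.
#'
#' @return Named list of [characteristic_rule()] objects.
#' @export
preset_characteristic_rules <- function() {
  list(
    binge_finnish = characteristic_rule("binge_drinker", list(
      list(score_condition("audit_c", "gt", 7, gender = "male")),
      list(score_condition("audit_c", "gt", 4, gender = "female"))
    )),
    binge_finnish_alt = characteristic_rule("binge_drinker", list(
      list(score_condition("audit_c", "ge", 7, gender = "male")),
      list(score_condition("audit_c", "ge", 5, gender = "female"))
    )),
    binge_spanish = characteristic_rule("binge_drinker", list(
      list(score_condition("audit_c", "gt", 4, gender = "any"))
    )),
    binge_spanish_ge = characteristic_rule("binge_drinker", list(
      list(score_condition("audit_c", "ge", 4, gender = "any"))
    )),
    popular = characteristic_rule("popular", list(
      list(score_condition("metric:in_degree", "ge", 4, gender = "any"))
    )),
    bad_influence = characteristic_rule("bad_influence", list(
      list(score_condition("audit_c", "gt", 4, gender = "any"),
           score_condition("metric:degree", "ge", 4, gender = "any"))
    ))
  )
}
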