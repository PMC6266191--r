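#' AUDIT and AUDIT-C scoring
#'
#' The Alcohol Use Disorders Identification Test (AUDIT) is a 10-item
#' screening instrument. Items 1-8 score 0-4; items 9 and 10 offer only
#' three response options scoring 0, 2 or 4. `score_audit()` returns the
#' total score (0-40). `score_audit_c()` returns the consumption subscore
#' AUDIT-C, the sum of items 1-3 only (0-12).
#'
#' @param items Integer vector of exactly 10 already-scored AUDIT items,
#'   in questionnaire order.
#' @return A single integer score.
#' @examples
#' score_audit(c(1, 2, 3, 0, 0, 0, 0, 0, 0, 0)) # 6
#' score_audit_c(c(2, 1, 3, 4, 4, 4, 4, 4, 4, 4)) # 6: items 4-10 ignored
#' @export
score_audit <- function(items) {
  validate_audit_items(items)
  as.integer(sum(items))
}

#' @rdname score_audit
#' @export
score_audit_c <- function(items) {
  validate_audit_items(items)
  as.integer(sum(items[1:3]))
}

validate_audit_items <- function(items) {
  if (length(items) != 10L) {
    ts_validation_error(sprintf(
      "AUDIT requires exactly 10 item scores, got %d", length(items)
    ))
  }
  if (anyNA(items)) {
    ts_validation_error("AUDIT item scores contain missing values")
  }
  if (!is.numeric(items) || any(items != as.integer(items))) {
    ts_validation_error("AUDIT item scores must be integers")
  }
  bad18 <- which(!(items[1:8] %in% 0:4))
  if (length(bad18)) {
    ts_validation_error(sprintf(
      "AUDIT items 1-8 must score 0-4; item %d has value %s",
      bad18[1], items[bad18[1]]
    ))
  }
  bad910 <- which(!(items[9:10] %in% c(0L, 2L, 4L)))
  if (length(bad910)) {
    ts_validation_error(sprintf(
      "AUDIT items 9-10 must score 0, 2 or 4; item %d has value %s",
      8L + bad910[1], items[8L + bad910[1]]
    ))
  }
  invisible(items)
}

# Printed response options per AUDIT question and their scores.
# Items 9 and 10 have only three options (0 / 2 / 4).
audit_option_table <- function() {
  freq <- c("Never" = 0L, "Less than monthly" = 1L, "Monthly" = 2L,
            "Weekly" = 3L, "Daily or almost daily" = 4L)
  yesno <- c("No" = 0L, "Yes, but not in the last year" = 2L,
             "Yes, in the last year" = 4L)
  list(
    q1 = c("Never" = 0L, "Monthly or less" = 1L, "2-4 times a month" = 2L,
           "2-3 times a week" = 3L, "4 or more times a week" = 4L),
    q2 = c("0-2" = 0L, "3 or 4" = 1L, "5 or 6" = 2L, "7-9" = 3L,
           "10 or more" = 4L),
    q3 = freq, q4 = freq, q5 = freq, q6 = freq, q7 = freq, q8 = freq,
    q9 = yesno, q10 = yesno
  )
}

#' Map an AUDIT response text to its score
#'
#' Field data sometimes arrive as the verbatim response options rather than
#' pre-scored integers. This maps the printed option text of one AUDIT
#' question to its score. Matching is lenient about case, surrounding
#' whitespace and dash variants (en dash vs hyphen).
#'
#' @param question_index AUDIT question number, 1-10.
#' @param response_text One of the printed response options for that question.
#' @return The integer score for that option.
#' @examples
#' map_audit_response_text(1, "2-4 times a month") # 2
#' map_audit_response_text(9, "Yes, but not in the last year") # 2
#' @export
map_audit_response_text <- function(question_index, response_text) {
  if (!is_scalar_number(question_index) || !(question_index %in% 1:10)) {
    ts_validation_error("question_index must be an integer in 1-10")
  }
  opts <- audit_option_table()[[question_index]]
  hit <- match(normalize_option_text(response_text),
               normalize_option_text(names(opts)))
  if (is.na(hit)) {
    ts_validation_error(sprintf(
      "unknown response '%s' for AUDIT question %d; valid options: %s",
      response_text, question_index,
      paste(sprintf("'%s'", names(opts)), collapse = ", ")
    ))
  }
  unname(opts[hit])
}

#' Roster contact scale
#'
#' The roster name-generator question ("How much time do you spend with each
#' of the following classmates?") offers five statements; each maps to the
#' contact weight used to quantify the relationship.
#'
#' @return Named integer vector: statement text -> weight 1-5.
#' @export
roster_contact_scale <- function() {
  c("We never spend time together."      = 1L,
    "We sometimes spend time together."  = 2L,
    "We spend quite a lot of time together." = 3L,
    "We are almost always together."     = 4L,
    "We are always together."            = 5L)
}
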