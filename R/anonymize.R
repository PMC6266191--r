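#' Pseudonymize a response set
#'
#' Replaces every individual id with an uninformative pseudonym,
#' consistently across the individuals table and the ratings. The mapping
#' is a bijection drawn from a permutation seeded by the study secret, so
#' the same secret over the same id set always yields the same
#' pseudonyms (re-runs are stable), while the pseudonyms themselves carry
#' no information about the originals. Network structure, and with it
#' every SNA measure, is invariant under the renaming.
#'
#' @param responses A `response_set`.
#' @param secret Study secret string salting the pseudonym permutation.
#' @return List with `responses` (pseudonymized `response_set`) and `map`
#'   (class `pseudonym_map`: data frame original -> pseudonym).
#' @export
anonymize <- function(responses, secret) {
  stopifnot(inherits(responses, "response_set"))
  if (!is.character(secret) || length(secret) != 1L) {
    ts_validation_error("secret must be a single string")
  }
  ids <- sort(responses$individuals$id)
  n <- length(ids)
  perm <- with_seed(string_seed(secret), sample.int(n))
  pseud <- sprintf("P%0*d", max(3L, nchar(n)), perm)
  map <- data.frame(original = ids, pseudonym = pseud,
                    stringsAsFactors = FALSE)
  lut <- stats::setNames(map$pseudonym, map$original)

  out <- responses
  out$individuals$id <- unname(lut[out$individuals$id])
  out$ratings$rater_id <- unname(lut[out$ratings$rater_id])
  out$ratings$ratee_id <- unname(lut[out$ratings$ratee_id])
  if (!is.null(out$missing_pairs)) {
    out$missing_pairs$rater_id <- unname(lut[out$missing_pairs$rater_id])
    out$missing_pairs$ratee_id <- unname(lut[out$missing_pairs$ratee_id])
  }
  out$metadata$anonymized <- TRUE
  list(responses = out, map = structure(map, class = c("pseudonym_map",
                                                       "data.frame")))
}

#' @export
print.pseudonym_map <- function(x, ...) {
  cat(sprintf("<pseudonym_map> %d id(s); keep this file out of reports\n",
              nrow(x)))
  invisible(x)
}
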