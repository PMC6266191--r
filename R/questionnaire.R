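#' Construct a response set
#'
#' A response set bundles the individuals table and the dyadic roster
#' ratings of one study. It is the validated input to everything else in
#' the package.
#'
#' @param individuals Data frame with columns `id`, `classroom_id`,
#'   `gender` (`"male"`/`"female"`; other values are carried through but
#'   gender-scoped classification clauses will never match them),
#'   `audit_q1`..`audit_q10` (optional; either all ten present per row or
#'   all `NA`), plus any number of extra numeric attribute columns
#'   (precomputed instrument totals such as a family-affluence score).
#' @param ratings Data frame with columns `rater_id`, `ratee_id`,
#'   `weight` (integer 1-5), one row per ordered pair at most.
#' @param metadata Optional list of free-form study metadata (study label,
#'   instrument names).
#' @param cross_classroom If `FALSE` (default), ratings crossing classroom
#'   boundaries are a validation error, matching a classroom roster design.
#' @param missing_policy What to do with within-classroom ordered pairs the
#'   rater did not rate. `"floor"` (default) imputes the scale floor,
#'   weight 1 ("We never spend time together."), with one warning giving
#'   the count; the roster question rates every classmate, so absence is
#'   read as the floor response. `"strict"` leaves the pair absent; tie
#'   rules then see a missing direction.
#' @return An object of class `response_set`.
#' @export
response_set <- function(individuals, ratings,
                         metadata = list(),
                         cross_classroom = FALSE,
                         missing_policy = c("floor", "strict")) {
  missing_policy <- match.arg(missing_policy)
  problems <- character(0)
  note <- function(msg) problems[[length(problems) + 1L]] <<- msg

  ind_req <- c("id", "classroom_id", "gender")
  miss <- setdiff(ind_req, names(individuals))
  if (length(miss)) {
    ts_schema_error(sprintf(
      "individuals table lacks required column(s): %s",
      paste(miss, collapse = ", ")
    ))
  }
  rat_req <- c("rater_id", "ratee_id", "weight")
  miss <- setdiff(rat_req, names(ratings))
  if (length(miss)) {
    ts_schema_error(sprintf(
      "ratings table lacks required column(s): %s",
      paste(miss, collapse = ", ")
    ))
  }

  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  ratings <- as.data.frame(ratings, stringsAsFactors = FALSE)
  individuals$id <- as.character(individuals$id)
  individuals$classroom_id <- as.character(individuals$classroom_id)
  individuals$gender <- as.character(individuals$gender)
  ratings$rater_id <- as.character(ratings$rater_id)
  ratings$ratee_id <- as.character(ratings$ratee_id)

  dup <- individuals$id[duplicated(individuals$id)]
  if (length(dup)) {
    note(sprintf("duplicate individual id(s): %s",
                 paste(unique(dup), collapse = ", ")))
  }

  audit_cols <- paste0("audit_q", 1:10)
  have_audit <- audit_cols %in% names(individuals)
  if (any(have_audit) && !all(have_audit)) {
    ts_schema_error(sprintf(
      "individuals table has only %d of the 10 audit_q columns",
      sum(have_audit)
    ))
  }
  if (all(have_audit)) {
    am <- as.matrix(individuals[audit_cols])
    storage.mode(am) <- "integer"
    for (i in seq_len(nrow(individuals))) {
      row <- am[i, ]
      if (all(is.na(row))) next   # AUDIT not administered to this individual
      ok <- tryCatch({ validate_audit_items(row); TRUE },
                     tiescope_validation_error = function(e) e)
      if (!isTRUE(ok)) {
        note(sprintf("individuals row %d (id %s): %s",
                     i, individuals$id[i], conditionMessage(ok)))
      }
    }
    individuals[audit_cols] <- as.data.frame(am)
  }

  # ratings validation, row by row so every malformed row is reported
  known <- individuals$id
  room <- stats::setNames(individuals$classroom_id, known)
  w <- suppressWarnings(as.numeric(ratings$weight))
  for (i in seq_len(nrow(ratings))) {
    a <- ratings$rater_id[i]; b <- ratings$ratee_id[i]
    if (!(a %in% known)) note(sprintf("ratings row %d: unknown rater id '%s'", i, a))
    if (!(b %in% known)) note(sprintf("ratings row %d: unknown ratee id '%s'", i, b))
    if (identical(a, b)) note(sprintf("ratings row %d: self-rating by '%s'", i, a))
    if (is.na(w[i]) || w[i] != as.integer(w[i]) || !(w[i] %in% 1:5)) {
      note(sprintf("ratings row %d: weight '%s' outside the 1-5 contact scale",
                   i, ratings$weight[i]))
    }
    if (!cross_classroom && a %in% known && b %in% known &&
        !identical(room[[a]], room[[b]])) {
      note(sprintf("ratings row %d: %s -> %s crosses classrooms (%s -> %s)",
                   i, a, b, room[[a]], room[[b]]))
    }
  }
  key <- paste(ratings$rater_id, ratings$ratee_id, sep = "\r")
  dup_rows <- which(duplicated(key))
  for (i in dup_rows) {
    note(sprintf("ratings row %d: duplicate rating for ordered pair %s -> %s",
                 i, ratings$rater_id[i], ratings$ratee_id[i]))
  }

  if (length(problems)) {
    ts_validation_error(paste(
      c(sprintf("%d problem(s) found in response data:", length(problems)),
        problems), collapse = "\n  "))
  }
  ratings$weight <- as.integer(w)

  extra <- setdiff(names(individuals), c(ind_req, audit_cols))

  rs <- structure(list(
    individuals = individuals,
    ratings = ratings,
    extra_attributes = extra,
    metadata = metadata,
    cross_classroom = cross_classroom,
    missing_policy = missing_policy
  ), class = "response_set")

  if (!cross_classroom) rs <- fill_missing_ratings(rs)
  rs
}

# Complete the roster: every ordered within-classroom pair should carry a
# rating. Under the "floor" policy absent pairs get weight 1 (with one
# warning); under "strict" they stay absent and are recorded.
fill_missing_ratings <- function(rs) {
  ind <- rs$individuals
  expected <- do.call(rbind, lapply(split(ind$id, ind$classroom_id), function(ids) {
    if (length(ids) < 2) return(NULL)
    g <- expand.grid(rater_id = ids, ratee_id = ids,
                     stringsAsFactors = FALSE)
    g[g$rater_id != g$ratee_id, ]
  }))
  if (is.null(expected)) return(rs)
  have <- paste(rs$ratings$rater_id, rs$ratings$ratee_id, sep = "\r")
  want <- paste(expected$rater_id, expected$ratee_id, sep = "\r")
  absent <- expected[!(want %in% have), , drop = FALSE]
  rownames(absent) <- NULL
  if (nrow(absent) == 0) return(rs)
  if (rs$missing_policy == "floor") {
    warning(sprintf(
      "%d unanswered roster pair(s) imputed as weight 1 ('never spend time together')",
      nrow(absent)), call. = FALSE)
    absent$weight <- 1L
    rs$ratings <- rbind(rs$ratings, absent)
    rownames(rs$ratings) <- NULL
    rs$n_imputed <- nrow(absent)
  } else {
    rs$missing_pairs <- absent
  }
  rs
}

#' Read a response set from delimited text files
#'
#' Reads the individuals and ratings tables and validates them into a
#' [response_set()]. The delimiter is auto-detected among comma, semicolon
#' and tab; files are expected UTF-8 with a header row. Every malformed
#' row is reported with its row number and reason.
#'
#' @param individuals_path Path to the individuals file (columns `id`,
#'   `classroom_id`, `gender`, optional `audit_q1`..`audit_q10`, extras).
#' @param ratings_path Path to the ratings edge list (columns `rater_id`,
#'   `ratee_id`, `weight`).
#' @inheritParams response_set
#' @return A validated `response_set`.
#' @export
read_response_set <- function(individuals_path, ratings_path,
                              metadata = list(),
                              cross_classroom = FALSE,
                              missing_policy = c("floor", "strict")) {
  individuals <- read_delimited(individuals_path)
  ratings <- read_delimited(ratings_path)
  response_set(individuals, ratings, metadata = metadata,
               cross_classroom = cross_classroom,
               missing_policy = missing_policy)
}

read_delimited <- function(path) {
  if (!file.exists(path)) {
    ts_validation_error(sprintf("file not found: %s", path))
  }
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  counts <- vapply(c(",", ";", "\t"), function(d) {
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE)))
  }, integer(1))
  sep <- c(",", ";", "\t")[which.max(counts)]
  if (max(counts) == 0) sep <- ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    encoding = "UTF-8", colClasses = NA)
}

#' Write a response set back to delimited text files
#'
#' Inverse of [read_response_set()]: writes the individuals and ratings
#' tables as comma-separated UTF-8 text. Reading the written files yields
#' an identical response set.
#'
#' @param rs A `response_set`.
#' @param individuals_path,ratings_path Output paths.
#' @return Invisibly, `rs`.
#' @export
write_response_set <- function(rs, individuals_path, ratings_path) {
  stopifnot(inherits(rs, "response_set"))
  utils::write.table(rs$individuals, individuals_path, sep = ",",
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  utils::write.table(rs$ratings, ratings_path, sep = ",",
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(rs)
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf(
    "<response_set> %d individuals in %d classroom(s), %d ratings\n",
    nrow(x$individuals), length(unique(x$individuals$classroom_id)),
    nrow(x$ratings)))
  if (length(x$extra_attributes)) {
    cat("  extra attributes:", paste(x$extra_attributes, collapse = ", "), "\n")
  }
  if (!is.null(x$n_imputed)) {
    cat(sprintf("  %d unanswered roster pair(s) imputed as weight 1\n",
                x$n_imputed))
  }
  invisible(x)
}

# Per-individual score resolution used by the classification engine.
# Returns a named list: audit_total, audit_c, every extra attribute.
individual_scores <- function(rs) {
  audit_cols <- paste0("audit_q", 1:10)
  out <- vector("list", nrow(rs$individuals))
  has_audit <- all(audit_cols %in% names(rs$individuals))
  for (i in seq_len(nrow(rs$individuals))) {
    sc <- list()
    if (has_audit) {
      items <- as.integer(rs$individuals[i, audit_cols])
      if (!anyNA(items)) {
        sc$audit_total <- sum(items)
        sc$audit_c <- sum(items[1:3])
      }
    }
    for (a in rs$extra_attributes) {
      v <- rs$individuals[[a]][i]
      if (is.numeric(v) && !is.na(v)) sc[[a]] <- v
    }
    out[[i]] <- sc
  }
  names(out) <- rs$individuals$id
  out
}
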