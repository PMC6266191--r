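#' Configuration for the synthetic classroom-study generator
#'
#' The generator emulates the shape of a roster-based classroom study of
#' adolescent alcohol consumption: several classrooms of 20-30 students,
#' gendered nodes, a planted partition of each classroom into friendship
#' groups that drives the contact ratings, and AUDIT responses whose
#' distribution is shifted by a drinking propensity mixing a group-level
#' and an individual-level component.
#'
#' Defaults mirror a study of nine classrooms of 23-25 students
#' (about 214 students in total). Within-group contact ratings
#' concentrate on the high end of the 1-5 scale and between-group ratings
#' on the low end, so friendship-threshold sensitivity is visible in the
#' derived networks; `drinking_homophily` interpolates between purely
#' individual drinking propensities (0) and purely group-level ones (1).
#'
#' @param n_classrooms Number of classrooms.
#' @param students_per_classroom Integer or inclusive range (length-2
#'   vector) of students per classroom.
#' @param female_proportion Probability a student is female.
#' @param n_groups_per_classroom Friendship groups planted per classroom.
#' @param within_group_rating,between_group_rating Probability vectors
#'   over contact weights 1-5 for within/between-group ordered dyads.
#' @param rating_reciprocity_noise Probability that the second direction
#'   of a dyad is redrawn independently instead of copying the first.
#' @param drinking_homophily In `[0,1]`: weight of the group propensity in
#'   each student's drinking propensity.
#' @param audit_item_base,audit_item_elevated Lists of 10 probability
#'   vectors (items 1-8 over scores 0-4, items 9-10 over 0/2/4) for
#'   low-propensity and high-propensity respondents; each student's item
#'   distribution is the propensity-weighted mixture, with the shift
#'   damped on items 4-10 so it acts mainly on the consumption items 1-3.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_classrooms = 9,
                         students_per_classroom = c(23, 25),
                         female_proportion = 0.5,
                         n_groups_per_classroom = 4,
                         within_group_rating = c(0.05, 0.10, 0.15, 0.30, 0.40),
                         between_group_rating = c(0.80, 0.12, 0.05, 0.02, 0.01),
                         rating_reciprocity_noise = 0.15,
                         drinking_homophily = 0.6,
                         audit_item_base = default_audit_base(),
                         audit_item_elevated = default_audit_elevated(),
                         seed = 1L) {
  chk_prob <- function(p, what, len) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      ts_schema_error(sprintf(
        "%s must be a length-%d probability vector summing to 1", what, len))
    }
  }
  if (!is_scalar_number(n_classrooms) || n_classrooms < 1) {
    ts_schema_error("n_classrooms must be a positive integer")
  }
  if (!(length(students_per_classroom) %in% 1:2) ||
      any(students_per_classroom < 2)) {
    ts_schema_error("students_per_classroom must be an integer or range >= 2")
  }
  for (p in c("female_proportion", "rating_reciprocity_noise",
              "drinking_homophily")) {
    v <- get(p)
    if (!is_scalar_number(v) || v < 0 || v > 1) {
      ts_schema_error(sprintf("%s must lie in [0, 1]", p))
    }
  }
  chk_prob(within_group_rating, "within_group_rating", 5)
  chk_prob(between_group_rating, "between_group_rating", 5)
  stopifnot(length(audit_item_base) == 10, length(audit_item_elevated) == 10)
  for (i in 1:10) {
    len <- if (i <= 8) 5 else 3
    chk_prob(audit_item_base[[i]], sprintf("audit_item_base[[%d]]", i), len)
    chk_prob(audit_item_elevated[[i]], sprintf("audit_item_elevated[[%d]]", i), len)
  }
  structure(list(
    n_classrooms = as.integer(n_classrooms),
    students_per_classroom = as.integer(students_per_classroom),
    female_proportion = female_proportion,
    n_groups_per_classroom = as.integer(n_groups_per_classroom),
    within_group_rating = within_group_rating,
    between_group_rating = between_group_rating,
    rating_reciprocity_noise = rating_reciprocity_noise,
    drinking_homophily = drinking_homophily,
    audit_item_base = audit_item_base,
    audit_item_elevated = audit_item_elevated,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @rdname synth_config
#' @export
default_audit_base <- function() {
  freq_low <- c(0.80, 0.12, 0.05, 0.02, 0.01)
  list(
    c(0.45, 0.30, 0.15, 0.07, 0.03),  # q1 drinking frequency
    c(0.55, 0.25, 0.12, 0.05, 0.03),  # q2 typical quantity
    c(0.60, 0.22, 0.10, 0.05, 0.03),  # q3 heavy-episode frequency
    freq_low, freq_low, freq_low, freq_low, freq_low,  # q4-q8
    c(0.90, 0.07, 0.03),              # q9 over scores 0/2/4
    c(0.90, 0.07, 0.03)               # q10
  )
}

#' @rdname synth_config
#' @export
default_audit_elevated <- function() {
  freq_high <- c(0.45, 0.25, 0.15, 0.10, 0.05)
  cons_high <- c(0.05, 0.15, 0.25, 0.30, 0.25)
  list(
    cons_high, cons_high, cons_high,                   # q1-q3
    freq_high, freq_high, freq_high, freq_high, freq_high,
    c(0.60, 0.25, 0.15),
    c(0.60, 0.25, 0.15)
  )
}

#' Generate a synthetic classroom study
#'
#' Draws a complete, validated [response_set()] from a [synth_config()]:
#' every classroom is partitioned into friendship groups; every ordered
#' within-classroom dyad receives exactly one rating drawn from the
#' within- or between-group distribution (the two directions of a dyad
#' agree unless redrawn with probability `rating_reciprocity_noise`);
#' each classroom group gets a drinking propensity that is mixed with an
#' individual propensity by `drinking_homophily`, and AUDIT items are
#' drawn from propensity-shifted distributions. Identical seeds give
#' identical studies.
#'
#' @param config A `synth_config`.
#' @return A `response_set` with individuals, ratings and a
#'   `group` extra attribute recording the planted partition.
#' @export
generate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    individuals <- list()
    ratings <- list()
    for (ci in seq_len(config$n_classrooms)) {
      cls <- sprintf("C%02d", ci)
      n <- if (length(config$students_per_classroom) == 2) {
        sample(config$students_per_classroom[1]:config$students_per_classroom[2], 1)
      } else {
        config$students_per_classroom
      }
      ids <- sprintf("%s_S%02d", cls, seq_len(n))
      gender <- ifelse(stats::runif(n) < config$female_proportion,
                       "female", "male")
      group <- sort(rep_len(seq_len(config$n_groups_per_classroom), n))

      # planted-partition contact ratings over all ordered dyads
      pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      same <- group[pair[, 1]] == group[pair[, 2]]
      draw <- function(k, within) {
        probs <- if (within) config$within_group_rating else config$between_group_rating
        sample.int(5, k, replace = TRUE, prob = probs)
      }
      w_ab <- integer(nrow(pair)); w_ba <- integer(nrow(pair))
      w_ab[same] <- draw(sum(same), TRUE)
      w_ab[!same] <- draw(sum(!same), FALSE)
      redraw <- stats::runif(nrow(pair)) < config$rating_reciprocity_noise
      w_ba <- w_ab
      w_ba[same & redraw] <- draw(sum(same & redraw), TRUE)
      w_ba[!same & redraw] <- draw(sum(!same & redraw), FALSE)

      # drinking propensity: group-level mixed with individual-level
      g_prop <- stats::runif(config$n_groups_per_classroom)
      i_prop <- stats::runif(n)
      prop <- config$drinking_homophily * g_prop[group] +
        (1 - config$drinking_homophily) * i_prop

      audit <- matrix(0L, n, 10)
      for (q in 1:10) {
        damp <- if (q <= 3) 1 else 0.4   # shift acts mainly on AUDIT-C items
        scores <- if (q <= 8) 0:4 else c(0L, 2L, 4L)
        base <- config$audit_item_base[[q]]
        elev <- config$audit_item_elevated[[q]]
        for (i in seq_len(n)) {
          mix <- (1 - damp * prop[i]) * base + damp * prop[i] * elev
          audit[i, q] <- scores[sample.int(length(scores), 1, prob = mix)]
        }
      }

      individuals[[ci]] <- data.frame(
        id = ids, classroom_id = cls, gender = gender,
        stats::setNames(as.data.frame(audit), paste0("audit_q", 1:10)),
        group = group, stringsAsFactors = FALSE)
      ratings[[ci]] <- data.frame(
        rater_id = c(ids[pair[, 1]], ids[pair[, 2]]),
        ratee_id = c(ids[pair[, 2]], ids[pair[, 1]]),
        weight = c(w_ab, w_ba), stringsAsFactors = FALSE)
    }
    individuals <- do.call(rbind, individuals)
    ratings <- do.call(rbind, ratings)
    ord <- order(ratings$rater_id, ratings$ratee_id)
    ratings <- ratings[ord, , drop = FALSE]
    rownames(individuals) <- rownames(ratings) <- NULL
    response_set(individuals, ratings,
                 metadata = list(study = "synthetic classroom study",
                                 seed = config$seed))
  })
}

#' Same-label edge fraction (label assortativity)
#'
#' The fraction of edges of a derived network joining two nodes with the
#' same value of a logical label — the homophily summary used to check
#' that the generator's `drinking_homophily` knob is recoverable from the
#' derived networks.
#'
#' @param net A `derived_network`.
#' @param labels Data frame with columns `id` and `label_name`.
#' @param label_name Name of a logical column of `labels`.
#' @return Fraction in `[0,1]`, or `NA` for an edgeless network.
#' @export
same_label_edge_fraction <- function(net, labels, label_name) {
  stopifnot(inherits(net, "derived_network"))
  e <- net$edges
  if (nrow(e) == 0) return(NA_real_)
  v <- stats::setNames(labels[[label_name]], labels$id)
  mean(v[e$a] == v[e$b])
}
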