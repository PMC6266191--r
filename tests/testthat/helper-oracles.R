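# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's code paths (and igraph) wherever they are used to
# check a package computation.

# --- shortest-path oracles on an undirected simple graph ------------------

# Adjacency matrix from an edge data frame (columns a, b) over ids.
oracle_adjacency <- function(edges, ids) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    A[cbind(match(edges$a, ids), match(edges$b, ids))] <- TRUE
    A[cbind(match(edges$b, ids), match(edges$a, ids))] <- TRUE
  }
  A
}

# All-pairs BFS distances (Inf where unreachable).
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(A[v, ])) {
          if (is.infinite(D[s, u])) {
            D[s, u] <- d
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
  }
  D
}

# Geodesic counts sigma[s, v] from the distance matrix by dynamic
# programming over distance layers.
oracle_sigma <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    S[s, s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || is.infinite(D[s, v])) next
      pred <- which(A[v, ] & D[s, ] == D[s, v] - 1)
      S[s, v] <- sum(S[s, pred])
    }
  }
  S
}

# Normalised shortest-path betweenness: pair-by-pair enumeration of
# geodesics through each vertex.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  if (n <= 2) return(rep(0, n))
  D <- oracle_distances(A)
  S <- oracle_sigma(A, D)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(D[s, t]) || S[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          b[v] <- b[v] + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# Wasserman-Faust normalised closeness from its own BFS distances.
oracle_closeness <- function(A) {
  n <- nrow(A)
  if (n <= 1) return(rep(0, n))
  D <- oracle_distances(A)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / (n - 1)) * r / sum(d[is.finite(d)])
  }, numeric(1))
}

# --- tie-rule oracle ------------------------------------------------------

# Direct per-dyad enumeration: every unordered pair, straight through
# evaluate_tie (the scalar evaluator), independent of derive_network's
# vectorised path.
oracle_derive_edges <- function(raw, rule) {
  ids <- raw$nodes$name
  arcs <- raw$arcs
  wt <- function(a, b) {
    hit <- which(arcs$rater_id == a & arcs$ratee_id == b)
    if (length(hit)) arcs$weight[hit] else NA
  }
  out <- character(0)
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        if (evaluate_tie(rule, wt(ids[i], ids[j]), wt(ids[j], ids[i]))$verdict) {
          out <- c(out, paste(min(ids[i], ids[j]), max(ids[i], ids[j]),
                              sep = "|"))
        }
      }
    }
  }
  sort(out)
}

# --- fixture builders -----------------------------------------------------

# Minimal individuals table; audit items optional.
make_individuals <- function(ids, classroom = "C1",
                             gender = rep(c("male", "female"),
                                          length.out = length(ids)),
                             audit = NULL) {
  df <- data.frame(id = ids, classroom_id = classroom, gender = gender,
                   stringsAsFactors = FALSE)
  if (!is.null(audit)) {
    colnames(audit) <- paste0("audit_q", 1:10)
    df <- cbind(df, audit)
  }
  df
}

# Response set from explicit ratings, keeping unanswered pairs absent so
# tie evaluation sees missing directions.
make_response_set <- function(individuals, ratings,
                              missing_policy = "strict") {
  suppressWarnings(response_set(individuals, ratings,
                                missing_policy = missing_policy))
}

# Random sparse raw network: each ordered pair rated with probability p.
random_raw_network <- function(n, p = 0.4, classroom = "C1") {
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(rater_id = ids, ratee_id = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$rater_id != pairs$ratee_id, ]
  keep <- runif(nrow(pairs)) < p
  ratings <- pairs[keep, , drop = FALSE]
  ratings$weight <- sample.int(5, nrow(ratings), replace = TRUE)
  rs <- make_response_set(make_individuals(ids, classroom), ratings)
  build_raw_network(rs)
}

# Random tie rule with at least one weight condition set.
random_tie_rule <- function(name) {
  repeat {
    each <- if (runif(1) < 0.6) sample(1:5, 1) else NULL
    sm <- if (runif(1) < 0.4) sample(2:10, 1) else NULL
    mn <- if (runif(1) < 0.4) round(runif(1, 1, 5), 1) else NULL
    if (!is.null(each) || !is.null(sm) || !is.null(mn)) break
  }
  tie_rule(name, reciprocity = runif(1) < 0.7, min_each_weight = each,
           min_sum_weight = sm, min_mean_weight = mn,
           output_weighting = sample(c("dichotomous", "min", "mean", "sum"), 1))
}

# Random legal AUDIT item vector (items 9-10 restricted to 0/2/4).
random_audit_items <- function() {
  c(sample(0:4, 8, replace = TRUE), sample(c(0L, 2L, 4L), 2, replace = TRUE))
}

# A small deterministic study used by several files: two classrooms,
# hand-picked AUDIT vectors covering both binge cut-offs.
fixture_study <- function() {
  audit <- rbind(
    c(4, 4, 4, 0, 0, 0, 0, 0, 0, 0),  # audit_c 12: binge under both
    c(3, 3, 2, 0, 0, 0, 0, 0, 0, 0),  # audit_c 8:  male gt7 yes, gt4 yes
    c(2, 2, 1, 0, 0, 0, 0, 0, 0, 0),  # audit_c 5:  male gt7 no, gt4 yes
    c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),  # audit_c 3:  neither
    c(2, 2, 1, 1, 0, 0, 0, 0, 0, 0),  # audit_c 5 female: finnish yes
    c(1, 2, 1, 0, 0, 0, 0, 0, 2, 0)   # audit_c 4 female: finnish no, spanish no
  )
  ind <- make_individuals(c("A", "B", "C", "D", "E", "F"),
                          gender = c("male", "male", "male", "male",
                                     "female", "female"),
                          audit = audit)
  ratings <- data.frame(
    rater_id = c("A", "B", "A", "C", "B", "C", "D", "E", "E", "F"),
    ratee_id = c("B", "A", "C", "A", "C", "B", "E", "D", "F", "E"),
    weight   = c(5L,  4L,  4L,  3L,  2L,  2L,  5L,  5L,  4L,  4L),
    stringsAsFactors = FALSE)
  make_response_set(ind, ratings)
}
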