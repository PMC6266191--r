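test_that("the raw network mirrors the ratings one-to-one", {
  ind <- make_individuals(c("A", "B", "C"))
  ratings <- data.frame(rater_id = c("A", "B", "A"),
                        ratee_id = c("B", "A", "C"),
                        weight = c(5L, 4L, 1L))
  raw <- build_raw_network(make_response_set(ind, ratings))
  expect_identical(nrow(raw$nodes), 3L)
  expect_identical(nrow(raw$arcs), 3L)

  empty <- build_raw_network(make_response_set(
    ind, data.frame(rater_id = character(0), ratee_id = character(0),
                    weight = integer(0))))
  expect_identical(nrow(empty$arcs), 0L)
  expect_identical(nrow(empty$nodes), 3L)

  rs <- generate_study(synth_config(n_classrooms = 2, seed = 5))
  raw <- build_raw_network(rs)
  expect_identical(nrow(raw$arcs), nrow(rs$ratings))
})

test_that("derived edges are exactly the dyads satisfying the rule", {
  ind <- make_individuals(c("A", "B", "C"))
  ratings <- data.frame(rater_id = c("A", "B", "A"),
                        ratee_id = c("B", "A", "C"),
                        weight = c(4L, 5L, 5L))
  raw <- build_raw_network(make_response_set(ind, ratings))
  strong <- tie_rule("strong", min_each_weight = 4)
  net <- derive_network(raw, strong)
  expect_identical(edge_set(net), "A|B")
  expect_identical(nrow(net$nodes), 3L)  # isolate C retained
  # "best friends" needs both directions at 5; the 4 fails
  best <- tie_rule("best", min_each_weight = 5)
  expect_identical(edge_set(derive_network(raw, best)), character(0))
})

test_that("derive_network equals brute-force per-dyad evaluation", {
  set.seed(31)
  for (k in 1:25) {
    raw <- random_raw_network(n = sample(4:12, 1), p = runif(1, 0.2, 0.7))
    rule <- random_tie_rule(sprintf("r%d", k))
    expect_identical(edge_set(derive_network(raw, rule)),
                     oracle_derive_edges(raw, rule))
  }
})

test_that("edge sets are nested across the threshold family", {
  for (seed in c(2, 9, 17)) {
    rs <- generate_study(synth_config(n_classrooms = 2, seed = seed))
    raw <- build_raw_network(rs)
    sets <- lapply(2:5, function(t) {
      edge_set(derive_network(raw, tie_rule("t", min_each_weight = t)))
    })
    expect_true(all(sets[[4]] %in% sets[[3]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[1]]))
  }
})

test_that("output weighting attaches min/mean/sum edge weights", {
  ind <- make_individuals(c("A", "B"))
  ratings <- data.frame(rater_id = c("A", "B"), ratee_id = c("B", "A"),
                        weight = c(4L, 5L))
  raw <- build_raw_network(make_response_set(ind, ratings))
  w <- vapply(c("dichotomous", "min", "mean", "sum"), function(ow) {
    derive_network(raw, tie_rule("r", min_each_weight = 4,
                                 output_weighting = ow))$edges$weight
  }, numeric(1))
  expect_equal(unname(w), c(1, 4, 4.5, 9))
})

test_that("per-edge explanations justify every edge and are re-checkable", {
  rs <- fixture_study()
  net <- derive_network(build_raw_network(rs),
                        tie_rule("strong", min_each_weight = 4))
  expect_length(net$edge_explanations, nrow(net$edges))
  for (ex in net$edge_explanations) {
    expect_true(ex$verdict)
    expect_true(reevaluate_explanation(ex))
  }
  # a rejected dyad is explainable too
  ex <- explain_tie(net, "B", "C")
  expect_false(ex$verdict)
  expect_true(any(!ex$checks$satisfied))
})

test_that("metrics match closed forms on simple graphs", {
  ind <- make_individuals(c("A", "B", "C"))
  ratings <- data.frame(rater_id = c("A", "B", "B", "C"),
                        ratee_id = c("B", "A", "C", "B"),
                        weight = 5L)
  net <- derive_network(build_raw_network(make_response_set(ind, ratings)),
                        tie_rule("r", min_each_weight = 2))
  m <- compute_metrics(net)
  nb <- m$nodes[m$nodes$id == "B", ]
  expect_equal(nb$degree, 2)
  expect_equal(nb$betweenness, 1)  # the single A-C geodesic, normalised
  expect_equal(nb$closeness, 1)
  expect_equal(m$nodes$closeness[m$nodes$id == "A"], 2 / 3)
  expect_equal(m$graph$density, 2 / 3)
  expect_equal(sum(m$nodes$degree), 2 * m$graph$n_edges)

  lone <- derive_network(build_raw_network(make_response_set(
    ind, data.frame(rater_id = character(0), ratee_id = character(0),
                    weight = integer(0)))),
    tie_rule("r", min_each_weight = 2))
  m0 <- compute_metrics(lone)
  expect_true(all(m0$nodes$degree == 0))
  expect_true(all(m0$nodes$closeness == 0))
  expect_equal(m0$graph$density, 0)
  expect_equal(m0$graph$n_components, 3)
})

test_that("betweenness and closeness equal the brute-force oracle", {
  set.seed(41)
  for (k in 1:20) {
    raw <- random_raw_network(n = sample(5:15, 1), p = runif(1, 0.1, 0.5))
    net <- derive_network(raw, tie_rule("r", min_each_weight = sample(2:4, 1)))
    m <- compute_metrics(net)
    A <- oracle_adjacency(net$edges, net$nodes$name)
    expect_equal(m$nodes$betweenness, oracle_betweenness(A), tolerance = 1e-12)
    expect_equal(m$nodes$closeness, oracle_closeness(A), tolerance = 1e-12)
  }
})

test_that("raw-network degrees count mentions and reciprocity is in range", {
  ind <- make_individuals(c("A", "B", "C"))
  ratings <- data.frame(rater_id = c("A", "B", "A", "C"),
                        ratee_id = c("B", "A", "C", "A"),
                        weight = c(3L, 4L, 1L, 2L))
  raw <- build_raw_network(make_response_set(ind, ratings))
  m <- compute_metrics(raw)
  # weight-1 arc A->C is the floor response, not a mention
  expect_equal(m$nodes$out_degree[m$nodes$id == "A"], 1)
  expect_equal(m$nodes$in_degree[m$nodes$id == "A"], 2)
  expect_equal(m$graph$n_mentions, 3L)
  expect_gte(m$graph$reciprocity, 0); expect_lte(m$graph$reciprocity, 1)

  # symmetric-by-construction ratings have reciprocity exactly 1
  rs <- generate_study(synth_config(n_classrooms = 1,
                                    students_per_classroom = 10,
                                    rating_reciprocity_noise = 0, seed = 3))
  expect_equal(compute_metrics(build_raw_network(rs))$graph$reciprocity, 1)
})

test_that("classroom restriction induces the classroom subgraph", {
  rs <- generate_study(synth_config(n_classrooms = 3, seed = 13))
  raw_all <- build_raw_network(rs)
  raw_c2 <- build_raw_network(rs, classroom = "C02")
  expect_true(all(raw_c2$nodes$classroom == "C02"))
  rule <- tie_rule("strong", min_each_weight = 4)
  e_all <- edge_set(derive_network(raw_all, rule))
  e_c2 <- edge_set(derive_network(raw_c2, rule))
  in_c2 <- vapply(strsplit(e_all, "|", fixed = TRUE), function(ab) {
    all(startsWith(ab, "C02"))
  }, logical(1))
  expect_setequal(e_c2, e_all[in_c2])
  expect_error(build_raw_network(rs, classroom = "C99"),
               class = "tiescope_validation_error")
})

test_that("exports produce readable GraphML, GEXF and CSV", {
  rs <- fixture_study()
  net <- derive_network(build_raw_network(rs),
                        tie_rule("strong", min_each_weight = 4))
  d <- withr::local_tempdir()
  gml <- file.path(d, "net.graphml")
  write_graphml(net, gml,
                labels = data.frame(id = net$nodes$name,
                                    binge_drinker = rep(c(TRUE, FALSE), 3)))
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(net$nodes), ignore_attr = TRUE)
  expect_equal(igraph::ecount(g2), nrow(net$edges), ignore_attr = TRUE)
  expect_true("binge_drinker" %in% igraph::vertex_attr_names(g2))

  gexf <- file.path(d, "net.gexf")
  write_gexf(net, gexf)
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), nrow(net$nodes))
  expect_length(xml2::xml_find_all(doc, "//d1:edge", ns), nrow(net$edges))

  el <- file.path(d, "edges.csv")
  write_edge_list(net, el)
  expect_identical(nrow(utils::read.csv(el)), nrow(net$edges))
  mp <- file.path(d, "metrics.csv")
  write_metrics(compute_metrics(net), mp)
  expect_identical(nrow(utils::read.csv(mp)), nrow(net$nodes))
})
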