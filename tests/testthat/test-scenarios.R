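presets <- preset_characteristic_rules()
two_sets <- list(
  finnish = list(presets$binge_finnish),
  spanish = list(presets$binge_spanish)
)

test_that("the scenario cross-product enumerates n x m in declared order", {
  ties4 <- preset_tie_rules()
  scens <- enumerate_scenarios(ties4, two_sets)
  expect_length(scens, 8)
  expect_identical(vapply(scens, function(s) s$label, character(1))[1:3],
                   c("any_contact__finnish", "any_contact__spanish",
                     "some_contact__finnish"))

  expect_length(enumerate_scenarios(ties4[1], two_sets[1]), 1)
  labs <- vapply(enumerate_scenarios(ties4[1:3],
                                     c(two_sets, list(
                                       a = list(presets$popular),
                                       b = list(presets$bad_influence),
                                       c = list(presets$binge_spanish_ge)))),
                 function(s) s$label, character(1))
  expect_length(labs, 15)
  expect_identical(labs, as.vector(t(outer(
    c("any_contact", "some_contact", "strong_friendship"),
    c("finnish", "spanish", "a", "b", "c"), paste, sep = "__"))))

  expect_error(enumerate_scenarios(list(ties4[[1]], ties4[[1]]), two_sets),
               class = "tiescope_schema_error")
  expect_error(enumerate_scenarios(list(), two_sets),
               class = "tiescope_schema_error")
})

test_that("running a scenario classifies with the scenario's own metrics", {
  rs <- fixture_study()
  strong <- tie_rule("strong_friendship", min_each_weight = 4)
  scen <- enumerate_scenarios(list(strong), two_sets["finnish"])[[1]]
  res <- run_scenario(rs, scen)
  # male B has audit_c 8 (> 7): binge drinker under the Finnish criteria
  expect_true(res$labels$binge_drinker[res$labels$id == "B"])
  expect_false(res$labels$binge_drinker[res$labels$id == "C"])  # audit_c 5
  expect_identical(res$summary$n[res$summary$label == "binge_drinker"],
                   sum(res$labels$binge_drinker))

  # Spanish cut-off is laxer at equal data: superset of the Finnish labels
  res_sp <- run_scenario(rs, enumerate_scenarios(list(strong),
                                                 two_sets["spanish"])[[1]])
  expect_true(all(res$labels$binge_drinker <= res_sp$labels$binge_drinker))
  expect_gte(sum(res_sp$labels$binge_drinker), sum(res$labels$binge_drinker))

  # empty ratings: edgeless network, nobody popular
  ind <- make_individuals(c("A", "B", "C", "D", "E"))
  empty <- make_response_set(ind, data.frame(rater_id = character(0),
                                             ratee_id = character(0),
                                             weight = integer(0)))
  res0 <- run_scenario(empty, enumerate_scenarios(
    list(strong), list(pop = list(presets$popular)))[[1]])
  expect_identical(res0$metrics$graph$n_edges, 0L)
  expect_false(any(res0$labels$popular))
})

test_that("identical inputs give identical scenario results", {
  rs <- generate_study(synth_config(n_classrooms = 2, seed = 21))
  scen <- enumerate_scenarios(preset_tie_rules()[3], two_sets)[1:2]
  r1 <- run_scenarios(rs, scen)
  r2 <- run_scenarios(rs, scen)
  expect_identical(r1[[1]]$labels, r2[[1]]$labels)
  expect_identical(edge_set(r1[[2]]$network), edge_set(r2[[2]]$network))
  expect_identical(r1[[1]]$metrics$nodes, r2[[1]]$metrics$nodes)
})

test_that("scenario comparison computes Jaccard, confusion and kappa", {
  rs <- fixture_study()
  strong <- tie_rule("strong_friendship", min_each_weight = 4)
  scens <- enumerate_scenarios(list(strong), two_sets)
  a <- run_scenario(rs, scens[[1]])
  b <- run_scenario(rs, scens[[2]])

  self <- compare_scenarios(a, a)
  expect_equal(self$edge_jaccard, 1)
  expect_equal(self$labels$agreement, 1)
  expect_equal(self$labels$kappa, 1)

  ab <- compare_scenarios(a, b)
  expect_equal(ab$edge_jaccard, 1)  # same tie rule, same network
  lb <- ab$labels
  expect_identical(lb$both + lb$only_a + lb$only_b + lb$neither,
                   nrow(rs$individuals))
  # Finnish labels B (m, 8) and E (f, 5); Spanish adds C (m, 5) and A, keeps E
  expect_identical(lb$only_a, 0L)
  la <- a$labels$binge_drinker; lbv <- b$labels$binge_drinker
  po <- mean(la == lbv)
  pe <- mean(la) * mean(lbv) + mean(!la) * mean(!lbv)
  expect_equal(lb$agreement, po)
  expect_equal(lb$kappa, (po - pe) / (1 - pe))

  other <- run_scenario(make_response_set(
    make_individuals(c("X", "Y")),
    data.frame(rater_id = "X", ratee_id = "Y", weight = 5L)), strong)
  err <- expect_error(compare_scenarios(a, other),
                      class = "tiescope_validation_error")
  expect_match(conditionMessage(err), "node set")
})

test_that("edge Jaccard follows set arithmetic", {
  mk <- function(edges) {
    # scenario_result stub carrying just what compare_scenarios reads
    ind <- make_individuals(c("A", "B", "C", "D", "E"))
    ratings <- do.call(rbind, lapply(edges, function(e) {
      data.frame(rater_id = c(e[1], e[2]), ratee_id = c(e[2], e[1]),
                 weight = 5L)
    }))
    if (is.null(ratings)) ratings <- data.frame(rater_id = character(0),
                                                ratee_id = character(0),
                                                weight = integer(0))
    run_scenario(make_response_set(ind, ratings),
                 tie_rule("r", min_each_weight = 5))
  }
  ab <- mk(list(c("A", "B")))
  bc <- mk(list(c("B", "C")))
  expect_equal(compare_scenarios(ab, bc)$edge_jaccard, 0)
  x <- mk(list(c("A", "B"), c("B", "C"), c("C", "D")))
  y <- mk(list(c("A", "B"), c("C", "D"), c("D", "E")))
  expect_equal(compare_scenarios(x, y)$edge_jaccard, 0.5)
  expect_equal(compare_scenarios(mk(list()), mk(list()))$edge_jaccard, 1)
})

test_that("degenerate identical labellings report kappa 1 with a flag", {
  ind <- make_individuals(c("A", "B", "C"))
  ratings <- data.frame(rater_id = c("A", "B"), ratee_id = c("B", "A"),
                        weight = 5L)
  rs <- make_response_set(ind, ratings)
  # all-FALSE labels in both scenarios via an impossible in-degree bound
  impossible <- characteristic_rule("binge_drinker", list(list(
    score_condition("metric:in_degree", "ge", 99))))
  scens <- enumerate_scenarios(list(tie_rule("r", min_each_weight = 2)),
                               list(s1 = list(impossible),
                                    s2 = list(impossible)))
  a <- run_scenario(rs, scens[[1]])
  b <- run_scenario(rs, scens[[2]])
  cmp <- compare_scenarios(a, b)
  expect_equal(cmp$labels$kappa, 1)
  expect_true(cmp$labels$kappa_degenerate)
  expect_equal(cmp$labels$agreement, 1)
})

test_that("the sensitivity report collates all pairwise comparisons", {
  rs <- generate_study(synth_config(n_classrooms = 2, seed = 8))
  scens <- enumerate_scenarios(preset_tie_rules(), two_sets)
  results <- run_scenarios(rs, scens)
  rep <- sensitivity_report(results)
  expect_identical(nrow(rep$scenarios), 8L)
  expect_length(rep$comparison_objects, choose(8, 2))

  one <- sensitivity_report(results[1])
  expect_length(one$comparison_objects, 0)
  expect_identical(nrow(one$scenarios), 1L)

  ref <- sensitivity_report(results, reference = "any_contact__finnish")
  expect_length(ref$comparison_objects, 7)

  # report values equal independent recomputation
  cmp <- rep$comparison_objects[[1]]
  ra <- results[[cmp$a]]; rb <- results[[cmp$b]]
  ea <- edge_set(ra$network); eb <- edge_set(rb$network)
  expect_equal(cmp$edge_jaccard,
               length(intersect(ea, eb)) / length(union(ea, eb)))

  d <- withr::local_tempdir()
  write_sensitivity_report(rep, d, provenance = list(seed = 8))
  expect_true(file.exists(file.path(d, "report.json")))
  payload <- jsonlite::read_json(file.path(d, "report.json"))
  expect_length(payload$scenarios, 8)
  expect_equal(payload$provenance$seed, 8)
  expect_identical(nrow(utils::read.csv(file.path(d, "scenarios.csv"))), 8L)
})
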