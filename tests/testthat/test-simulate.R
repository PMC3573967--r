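test_that("scenario generation produces exact category counts", {
  pair <- generate_scenario(scenario_config("i", n = 200, seed = 2))
  expect_length(pair$truth, 160)
  tab <- table(pair$labels)
  expect_equal(unname(tab["ortholog_vertex_similar"]), 100)
  expect_equal(unname(tab["analog"]), 60)
  expect_equal(unname(tab["unrelated"]), 40)
  expect_false("paralog_case" %in% names(tab))
  expect_length(pair$decoys, 0)

  p2 <- generate_scenario(scenario_config("ii", n = 200, seed = 2))
  tab2 <- table(p2$labels)
  expect_equal(unname(tab2["paralog_case"]), 20)
  expect_equal(unname(tab2["ortholog_vertex_similar"]), 100)
  expect_equal(unname(tab2["analog"]), 40)
  expect_length(p2$decoys, 20)

  # counts stay exact for a non-default configuration
  p3 <- generate_scenario(scenario_config("ii", n = 60, frac_ortholog = 0.5,
                                          frac_vertex_similar_of_orthologs = 0.4,
                                          frac_paralog_of_orthologs = 0.2,
                                          seed = 3))
  expect_length(p3$truth, 30)
  expect_equal(sum(p3$labels == "ortholog_vertex_similar"), 12)
  expect_equal(sum(p3$labels == "paralog_case"), 6)
})

test_that("decoy paralogs copy the true partner's similarity exactly", {
  pair <- generate_scenario(scenario_config("iii", n = 200, seed = 4))
  truth_map <- stats::setNames(pair$truth$to, pair$truth$from)
  Th <- pair$theta$theta
  for (i in names(pair$decoys)) {
    th_true <- Th[i, truth_map[i]]
    th_decoy <- Th[i, pair$decoys[i]]
    expect_identical(unname(th_true), unname(th_decoy))
    expect_gt(th_true, 0)
  }
  # decoys sit on non-ortholog slots of the second network
  expect_length(intersect(pair$decoys, pair$truth$to), 0)
})

test_that("spurious similarities appear only in scenario iii", {
  p2 <- generate_scenario(scenario_config("ii", n = 100, seed = 5))
  p3 <- generate_scenario(scenario_config("iii", n = 100, seed = 5))
  nz2 <- length(p2$theta$theta@x)
  nz3 <- length(p3$theta$theta@x)
  expect_gt(nz3, nz2)
  # weak band is separated from the high-similarity band
  spur <- setdiff(p3$theta$theta@x, p2$theta$theta@x)
  expect_true(all(spur <= 0.3 + 1e-12))
  expect_true(all(p2$theta$theta@x >= 0.75 - 1e-12))
})

test_that("the same seed reproduces the pair exactly; scenarios i and ia differ only in weights", {
  c1 <- scenario_config("iii", n = 80, seed = 11)
  expect_identical(generate_scenario(c1), generate_scenario(c1))

  pi_ <- generate_scenario(scenario_config("i", n = 150, seed = 6))
  pia <- generate_scenario(scenario_config("ia", n = 150, seed = 6))
  expect_identical(pi_$truth, pia$truth)
  expect_identical(pi_$labels, pia$labels)
  expect_identical(pi_$g$adjacency != 0, pia$g$adjacency != 0)
  # normal weights cluster around 0.5; uniform weights do not
  wu <- pi_$g$adjacency[pi_$g$adjacency != 0]
  wn <- pia$g$adjacency[pia$g$adjacency != 0]
  expect_lt(stats::sd(wn), stats::sd(wu))
  expect_true(all(wn >= 0 & wn <= 1))
})

test_that("density and conservation track their configured values", {
  expect_equal(empirical_edge_density(
    make_network(matrix(1, 4, 4) - diag(4), letters[1:4])), 1)
  expect_equal(empirical_edge_density(
    make_network(matrix(0, 3, 3), letters[1:3])), 0)

  pair <- generate_scenario(scenario_config("i", n = 200, seed = 8))
  se_d <- sqrt(0.5 * 0.5 / choose(200, 2))
  expect_lt(abs(empirical_edge_density(pair$g) - 0.5), 3 * se_d)
  se_c <- sqrt(0.6 * 0.4 / choose(160, 2))
  expect_lt(abs(empirical_conservation(pair) - 0.6), 3 * se_c)

  perfect <- generate_scenario(scenario_config("i", n = 100,
                                               interaction_similarity = 1,
                                               seed = 9))
  expect_equal(empirical_conservation(perfect), 1)
  none <- generate_scenario(scenario_config("i", n = 100,
                                            interaction_similarity = 0,
                                            seed = 9))
  expect_lt(empirical_conservation(none), 0.01)
})

test_that("infeasible configurations are rejected", {
  expect_error(scenario_config("i", n = 3), "at least 4")
  expect_error(scenario_config("i", frac_ortholog = 1.2), "fractions")
  # more decoys than free slots in the second network
  expect_error(generate_scenario(
    scenario_config("ii", n = 40, frac_ortholog = 0.95,
                    frac_vertex_similar_of_orthologs = 0.4,
                    frac_paralog_of_orthologs = 0.5, seed = 1)),
    "slots")
})
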