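test_that("best-hit seeding matches an exhaustive search and discards ties", {
  # diagonal dominance: identity seed
  th <- make_similarity(sprintf("a%d", 1:4), sprintf("b%d", 1:4),
                        diag(4) * 5 + 0.1)
  a <- initial_alignment(th, min_theta = 1)
  expect_equal(sort(a$from), sprintf("a%d", 1:4))
  expect_equal(a$to[order(a$from)], sprintf("b%d", 1:4))

  # a tied best hit removes the pair (paralog-decoy situation)
  m <- matrix(0, 2, 3, dimnames = list(c("a1", "a2"), c("b1", "b2", "b3")))
  m["a1", "b1"] <- 1; m["a1", "b2"] <- 1 # tie for a1's best
  m["a2", "b3"] <- 2
  a <- initial_alignment(make_similarity(rownames(m), colnames(m), m))
  expect_equal(a$from, "a2")
  expect_equal(a$to, "b3")

  # random matrices against a brute-force bidirectional-best search
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(round(runif(100) * 20) / 2, 10, 10,
                dimnames = list(sprintf("a%d", 1:10), sprintf("b%d", 1:10)))
    got <- initial_alignment(make_similarity(rownames(m), colnames(m), m))
    want_from <- character(); want_to <- character()
    for (i in 1:10) {
      ri <- m[i, ]
      if (max(ri) <= 0 || sum(ri == max(ri)) > 1) next
      j <- which.max(ri)
      cj <- m[, j]
      if (sum(cj == max(cj)) > 1 || which.max(cj) != i) next
      want_from <- c(want_from, rownames(m)[i])
      want_to <- c(want_to, colnames(m)[j])
    }
    ord <- order(got$from)
    wrd <- order(want_from)
    expect_equal(got$from[ord], want_from[wrd])
    expect_equal(got$to[ord], want_to[wrd])
  }
})

test_that("the linearised assignment matrix matches a hand-expanded sum", {
  set.seed(15)
  g <- random_network(4, prefix = "a")
  g2 <- random_network(4, prefix = "b")
  th <- random_similarity(g, g2, density = 0.6)
  bins <- binary_bins()
  cur <- make_alignment(c("a001", "a002", "a003"), c("b002", "b003", "b001"))
  tb <- suppressWarnings(estimate_score_tables(g, g2, th, cur, bins))
  M <- build_assignment_matrix(g, g2, th, cur, tb, bins,
                               allow_unaligned = FALSE, edge_factor = 1)
  Thd <- as.matrix(th$theta)
  curmap <- stats::setNames(cur$to, cur$from)
  vterm <- function(i, i2) {
    # exact vertex-score change of aligning i to i2
    want <- vertex_scores(tb, Thd[i, i2])$s_aligned
    for (j2 in g2$vertex_ids)
      if (j2 != i2)
        want <- want + vertex_scores(tb, Thd[i, j2])$s_not_aligned
    want
  }
  for (i in g$vertex_ids) {
    for (i2 in g2$vertex_ids) {
      want <- vterm(i, i2)
      for (j in cur$from) {
        if (j == i) next
        want <- want + edge_score(tb, g$adjacency[i, j],
                                  g2$adjacency[i2, curmap[j]])
      }
      expect_equal(M[i, i2], unname(want), tolerance = 1e-10)
    }
  }

  # empty current alignment leaves only the vertex term
  M0 <- build_assignment_matrix(g, g2, th, make_alignment(), tb, bins,
                                allow_unaligned = FALSE)
  V <- outer(g$vertex_ids, g2$vertex_ids, Vectorize(vterm))
  expect_equal(unname(unclass(M0)), unname(V), tolerance = 1e-10,
               ignore_attr = TRUE)

  # flat tables give an identically zero matrix
  flat <- tables_from_counts(matrix(.25, 2, 2), c(.5, .5), c(.5, .5),
                             c(.5, .5), c(.5, .5), c(.5, .5), bins)
  Mf <- build_assignment_matrix(g, g2, th, cur, flat, bins,
                                allow_unaligned = FALSE)
  expect_lt(max(abs(Mf)), 1e-12)
})

test_that("the linear assignment solver is exact against permutation enumeration", {
  a <- solve_linear_assignment(matrix(c(2, 1, 1, 2), 2, 2))
  expect_equal(a$from, c("1", "2"))
  expect_equal(a$to, c("1", "2"))

  z <- solve_linear_assignment(matrix(0, 3, 3))
  expect_length(z, 3)
  expect_false(anyDuplicated(z$to) > 0)

  expect_error(solve_linear_assignment(matrix(c(1, NA, 0, 1), 2, 2)),
               "finite")

  set.seed(25)
  perm6 <- all_permutations(6)
  for (rep in 1:20) {
    M <- matrix(round(rnorm(36) * 4) / 2, 6, 6) # ties on purpose
    sol <- solve_linear_assignment(M)
    got <- sum(M[cbind(as.integer(sol$from), as.integer(sol$to))])
    best <- max(apply(perm6, 1, function(p) sum(M[cbind(1:6, p)])))
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("aligning identical rings recovers the identity; trivial sizes work", {
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  g <- make_network(ring, sprintf("a%d", 1:6))
  g2 <- make_network(ring, sprintf("b%d", 1:6))
  th <- make_similarity(g$vertex_ids, g2$vertex_ids, diag(6))
  bins <- binary_bins()
  a0 <- make_alignment(g$vertex_ids, g2$vertex_ids)
  tb <- suppressWarnings(estimate_score_tables(g, g2, th, a0, bins))
  res <- align_networks(g, g2, th, a0, tb, bins,
                        aligner_config(noise_initial_sd = 0,
                                       max_inner_iterations = 10,
                                       random_seed = 3))
  expect_equal(res$alignment$to[order(res$alignment$from)],
               sprintf("b%d", 1:6))
  expect_true(res$converged)
  expect_equal(res$total_score, res$edge_component + res$vertex_component,
               tolerance = 1e-6)

  # single-vertex networks: the one possible pairing or nothing
  g1 <- make_network(matrix(0, 1, 1), "a1")
  g1b <- make_network(matrix(0, 1, 1), "b1")
  th1 <- make_similarity("a1", "b1", matrix(1, 1, 1))
  r1 <- align_networks(g1, g1b, th1, make_alignment(), tb, bins,
                       aligner_config(max_inner_iterations = 5,
                                      random_seed = 1))
  expect_lte(length(r1$alignment), 1)
  expect_true(is.finite(r1$total_score))
})

test_that("the annealed search matches exhaustive enumeration on small instances", {
  set.seed(35)
  sizes <- c(sample(3:5, 40, replace = TRUE), rep(6, 5))
  hits <- 0L
  for (n in sizes) {
    g <- random_network(n, prefix = "a", binary = FALSE)
    g2 <- random_network(n, prefix = "b", binary = FALSE)
    th <- random_similarity(g, g2, density = 0.5)
    bins <- make_bins(g, g2, th, n_edge_bins = 3, n_theta_bins = 3)
    seed_a <- random_alignment(g, g2, max(2, n - 1))
    tb <- suppressWarnings(estimate_score_tables(g, g2, th, seed_a, bins))
    res <- align_networks(g, g2, th, make_alignment(), tb, bins,
                          aligner_config(random_seed = n))
    best <- -Inf
    for (map in all_partial_maps(n, n)) {
      a <- index_map_to_alignment(map, g, g2)
      best <- max(best, total_score(g, g2, th, a, tb, bins)$total)
    }
    expect_lte(res$total_score, best + 1e-9) # never exceeds the true optimum
    if (res$total_score >= best - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / length(sizes), 0.95)
})

test_that("the returned score never falls below the starting alignment's", {
  set.seed(45)
  for (rep in 1:5) {
    g <- random_network(10, prefix = "a")
    g2 <- random_network(10, prefix = "b")
    th <- random_similarity(g, g2, 0.4)
    bins <- make_bins(g, g2, th, n_edge_bins = 2, n_theta_bins = 3)
    start <- random_alignment(g, g2, 5)
    tb <- suppressWarnings(estimate_score_tables(g, g2, th, start, bins))
    res <- align_networks(g, g2, th, start, tb, bins,
                          aligner_config(max_inner_iterations = 15,
                                         random_seed = rep))
    expect_gte(res$total_score,
               total_score(g, g2, th, start, tb, bins)$total - 1e-9)
  }
})

test_that("fit_and_align is symmetric, deterministic, and handles degenerate input", {
  pair <- generate_scenario(scenario_config("ii", n = 50, seed = 9))
  cfg <- aligner_config(random_seed = 4, max_inner_iterations = 40)
  r1 <- suppressWarnings(
    fit_and_align(pair$g, pair$g2, pair$theta, config = cfg))
  tht <- structure(list(theta = Matrix::t(pair$theta$theta)),
                   class = "vertexsim")
  r2 <- suppressWarnings(
    fit_and_align(pair$g2, pair$g, tht, config = cfg))
  expect_true(netalign:::same_alignment(r1$alignment,
                                        invert_alignment(r2$alignment)))
  r1b <- suppressWarnings(
    fit_and_align(pair$g, pair$g2, pair$theta, config = cfg))
  expect_identical(r1$alignment, r1b$alignment)
  expect_identical(r1$trajectory, r1b$trajectory)

  # flat similarities between unrelated graphs: no crash, finite score
  set.seed(55)
  ga <- random_network(16, prefix = "x")
  gb <- random_network(16, prefix = "y")
  flat_th <- make_similarity(ga$vertex_ids, gb$vertex_ids,
                             matrix(0.5, 16, 16))
  rd <- suppressWarnings(
    fit_and_align(ga, gb, flat_th,
                  config = aligner_config(random_seed = 2,
                                          max_inner_iterations = 20)))
  expect_true(is.finite(rd$total_score))

  # all-zero similarities cannot seed an alignment
  zero_th <- make_similarity(ga$vertex_ids, gb$vertex_ids)
  expect_error(suppressWarnings(fit_and_align(ga, gb, zero_th)),
               "fewer than 2 pairs")
})
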