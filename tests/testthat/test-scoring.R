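make_pair_copy <- function(edges, n = 5) {
  # identical binary networks on n vertices (different id sets), plus an
  # identity-like alignment and a diagonal similarity
  A <- matrix(0, n, n)
  for (e in edges) A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  g <- make_network(A, sprintf("a%d", 1:n))
  g2 <- make_network(A, sprintf("b%d", 1:n))
  th <- make_similarity(g$vertex_ids, g2$vertex_ids, diag(n))
  a <- make_alignment(g$vertex_ids, g2$vertex_ids)
  list(g = g, g2 = g2, theta = th, a = a)
}

test_that("tables from an identity alignment of identical networks reward conserved edges", {
  px <- make_pair_copy(list(c(1, 2), c(1, 3), c(2, 3), c(4, 5)))
  bins <- binary_bins()
  tb <- suppressWarnings(
    estimate_score_tables(px$g, px$g2, px$theta, px$a, bins,
                          pseudocount = 0.01))
  # hand count over the 10 induced pairs: 4 conserved edges, 6 conserved gaps
  counts <- matrix(c(6, 0, 0, 4), 2, 2) + 0.01
  expect_equal(tb$joint_edge, counts / sum(counts))
  expect_gt(tb$s_edge[2, 2], 0)
  expect_gt(tb$s_edge[1, 1], 0)
  expect_lt(tb$s_edge[2, 1], 0)
  expect_lt(tb$s_edge[1, 2], 0)
  # every distribution is a proper probability vector/matrix
  for (nm in c("joint_edge", "marginal_edge_g", "marginal_edge_g2",
               "q_ortho_theta", "q_unrel_theta", "background_theta")) {
    expect_true(all(tb[[nm]] >= 0))
    expect_lt(abs(sum(tb[[nm]]) - 1), 1e-9)
  }
  expect_true(all(is.finite(unlist(tb[c("s_edge", "s_aligned",
                                        "s_not_aligned")]))))
})

test_that("a very large pseudocount flattens every edge score to zero", {
  set.seed(11)
  g <- random_network(60, prefix = "a")
  g2 <- random_network(60, prefix = "b")
  th <- random_similarity(g, g2)
  a <- make_alignment(g$vertex_ids[1:30], g2$vertex_ids[1:30])
  tb <- estimate_score_tables(g, g2, th, a, binary_bins(), pseudocount = 1e8)
  expect_lt(max(abs(tb$s_edge)), 1e-3)
})

test_that("edge_score reproduces the log-ratio of a given count table", {
  bins <- binary_bins()
  tb <- tables_from_counts(matrix(c(30, 10, 10, 50), 2, 2, byrow = TRUE),
                           c(0.4, 0.6), c(0.4, 0.6),
                           c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5), bins)
  expect_equal(edge_score(tb, 0, 0), log(0.30 / 0.16), tolerance = 1e-12)
  expect_equal(edge_score(tb, 1, 1), log(0.50 / 0.36), tolerance = 1e-12)
  # factorising joint gives identically zero scores
  marg <- c(0.3, 0.7)
  tb0 <- tables_from_counts(outer(marg, marg), marg, marg,
                            c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5), bins)
  for (w in c(0, 1)) for (w2 in c(0, 1))
    expect_lt(abs(edge_score(tb0, w, w2)), 1e-9)
  # lookup contract: query (1,1) is exactly the table cell
  expect_identical(edge_score(tb, 1, 1), tb$s_edge[2, 2])
})

test_that("vertex scores vanish when Q equals the background and follow log ratios", {
  bins <- binary_bins()
  tb <- tables_from_counts(matrix(0.25, 2, 2), c(.5, .5), c(.5, .5),
                           q_ortho = c(0.2, 0.8), q_unrel = c(0.8, 0.2),
                           background = c(0.8, 0.2), bins)
  vs <- vertex_scores(tb, 0.9) # falls in bin 2
  expect_equal(vs$s_aligned, log(0.8 / 0.2), tolerance = 1e-12)
  expect_equal(vs$s_not_aligned, 0, tolerance = 1e-12)
  tb2 <- tables_from_counts(matrix(0.25, 2, 2), c(.5, .5), c(.5, .5),
                            q_ortho = c(0.6, 0.4), q_unrel = c(0.6, 0.4),
                            background = c(0.6, 0.4), bins)
  expect_equal(vertex_scores(tb2, 0)$s_aligned, 0, tolerance = 1e-12)
  expect_equal(vertex_scores(tb2, 0.7)$s_not_aligned, 0, tolerance = 1e-12)
})

test_that("edge and vertex totals match explicit enumeration oracles", {
  set.seed(21)
  bins <- binary_bins()
  g <- random_network(8, prefix = "a")
  g2 <- random_network(8, prefix = "b")
  th <- random_similarity(g, g2, density = 0.5)
  seed_a <- random_alignment(g, g2, 5)
  tb <- suppressWarnings(estimate_score_tables(g, g2, th, seed_a, bins))

  expect_equal(edge_score_total(g, g2, make_alignment(), tb), 0)
  a1 <- random_alignment(g, g2, 1)
  expect_equal(edge_score_total(g, g2, a1, tb), 0)

  a4 <- random_alignment(g, g2, 4)
  orc <- oracle_total_score(g, g2, th, a4, tb, bins)
  expect_equal(edge_score_total(g, g2, a4, tb), orc$edge, tolerance = 1e-10)
  expect_equal(vertex_score_total(th, a4, tb), orc$vertex, tolerance = 1e-10)

  # flat score tables give zero regardless of the alignment
  flat <- tables_from_counts(matrix(0.25, 2, 2), c(.5, .5), c(.5, .5),
                             c(.5, .5), c(.5, .5), c(.5, .5), bins)
  expect_equal(vertex_score_total(th, a4, flat), 0, tolerance = 1e-12)
  expect_equal(vertex_score_total(th, make_alignment(), tb), 0)
})

test_that("total score is additive and matches the brute-force oracle up to N = 12", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    g <- random_network(n, prefix = "a", binary = rep %% 2 == 0)
    g2 <- random_network(n, prefix = "b", binary = rep %% 2 == 0)
    th <- random_similarity(g, g2, density = 0.5)
    bins <- make_bins(g, g2, th, n_edge_bins = 3, n_theta_bins = 3)
    seed_a <- random_alignment(g, g2, max(2, n %/% 2))
    tb <- suppressWarnings(estimate_score_tables(g, g2, th, seed_a, bins))
    a <- random_alignment(g, g2, sample(0:n, 1))
    sc <- total_score(g, g2, th, a, tb, bins)
    expect_equal(sc$total, sc$edge + sc$vertex, tolerance = 1e-12)
    orc <- oracle_total_score(g, g2, th, a, tb, bins)
    expect_equal(sc$total, orc$total, tolerance = 1e-9)
  }
})

test_that("the identity alignment of identical networks beats any transposition", {
  set.seed(41)
  n <- 6
  px <- make_pair_copy(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                            c(1, 6), c(2, 5)), n = n)
  bins <- binary_bins()
  tb <- suppressWarnings(
    estimate_score_tables(px$g, px$g2, px$theta, px$a, bins))
  sc_id <- total_score(px$g, px$g2, px$theta, px$a, tb, bins)$total
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      to <- px$g2$vertex_ids
      to[c(i, j)] <- to[c(j, i)]
      sc <- total_score(px$g, px$g2, px$theta,
                        make_alignment(px$g$vertex_ids, to), tb, bins)$total
      expect_lt(sc, sc_id)
    }
  }
})

test_that("edge scores are invariant under swapping the networks with pooled marginals", {
  set.seed(51)
  g <- random_network(12, prefix = "a", binary = FALSE)
  g2 <- random_network(12, prefix = "b", binary = FALSE)
  th <- random_similarity(g, g2, density = 0.4)
  bins <- make_bins(g, g2, th)
  a <- random_alignment(g, g2, 7)
  tb <- suppressWarnings(
    estimate_score_tables(g, g2, th, a, bins, pool_marginals = TRUE))
  tht <- structure(list(theta = Matrix::t(th$theta)), class = "vertexsim")
  tbt <- suppressWarnings(
    estimate_score_tables(g2, g, tht, invert_alignment(a), bins,
                          pool_marginals = TRUE))
  # the edge tables of the swapped run are the exact transpose, so the edge
  # component is identical; the similarity tables of the orthologs coincide
  expect_equal(tbt$s_edge, t(tb$s_edge), tolerance = 1e-12)
  expect_equal(tbt$q_ortho_theta, tb$q_ortho_theta, tolerance = 1e-12)
  sc <- total_score(g, g2, th, a, tb, bins)
  sct <- total_score(g2, g, tht, invert_alignment(a), tbt, bins)
  expect_equal(sc$edge, sct$edge, tolerance = 1e-9)
})

test_that("score tables round-trip through their TSV serialization bit-exactly", {
  set.seed(61)
  g <- random_network(15, prefix = "a", binary = FALSE)
  g2 <- random_network(15, prefix = "b", binary = FALSE)
  th <- random_similarity(g, g2)
  bins <- make_bins(g, g2, th)
  a <- random_alignment(g, g2, 8)
  tb <- suppressWarnings(estimate_score_tables(g, g2, th, a, bins))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_tables(tb, path)
  tb2 <- read_score_tables(path)
  for (nm in c("joint_edge", "s_edge", "marginal_edge_g", "marginal_edge_g2",
               "q_ortho_theta", "q_unrel_theta", "background_theta",
               "s_aligned", "s_not_aligned", "pseudocount"))
    expect_identical(unname(tb2[[nm]]), unname(tb[[nm]]), label = nm)
  expect_identical(tb2$bins$edge_bin_edges, tb$bins$edge_bin_edges)
})
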