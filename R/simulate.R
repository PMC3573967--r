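#' Configuration of a simulated benchmark scenario
#'
#' Describes a pair of networks evolved from a common ancestor, with known
#' ground truth, used to benchmark the aligner:
#'
#' * scenario `"i"` — a fraction of vertices are orthologs (descend from one
#'   ancestral vertex); their mutual edge states are conserved with a given
#'   probability; a fraction of the orthologs additionally carries high
#'   vertex similarity, the rest are analogs (recognisable only through
#'   their interactions). Edge weights are uniform on \[0, 1\].
#' * scenario `"ia"` — as `"i"` but edge weights drawn from a truncated
#'   normal distribution.
#' * scenario `"ii"` — as `"i"`, plus a further fraction of orthologs
#'   (disjoint from the plain vertex-similar set) that each get a decoy
#'   paralog in the second network: a vertex with *exactly equal* vertex
#'   similarity but independent random interactions. Resolving the decoy
#'   requires using edge information.
#' * scenario `"iii"` — as `"ii"`, plus spurious weak similarities sprinkled
#'   over random vertex pairs, emulating noise in real similarity data.
#'
#' @param scenario one of `"i"`, `"ia"`, `"ii"`, `"iii"`.
#' @param n vertices per network (>= 4).
#' @param frac_ortholog fraction of vertices with a true partner
#'   (default 0.8).
#' @param edge_density probability of each possible edge (default 0.5).
#' @param interaction_similarity probability that an ortholog-pair edge state
#'   is conserved between the networks (default 0.6).
#' @param frac_vertex_similar_of_orthologs fraction of orthologs given high
#'   vertex similarity, not counting paralog cases (default 0.625).
#' @param frac_paralog_of_orthologs fraction of orthologs given a decoy
#'   paralog (default 0.125; scenarios `"ii"`/`"iii"` only).
#' @param spurious_rate expected spurious weak similarities per vertex
#'   (default 1; scenario `"iii"` only).
#' @param weight_distribution `"uniform"` or `"normal"`; defaults to
#'   `"normal"` for scenario `"ia"`, `"uniform"` otherwise.
#' @param seed integer seed; the generated pair is fully reproducible.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("i", "ia", "ii", "iii"), n = 200,
                            frac_ortholog = 0.8, edge_density = 0.5,
                            interaction_similarity = 0.6,
                            frac_vertex_similar_of_orthologs = 0.625,
                            frac_paralog_of_orthologs = 0.125,
                            spurious_rate = 1,
                            weight_distribution = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  if (is.null(weight_distribution))
    weight_distribution <- if (scenario == "ia") "normal" else "uniform"
  weight_distribution <- match.arg(weight_distribution, c("uniform", "normal"))
  fr <- c(frac_ortholog, edge_density, interaction_similarity,
          frac_vertex_similar_of_orthologs, frac_paralog_of_orthologs)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (n < 4) stop("n must be at least 4")
  structure(list(scenario = scenario, n = as.integer(n),
                 frac_ortholog = frac_ortholog, edge_density = edge_density,
                 interaction_similarity = interaction_similarity,
                 frac_vertex_similar_of_orthologs =
                   frac_vertex_similar_of_orthologs,
                 frac_paralog_of_orthologs = frac_paralog_of_orthologs,
                 spurious_rate = spurious_rate,
                 weight_distribution = weight_distribution,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# weight draws on the common (0, 1] scale; the normal variant is a
# mean-0.5, sd-0.15 normal truncated to (0, 1) by inverse-CDF sampling so no
# probability mass collapses onto 0 (which would delete edges)
draw_weights <- function(n, distribution) {
  u <- stats::runif(n)
  if (distribution == "uniform") {
    u
  } else {
    plo <- stats::pnorm(0, 0.5, 0.15)
    phi <- stats::pnorm(1, 0.5, 0.15)
    stats::qnorm(plo + u * (phi - plo), 0.5, 0.15)
  }
}

#' Generate a simulated network pair with ground truth
#'
#' Builds an ancestor network at the configured edge density, copies it into
#' both networks restricted to the ortholog pairs — resampling each
#' ortholog-pair edge state independently in both copies with probability
#' 1 - `interaction_similarity` — and gives every non-ortholog vertex
#' independent random edges at the same density. High vertex similarity
#' (uniform on 0.75-1) is assigned to the configured fraction of ortholog
#' pairs; paralog decoys occupy non-ortholog slots of the second network and
#' copy the true partner's similarity value exactly; spurious weak
#' similarities (uniform on 0.05-0.3) go to random unrelated pairs. All
#' category counts are exact by construction (rounded), not merely expected.
#' The mapping of orthologs onto the second network is a random permutation,
#' so the true alignment is never the identity by accident.
#'
#' @param config a [scenario_config()].
#' @return An object of class `"simulated_pair"`: list with networks `g`,
#'   `g2`, similarity `theta`, `truth` (a `netalignment` with the true
#'   pairs), `labels` (per-vertex category of `g` in
#'   `ortholog_vertex_similar`, `analog`, `paralog_case`, `unrelated`),
#'   `decoys` (named character vector: paralog-case vertex of `g` -> decoy
#'   vertex of `g2`), and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n
  n_orth <- round(config$frac_ortholog * n)
  n_vs <- round(config$frac_vertex_similar_of_orthologs * n_orth)
  n_par <- if (config$scenario %in% c("ii", "iii"))
    round(config$frac_paralog_of_orthologs * n_orth) else 0L
  if (n_vs + n_par > n_orth)
    stop("vertex-similar plus paralog fractions exceed the ortholog count")
  if (n_par > n - n_orth)
    stop("paralog decoys require more non-ortholog slots in the second ",
         "network than exist (", n_par, " > ", n - n_orth, ")")

  ids_g <- sprintf("a%04d", seq_len(n))
  ids_g2 <- sprintf("b%04d", seq_len(n))

  # orthologs are the first n_orth vertices of g, mapped onto a random
  # subset/permutation of g2
  partner <- rep(NA_integer_, n)
  partner[seq_len(n_orth)] <- sample.int(n, n_orth)
  dist <- config$weight_distribution

  # Ancestor edge states among ortholog pairs. A pair's state is conserved
  # (kept identical in both copies) with probability interaction_similarity;
  # otherwise the two copies diverge: their states are redrawn from the
  # maximally diverged coupling that preserves the marginal edge density but
  # never reproduces an identical state (at density 0.5 exactly one of the
  # two copies carries the edge). The realised conservation therefore equals
  # the configured probability, and the density stays at its configured value.
  #
  # All structural randomness (edge presence, categories, similarities) is
  # drawn before the edge weights, so scenarios differing only in the weight
  # distribution share their whole structure under the same seed.
  d <- config$edge_density
  npair <- n_orth * (n_orth - 1L) / 2L
  anc_present <- stats::runif(npair) < d
  conserved <- stats::runif(npair) < config$interaction_similarity
  u <- stats::runif(npair)
  present1 <- ifelse(conserved, anc_present, u < d)
  present2 <- ifelse(conserved, anc_present, u > 1 - d)
  member1 <- seq_len(n) <= n_orth
  member2 <- seq_len(n) %in% partner[seq_len(n_orth)]
  ut_full <- upper.tri(matrix(0, n, n))
  miss1 <- which(ut_full & (!member1[row(ut_full)] | !member1[col(ut_full)]))
  miss2 <- which(ut_full & (!member2[row(ut_full)] | !member2[col(ut_full)]))
  rest1_present <- stats::runif(length(miss1)) < d
  rest2_present <- stats::runif(length(miss2)) < d

  # vertex categories among the orthologs
  orth_idx <- seq_len(n_orth)
  vs_idx <- sort(sample(orth_idx, n_vs))
  par_idx <- if (n_par > 0) sort(sample(setdiff(orth_idx, vs_idx), n_par))
             else integer()
  labels <- rep("unrelated", n)
  labels[orth_idx] <- "analog"
  labels[vs_idx] <- "ortholog_vertex_similar"
  labels[par_idx] <- "paralog_case"
  names(labels) <- ids_g

  sim_i <- c(vs_idx, par_idx)
  sim_j <- partner[sim_i]
  sim_x <- stats::runif(length(sim_i), 0.75, 1)

  decoys <- character(0)
  if (n_par > 0) {
    free_slots <- setdiff(seq_len(n), partner[orth_idx])
    decoy_j <- sample(free_slots, n_par)
    # the decoy's similarity equals the true partner's exactly
    decoy_x <- sim_x[match(par_idx, sim_i)]
    sim_i <- c(sim_i, par_idx)
    sim_j <- c(sim_j, decoy_j)
    sim_x <- c(sim_x, decoy_x)
    decoys <- stats::setNames(ids_g2[decoy_j], ids_g[par_idx])
  }

  if (config$scenario == "iii" && config$spurious_rate > 0) {
    n_spur <- round(config$spurious_rate * n)
    taken <- sim_i + n * (sim_j - 1L)
    cand <- setdiff(sample.int(n * n, min(n * n, 4L * n_spur + 16L)), taken)
    cand <- utils::head(cand, n_spur)
    sim_i <- c(sim_i, (cand - 1L) %% n + 1L)
    sim_j <- c(sim_j, (cand - 1L) %/% n + 1L)
    sim_x <- c(sim_x, stats::runif(length(cand), 0.05, 0.3))
  }

  # edge weights last: the only distribution-dependent draws
  anc_w <- draw_weights(npair, dist)
  w1 <- draw_weights(npair, dist)
  w2 <- draw_weights(npair, dist)
  s1 <- ifelse(conserved, anc_present * anc_w, (u < d) * w1)
  s2 <- ifelse(conserved, anc_present * anc_w, (u > 1 - d) * w2)
  A <- matrix(0, n, n)
  A2 <- matrix(0, n, n)
  ut <- which(upper.tri(matrix(0, n_orth, n_orth)), arr.ind = TRUE)
  A[cbind(ut[, 1], ut[, 2])] <- s1
  p1 <- partner[ut[, 1]]; p2 <- partner[ut[, 2]]
  A2[cbind(pmin(p1, p2), pmax(p1, p2))] <- s2
  A[miss1] <- rest1_present * draw_weights(length(miss1), dist)
  A2[miss2] <- rest2_present * draw_weights(length(miss2), dist)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A2[lower.tri(A2)] <- t(A2)[lower.tri(A2)]

  g <- make_network(A, ids_g, directed = FALSE, weight_kind = "continuous")
  g2 <- make_network(A2, ids_g2, directed = FALSE, weight_kind = "continuous")

  theta <- make_similarity(ids_g, ids_g2,
                           data.frame(row = ids_g[sim_i], col = ids_g2[sim_j],
                                      theta = sim_x))
  truth <- make_alignment(ids_g[orth_idx], ids_g2[partner[orth_idx]])
  structure(list(g = g, g2 = g2, theta = theta, truth = truth,
                 labels = labels, decoys = decoys, config = config),
            class = "simulated_pair")
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat(sprintf("<simulated_pair> scenario %s, n = %d, seed = %d\n",
              x$config$scenario, x$config$n, x$config$seed))
  print(table(x$labels))
  invisible(x)
}

#' Empirical edge density of a network
#'
#' Fraction of all possible distinct vertex pairs that carry an edge
#' (unordered pairs for undirected networks, ordered for directed).
#'
#' @param g a `netgraph`.
#' @return Scalar in \[0, 1\].
#' @export
empirical_edge_density <- function(g) {
  n <- n_vertices(g)
  if (n < 2) return(0)
  if (g$directed) {
    sum(g$adjacency != 0) / (n * (n - 1))
  } else {
    sum(g$adjacency[upper.tri(g$adjacency)] != 0) / (n * (n - 1) / 2)
  }
}

#' Empirical edge-state conservation between true ortholog pairs
#'
#' Fraction of unordered pairs of true partner vertices whose edge states are
#' identical in the two networks — the realised interaction similarity of a
#' simulated pair.
#'
#' @param pair a `simulated_pair` with at least 2 true pairs.
#' @return Scalar in \[0, 1\].
#' @export
empirical_conservation <- function(pair) {
  stopifnot(inherits(pair, "simulated_pair"))
  tr <- pair$truth
  if (length(tr) < 2) stop("need at least 2 true pairs")
  fi <- match(tr$from, pair$g$vertex_ids)
  ti <- match(tr$to, pair$g2$vertex_ids)
  sub <- pair$g$adjacency[fi, fi, drop = FALSE]
  sub2 <- pair$g2$adjacency[ti, ti, drop = FALSE]
  sel <- upper.tri(sub)
  mean(sub[sel] == sub2[sel])
}
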