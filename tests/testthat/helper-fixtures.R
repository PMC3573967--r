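# fixtures and independent oracles used across the test files

# random symmetric network with given edge density; binary or uniform weights
random_network <- function(n, density = 0.5, prefix = "v", binary = TRUE,
                           directed = FALSE) {
  w <- if (binary) rbinom(n * n, 1, density)
       else runif(n * n) * (runif(n * n) < density)
  A <- matrix(w, n, n)
  if (!directed) A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  make_network(A, sprintf("%s%03d", prefix, seq_len(n)), directed = directed)
}

random_similarity <- function(g, g2, density = 0.3) {
  n <- length(g$vertex_ids); n2 <- length(g2$vertex_ids)
  m <- matrix(runif(n * n2) * (runif(n * n2) < density), n, n2)
  make_similarity(g$vertex_ids, g2$vertex_ids, m)
}

# random injective partial map as a netalignment
random_alignment <- function(g, g2, k) {
  make_alignment(sample(g$vertex_ids, k), sample(g2$vertex_ids, k))
}

# brute-force total score: elementary per-pair lookups in explicit loops,
# independent of the vectorised/sparse paths in the package
oracle_total_score <- function(g, g2, theta, a, tables, bins) {
  k <- length(a$from)
  se <- 0
  if (k >= 2) {
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) {
        w <- g$adjacency[a$from[p], a$from[q]]
        w2 <- g2$adjacency[a$to[p], a$to[q]]
        se <- se + edge_score(tables, w, w2, bins)
      }
    }
  }
  sv <- 0
  Th <- as.matrix(theta$theta)
  for (p in seq_len(k)) {
    i <- a$from[p]; i2 <- a$to[p]
    sv <- sv + vertex_scores(tables, Th[i, i2], bins)$s_aligned
    for (j2 in colnames(Th)) {
      if (j2 == i2) next
      sv <- sv + vertex_scores(tables, Th[i, j2], bins)$s_not_aligned
    }
  }
  list(total = se + sv, edge = se, vertex = sv)
}

# all injective partial maps from 1..n to 1..n2, as a list of integer vectors
# (NA = unaligned); grows fast, keep n, n2 <= 6
all_partial_maps <- function(n, n2) {
  res <- list()
  recurse <- function(i, map, used) {
    if (i > n) {
      res[[length(res) + 1L]] <<- map
      return(invisible(NULL))
    }
    recurse(i + 1L, map, used)
    for (j in seq_len(n2)) {
      if (!used[j]) {
        map2 <- map; map2[i] <- j
        used2 <- used; used2[j] <- TRUE
        recurse(i + 1L, map2, used2)
      }
    }
  }
  recurse(1L, rep(NA_integer_, n), rep(FALSE, n2))
  res
}

# all permutations of 1..n
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub)))))
}

alignment_to_index_map <- function(a, g, g2) {
  map <- rep(NA_integer_, length(g$vertex_ids))
  map[match(a$from, g$vertex_ids)] <- match(a$to, g2$vertex_ids)
  map
}

# precomputed-lookup scorer over integer index maps, for exhaustive
# enumeration; cross-checked against total_score() where used
fast_map_scorer <- function(g, g2, theta, tables, bins) {
  n <- length(g$vertex_ids); n2 <- length(g2$vertex_ids)
  BA <- matrix(netalign:::bin_edge_weight(g$adjacency, bins), n, n)
  BA2 <- matrix(netalign:::bin_edge_weight(g2$adjacency, bins), n2, n2)
  THb <- matrix(netalign:::bin_theta_value(as.matrix(theta$theta), bins),
                n, n2)
  s_al <- matrix(tables$s_aligned[THb], n, n2)
  s_na <- matrix(tables$s_not_aligned[THb], n, n2)
  row_na <- rowSums(s_na)
  s_edge <- tables$s_edge
  function(map) {
    fi <- which(!is.na(map))
    k <- length(fi)
    if (k == 0) return(0)
    ti <- map[fi]
    se <- 0
    if (k >= 2) {
      sub <- BA[fi, fi, drop = FALSE]
      sub2 <- BA2[ti, ti, drop = FALSE]
      sel <- upper.tri(sub)
      se <- sum(s_edge[cbind(sub[sel], sub2[sel])])
    }
    pick <- cbind(fi, ti)
    se + sum(s_al[pick]) + sum(row_na[fi]) - sum(s_na[pick])
  }
}

index_map_to_alignment <- function(map, g, g2) {
  fi <- which(!is.na(map))
  make_alignment(g$vertex_ids[fi], g2$vertex_ids[map[fi]])
}

# score tables built directly from given count tables / marginal fractions,
# bypassing estimate_score_tables (arithmetic per the table definitions)
tables_from_counts <- function(joint_counts, marg_g, marg_g2,
                               q_ortho, q_unrel, background, bins) {
  joint <- joint_counts / sum(joint_counts)
  structure(list(
    joint_edge = joint,
    marginal_edge_g = marg_g, marginal_edge_g2 = marg_g2,
    q_ortho_theta = q_ortho, q_unrel_theta = q_unrel,
    background_theta = background,
    s_edge = log(joint / outer(marg_g, marg_g2)),
    s_aligned = log(q_ortho / background),
    s_not_aligned = log(q_unrel / background),
    pseudocount = 0, pool_marginals = FALSE, bins = bins),
    class = "score_tables")
}

# two edge bins ({0}, {1}) and two similarity bins ({0}, (0, 1])
binary_bins <- function() {
  structure(list(edge_bin_edges = c(0, 0.5, 1),
                 theta_bin_edges = c(0, 1)),
            class = "bin_spec")
}
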