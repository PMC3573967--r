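#' Estimate likelihood-ratio score tables from an alignment
#'
#' Given an alignment assumed to pair orthologous vertices, estimates the
#' empirical distributions that parameterise the alignment score and turns
#' them into log-likelihood-ratio lookup tables:
#'
#' * `joint_edge` — joint distribution of the binned edge states
#'   (A\[i,j\], A'\[A(i),A(j)\]) over all pairs of distinct aligned vertices;
#'   its log-ratio against the product of the marginal edge distributions of
#'   the two whole networks is the edge score `s_edge`. When the joint
#'   factorises into the marginals the edge states carry no information on
#'   shared ancestry and the score vanishes.
#' * `q_ortho_theta` — distribution of vertex similarities between aligned
#'   partners; its log-ratio against the background similarity distribution
#'   is `s_aligned`.
#' * `q_unrel_theta` — distribution of similarities between an aligned vertex
#'   and the non-partner vertices of the other network; its log-ratio against
#'   the background is `s_not_aligned`.
#'
#' The background distribution is estimated from similarities involving at
#' least one unaligned vertex (vertices that emerged or disappeared after
#' speciation); when fewer than `10 * K` such pairs exist (K similarity bins)
#' it falls back to all similarity values, with a warning. Every histogram
#' cell receives `pseudocount` before normalisation so all scores are finite.
#'
#' @param g,g2 the two `netgraph` objects.
#' @param theta a `vertexsim` covering the vertex sets of `g` (rows) and
#'   `g2` (columns).
#' @param a a `netalignment` with at least 2 pairs.
#' @param bins a `bin_spec` (see [make_bins()]).
#' @param pseudocount positive smoothing count added to every histogram cell
#'   (default 1, Laplace smoothing).
#' @param pool_marginals if `TRUE` (default) the marginal edge distributions
#'   of the two networks are pooled into one shared estimate, which makes
#'   every score exactly symmetric under exchanging the two networks.
#' @return An object of class `"score_tables"` with the empirical
#'   distributions, the score tables `s_edge`, `s_aligned`, `s_not_aligned`
#'   (natural logarithms), and the settings used.
#' @export
estimate_score_tables <- function(g, g2, theta, a, bins, pseudocount = 1,
                                  pool_marginals = TRUE) {
  stopifnot(inherits(g, "netgraph"), inherits(g2, "netgraph"),
            inherits(theta, "vertexsim"), inherits(a, "netalignment"),
            inherits(bins, "bin_spec"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  k <- length(a$from)
  if (k < 2) stop("need at least 2 aligned pairs to estimate score tables")
  B <- n_edge_bins(bins)
  K <- n_theta_bins(bins)
  N <- n_vertices(g); N2 <- n_vertices(g2)
  fi <- match(a$from, g$vertex_ids)
  ti <- match(a$to, g2$vertex_ids)
  if (anyNA(fi) || anyNA(ti)) stop("alignment refers to unknown vertex")
  directed <- g$directed || g2$directed

  BA <- matrix(bin_edge_weight(g$adjacency, bins), N, N)
  BA2 <- matrix(bin_edge_weight(g2$adjacency, bins), N2, N2)

  # joint over induced edge pairs
  sub <- BA[fi, fi, drop = FALSE]
  sub2 <- BA2[ti, ti, drop = FALSE]
  sel <- if (directed) row(sub) != col(sub) else upper.tri(sub)
  joint_counts <- matrix(tabulate(sub[sel] + B * (sub2[sel] - 1L), nbins = B * B),
                         B, B)

  # marginals over all distinct vertex pairs of each whole network
  off1 <- if (directed) BA[row(BA) != col(BA)] else BA[upper.tri(BA)]
  off2 <- if (directed) BA2[row(BA2) != col(BA2)] else BA2[upper.tri(BA2)]
  cnt_g <- tabulate(off1, nbins = B)
  cnt_g2 <- tabulate(off2, nbins = B)
  if (pool_marginals) {
    pooled <- cnt_g + cnt_g2
    cnt_g <- pooled
    cnt_g2 <- pooled
  }

  Th <- theta$theta
  # similarities between aligned partners
  th_pairs <- as.numeric(Th[cbind(fi, ti)])
  cnt_ortho <- tabulate(bin_theta_value(th_pairs, bins), nbins = K)

  # similarities between aligned vertices and their non-partners in g2
  nz_rows <- sparse_row_nonzeros(Th, fi)
  cnt_unrel <- tabulate(bin_theta_value(nz_rows, bins), nbins = K) -
    tabulate(bin_theta_value(th_pairs[th_pairs > 0], bins), nbins = K)
  cnt_unrel[1] <- cnt_unrel[1] + (k * (N2 - 1L) - sum(nz_rows > 0) +
                                    sum(th_pairs > 0))

  # background: similarities involving at least one unaligned vertex
  n_bg <- N * N2 - k * k
  if (n_bg >= 10 * K) {
    nz_all <- Th@x[Th@x != 0]
    nz_alal <- sparse_submatrix_nonzeros(Th, fi, ti)
    cnt_bg <- tabulate(bin_theta_value(nz_all, bins), nbins = K) -
      tabulate(bin_theta_value(nz_alal, bins), nbins = K)
    cnt_bg[1] <- cnt_bg[1] + (n_bg - (length(nz_all) - length(nz_alal)))
  } else {
    warning("fewer than ", 10 * K, " background similarity pairs; ",
            "falling back to all similarity values for P(theta)")
    cnt_bg <- tabulate(bin_theta_value(Th@x, bins), nbins = K)
    cnt_bg[1] <- cnt_bg[1] + (N * N2 - length(Th@x))
  }

  normalize <- function(cnt) {
    cnt <- cnt + pseudocount
    cnt / sum(cnt)
  }
  joint_edge <- normalize(joint_counts)
  marginal_edge_g <- normalize(cnt_g)
  marginal_edge_g2 <- normalize(cnt_g2)
  q_ortho_theta <- normalize(cnt_ortho)
  q_unrel_theta <- normalize(cnt_unrel)
  background_theta <- normalize(cnt_bg)

  s_edge <- log(joint_edge / outer(marginal_edge_g, marginal_edge_g2))
  s_aligned <- log(q_ortho_theta / background_theta)
  s_not_aligned <- log(q_unrel_theta / background_theta)

  structure(list(
    joint_edge = joint_edge,
    marginal_edge_g = marginal_edge_g,
    marginal_edge_g2 = marginal_edge_g2,
    q_ortho_theta = q_ortho_theta,
    q_unrel_theta = q_unrel_theta,
    background_theta = background_theta,
    s_edge = s_edge,
    s_aligned = s_aligned,
    s_not_aligned = s_not_aligned,
    pseudocount = pseudocount,
    pool_marginals = pool_marginals,
    bins = bins), class = "score_tables")
}

#' @export
print.score_tables <- function(x, ...) {
  cat(sprintf("<score_tables> %d edge bins, %d theta bins, pseudocount %g%s\n",
              nrow(x$s_edge), length(x$s_aligned), x$pseudocount,
              if (x$pool_marginals) ", pooled marginals" else ""))
  invisible(x)
}

# nonzero values of the rows `fi` of a CsparseMatrix
sparse_row_nonzeros <- function(m, fi) {
  tm <- methods::as(Matrix::t(m), "CsparseMatrix") # columns = original rows
  idx <- unlist(lapply(fi, function(i) {
    if (tm@p[i] < tm@p[i + 1L]) (tm@p[i] + 1L):tm@p[i + 1L] else integer()
  }))
  x <- tm@x[idx]
  x[x != 0]
}

# nonzero values of the [fi, ti] submatrix of a CsparseMatrix
sparse_submatrix_nonzeros <- function(m, fi, ti) {
  sub <- m[fi, ti, drop = FALSE]
  sub <- methods::as(sub, "CsparseMatrix")
  sub@x[sub@x != 0]
}

#' Edge score of a pair of edge states
#'
#' Looks up the log-likelihood ratio comparing the hypothesis that the two
#' edge states descend from a common ancestral edge against the hypothesis
#' that they are independent draws from the networks' marginal edge
#' distributions. Out-of-range weights are clamped to the extreme bins.
#'
#' @param tables a `score_tables` object.
#' @param w,w2 edge weights in the first and second network (vectorised).
#' @param bins the `bin_spec` the tables were built with.
#' @return Numeric vector of scores.
#' @export
edge_score <- function(tables, w, w2, bins = tables$bins) {
  tables$s_edge[cbind(bin_edge_weight(w, bins), bin_edge_weight(w2, bins))]
}

#' Vertex-similarity scores of a similarity value
#'
#' Returns both vertex-score lookups for a similarity value: `s_aligned`,
#' weighing the hypothesis that the pair is orthologous, and
#' `s_not_aligned`, weighing the presence of vertex-similar pairs that are
#' not aligned to each other.
#'
#' @param tables a `score_tables` object.
#' @param theta_value non-negative similarity value(s).
#' @param bins the `bin_spec` the tables were built with.
#' @return A list with components `s_aligned` and `s_not_aligned` (vectors).
#' @export
vertex_scores <- function(tables, theta_value, bins = tables$bins) {
  b <- bin_theta_value(theta_value, bins)
  list(s_aligned = tables$s_aligned[b],
       s_not_aligned = tables$s_not_aligned[b])
}

#' Total edge score of an alignment
#'
#' Sums the edge score over all induced edge pairs — every pair of distinct
#' aligned vertices, whether or not an edge is present on either side
#' (unordered pairs for undirected networks, ordered for directed).
#'
#' @inheritParams estimate_score_tables
#' @param tables a `score_tables` object.
#' @return Scalar edge score.
#' @export
edge_score_total <- function(g, g2, a, tables, bins = tables$bins) {
  k <- length(a$from)
  if (k < 2) return(0)
  fi <- match(a$from, g$vertex_ids)
  ti <- match(a$to, g2$vertex_ids)
  sub <- matrix(bin_edge_weight(g$adjacency[fi, fi, drop = FALSE], bins), k, k)
  sub2 <- matrix(bin_edge_weight(g2$adjacency[ti, ti, drop = FALSE], bins), k, k)
  sel <- if (g$directed || g2$directed) row(sub) != col(sub) else upper.tri(sub)
  sum(tables$s_edge[cbind(sub[sel], sub2[sel])])
}

#' Total vertex score of an alignment
#'
#' Sums, over every aligned vertex i, the `s_aligned` score of its similarity
#' to its partner plus the `s_not_aligned` scores of its similarities to all
#' other vertices of the second network. Pairs without a recorded similarity
#' contribute through the reserved theta = 0 bin; the sum is evaluated
#' sparsely, adding the zero-bin score times the number of absent entries in
#' closed form, so the cost is proportional to the number of stored
#' similarities. The empty alignment scores exactly 0.
#'
#' @param theta a `vertexsim`.
#' @param a a `netalignment` whose identifiers appear in `theta`'s dimnames.
#' @param tables a `score_tables` object.
#' @param bins the `bin_spec` the tables were built with.
#' @return Scalar vertex score.
#' @export
vertex_score_total <- function(theta, a, tables, bins = tables$bins) {
  k <- length(a$from)
  if (k == 0) return(0)
  Th <- theta$theta
  fi <- match(a$from, rownames(Th))
  ti <- match(a$to, colnames(Th))
  if (anyNA(fi) || anyNA(ti)) stop("alignment refers to unknown vertex")
  N2 <- ncol(Th)
  th_pairs <- as.numeric(Th[cbind(fi, ti)])
  s_al <- sum(tables$s_aligned[bin_theta_value(th_pairs, bins)])
  nz <- sparse_row_nonzeros(Th, fi)
  s_na_zero <- tables$s_not_aligned[1]
  s_na <- sum(tables$s_not_aligned[bin_theta_value(nz, bins)]) +
    (k * N2 - length(nz)) * s_na_zero -
    sum(tables$s_not_aligned[bin_theta_value(th_pairs, bins)])
  s_al + s_na
}

#' Total alignment score
#'
#' The total score S(A) = Se(A) + Sv(A) of an alignment: the edge component
#' from conserved interactions plus the vertex component from cross-network
#' vertex similarity.
#'
#' @inheritParams edge_score_total
#' @param theta a `vertexsim`.
#' @return A list with components `total`, `edge`, `vertex`.
#' @export
total_score <- function(g, g2, theta, a, tables, bins = tables$bins) {
  se <- edge_score_total(g, g2, a, tables, bins)
  sv <- vertex_score_total(theta, a, tables, bins)
  list(total = se + sv, edge = se, vertex = sv)
}
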