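#' Aligner configuration
#'
#' Controls of the iterated linear-assignment search. The quadratic
#' assignment objective is linearised around the current alignment and solved
#' as a linear assignment problem (LAP); i.i.d. Gaussian noise with a
#' standard deviation decaying linearly to zero is added to the LAP matrix so
#' the search can escape local score maxima, as in simulated annealing.
#'
#' @param max_inner_iterations total LAP iterations per alignment search
#'   (default 100), shared across the annealing cycles.
#' @param noise_initial_sd initial standard deviation of the annealing noise,
#'   in score units (default 1). Within each cycle the noise decays linearly
#'   to 0 over the first two thirds of the cycle's iterations; the remainder
#'   runs noise-free so a fixed point can be detected.
#' @param restart_cycles number of annealing cycles (default 4): after a
#'   cycle settles, the search reheats — it restarts from the starting
#'   alignment with fresh noise — while the best alignment found so far is
#'   kept across cycles. With `noise_initial_sd = 0` extra cycles are
#'   deterministic repeats, so a single cycle is run.
#' @param max_outer_iterations alternations of parameter estimation and
#'   alignment (default 10).
#' @param convergence_patience consecutive unchanged alignments at zero
#'   noise that end a cycle (default 3).
#' @param random_seed integer seed making the search reproducible (default 1).
#' @param allow_unaligned if `TRUE` (default) vertices may stay unaligned:
#'   the LAP matrix is extended with zero-valued dummy rows and columns
#'   representing the "leave unaligned" option.
#' @return An object of class `"aligner_config"`.
#' @export
aligner_config <- function(max_inner_iterations = 100, noise_initial_sd = 1,
                           restart_cycles = 4,
                           max_outer_iterations = 10, convergence_patience = 3,
                           random_seed = 1, allow_unaligned = TRUE) {
  stopifnot(max_inner_iterations >= 1, noise_initial_sd >= 0,
            restart_cycles >= 1, max_outer_iterations >= 1,
            convergence_patience >= 1)
  structure(list(max_inner_iterations = as.integer(max_inner_iterations),
                 noise_initial_sd = noise_initial_sd,
                 restart_cycles = as.integer(restart_cycles),
                 max_outer_iterations = as.integer(max_outer_iterations),
                 convergence_patience = as.integer(convergence_patience),
                 random_seed = as.integer(random_seed),
                 allow_unaligned = isTRUE(allow_unaligned)),
            class = "aligner_config")
}

#' Seed alignment from bidirectional best similarity hits
#'
#' Returns the pairs (i, i') such that i' is i's unique highest-similarity
#' partner and vice versa (bidirectional best hits), restricted to
#' similarities of at least `min_theta`. Pairs whose best hit is tied are
#' discarded, which makes the result deterministic and injective by
#' construction — a paralog with a similarity exactly equal to the true
#' ortholog's therefore never enters the seed.
#'
#' @param theta a `vertexsim`.
#' @param min_theta minimal similarity for a seed pair (default 0; zero
#'   similarities never seed a pair regardless).
#' @return A `netalignment`.
#' @export
initial_alignment <- function(theta, min_theta = 0) {
  Th <- theta$theta
  tr <- Matrix::summary(Th)
  tr <- tr[tr$x > 0 & tr$x >= min_theta, , drop = FALSE]
  if (nrow(tr) == 0) return(make_alignment())
  rmax <- tapply(tr$x, tr$i, max)
  cmax <- tapply(tr$x, tr$j, max)
  is_rbest <- tr$x == rmax[as.character(tr$i)]
  is_cbest <- tr$x == cmax[as.character(tr$j)]
  # discard rows/columns whose best hit is tied
  rties <- tapply(is_rbest, tr$i, sum)
  cties <- tapply(is_cbest, tr$j, sum)
  keep <- is_rbest & is_cbest &
    rties[as.character(tr$i)] == 1L & cties[as.character(tr$j)] == 1L
  tr <- tr[keep, , drop = FALSE]
  make_alignment(rownames(Th)[tr$i], colnames(Th)[tr$j])
}

#' Linearised assignment matrix around a current alignment
#'
#' One step of the quadratic-to-linear assignment reduction: the benefit of
#' pairing i with i' is scored as the sum of edge scores of (i, j) against
#' (i', A(j)) over the currently aligned vertices j (j != i), plus the exact
#' vertex-score change of aligning i to i', i.e.
#' s_aligned(theta(i,i')) + the sum over j' != i' of
#' s_not_aligned(theta(i,j')). When `allow_unaligned` the matrix is extended
#' to a square with zero-valued dummy rows and columns so that every vertex
#' has a "stay unaligned" option on the same scale as the real cells.
#'
#' @inheritParams estimate_score_tables
#' @param current the alignment the linearisation is taken around (may be
#'   empty, leaving only the vertex term).
#' @param tables a `score_tables` object.
#' @param allow_unaligned extend with dummy rows/columns (default `TRUE`).
#' @param edge_factor scale of the edge term (default 0.5: in the assignment
#'   objective every unordered edge pair is seen from both endpoints' rows,
#'   so halving makes the objective of a full reassignment coincide with the
#'   alignment score it attains).
#' @return A numeric matrix of class `"assignment_matrix"`, with attributes
#'   `n_real_rows`/`n_real_cols` marking the real block.
#' @export
build_assignment_matrix <- function(g, g2, theta, current, tables,
                                    bins = tables$bins,
                                    allow_unaligned = TRUE,
                                    edge_factor = 0.5) {
  M <- assignment_matrix_real(g, g2, theta, alignment_index(current, g, g2),
                              tables, bins, edge_factor)
  dimnames(M) <- list(g$vertex_ids, g2$vertex_ids)
  extend_assignment_matrix(M, allow_unaligned)
}

# Real N x N2 block, current given as an integer index map. In the LAP
# objective sum_i M[i, sigma(i)] every edge pair (i, j) contributes from both
# endpoints' rows, i.e. twice, while the alignment score counts each unordered
# pair once; edge_factor = 1/2 rescales the edge term so the LAP objective of
# a full reassignment matches the score it actually attains.
assignment_matrix_real <- function(g, g2, theta, cur_map, tables, bins,
                                   edge_factor = 0.5) {
  N <- n_vertices(g); N2 <- n_vertices(g2)
  B <- n_edge_bins(bins)
  BA <- matrix(bin_edge_weight(g$adjacency, bins), N, N)
  BA2 <- matrix(bin_edge_weight(g2$adjacency, bins), N2, N2)
  fi <- which(!is.na(cur_map))
  M <- edge_factor *
    assignment_edge_term_cpp(BA, BA2, tables$s_edge, fi, cur_map[fi],
                             g$directed || g2$directed)
  # vertex term, filled sparsely over the theta = 0 baseline
  v0 <- tables$s_aligned[1] - tables$s_not_aligned[1]
  V <- matrix(v0, N, N2)
  tr <- Matrix::summary(theta$theta)
  if (nrow(tr) > 0) {
    b <- bin_theta_value(tr$x, bins)
    V[cbind(tr$i, tr$j)] <- tables$s_aligned[b] - tables$s_not_aligned[b]
  }
  # Row constant sum_{j'} s_not_aligned(theta(i, j')): together with the
  # -s_not_aligned(theta(i, i')) part of V, cell (i, i') then holds the exact
  # vertex-score change of aligning i to i', so the zero-valued dummy
  # ("leave i unaligned") is on the same scale as the real cells.
  s_na0 <- tables$s_not_aligned[1]
  rowconst <- rep(N2 * s_na0, N)
  if (nrow(tr) > 0) {
    b <- bin_theta_value(tr$x, bins)
    extra <- tables$s_not_aligned[b] - s_na0
    rowconst <- rowconst + as.numeric(tapply(extra, factor(tr$i, levels = 1:N),
                                             sum, default = 0))
  }
  M + V + rowconst
}

extend_assignment_matrix <- function(M, allow_unaligned) {
  if (allow_unaligned) {
    N <- nrow(M); N2 <- ncol(M)
    ext <- matrix(0, N + N2, N2 + N)
    ext[seq_len(N), seq_len(N2)] <- M
    rownames(ext) <- c(rownames(M), rep("", N2))
    colnames(ext) <- c(colnames(M), rep("", N))
    attr(ext, "n_real_rows") <- N
    attr(ext, "n_real_cols") <- N2
    class(ext) <- c("assignment_matrix", class(ext))
    ext
  } else {
    attr(M, "n_real_rows") <- nrow(M)
    attr(M, "n_real_cols") <- ncol(M)
    class(M) <- c("assignment_matrix", class(M))
    M
  }
}

#' Solve a linear assignment problem
#'
#' Finds an injective assignment of rows to columns maximising the sum of the
#' selected cells, by a shortest-augmenting-path algorithm with dual
#' potentials (the algorithm family behind the classical Jonker-Volgenant
#' solver). For a matrix produced by [build_assignment_matrix()] the dummy
#' assignments (vertices left unaligned) are dropped from the result.
#'
#' @param M numeric matrix with finite entries; rows in excess of columns are
#'   left unassigned.
#' @return A `netalignment` pairing row and column identifiers (dimnames when
#'   present, 1-based indices as strings otherwise).
#' @export
solve_linear_assignment <- function(M) {
  nrr <- attr(M, "n_real_rows"); nrc <- attr(M, "n_real_cols")
  if (is.null(nrr)) { nrr <- nrow(M); nrc <- ncol(M) }
  if (anyNA(M) || any(!is.finite(M)))
    stop("assignment matrix must have finite entries")
  sol <- lap_max(unclass(M))
  keep <- which(seq_along(sol) <= nrr & !is.na(sol) & sol <= nrc)
  rn <- rownames(M); cn <- colnames(M)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(M)))
  if (is.null(cn)) cn <- as.character(seq_len(ncol(M)))
  make_alignment(rn[keep], cn[sol[keep]])
}

# maximisation wrapper around the C++ minimiser; returns 1-based column per
# row, NA for unassigned rows (when nrow > ncol)
lap_max <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) <= ncol(M)) {
    lap_min_cpp(max(M) - M)
  } else {
    sol_t <- lap_min_cpp(max(M) - t(M))
    out <- rep(NA_integer_, nrow(M))
    out[sol_t] <- seq_len(ncol(M))
    out
  }
}

# annealing noise oriented canonically so that swapping the two networks
# yields the transposed noise matrix under the same seed
draw_noise <- function(g, g2, sd) {
  N <- n_vertices(g); N2 <- n_vertices(g2)
  key <- paste(g$vertex_ids, collapse = "\r")
  key2 <- paste(g2$vertex_ids, collapse = "\r")
  if (key <= key2) {
    matrix(stats::rnorm(N * N2, sd = sd), N, N2)
  } else {
    t(matrix(stats::rnorm(N2 * N, sd = sd), N2, N))
  }
}

# per-cycle linear decay: noisy for the first two thirds, zero after
noise_schedule <- function(cycle_len, noise_initial_sd) {
  decay_end <- max(1L, ceiling(2 * cycle_len / 3))
  noise_initial_sd * pmax(0, 1 - (seq_len(cycle_len) - 1) / decay_end)
}

#' Search for a high-scoring alignment with fixed score tables
#'
#' Iterates linearisation around the current alignment, perturbation of the
#' assignment matrix with scheduled Gaussian noise, and an exact linear
#' assignment solve, over `restart_cycles` annealing cycles: within a cycle
#' the noise decays linearly to zero and the cycle ends once the alignment
#' is stable; the next cycle reheats from the starting alignment with fresh
#' noise. The best-scoring alignment ever encountered (under
#' [total_score()] with the given tables) is tracked across cycles and
#' returned, so the result never scores below the starting alignment.
#' Deterministic for a fixed `random_seed`.
#'
#' @inheritParams build_assignment_matrix
#' @param start the starting `netalignment` (may be empty).
#' @param config an [aligner_config()].
#' @return A list with elements `alignment`, `total_score`, `edge_component`,
#'   `vertex_component`, `trajectory` (score per iteration), `converged`.
#' @export
align_networks <- function(g, g2, theta, start, tables, bins = tables$bins,
                           config = aligner_config()) {
  stopifnot(inherits(config, "aligner_config"))
  set.seed(config$random_seed)
  start_map <- alignment_index(start, g, g2)
  best_a <- start
  best <- total_score(g, g2, theta, start, tables, bins)
  cycles <- if (config$noise_initial_sd > 0) config$restart_cycles else 1L
  cycle_len <- max(1L, config$max_inner_iterations %/% cycles)
  sds <- noise_schedule(cycle_len, config$noise_initial_sd)
  trajectory <- numeric(0)
  converged <- FALSE
  undirected <- !g$directed && !g2$directed
  for (cycle in seq_len(cycles)) {
    cur_map <- start_map
    streak <- 0L
    cycle_best_a <- NULL
    cycle_best <- -Inf
    for (t in seq_len(cycle_len)) {
      M <- assignment_matrix_real(g, g2, theta, cur_map, tables, bins)
      if (sds[t] > 0) M <- M + draw_noise(g, g2, sds[t])
      dimnames(M) <- list(g$vertex_ids, g2$vertex_ids)
      a_new <- solve_linear_assignment(
        extend_assignment_matrix(M, config$allow_unaligned))
      new_map <- alignment_index(a_new, g, g2)
      sc <- total_score(g, g2, theta, a_new, tables, bins)
      trajectory <- c(trajectory, sc$total)
      if (sc$total > best$total) {
        best <- sc
        best_a <- a_new
      }
      if (sc$total > cycle_best) {
        cycle_best <- sc$total
        cycle_best_a <- a_new
      }
      if (sds[t] == 0 && identical(new_map, cur_map)) {
        streak <- streak + 1L
        if (streak >= config$convergence_patience) {
          converged <- TRUE
          break
        }
      } else {
        streak <- 0L
      }
      cur_map <- new_map
    }
    # Deterministic local refinement of the cycle's best alignment: greedy
    # reassignment and pairwise-exchange moves until no single move improves
    # the score — coordinated moves the row-wise LAP relinearisation can
    # miss. Move deltas assume unordered edge pairs, so directed networks
    # skip this step.
    if (undirected && !is.null(cycle_best_a)) {
      pol_a <- polish_alignment(g, g2, theta, cycle_best_a, tables, bins)
      pol_sc <- total_score(g, g2, theta, pol_a, tables, bins)
      if (pol_sc$total > best$total) {
        best <- pol_sc
        best_a <- pol_a
      }
    }
  }
  list(alignment = best_a,
       total_score = best$total,
       edge_component = best$edge,
       vertex_component = best$vertex,
       trajectory = trajectory,
       converged = converged)
}

polish_alignment <- function(g, g2, theta, a, tables, bins,
                             max_passes = 30L) {
  N <- n_vertices(g); N2 <- n_vertices(g2)
  BA <- matrix(bin_edge_weight(g$adjacency, bins), N, N)
  BA2 <- matrix(bin_edge_weight(g2$adjacency, bins), N2, N2)
  THb <- matrix(bin_theta_value(as.matrix(theta$theta), bins), N, N2)
  SAL <- matrix(tables$s_aligned[THb], N, N2)
  SNA <- matrix(tables$s_not_aligned[THb], N, N2)
  map0 <- alignment_index(a, g, g2)
  map0[is.na(map0)] <- 0L
  out <- polish_alignment_cpp(BA, BA2, tables$s_edge, SAL, SNA,
                              rowSums(SNA), map0 - 1L, as.integer(max_passes))
  out <- out + 1L
  out[out == 0L] <- NA_integer_
  alignment_from_index(out, g, g2)
}

#' Estimate scoring parameters and align two networks
#'
#' The full procedure: starting from a seed alignment (bidirectional best
#' similarity hits unless one is supplied), it alternates (i) maximum
#' likelihood estimation of the score tables from the current alignment and
#' (ii) an annealed linear-assignment search for a better alignment under
#' those tables, until the alignment no longer changes between outer
#' iterations. Both the final alignment and the final score tables are
#' returned. With pooled marginal estimates (the default) the two networks
#' are treated symmetrically: aligning (G', G) with the transposed
#' similarities and the same seed yields the inverse alignment.
#'
#' @inheritParams estimate_score_tables
#' @param bins a `bin_spec`; defaults to [make_bins()] on the inputs.
#' @param config an [aligner_config()].
#' @param start optional starting `netalignment`; default is
#'   [initial_alignment()], falling back to a linear-assignment match on the
#'   raw similarities when best-hit seeding yields fewer than 2 pairs (for
#'   example when all similarities are tied).
#' @param min_theta similarity threshold for the best-hit seed.
#' @return An alignment result (class `"alignment_result"`): a list with
#'   `alignment`, `total_score`, `edge_component`, `vertex_component`,
#'   `tables`, `bins`, `trajectory` (score per outer iteration), `converged`,
#'   `outer_iterations`.
#' @export
fit_and_align <- function(g, g2, theta, bins = NULL, config = aligner_config(),
                          start = NULL, min_theta = 0, pseudocount = 1,
                          pool_marginals = TRUE) {
  vt <- validate_inputs(g, g2, theta)
  g <- vt$g; g2 <- vt$g2; theta <- vt$theta
  if (is.null(bins)) bins <- make_bins(g, g2, theta)
  if (is.null(start)) {
    start <- initial_alignment(theta, min_theta)
    if (length(start) < 2) {
      # tie-heavy or sparse similarities: fall back to a plain LAP seed on theta
      dense <- as.matrix(theta$theta)
      if (any(dense > 0)) {
        dimnames(dense) <- dimnames(theta$theta)
        start <- solve_linear_assignment(extend_assignment_matrix(dense, TRUE))
      }
    }
    if (length(start) < 2)
      stop("best-hit seeding produced fewer than 2 pairs; supply `start`")
  }
  current <- start
  trajectory <- numeric(0)
  converged <- FALSE
  tables <- NULL
  res <- NULL
  outer <- 0L
  for (it in seq_len(config$max_outer_iterations)) {
    outer <- it
    tables <- estimate_score_tables(g, g2, theta, current, bins,
                                    pseudocount = pseudocount,
                                    pool_marginals = pool_marginals)
    res <- align_networks(g, g2, theta, current, tables, bins, config)
    trajectory <- c(trajectory, res$total_score)
    if (same_alignment(res$alignment, current)) {
      converged <- TRUE
      break
    }
    if (length(res$alignment) < 2) {
      # degenerate data: the best alignment is (near) empty, nothing left to
      # re-estimate the tables from
      converged <- TRUE
      break
    }
    current <- res$alignment
  }
  structure(list(alignment = res$alignment,
                 total_score = res$total_score,
                 edge_component = res$edge_component,
                 vertex_component = res$vertex_component,
                 tables = tables,
                 bins = bins,
                 trajectory = trajectory,
                 converged = converged,
                 outer_iterations = outer,
                 seed = config$random_seed),
            class = "alignment_result")
}

same_alignment <- function(a, b) {
  if (length(a$from) != length(b$from)) return(FALSE)
  oa <- order(a$from); ob <- order(b$from)
  identical(a$from[oa], b$from[ob]) && identical(a$to[oa], b$to[ob])
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(paste0("<alignment_result> %d pairs, total score %.3f ",
                     "(edge %.3f, vertex %.3f)\n"),
              length(x$alignment$from), x$total_score, x$edge_component,
              x$vertex_component))
  cat(sprintf("  outer iterations: %d, converged: %s\n",
              x$outer_iterations, x$converged))
  invisible(x)
}
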