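#' Read an expression matrix from TSV
#'
#' Tab-separated matrix with profile identifiers in the header row and gene
#' identifiers in the first column; empty cells or `NA` mark genes not
#' detected in a profile.
#'
#' @param path file path.
#' @return A list of class `"expression_matrix"` with `gene_ids`,
#'   `profile_ids` and the numeric `values` matrix.
#' @export
read_expression <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, comment.char = "#",
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  make_expression(m)
}

#' Construct an expression matrix object
#' @param values numeric genes x profiles matrix with dimnames; `NA` entries
#'   mark undetected genes.
#' @return An `"expression_matrix"`.
#' @export
make_expression <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene ids as row names and profile ids as ",
         "column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("gene and profile identifiers must be unique")
  if (ncol(values) < 2) stop("need at least 2 expression profiles")
  structure(list(gene_ids = rownames(values), profile_ids = colnames(values),
                 values = values), class = "expression_matrix")
}

#' Build a co-expression network from an expression matrix
#'
#' Genes detected in at least `detection_frac` of the profiles are kept.
#' Co-expression of each gene pair is the absolute Spearman rank correlation
#' over pairwise-complete observations; values below `corr_threshold` are
#' hard-thresholded to 0 (a correlation exactly at the threshold is kept).
#' Surviving correlations are retained only when statistically significant
#' at Benjamini-Hochberg adjusted q < `fdr_q`, with p-values from the exact
#' Spearman null distribution for up to 9 complete observations and the
#' large-sample t approximation otherwise. Pairs with fewer than 3 complete
#' observations are skipped with a warning. The result is a weighted
#' undirected network over the surviving genes.
#'
#' @param expr an `expression_matrix`.
#' @param detection_frac minimal fraction of profiles a gene must be
#'   detected in (default 0.75).
#' @param corr_threshold hard threshold on the absolute correlation
#'   (default 0.5).
#' @param fdr_q Benjamini-Hochberg false-discovery cutoff (default 0.001).
#' @return A `netgraph` with continuous weights.
#' @export
coexpression_network <- function(expr, detection_frac = 0.75,
                                 corr_threshold = 0.5, fdr_q = 0.001) {
  stopifnot(inherits(expr, "expression_matrix"))
  detected <- rowMeans(!is.na(expr$values)) >= detection_frac
  vals <- expr$values[detected, , drop = FALSE]
  genes <- rownames(vals)
  ng <- length(genes)
  if (ng < 2)
    return(make_network(matrix(0, ng, ng), genes, weight_kind = "continuous"))

  rho <- suppressWarnings(
    stats::cor(t(vals), method = "spearman", use = "pairwise.complete.obs"))
  nobs <- crossprod(!t(is.na(vals))) # complete observations per pair

  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[pairs]
  n <- nobs[pairs]
  too_few <- is.na(r) | n < 3
  if (any(too_few & !is.na(r)))
    warning(sum(too_few), " gene pair(s) with fewer than 3 complete ",
            "observations skipped")
  pval <- rep(NA_real_, length(r))
  ok <- !too_few
  small <- ok & n <= 9
  large <- ok & n > 9
  if (any(large)) {
    # large-sample t approximation on the signed correlation
    rr <- pmin(pmax(r[large], -1 + 1e-12), 1 - 1e-12)
    tt <- rr * sqrt((n[large] - 2) / (1 - rr^2))
    pval[large] <- 2 * stats::pt(-abs(tt), df = n[large] - 2)
  }
  if (any(small)) {
    pval[small] <- mapply(function(i1, i2) {
      x <- vals[i1, ]; y <- vals[i2, ]
      cc <- stats::complete.cases(x, y)
      suppressWarnings(stats::cor.test(x[cc], y[cc],
                                       method = "spearman")$p.value)
    }, pairs[small, 1], pairs[small, 2])
  }
  qval <- stats::p.adjust(pval, method = "BH")

  w <- abs(r)
  w[too_few] <- 0
  w[w < corr_threshold] <- 0
  w[!is.na(qval) & qval >= fdr_q] <- 0
  w[is.na(w)] <- 0

  adj <- matrix(0, ng, ng, dimnames = list(genes, genes))
  adj[pairs] <- w
  adj[pairs[, c(2, 1), drop = FALSE]] <- w
  make_network(adj, genes, directed = FALSE, weight_kind = "continuous")
}
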