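num9 <- function(x) formatC(x, digits = 9, format = "g")
num17 <- function(x) formatC(x, digits = 17, format = "g")

read_tsv_table <- function(path, col.names = NULL, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, quote = "",
                      colClasses = colClasses),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stop("malformed TSV in ", path, ": ", conditionMessage(e))
    })
  if (!is.null(col.names) && ncol(df) > 0) {
    if (ncol(df) < length(col.names))
      names(df) <- col.names[seq_len(ncol(df))]
    else
      names(df)[seq_along(col.names)] <- col.names
  }
  df
}

#' Read a network from a TSV file
#'
#' Edge-list format: tab-separated columns `vertex1`, `vertex2` and an
#' optional `weight` (default 1); lines starting with `#` are comments.
#' Matrix format: a dense tab-separated matrix with vertex identifiers in the
#' header row and first column. Undirected edge lists are symmetrised;
#' duplicate edges with identical weights collapse to one, conflicting
#' weights are an error.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"matrix"`.
#' @param directed logical.
#' @return A `netgraph`.
#' @export
read_network <- function(path, format = c("edgelist", "matrix"),
                         directed = FALSE) {
  format <- match.arg(format)
  if (format == "matrix") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = 1, comment.char = "#",
                                     check.names = FALSE))
    return(make_network(m, directed = directed))
  }
  df <- read_tsv_table(path, c("vertex1", "vertex2", "weight"))
  if (ncol(df) == 0)
    stop("empty network file: ", path)
  if (ncol(df) < 2)
    stop("edge list needs at least 2 columns (vertex1, vertex2): ", path)
  if (ncol(df) < 3) df$weight <- 1
  df$weight <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(df$weight))
    stop("non-numeric edge weight in ", path)
  df$vertex1 <- as.character(df$vertex1)
  df$vertex2 <- as.character(df$vertex2)
  ids <- sort(unique(c(df$vertex1, df$vertex2)))
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  key <- if (directed) paste0(df$vertex1, "\r", df$vertex2)
         else paste0(pmin(df$vertex1, df$vertex2), "\r",
                     pmax(df$vertex1, df$vertex2))
  for (kk in unique(key[duplicated(key)])) {
    w <- unique(df$weight[key == kk])
    if (length(w) > 1)
      stop("conflicting duplicate edge ", sub("\r", " -- ", kk),
           " with weights ", paste(w, collapse = ", "))
  }
  adj[cbind(df$vertex1, df$vertex2)] <- df$weight
  if (!directed) adj[cbind(df$vertex2, df$vertex1)] <- df$weight
  make_network(adj, directed = directed)
}

#' Write a network to an edge-list TSV
#'
#' @param g a `netgraph`.
#' @param path output file.
#' @export
write_network <- function(g, path) {
  a <- g$adjacency
  sel <- if (g$directed) which(a != 0, arr.ind = TRUE)
         else which(a != 0 & upper.tri(a), arr.ind = TRUE)
  lines <- c(sprintf("# netalign network: %d vertices, directed=%s",
                     n_vertices(g), g$directed),
             sprintf("%s\t%s\t%s", g$vertex_ids[sel[, 1]],
                     g$vertex_ids[sel[, 2]], num9(a[sel])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a vertex-similarity matrix from a triplet TSV
#'
#' Columns `vertex_g`, `vertex_g2`, `theta`; absent pairs have theta = 0.
#'
#' @param path file path.
#' @param rows,cols optional full vertex-id vectors for the two networks;
#'   default is the identifiers observed in the file.
#' @return A `vertexsim`.
#' @export
read_similarity <- function(path, rows = NULL, cols = NULL) {
  df <- read_tsv_table(path, c("vertex_g", "vertex_g2", "theta"))
  if (ncol(df) > 0 && ncol(df) < 3)
    stop("similarity file needs 3 columns (vertex_g, vertex_g2, theta): ", path)
  if (ncol(df) == 0)
    df <- data.frame(vertex_g = character(), vertex_g2 = character(),
                     theta = numeric())
  df$theta <- suppressWarnings(as.numeric(df$theta))
  if (anyNA(df$theta)) stop("non-numeric theta in ", path)
  if (is.null(rows)) rows <- sort(unique(as.character(df$vertex_g)))
  if (is.null(cols)) cols <- sort(unique(as.character(df$vertex_g2)))
  make_similarity(rows, cols,
                  data.frame(row = df$vertex_g, col = df$vertex_g2,
                             theta = df$theta))
}

#' Write a vertex-similarity matrix to a triplet TSV
#' @param theta a `vertexsim`.
#' @param path output file.
#' @export
write_similarity <- function(theta, path) {
  tr <- Matrix::summary(theta$theta)
  writeLines(c("# netalign similarity triplets: vertex_g vertex_g2 theta",
               sprintf("%s\t%s\t%s", rownames(theta$theta)[tr$i],
                       colnames(theta$theta)[tr$j], num9(tr$x))),
             path)
  invisible(path)
}

#' Build vertex similarities from tabular BLAST output
#'
#' Reads 12-column tabular BLAST hits (query, subject, identity, length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore),
#' keeps hits with e-value below 1e-10, and scores each (query, subject) pair
#' by its maximal retained bit score.
#'
#' @param path BLAST tabular output file.
#' @param evalue_cutoff retain hits with e-value strictly below this
#'   (default `1e-10`).
#' @return A `vertexsim` over the identifiers observed in the retained hits.
#' @export
read_theta_from_blast <- function(path, evalue_cutoff = 1e-10) {
  df <- read_tsv_table(path)
  if (ncol(df) == 0)
    return(make_similarity(character(), character()))
  if (ncol(df) != 12)
    stop("expected 12-column tabular BLAST output, got ", ncol(df),
         " columns in ", path)
  names(df) <- c("query", "subject", "identity", "length", "mismatches",
                 "gapopens", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")
  df$evalue <- suppressWarnings(as.numeric(df$evalue))
  df$bitscore <- suppressWarnings(as.numeric(df$bitscore))
  if (anyNA(df$evalue) || anyNA(df$bitscore))
    stop("non-numeric e-value or bit score in ", path)
  df <- df[df$evalue < evalue_cutoff, , drop = FALSE]
  if (nrow(df) == 0)
    return(make_similarity(character(), character()))
  best <- stats::aggregate(bitscore ~ query + subject, data = df, FUN = max)
  make_similarity(sort(unique(best$query)), sort(unique(best$subject)),
                  data.frame(row = best$query, col = best$subject,
                             theta = best$bitscore))
}

#' Drop orphan vertices
#'
#' Removes vertices that simultaneously have no edge in their network and no
#' similarity entry towards the other network — they carry no alignable
#' information.
#'
#' @param g,g2 `netgraph` objects.
#' @param theta a `vertexsim` covering both vertex sets.
#' @return A list `list(g, g2, theta)` with orphans removed.
#' @export
drop_orphans <- function(g, g2, theta) {
  vt <- validate_inputs(g, g2, theta)
  g <- vt$g; g2 <- vt$g2; Th <- vt$theta$theta
  deg <- rowSums(g$adjacency != 0)
  deg2 <- rowSums(g2$adjacency != 0)
  hits <- Matrix::rowSums(Th != 0)
  hits2 <- Matrix::colSums(Th != 0)
  keep <- deg > 0 | hits > 0
  keep2 <- deg2 > 0 | hits2 > 0
  g <- make_network(g$adjacency[keep, keep, drop = FALSE],
                    g$vertex_ids[keep], g$directed, g$weight_kind)
  g2 <- make_network(g2$adjacency[keep2, keep2, drop = FALSE],
                     g2$vertex_ids[keep2], g2$directed, g2$weight_kind)
  theta <- structure(list(theta = Th[keep, keep2, drop = FALSE]),
                     class = "vertexsim")
  list(g = g, g2 = g2, theta = theta)
}

#' Write an alignment to a TSV file
#'
#' Columns `vertex_g`, `vertex_g2`, `theta` and the per-pair vertex score;
#' `#`-prefixed header lines record the total/edge/vertex scores, the seed
#' and the iteration counts when a full alignment result is given.
#'
#' @param x a `netalignment` or an `alignment_result`.
#' @param path output file.
#' @param theta optional `vertexsim` supplying the per-pair similarities.
#' @export
write_alignment <- function(x, path, theta = NULL) {
  header <- "# netalign alignment: vertex_g vertex_g2 theta s_aligned"
  a <- x
  if (inherits(x, "alignment_result")) {
    a <- x$alignment
    header <- c(header,
                sprintf("# total_score\t%s", num9(x$total_score)),
                sprintf("# edge_score\t%s", num9(x$edge_component)),
                sprintf("# vertex_score\t%s", num9(x$vertex_component)),
                sprintf("# seed\t%d", x$seed),
                sprintf("# outer_iterations\t%d", x$outer_iterations))
  }
  th <- rep(NA_real_, length(a$from))
  sal <- rep(NA_real_, length(a$from))
  if (!is.null(theta)) {
    fi <- match(a$from, rownames(theta$theta))
    ti <- match(a$to, colnames(theta$theta))
    ok <- !is.na(fi) & !is.na(ti)
    th[ok] <- as.numeric(theta$theta[cbind(fi[ok], ti[ok])])
    if (inherits(x, "alignment_result"))
      sal[ok] <- vertex_scores(x$tables, th[ok], x$bins)$s_aligned
  }
  writeLines(c(header,
               sprintf("%s\t%s\t%s\t%s", a$from, a$to,
                       ifelse(is.na(th), "NA", num9(th)),
                       ifelse(is.na(sal), "NA", num9(sal)))),
             path)
  invisible(path)
}

#' Read an alignment from a TSV file (first two columns)
#' @param path file path.
#' @return A `netalignment`.
#' @export
read_alignment <- function(path) {
  df <- read_tsv_table(path, c("vertex_g", "vertex_g2"))
  if (ncol(df) == 0) return(make_alignment())
  make_alignment(as.character(df$vertex_g), as.character(df$vertex_g2))
}

#' Serialize score tables to a flat TSV
#'
#' Writes bin edges and every table cell with full double precision so a
#' round-trip through [read_score_tables()] is bit-exact.
#'
#' @param tables a `score_tables`.
#' @param path output file.
#' @export
write_score_tables <- function(tables, path) {
  vec_line <- function(tag, i, x) sprintf("%s\t%d\t%d\t%s", tag, i,
                                          seq_along(x), num17(x))
  lines <- c("# netalign score tables: table  row  col  value",
             sprintf("meta\t1\t1\t%s", num17(tables$pseudocount)),
             sprintf("meta\t1\t2\t%d", as.integer(tables$pool_marginals)),
             vec_line("edge_bin_edges", 1L, tables$bins$edge_bin_edges),
             vec_line("theta_bin_edges", 1L, tables$bins$theta_bin_edges))
  for (nm in c("joint_edge", "s_edge")) {
    m <- tables[[nm]]
    for (i in seq_len(nrow(m))) lines <- c(lines, vec_line(nm, i, m[i, ]))
  }
  for (nm in c("marginal_edge_g", "marginal_edge_g2", "q_ortho_theta",
               "q_unrel_theta", "background_theta", "s_aligned",
               "s_not_aligned"))
    lines <- c(lines, vec_line(nm, 1L, tables[[nm]]))
  writeLines(lines, path)
  invisible(path)
}

#' Read score tables from the flat TSV written by [write_score_tables()]
#' @param path file path.
#' @return A `score_tables`.
#' @export
read_score_tables <- function(path) {
  df <- read_tsv_table(path, c("table", "row", "col", "value"))
  if (ncol(df) < 4) stop("malformed score-table file: ", path)
  get_vec <- function(tag) {
    s <- df[df$table == tag & df$row == 1, , drop = FALSE]
    as.numeric(s$value[order(s$col)])
  }
  get_mat <- function(tag) {
    s <- df[df$table == tag, , drop = FALSE]
    nr <- max(s$row); nc <- max(s$col)
    m <- matrix(NA_real_, nr, nc)
    m[cbind(s$row, s$col)] <- as.numeric(s$value)
    m
  }
  meta <- df[df$table == "meta", , drop = FALSE]
  bins <- structure(list(edge_bin_edges = get_vec("edge_bin_edges"),
                         theta_bin_edges = get_vec("theta_bin_edges")),
                    class = "bin_spec")
  structure(list(
    joint_edge = get_mat("joint_edge"),
    marginal_edge_g = get_vec("marginal_edge_g"),
    marginal_edge_g2 = get_vec("marginal_edge_g2"),
    q_ortho_theta = get_vec("q_ortho_theta"),
    q_unrel_theta = get_vec("q_unrel_theta"),
    background_theta = get_vec("background_theta"),
    s_edge = get_mat("s_edge"),
    s_aligned = get_vec("s_aligned"),
    s_not_aligned = get_vec("s_not_aligned"),
    pseudocount = as.numeric(meta$value[meta$col == 1]),
    pool_marginals = as.integer(meta$value[meta$col == 2]) == 1L,
    bins = bins), class = "score_tables")
}

#' Write a simulated pair to a directory
#'
#' Produces `g1.tsv` and `g2.tsv` (edge lists), `theta.tsv` (similarity
#' triplets) and `truth.tsv` (columns vertex_g, vertex_g2 — `NA` when the
#' vertex has no true partner — and the vertex category label).
#'
#' @param pair a `simulated_pair`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulated_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(pair$g, file.path(dir, "g1.tsv"))
  write_network(pair$g2, file.path(dir, "g2.tsv"))
  write_similarity(pair$theta, file.path(dir, "theta.tsv"))
  partner <- stats::setNames(pair$truth$to, pair$truth$from)[pair$g$vertex_ids]
  writeLines(c("# netalign truth: vertex_g vertex_g2 label",
               sprintf("%s\t%s\t%s", pair$g$vertex_ids,
                       ifelse(is.na(partner), "NA", partner),
                       pair$labels[pair$g$vertex_ids])),
             file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read the truth table written by [write_simulated_pair()]
#'
#' Returns a minimal ground-truth object usable with
#' [evaluate_against_truth()].
#'
#' @param path path to `truth.tsv`.
#' @return A `simulated_pair`-classed list with `truth` and `labels`.
#' @export
read_truth <- function(path) {
  df <- read_tsv_table(path, c("vertex_g", "vertex_g2", "label"),
                       colClasses = "character")
  has <- !is.na(df$vertex_g2) & df$vertex_g2 != "NA"
  structure(list(truth = make_alignment(df$vertex_g[has], df$vertex_g2[has]),
                 labels = stats::setNames(df$label, df$vertex_g)),
            class = "simulated_pair")
}
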