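#' Construct a network from an adjacency matrix
#'
#' A network is a set of uniquely named vertices together with an adjacency
#' matrix of edge weights. Weights are dimensionless; a weight of 0 means the
#' edge is absent. Absence is informative to the alignment score, so the
#' adjacency matrix is kept dense. Networks may be undirected (symmetric
#' adjacency) or directed, and carry either binary (0/1) or continuous
#' weights. Self-loops (diagonal entries) are never scored and are zeroed on
#' construction.
#'
#' @param adjacency square numeric matrix; if it has row names they are used
#'   as vertex identifiers (row and column names must then agree).
#' @param vertex_ids character vector of unique vertex identifiers; required
#'   when `adjacency` has no dimnames.
#' @param directed logical; if `FALSE` (default) `adjacency` must be symmetric.
#' @param weight_kind `"binary"` or `"continuous"`; `"auto"` (default) picks
#'   `"binary"` when every entry is 0 or 1.
#' @return An object of class `"netgraph"` with elements `vertex_ids`,
#'   `adjacency`, `directed`, `weight_kind`.
#' @export
make_network <- function(adjacency, vertex_ids = NULL, directed = FALSE,
                         weight_kind = c("auto", "binary", "continuous")) {
  weight_kind <- match.arg(weight_kind)
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency matrix must be square, got ", nrow(adjacency), "x",
         ncol(adjacency))
  if (is.null(vertex_ids)) {
    vertex_ids <- rownames(adjacency)
    if (is.null(vertex_ids))
      stop("vertex_ids must be given when the adjacency matrix has no dimnames")
  }
  vertex_ids <- as.character(vertex_ids)
  if (length(vertex_ids) != nrow(adjacency))
    stop("length of vertex_ids (", length(vertex_ids),
         ") does not match adjacency dimension (", nrow(adjacency), ")")
  if (anyDuplicated(vertex_ids))
    stop("vertex identifiers must be unique; duplicated: ",
         paste(unique(vertex_ids[duplicated(vertex_ids)]), collapse = ", "))
  if (!is.numeric(adjacency) || anyNA(adjacency) || any(!is.finite(adjacency)))
    stop("adjacency entries must be finite numbers")
  if (!directed && !isTRUE(all.equal(adjacency, t(adjacency),
                                     check.attributes = FALSE)))
    stop("adjacency matrix of an undirected network must be symmetric")
  diag(adjacency) <- 0
  is_binary <- all(adjacency %in% c(0, 1))
  if (weight_kind == "auto")
    weight_kind <- if (is_binary) "binary" else "continuous"
  if (weight_kind == "binary" && !is_binary)
    stop("weight_kind is \"binary\" but adjacency has entries other than 0/1")
  dimnames(adjacency) <- list(vertex_ids, vertex_ids)
  structure(
    list(vertex_ids = vertex_ids, adjacency = adjacency,
         directed = directed, weight_kind = weight_kind),
    class = "netgraph")
}

#' @export
print.netgraph <- function(x, ...) {
  n <- length(x$vertex_ids)
  ne <- if (x$directed) sum(x$adjacency != 0) else sum(x$adjacency != 0) / 2
  cat(sprintf("<netgraph> %d vertices, %d %s edges (%s weights)\n",
              n, ne, if (x$directed) "directed" else "undirected",
              x$weight_kind))
  invisible(x)
}

n_vertices <- function(g) length(g$vertex_ids)

#' Construct a cross-network vertex-similarity matrix
#'
#' Vertex similarities theta(i, i') are non-negative numbers in arbitrary
#' units (for example BLAST bit scores) relating vertices of one network to
#' vertices of another. Pairs with no recorded similarity have theta = 0; the
#' matrix is stored sparsely.
#'
#' @param rows character vector of vertex identifiers of the first network.
#' @param cols character vector of vertex identifiers of the second network.
#' @param entries data frame (or list) with components `row`, `col`, `theta`
#'   giving the non-zero similarities; may be empty. Alternatively a dense
#'   matrix whose dimnames are `rows`/`cols`.
#' @return An object of class `"vertexsim"` wrapping a sparse `Matrix` with
#'   `rows` and `cols` as dimnames.
#' @export
make_similarity <- function(rows, cols, entries = NULL) {
  rows <- as.character(rows); cols <- as.character(cols)
  if (anyDuplicated(rows) || anyDuplicated(cols))
    stop("vertex identifiers must be unique on each side of the similarity matrix")
  if (is.matrix(entries) || methods::is(entries, "Matrix")) {
    entries <- as.matrix(entries)
    if (nrow(entries) != length(rows) || ncol(entries) != length(cols))
      stop("dense similarity matrix does not match the given id vectors")
    nz <- which(entries != 0, arr.ind = TRUE)
    m <- Matrix::sparseMatrix(i = nz[, 1], j = nz[, 2], x = entries[nz],
                              dims = dim(entries),
                              dimnames = list(rows, cols))
  } else if (is.null(entries) || NROW(entries$row) == 0) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(),
                              x = numeric(), dims = c(length(rows), length(cols)),
                              dimnames = list(rows, cols))
  } else {
    ri <- match(as.character(entries$row), rows)
    ci <- match(as.character(entries$col), cols)
    if (anyNA(ri))
      stop("similarity entry refers to unknown vertex: ",
           paste(unique(entries$row[is.na(ri)]), collapse = ", "))
    if (anyNA(ci))
      stop("similarity entry refers to unknown vertex: ",
           paste(unique(entries$col[is.na(ci)]), collapse = ", "))
    th <- as.numeric(entries$theta)
    if (anyNA(th) || any(!is.finite(th)) || any(th < 0))
      stop("similarity values must be finite and non-negative")
    m <- Matrix::sparseMatrix(i = ri, j = ci, x = th,
                              dims = c(length(rows), length(cols)),
                              dimnames = list(rows, cols))
  }
  m <- methods::as(m, "CsparseMatrix")
  if (any(m@x < 0) || anyNA(m@x) || any(!is.finite(m@x)))
    stop("similarity values must be finite and non-negative")
  structure(list(theta = Matrix::drop0(m)), class = "vertexsim")
}

#' @export
print.vertexsim <- function(x, ...) {
  cat(sprintf("<vertexsim> %d x %d, %d non-zero entries\n",
              nrow(x$theta), ncol(x$theta), length(x$theta@x)))
  invisible(x)
}

#' Construct an alignment
#'
#' An alignment is an injective partial map from vertices of one network to
#' vertices of another: no two vertices share a partner and vertices may be
#' left unaligned.
#'
#' @param from,to character vectors of equal length: `from[k]` is aligned to
#'   `to[k]`. Alternatively `from` may be a named character vector
#'   (names = source vertices, values = targets) with `to` missing.
#' @return An object of class `"netalignment"`.
#' @export
make_alignment <- function(from = character(), to = NULL) {
  if (is.null(to)) {
    to <- unname(from)
    from <- names(from)
    if (is.null(from) && length(to) > 0)
      stop("`from` must be named when `to` is missing")
    if (is.null(from)) from <- character()
  }
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to))
    stop("from and to must have equal length")
  if (anyDuplicated(from))
    stop("alignment maps a vertex twice: ",
         paste(unique(from[duplicated(from)]), collapse = ", "))
  if (anyDuplicated(to))
    stop("alignment is not injective; repeated target: ",
         paste(unique(to[duplicated(to)]), collapse = ", "))
  structure(list(from = from, to = to), class = "netalignment")
}

#' @export
length.netalignment <- function(x) length(x$from)

#' @export
print.netalignment <- function(x, ...) {
  cat(sprintf("<netalignment> %d aligned pairs\n", length(x$from)))
  if (length(x$from) > 0) {
    show <- utils::head(seq_along(x$from), 6)
    cat(paste0("  ", x$from[show], " -> ", x$to[show], collapse = "\n"), "\n")
    if (length(x$from) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' Validate a network pair and its similarity matrix
#'
#' Cross-checks two networks against a vertex-similarity matrix: adjacency
#' matrices must satisfy their declared symmetry, theta entries must be
#' non-negative and refer only to known vertices. Plain matrices are promoted
#' to `netgraph` / `vertexsim` objects.
#'
#' @param g,g2 networks (`netgraph` or plain adjacency matrices with dimnames).
#' @param theta a `vertexsim`, or a dense matrix with dimnames matching the
#'   vertex identifiers of `g` (rows) and `g2` (columns).
#' @return A list `list(g, g2, theta)` of validated objects.
#' @export
validate_inputs <- function(g, g2, theta) {
  if (!inherits(g, "netgraph")) g <- make_network(g)
  if (!inherits(g2, "netgraph")) g2 <- make_network(g2)
  if (!inherits(theta, "vertexsim")) {
    theta <- as.matrix(theta)
    rn <- rownames(theta); cn <- colnames(theta)
    if (is.null(rn) || is.null(cn))
      stop("a plain theta matrix must carry row and column names")
    bad <- setdiff(c(rn, cn), c(g$vertex_ids, g2$vertex_ids))
    if (length(bad) > 0)
      stop("theta refers to unknown vertex: ", paste(bad, collapse = ", "))
    full <- matrix(0, n_vertices(g), n_vertices(g2),
                   dimnames = list(g$vertex_ids, g2$vertex_ids))
    full[rn, cn] <- theta
    theta <- make_similarity(g$vertex_ids, g2$vertex_ids, full)
  } else {
    bad <- c(setdiff(rownames(theta$theta), g$vertex_ids),
             setdiff(colnames(theta$theta), g2$vertex_ids))
    if (length(bad) > 0)
      stop("theta refers to unknown vertex: ", paste(bad, collapse = ", "))
    if (nrow(theta$theta) != n_vertices(g) || ncol(theta$theta) != n_vertices(g2)) {
      # expand to the full vertex sets so indices line up downstream
      full <- Matrix::sparseMatrix(
        i = match(rownames(theta$theta), g$vertex_ids)[theta$theta@i + 1L],
        j = match(colnames(theta$theta),
                  g2$vertex_ids)[rep(seq_len(ncol(theta$theta)),
                                     diff(theta$theta@p))],
        x = theta$theta@x,
        dims = c(n_vertices(g), n_vertices(g2)),
        dimnames = list(g$vertex_ids, g2$vertex_ids))
      theta <- structure(list(theta = full), class = "vertexsim")
    }
  }
  list(g = g, g2 = g2, theta = theta)
}

#' Invert an alignment
#'
#' Swaps the two sides of every aligned pair. Because the alignment method
#' treats the two networks symmetrically, the inverse of an alignment of
#' (G, G') is an alignment of (G', G); inverting twice is the identity.
#'
#' @param a a `netalignment`.
#' @return The inverted `netalignment`.
#' @export
invert_alignment <- function(a) {
  stopifnot(inherits(a, "netalignment"))
  make_alignment(a$to, a$from)
}

#' Edge pairs induced by a vertex alignment
#'
#' A vertex alignment induces an alignment of edges: every pair of distinct
#' aligned vertices (i, j) puts the edge state `A[i, j]` in register with
#' `A2[A(i), A(j)]`. Pairs are enumerated whether or not either edge is present
#' (absence of an edge on both sides is itself informative). Unordered pairs
#' are returned for undirected networks, ordered pairs for directed ones.
#'
#' @param a a `netalignment` valid on `g`, `g2`.
#' @param g,g2 the two `netgraph` objects.
#' @return A data frame with columns `i`, `j`, `i2`, `j2` (vertex identifiers)
#'   and `w`, `w2` (the corresponding edge weights).
#' @export
induced_edge_alignment <- function(a, g, g2) {
  stopifnot(inherits(a, "netalignment"))
  k <- length(a$from)
  if (k < 2)
    return(data.frame(i = character(), j = character(), i2 = character(),
                      j2 = character(), w = numeric(), w2 = numeric(),
                      stringsAsFactors = FALSE))
  directed <- g$directed || g2$directed
  idx <- if (directed) {
    ij <- expand.grid(p = seq_len(k), q = seq_len(k))
    ij[ij$p != ij$q, , drop = FALSE]
  } else {
    cmb <- utils::combn(k, 2)
    data.frame(p = cmb[1, ], q = cmb[2, ])
  }
  i <- a$from[idx$p]; j <- a$from[idx$q]
  i2 <- a$to[idx$p]; j2 <- a$to[idx$q]
  data.frame(i = i, j = j, i2 = i2, j2 = j2,
             w = g$adjacency[cbind(i, j)],
             w2 = g2$adjacency[cbind(i2, j2)],
             stringsAsFactors = FALSE)
}

# integer-index view of an alignment: vector of length n_vertices(g),
# entry = index of the partner in g2, NA when unaligned
alignment_index <- function(a, g, g2) {
  map <- rep(NA_integer_, n_vertices(g))
  if (length(a$from) > 0) {
    fi <- match(a$from, g$vertex_ids)
    ti <- match(a$to, g2$vertex_ids)
    if (anyNA(fi) || anyNA(ti))
      stop("alignment refers to unknown vertex: ",
           paste(c(a$from[is.na(fi)], a$to[is.na(ti)]), collapse = ", "))
    map[fi] <- ti
  }
  map
}

alignment_from_index <- function(map, g, g2) {
  fi <- which(!is.na(map))
  make_alignment(g$vertex_ids[fi], g2$vertex_ids[map[fi]])
}
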