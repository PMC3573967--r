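#' Discretization of edge weights and vertex similarities
#'
#' The likelihood-ratio scores are defined over distributions of edge weights
#' and vertex similarities. For continuous data these distributions are
#' realised as binned histograms; a bin specification fixes the bin
#' boundaries once so that every score is a table lookup.
#'
#' Edge-weight bins are given by `edge_bin_edges`, a strictly increasing
#' break vector of length B+1 defining B left-closed, right-open bins (the
#' last bin is right-closed). Binary networks use the two bins \{0\} and \{1\}.
#' Similarity bins reserve bin 1 for theta = 0 — absence of any recorded
#' similarity — and split the positive range by `theta_bin_edges`, a break
#' vector of length K defining K-1 positive bins, so there are K similarity
#' bins in total.
#'
#' @param g,g2 the two networks whose observed weights set the default ranges.
#' @param theta a `vertexsim`; its maximal entry sets the positive
#'   similarity range.
#' @param n_edge_bins number of edge-weight bins for continuous weights
#'   (default 8; ignored when both networks are binary, which get bins
#'   \{0\},\{1\}).
#' @param n_theta_bins total number of similarity bins including the
#'   reserved zero bin (default 8).
#' @param edge_bin_edges,theta_bin_edges optional explicit break vectors
#'   overriding the defaults.
#' @return An object of class `"bin_spec"`.
#' @export
make_bins <- function(g, g2, theta, n_edge_bins = 8, n_theta_bins = 8,
                      edge_bin_edges = NULL, theta_bin_edges = NULL) {
  if (is.null(edge_bin_edges)) {
    if (g$weight_kind == "binary" && g2$weight_kind == "binary") {
      edge_bin_edges <- c(0, 0.5, 1)
    } else {
      wmax <- max(g$adjacency, g2$adjacency, 0)
      if (wmax <= 0) wmax <- 1
      edge_bin_edges <- seq(0, wmax, length.out = n_edge_bins + 1)
    }
  }
  if (is.null(theta_bin_edges)) {
    tmax <- if (length(theta$theta@x) > 0) max(theta$theta@x) else 1
    if (tmax <= 0) tmax <- 1
    theta_bin_edges <- seq(0, tmax, length.out = n_theta_bins)
  }
  validate_bin_spec(edge_bin_edges, theta_bin_edges)
  structure(list(edge_bin_edges = edge_bin_edges,
                 theta_bin_edges = theta_bin_edges),
            class = "bin_spec")
}

validate_bin_spec <- function(edge_bin_edges, theta_bin_edges) {
  if (length(edge_bin_edges) < 3 || any(diff(edge_bin_edges) <= 0))
    stop("edge_bin_edges must be strictly increasing and define at least 2 bins")
  if (length(theta_bin_edges) < 2 || any(diff(theta_bin_edges) <= 0))
    stop("theta_bin_edges must be strictly increasing and define at least 2 bins")
  invisible(TRUE)
}

n_edge_bins <- function(bins) length(bins$edge_bin_edges) - 1L
n_theta_bins <- function(bins) length(bins$theta_bin_edges)

# Bin index of edge weights; out-of-range values are clamped to the extreme
# bins so that alignment-time queries never error.
bin_edge_weight <- function(w, bins) {
  b <- findInterval(w, bins$edge_bin_edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), n_edge_bins(bins))
}

# Bin index of similarity values: bin 1 is reserved for theta <= 0,
# positive values fall into bins 2..K (clamped).
bin_theta_value <- function(th, bins) {
  K <- n_theta_bins(bins)
  b <- findInterval(th, bins$theta_bin_edges, rightmost.closed = TRUE)
  out <- 1L + pmin(pmax(b, 1L), K - 1L)
  out[th <= 0] <- 1L
  out
}
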