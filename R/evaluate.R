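#' Evaluate an alignment against simulation ground truth
#'
#' Compares an alignment with the true partner map of a simulated pair. An
#' aligned pair (i, i') is *correct* when i' is i's true partner; it is
#' *misaligned* when either vertex has a true partner (or is one) and the
#' pair does not match; a pair of two truthless vertices aligned together is
#' neutral — counted as aligned but neither correct nor misaligned, since no
#' information existed to align them. Sensitivity is NC/NA (correct over
#' aligned), coverage NC/NO (correct over true pairs).
#'
#' @param a a `netalignment` on the vertex sets of `pair`.
#' @param pair a `simulated_pair` (see [generate_scenario()]).
#' @return An object of class `"evaluation_report"`: list with counts
#'   `n_aligned`, `n_correct`, `n_groups`, `misaligned`, rates `sensitivity`
#'   (0 with `sensitivity_defined = FALSE` when nothing is aligned) and
#'   `coverage`, and `per_category`, a data frame with per-label counts
#'   (`n`, `aligned`, `correct`, `misaligned`, `unaligned`) and `accuracy`
#'   (= correct / n).
#' @export
evaluate_against_truth <- function(a, pair) {
  stopifnot(inherits(a, "netalignment"), inherits(pair, "simulated_pair"))
  truth_from <- pair$truth$from
  truth_to <- pair$truth$to
  truth_map <- stats::setNames(truth_to, truth_from)

  na_ <- length(a$from)
  expected <- unname(truth_map[a$from]) # NA when i has no true partner
  correct <- !is.na(expected) & expected == a$to
  # a pair is misaligned when i has a true partner and missed it, or when i
  # is truthless but its target i' is some other vertex's true partner
  target_is_partner <- a$to %in% truth_to
  mis <- (!is.na(expected) & expected != a$to) |
    (is.na(expected) & target_is_partner)
  nc <- sum(correct)
  no <- length(truth_from)

  cats <- c("ortholog_vertex_similar", "analog", "paralog_case", "unrelated")
  lab_aligned <- pair$labels[a$from]
  per <- do.call(rbind, lapply(cats, function(cc) {
    in_cat <- pair$labels == cc
    al <- lab_aligned == cc
    data.frame(category = cc,
               n = sum(in_cat),
               aligned = sum(al),
               correct = sum(correct & al),
               misaligned = sum(mis & al),
               unaligned = sum(in_cat) - sum(al),
               stringsAsFactors = FALSE)
  }))
  per$accuracy <- ifelse(per$n > 0, per$correct / per$n, NA_real_)

  structure(list(
    n_aligned = na_,
    n_correct = nc,
    n_groups = no,
    misaligned = sum(mis),
    sensitivity = if (na_ > 0) nc / na_ else 0,
    sensitivity_defined = na_ > 0,
    coverage = if (no > 0) nc / no else 0,
    per_category = per), class = "evaluation_report")
}

#' Evaluate an alignment against an orthology group table
#'
#' For empirical data the ground truth is approximated by orthologous groups
#' (for example from an orthology database): an aligned pair counts as
#' correct when its two vertices share a group. `n_aligned` counts only pairs
#' where both vertices carry a group id; `n_groups` is the number of groups
#' present on both sides, so coverage can exceed 1 when several aligned pairs
#' recover the same group.
#'
#' @param a a `netalignment`.
#' @param groups_g,groups_g2 named character vectors mapping vertex id to
#'   group id for the first and second network.
#' @return An `"evaluation_report"` (without per-category breakdown).
#' @export
evaluate_against_groups <- function(a, groups_g, groups_g2) {
  stopifnot(inherits(a, "netalignment"))
  gi <- unname(groups_g[a$from])
  gj <- unname(groups_g2[a$to])
  both <- !is.na(gi) & !is.na(gj)
  na_ <- sum(both)
  nc <- sum(both & gi == gj, na.rm = TRUE)
  no <- length(intersect(unique(groups_g), unique(groups_g2)))
  structure(list(
    n_aligned = na_,
    n_correct = nc,
    n_groups = no,
    misaligned = na_ - nc,
    sensitivity = if (na_ > 0) nc / na_ else 0,
    sensitivity_defined = na_ > 0,
    coverage = if (no > 0) nc / no else 0,
    per_category = NULL), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> NA = %d aligned, NC = %d correct, ",
                     "NO = %d groups\n"),
              x$n_aligned, x$n_correct, x$n_groups))
  cat(sprintf("  sensitivity (NC/NA): %.3f%s   coverage (NC/NO): %.3f   misaligned: %d\n",
              x$sensitivity,
              if (!x$sensitivity_defined) " (undefined: nothing aligned)" else "",
              x$coverage, x$misaligned))
  if (!is.null(x$per_category)) {
    print(x$per_category, row.names = FALSE)
  }
  invisible(x)
}
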