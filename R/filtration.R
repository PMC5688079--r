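#' Threshold vector of a weighted matrix
#'
#' The sorted multiset of all off-diagonal values of a symmetric matrix:
#' every value at which the thresholded network can change, bounded by the
#' minimum and maximum connectivity values. The upper-triangle multiset
#' (n(n-1)/2 values) is used; including the symmetric halves or the
#' diagonal would induce the identical network family.
#'
#' @param M square symmetric matrix (n >= 2).
#' @param dedup drop duplicated values (default FALSE: keep the multiset).
#' @return Sorted numeric vector of thresholds.
#' @export
build_threshold_vector <- function(M, dedup = FALSE) {
  if (nrow(M) < 2L) stop("need at least 2 channels")
  v <- sort(M[upper.tri(M)])
  if (dedup) v <- unique(v)
  v
}

#' Threshold filtration of a weighted matrix
#'
#' Sweeps a threshold across all values of the matrix and computes, for
#' each resulting binary network, the mean local clustering coefficient,
#' edge density, characteristic path length (mean geodesic over reachable
#' pairs) and total wiring cost (sum of `D_ij * F_ij` over surviving
#' edges). Under the default sublevel rule (edge iff value <= tau) the
#' family is a true filtration: edge sets are nested along the threshold
#' vector, starting empty below the minimum value and complete at the
#' maximum, so no single arbitrary threshold has to be chosen.
#'
#' @param M symmetric matrix to threshold: a connectivity matrix or a
#'   wiring-cost matrix.
#' @param D optional distance matrix; when given, the per-network wiring
#'   cost sums `D_ij * M_ij` over surviving edges. When `NULL`, `M` itself
#'   is taken as the wiring-cost weights (i.e. `M` is already `D * F`).
#' @param rule `"sublevel"` (edge iff value <= tau; default) or
#'   `"superlevel"` (edge iff value >= tau).
#' @param thresholds optional threshold vector; defaults to
#'   [build_threshold_vector()] of `M`.
#' @return A `filtration_result`: list with `thresholds`, `metrics`
#'   (length(thresholds) x 4 matrix: clustering, density, path_length,
#'   wiring_cost), `rule`, and the matrices used.
#' @export
filtrate <- function(M, D = NULL, rule = c("sublevel", "superlevel"),
                     thresholds = NULL) {
  rule <- match.arg(rule)
  M <- unclass(M)
  if (nrow(M) != ncol(M)) stop("M must be square")
  if (!is.null(D)) {
    if (!all(dim(D) == dim(M))) stop("D and M must have the same shape")
    cost <- unclass(D) * M
  } else {
    cost <- M
  }
  diag(cost) <- 0
  if (is.null(thresholds)) thresholds <- build_threshold_vector(M)
  metrics <- filtration_curves_cpp(M, cost, as.numeric(thresholds),
                                   rule == "sublevel")
  structure(list(thresholds = as.numeric(thresholds), metrics = metrics,
                 rule = rule, m = M, cost = cost,
                 measure = attr(M, "measure")),
            class = "filtration_result")
}

#' @export
print.filtration_result <- function(x, ...) {
  cat(sprintf("<filtration_result> %d thresholds in [%.4g, %.4g], rule %s\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds),
              x$rule))
  invisible(x)
}

#' Difference of two filtration curve sets on a common grid
#'
#' The two conditions' threshold vectors generally differ, so both curve
#' sets are re-evaluated exactly (not interpolated) on the union of the
#' two threshold grids -- the curves are right-continuous step functions
#' of the threshold, and the network at any threshold is fully determined
#' by the parent matrix -- then subtracted EC - EO. At the final grid
#' point both sublevel networks are complete, so the density and
#' clustering differences always end at exactly zero.
#'
#' @param f_ec,f_eo `filtration_result`s for eyes closed / eyes open with
#'   the same rule.
#' @return List with `thresholds` (union grid) and `difference`
#'   (grid x 4 matrix of EC - EO values), plus the re-evaluated per
#'   condition curves `ec` and `eo`.
#' @export
filtration_difference <- function(f_ec, f_eo) {
  if (!identical(f_ec$rule, f_eo$rule))
    stop("filtration rules differ between conditions")
  grid <- sort(unique(c(f_ec$thresholds, f_eo$thresholds)))
  sub <- f_ec$rule == "sublevel"
  ec <- filtration_curves_cpp(f_ec$m, f_ec$cost, grid, sub)
  eo <- filtration_curves_cpp(f_eo$m, f_eo$cost, grid, sub)
  structure(list(thresholds = grid, difference = ec - eo, ec = ec, eo = eo,
                 rule = f_ec$rule),
            class = "filtration_difference")
}
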