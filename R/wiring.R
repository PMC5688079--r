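#' Inter-electrode Euclidean distance matrix
#'
#' `D_ij` is the straight-line distance in mm between electrode `i` at
#' `(x_i, y_i, z_i)` and electrode `j`. Duplicate coordinates (touching
#' contacts) are allowed but reported.
#'
#' @param layout an `electrode_layout` (see [read_layout()],
#'   [make_layout()]).
#' @return Symmetric n x n matrix in mm with zero diagonal, labelled by
#'   electrode.
#' @export
distance_matrix <- function(layout) {
  if (nrow(layout) < 2L) stop("need at least 2 electrodes")
  coords <- as.matrix(layout[, c("x_mm", "y_mm", "z_mm")])
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- list(layout$label, layout$label)
  dup <- sum(D[upper.tri(D)] == 0)
  if (dup > 0)
    message(dup, " electrode pair(s) share identical coordinates")
  D
}

#' Wiring-cost matrix
#'
#' The elementwise product `W = D * F` of the Euclidean distance matrix
#' and a functional connectivity matrix: the further apart two electrodes
#' and the stronger their statistical coupling, the larger the cost of
#' "wiring" them together. Units are mm times the connectivity unit.
#'
#' @param D distance matrix (mm), labelled.
#' @param F_mat connectivity matrix with the same shape and label order.
#' @return Matrix of class `wiring_cost_matrix`, carrying the parent
#'   measure/band attributes when present on `F_mat`.
#' @export
wiring_cost <- function(D, F_mat) {
  if (!all(dim(D) == dim(F_mat)))
    stop("D and F must have the same shape")
  ld <- rownames(D); lf <- rownames(F_mat)
  if (!is.null(ld) && !is.null(lf) && !identical(ld, lf))
    stop("label order mismatch between D and F; align them explicitly")
  W <- unclass(D) * unclass(F_mat)
  diag(W) <- 0
  structure(W, measure = attr(F_mat, "measure"), band = attr(F_mat, "band"),
            labels = rownames(D), class = c("wiring_cost_matrix", "matrix"))
}

#' Total wiring cost of a network
#'
#' Scalar summary: the sum of `W_ij` over unordered off-diagonal pairs
#' (i < j), optionally restricted to the edges of a binary network. With
#' a thresholded network this is the sum of `D_ij * F_ij` over surviving
#' edges. `per_edge = TRUE` returns the mean per edge instead of the sum.
#'
#' @param W square symmetric cost matrix.
#' @param adjacency optional 0/1 symmetric matrix selecting edges.
#' @param per_edge report the mean cost per surviving edge.
#' @return A scalar (0 for an empty edge set).
#' @export
total_wiring_cost <- function(W, adjacency = NULL, per_edge = FALSE) {
  up <- upper.tri(W)
  if (!is.null(adjacency)) {
    if (!all(dim(adjacency) == dim(W)))
      stop("adjacency must match W in shape")
    up <- up & (adjacency > 0)
  }
  vals <- W[up]
  if (length(vals) == 0L) return(0)
  if (per_edge) mean(vals) else sum(vals)
}
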