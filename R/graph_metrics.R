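#' Binary network container
#'
#' @param adjacency 0/1 symmetric matrix, zero diagonal.
#' @param threshold threshold value used.
#' @param rule `"superlevel"` (edge iff value >= threshold) or
#'   `"sublevel"` (edge iff value <= threshold).
#' @param parent identifier of the parent weighted matrix (optional).
#' @return A `binary_network` object.
#' @export
binary_network <- function(adjacency, threshold = NA_real_,
                           rule = c("superlevel", "sublevel"),
                           parent = NULL) {
  rule <- match.arg(rule)
  adjacency <- (unclass(adjacency) != 0) * 1L
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  diag(adjacency) <- 0L
  structure(list(adjacency = adjacency, threshold = threshold,
                 rule = rule, parent = parent),
            class = "binary_network")
}

#' Fixed-threshold network from a connectivity matrix
#'
#' Applies the mean-plus-one-standard-deviation rule: the threshold is
#' `tau = mean + sd` of the off-diagonal upper-triangle values (population
#' standard deviation, dividing by N), and two electrodes are connected
#' when their connectivity is at least `tau` (superlevel rule). With a
#' zero-variance matrix `tau` equals the common value and the network is
#' complete.
#'
#' @param F_mat symmetric connectivity (or wiring-cost) matrix.
#' @return A [binary_network()] with the threshold recorded.
#' @export
threshold_fixed <- function(F_mat) {
  n <- nrow(F_mat)
  if (n < 2L) stop("need at least 2 channels")
  v <- F_mat[upper.tri(F_mat)]
  tau <- mean(v) + sqrt(mean((v - mean(v))^2))
  A <- (unclass(F_mat) >= tau) * 1L
  diag(A) <- 0L
  dimnames(A) <- dimnames(F_mat)
  binary_network(A, tau, "superlevel", parent = attr(F_mat, "measure"))
}

metric_battery <- c("gtom", "matching_index", "density", "clustering",
                    "transitivity", "n_components", "largest_component",
                    "modularity", "assortativity", "core_periphery",
                    "path_length", "eigenvector_centrality", "pagerank",
                    "degree")

#' Network metric battery
#'
#' Computes the 14-metric summary of a binary undirected network:
#' generalized topological overlap (mean), matching index (mean), density,
#' mean local clustering coefficient, transitivity, number of connected
#' components, size of the largest component, modularity of a greedy
#' modularity-maximizing partition, degree assortativity, core/periphery
#' quality (Borgatti-Everett correlation with an ideal core structure),
#' characteristic path length (mean geodesic over reachable pairs),
#' eigenvector centrality (computed on the largest component, zeros
#' elsewhere, normalized to unit maximum; mean reported), PageRank
#' (damping 0.85; mean), and mean degree. Per-node metrics are averaged
#' over nodes. Degenerate graphs return finite conventions: undefined
#' clustering/transitivity/assortativity/modularity/path length are 0.
#'
#' @param B a [binary_network()] or a 0/1 adjacency matrix.
#' @return Named numeric vector over the 14 metrics.
#' @export
compute_metrics <- function(B) {
  A <- if (inherits(B, "binary_network")) B$adjacency else (unclass(B) != 0) * 1L
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  deg <- igraph::degree(g)
  comp <- igraph::components(g)

  clustering <- finite_or(igraph::transitivity(g, type = "localaverage",
                                               isolates = "zero"), 0)
  trans <- finite_or(igraph::transitivity(g, type = "global"), 0)
  cpl <- finite_or(suppressWarnings(
    igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)), 0)
  modularity <- if (igraph::ecount(g) == 0) 0 else
    finite_or(igraph::modularity(igraph::cluster_fast_greedy(g)), 0)
  assort <- finite_or(suppressWarnings(igraph::assortativity_degree(g)), 0)

  # eigenvector centrality: largest component, zeros elsewhere, unit max
  # (leading eigenvector via LAPACK: deterministic across runs)
  ev <- numeric(n)
  big <- which(comp$membership == which.max(comp$csize))
  if (length(big) > 1L && sum(A[big, big]) > 0) {
    v <- abs(eigen(A[big, big, drop = FALSE], symmetric = TRUE)$vectors[, 1L])
    if (max(v) > 0) v <- v / max(v)
    ev[big] <- v
  }
  pr <- igraph::page_rank(g, damping = 0.85)$vector

  c(gtom = gtom_mean(A),
    matching_index = matching_index_mean(A),
    density = if (n > 1) sum(A) / (n * (n - 1)) else 0,
    clustering = clustering,
    transitivity = trans,
    n_components = comp$no,
    largest_component = max(comp$csize),
    modularity = modularity,
    assortativity = assort,
    core_periphery = core_periphery_quality(A),
    path_length = cpl,
    eigenvector_centrality = mean(ev),
    pagerank = mean(pr),
    degree = mean(deg))
}

finite_or <- function(x, default) if (length(x) == 1L && is.finite(x)) x else default

# generalized topological overlap (one-step), mean over off-diagonal pairs
gtom_mean <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(0)
  L <- A %*% A
  k <- rowSums(A)
  num <- L + A
  den <- outer(k, k, pmin) + 1 - A
  w <- ifelse(den > 0, num / den, 0)
  mean(w[upper.tri(w)])
}

# matching index: shared neighbours (excluding the pair) over the union,
# mean over off-diagonal pairs; 0/0 pairs count as 0
matching_index_mean <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(0)
  cn <- A %*% A
  k <- rowSums(A)
  uni <- outer(k, k, `+`) - 2 * A - cn
  m <- ifelse(uni > 0, cn / uni, 0)
  mean(m[upper.tri(m)])
}

# Borgatti-Everett core/periphery quality: nodes ranked by degree, core
# sizes 1..n-1 scanned, quality = max Pearson correlation between the
# adjacency and the ideal pattern (edge iff either endpoint in the core)
core_periphery_quality <- function(A) {
  n <- nrow(A)
  if (n < 3L) return(0)
  ord <- order(rowSums(A), seq_len(n), decreasing = c(TRUE, FALSE),
               method = "radix")
  up <- upper.tri(A)
  a <- A[up]
  if (sd(a) == 0) return(0)
  best <- 0
  in_core <- rep(FALSE, n)
  for (k in seq_len(n - 1L)) {
    in_core[ord[k]] <- TRUE
    ideal <- outer(in_core, in_core, `|`)[up] * 1
    if (sd(ideal) == 0) next
    q <- cor(a, ideal)
    if (is.finite(q) && q > best) best <- q
  }
  best
}

#' Per-metric condition difference
#'
#' Signed eyes-closed minus eyes-open difference for each metric; a
#' positive value means the metric is larger with eyes closed.
#'
#' @param m_ec,m_eo named metric vectors (same names, e.g. from
#'   [compute_metrics()]).
#' @return Named numeric vector of `EC - EO` differences.
#' @export
condition_difference <- function(m_ec, m_eo) {
  if (!identical(names(m_ec), names(m_eo)))
    stop("metric names do not match between conditions")
  m_ec - m_eo
}
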