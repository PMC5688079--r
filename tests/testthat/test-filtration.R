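toy3 <- function(vals) {
  M <- matrix(0, 3, 3)
  M[upper.tri(M)] <- vals   # (1,2), (1,3), (2,3)
  M + t(M)
}

test_that("threshold vector is the sorted off-diagonal multiset with bounds", {
  M <- toy3(c(0.3, 0.7, 0.7))
  expect_equal(build_threshold_vector(M), c(0.3, 0.7, 0.7))
  expect_equal(build_threshold_vector(M, dedup = TRUE), c(0.3, 0.7))
  M2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  expect_equal(build_threshold_vector(M2), 0.4)
  set.seed(3)
  R <- matrix(rnorm(36), 6, 6); R <- R + t(R); diag(R) <- 0
  tv <- build_threshold_vector(R)
  expect_equal(min(tv), min(R[upper.tri(R)]))
  expect_equal(max(tv), max(R[upper.tri(R)]))
  expect_length(tv, 15)
})

test_that("3-channel sublevel filtration matches hand enumeration", {
  # W pairs: (1,2)=0.2, (1,3)=1.0, (2,3)=2.4
  W <- toy3(c(0.2, 1.0, 2.4))
  fr <- filtrate(W)
  expect_equal(fr$thresholds, c(0.2, 1.0, 2.4))
  # tau=0.2: single edge; tau=1.0: 2-path; tau=2.4: triangle
  expect_equal(unname(fr$metrics[, "density"]), c(1 / 3, 2 / 3, 1))
  expect_equal(unname(fr$metrics[, "clustering"]), c(0, 0, 1))
  expect_equal(unname(fr$metrics[, "path_length"]), c(1, 4 / 3, 1))
  expect_equal(unname(fr$metrics[, "wiring_cost"]), c(0.2, 1.2, 3.6))
})

test_that("sublevel family is nested from empty to complete", {
  set.seed(13)
  M <- matrix(runif(64), 8, 8); M <- (M + t(M)) / 2; diag(M) <- 0
  fr <- filtrate(M)
  dens <- fr$metrics[, "density"]
  expect_true(all(diff(dens) >= 0))                  # monotone density
  expect_equal(dens[length(dens)], 1)                # complete at max(T)
  expect_equal(unname(fr$metrics[length(dens), "clustering"]), 1)
  # below min(T): empty graph
  eps <- filtrate(M, thresholds = min(fr$thresholds) - 1e-9)
  expect_equal(unname(eps$metrics[1, "density"]), 0)
  # explicit nesting of edge sets
  tv <- fr$thresholds
  prev <- NULL
  for (tau in tv) {
    edges <- which(M <= tau & upper.tri(M))
    if (!is.null(prev)) expect_true(all(prev %in% edges))
    prev <- edges
  }
  # component count is non-increasing along the sweep
  ig_comps <- vapply(tv, function(tau) {
    A <- (M <= tau & upper.tri(M)) * 1; A <- A + t(A)
    igraph::components(igraph::graph_from_adjacency_matrix(A, "undirected"))$no
  }, numeric(1))
  expect_true(all(diff(ig_comps) <= 0))
})

test_that("curves are step functions changing only at matrix values", {
  M <- toy3(c(0.2, 1.0, 2.4))
  fr <- filtrate(M)
  dense <- seq(0.21, 0.99, length.out = 11)   # strictly inside (0.2, 1.0)
  re <- filtrate(M, thresholds = dense)
  for (cn in colnames(re$metrics))
    expect_true(all(re$metrics[, cn] == fr$metrics[1, cn]))
})

test_that("condition difference curves align on the union grid and end at zero", {
  M <- toy3(c(1, 2, 3))
  f1 <- filtrate(M)
  expect_equal(filtration_difference(f1, f1)$difference,
               matrix(0, 3, 4, dimnames = list(NULL, colnames(f1$metrics))))

  M2 <- toy3(c(1, 2.5, 3))   # one differing entry
  f2 <- filtrate(M2)
  fd <- filtration_difference(f1, f2)
  expect_equal(fd$thresholds, c(1, 2, 2.5, 3))
  # difference nonzero only on [2, 2.5): the interval between the two values
  expect_equal(unname(fd$difference[, "density"]), c(0, 1 / 3, 0, 0))
  # density and clustering differences are exactly zero at the final grid
  # point, where both networks are complete
  last <- nrow(fd$difference)
  expect_identical(unname(fd$difference[last, "density"]), 0)
  expect_identical(unname(fd$difference[last, "clustering"]), 0)

  sup <- filtrate(M, rule = "superlevel")
  expect_error(filtration_difference(f1, sup), "rules differ")
})

test_that("superlevel rule inverts the sweep direction", {
  M <- toy3(c(0.2, 1.0, 2.4))
  fr <- filtrate(M, rule = "superlevel")
  expect_equal(unname(fr$metrics[, "density"]), c(1, 2 / 3, 1 / 3))
})

test_that("distance weighting feeds the per-network wiring cost", {
  F_mat <- toy3(c(0.5, 0.5, 0.5))
  D <- toy3(c(1, 2, 4))
  fr <- filtrate(F_mat, D = D)
  # all entries equal 0.5 -> single threshold value repeated; complete
  # network at every step, wiring cost = sum D*F = 0.5 + 1 + 2
  expect_equal(unname(fr$metrics[, "wiring_cost"]), rep(3.5, 3))
})
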