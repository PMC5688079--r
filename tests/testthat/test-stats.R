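test_that("star coding follows the p < 0.05 / p < 0.001 rule", {
  expect_equal(significance_stars(c(0.0005, 0.001, 0.01, 0.05, 0.3)),
               c("**", "*", "*", "", ""))
})

test_that("channel test: complete separation, identical sets, determinism", {
  set.seed(7)
  base <- matrix(rnorm(36 * 3), 36, 3)
  ec <- base + 5    # every EC window above every EO window
  eo <- base
  r <- channel_condition_test(ec, eo, n_perm = 9999, seed = 2)
  expect_true(all(r$p <= 0.001))
  expect_true(all(r$stars == "**"))
  expect_true(all(r$statistic > 0))

  same <- channel_condition_test(base, base, n_perm = 999, seed = 2)
  expect_true(all(same$p == 1))

  r2 <- channel_condition_test(ec, eo, n_perm = 9999, seed = 2)
  expect_identical(r$p, r2$p)
  # a moderate effect: p depends on the permutation stream
  mod_a <- channel_condition_test(base + 0.3, eo, n_perm = 199, seed = 2)
  mod_b <- channel_condition_test(base + 0.3, eo, n_perm = 199, seed = 3)
  expect_false(identical(mod_a$p, mod_b$p))
  expect_error(channel_condition_test(ec[1:3, ], eo, n_perm = 99), "5 windows")
})

test_that("channel test groups channels by implant region", {
  set.seed(17)
  lay <- make_layout(list(
    layout_spec("strip", 2, 10, origin = c(0, 0, 0), region = "T",
                laterality = "L", label_prefix = "T"),
    layout_spec("depth", 2, 10, origin = c(30, 0, 0), region = "H",
                laterality = "L", label_prefix = "H")))
  ec <- matrix(rnorm(40 * 4), 40, 4)
  colnames(ec) <- lay$label
  eo <- ec
  eo[, 3:4] <- eo[, 3:4] - 4   # only the H channels differ
  r <- channel_condition_test(ec, eo, n_perm = 999, seed = 5, layout = lay)
  expect_equal(sort(unique(r$region)), c("H", "T"))
  regions <- attr(r, "regions")
  expect_equal(sort(regions$region), c("H", "T"))
  expect_lt(regions$p[regions$region == "H"], 0.01)
  expect_gt(regions$p[regions$region == "T"], 0.1)
  bad <- ec; colnames(bad) <- paste0("X", 1:4)
  expect_error(channel_condition_test(bad, eo, n_perm = 99, layout = lay),
               "missing from layout")
})

test_that("curve test: identical inputs give zero area and p = 1", {
  lay <- make_layout(layout_spec("strip", 4, 10, region = "T",
                                 laterality = "L"))
  D <- distance_matrix(lay)
  set.seed(23)
  wins <- replicate(12, {
    m <- matrix(0, 4, 4); m[upper.tri(m)] <- runif(6); m + t(m)
  }, simplify = FALSE)
  r <- curve_condition_test(wins, wins, D, n_perm = 99, grid_size = 20,
                            seed = 4)
  expect_equal(r$statistic, rep(0, 4))
  expect_true(all(r$p == 1))
  expect_equal(r$metric, c("clustering", "density", "path_length",
                           "wiring_cost"))

  r2 <- curve_condition_test(wins, wins, D, n_perm = 99, grid_size = 20,
                             seed = 4)
  expect_identical(r$p, r2$p)
})

test_that("curve test detects a strong coupling contrast", {
  lay <- make_layout(layout_spec("strip", 4, 10, region = "T",
                                 laterality = "L"))
  D <- distance_matrix(lay)
  cfg <- synthetic_config(n_channels = 4, fs = 250, duration_s = 90, seed = 77)
  de <- wavelet_decompose(simulate_recording(cfg, "EC", lay$label), 8:12)
  do <- wavelet_decompose(simulate_recording(cfg, "EO", lay$label), 8:12)
  r <- curve_condition_test(connectivity_windows(de, "spearman_power"),
                            connectivity_windows(do, "spearman_power"),
                            D, n_perm = 199, grid_size = 50, seed = 77)
  expect_lt(r$p[r$metric == "wiring_cost"], 0.05)
})

test_that("cohort summaries count subjects significant per metric", {
  res <- data.frame(subject = rep(c("S1", "S2", "S3"), each = 2),
                    metric = rep(c("density", "wiring_cost"), 3),
                    p = c(0.01, 0.2, 0.03, 0.01, 0.5, 0.04))
  s <- cohort_summary(res)
  expect_equal(s$label[s$metric == "density"], "2/3")
  expect_equal(s$label[s$metric == "wiring_cost"], "2/3")
  all_sig <- transform(res, p = 0.01)
  expect_true(all(cohort_summary(all_sig)$k == 3))
  none <- transform(res, p = 0.5)
  expect_true(all(cohort_summary(none)$k == 0))
  expect_error(cohort_summary(res[0, ]), "at least one")
})
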