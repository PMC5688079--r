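test_that("grid, strip and degenerate layouts reproduce their geometry", {
  g <- make_layout(layout_spec("grid", c(8, 8), 10, region = "Grid",
                               laterality = "L"))
  expect_equal(nrow(g), 64)
  D <- distance_matrix(g)
  nn <- apply(D + diag(Inf, 64), 1, min)
  expect_equal(unname(nn), rep(10, 64))

  s <- make_layout(layout_spec("strip", 6, 10, region = "T",
                               laterality = "L"))
  Ds <- distance_matrix(s)
  expect_equal(max(Ds), 50)

  one <- make_layout(layout_spec("strip", 1, 10, region = "T",
                                 laterality = "L"))
  expect_equal(nrow(one), 1)
  expect_error(distance_matrix(one), "at least 2")

  expect_error(layout_spec("strip", 0, 10, region = "T", laterality = "L"),
               "positive")
  expect_error(layout_spec("strip", 4, -1, region = "T", laterality = "L"),
               "spacing")
})

test_that("simulation is deterministic given the seed and rejects bad labels", {
  cfg <- synthetic_config(n_channels = 3, fs = 200, duration_s = 10, seed = 5)
  a <- simulate_recording(cfg, "EC")
  b <- simulate_recording(cfg, "EC")
  expect_identical(a$data, b$data)
  eo <- simulate_recording(cfg, "EO")
  expect_false(identical(a$data, eo$data))
  expect_error(simulate_recording(cfg, "XX"), "unknown condition")
})

test_that("uncoupled channels show near-zero ISPC; a fully coupled pair locks", {
  est <- function(coup, seeds) {
    vapply(seeds, function(s) {
      cfg <- synthetic_config(n_channels = 2, fs = 500, duration_s = 180,
                              coupling = list(EC = coup, EO = coup),
                              seed = s)
      dec <- wavelet_decompose(simulate_recording(cfg, "EC"), 10)
      ph <- decomposition_phase(dec)
      ispc(ph[1, 1, ], ph[2, 1, ])
    }, numeric(1))
  }
  expect_lt(mean(est(0, 1:15)), 0.1)
  expect_gt(min(est(1, 1:5)), 0.9)
})

test_that("estimated coupling is monotone in the generator coupling", {
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  vals <- sapply(levels, function(cc) vapply(1:20, function(s) {
    cfg <- synthetic_config(n_channels = 2, fs = 250, duration_s = 60,
                            coupling = list(EC = cc, EO = cc), seed = s)
    dec <- wavelet_decompose(simulate_recording(cfg, "EC"), 10)
    ph <- decomposition_phase(dec)
    ispc(ph[1, 1, ], ph[2, 1, ])
  }, numeric(1)))
  ct <- suppressWarnings(
    cor.test(rep(levels, each = 20), as.vector(vals), method = "spearman",
             alternative = "greater"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("background-only simulation has the requested 1/f spectral slope", {
  slopes <- vapply(1:3, function(s) {
    cfg <- synthetic_config(n_channels = 1, fs = 500, duration_s = 60,
                            alpha_power_scale = list(EC = 0, EO = 0),
                            noise_exponent = 1, seed = s)
    rec <- simulate_recording(cfg, "EC")
    sp <- stats::spec.pgram(stats::ts(rec$data[1, ], frequency = 500),
                            spans = 21, plot = FALSE)
    sel <- sp$freq >= 2 & sp$freq <= 45
    unname(stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-1)), 0.3)
})

test_that("cohorts have heterogeneous layouts and are seed-reproducible", {
  cfg <- synthetic_config(fs = 100, duration_s = 4, seed = 9)
  co <- make_cohort(11, config = cfg)
  expect_length(co, 11)
  sizes <- vapply(co, function(s) nrow(s$layout), numeric(1))
  expect_gt(length(unique(sizes)), 1)
  expect_false(identical(co$S01$layout, co$S02$layout))
  for (s in co) {
    expect_identical(s$EC$labels, s$layout$label)
    expect_identical(s$EO$labels, s$layout$label)
  }
  co2 <- make_cohort(11, config = cfg)
  expect_identical(co, co2)
  expect_length(make_cohort(1, config = cfg), 1)
})

test_that("synthetic config validates coupling and duration invariants", {
  expect_error(synthetic_config(coupling = list(EC = 1.5, EO = 0)), "\\[0,1\\]")
  bad <- matrix(c(0, 0.2, 0.4, 0), 2, 2)
  expect_error(synthetic_config(n_channels = 2,
                                coupling = list(EC = bad, EO = 0)),
               "symmetric")
  expect_error(synthetic_config(fs = 3, duration_s = 0.5), "integer")
})
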