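test_that("windowed Spearman power correlation matches the rank-Pearson oracle", {
  px <- c(3, 1, 4, 1.5, 5, 9, 2, 6)
  py <- c(2, 7, 1, 8, 2.5, 8.5, 3, 9)
  # frozen value computed with oracle_spearman (rank, then Pearson, with
  # average ranks for ties): 5/21
  expect_equal(as.numeric(spearman_power(px, py, fs = 8, window_s = 1)),
               0.238095238095238, tolerance = 1e-12)
  expect_equal(oracle_spearman(px, py), 0.238095238095238, tolerance = 1e-12)

  x <- c(0.3, 1.2, 0.7, 2.2, 1.9, 0.1)
  expect_equal(as.numeric(spearman_power(x, x, fs = 6, window_s = 1)), 1.0)
  expect_equal(as.numeric(spearman_power(1:6, 6:1, fs = 6, window_s = 1)), -1.0)
  expect_error(spearman_power(1:5, 1:6, fs = 1), "equal length")
})

test_that("Spearman windows skip degenerate segments and average the rest", {
  px <- c(1, 1, 1, 1, 2, 1, 3, 4)   # first window constant
  py <- c(5, 2, 7, 1, 1, 2, 3, 4)
  r <- spearman_power(px, py, fs = 4, window_s = 1)
  expect_equal(attr(r, "n_windows"), 1L)
  expect_equal(as.numeric(r), oracle_spearman(px[5:8], py[5:8]))
  # all windows degenerate -> error
  expect_error(spearman_power(rep(1, 8), py, fs = 4, window_s = 1),
               "degenerate")
})

test_that("Fisher-Z matches atanh and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306144334055, tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("ISPC analytic cases: perfect clustering, cancelling vectors", {
  ph <- runif(50, -pi, pi)
  expect_equal(ispc(ph, ph), 1.0)
  expect_equal(ispc(ph + 1.3, ph), 1.0)
  expect_equal(ispc(c(0, pi / 2, pi, 3 * pi / 2), rep(0, 4)), 0.0,
               tolerance = 1e-12)
  expect_error(ispc(numeric(0), numeric(0)), "empty")
})

test_that("PLI analytic cases: constant lead, cancelling lags, zero-lag blindness", {
  ph <- runif(64, -pi, pi)
  expect_equal(pli(exp(1i * (ph + pi / 2)), exp(1i * ph)), 1.0)
  lags <- rep(c(pi / 4, -pi / 4), 32)
  expect_equal(pli(exp(1i * (ph + lags)), exp(1i * ph)), 0.0)
  # exactly zero-lag coupling is invisible: sgn(0) = 0
  expect_equal(pli(exp(1i * ph), exp(1i * ph)), 0.0)
  expect_error(pli(complex(0), complex(0)), "empty")
})

test_that("estimators agree with brute-force oracles on random inputs", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    px <- rnorm(n)^2
    py <- rnorm(n)^2
    expect_equal(as.numeric(spearman_power(px, py, fs = n, window_s = 1)),
                 oracle_spearman(px, py), tolerance = 1e-12)
    phx <- runif(n, -pi, pi); phy <- runif(n, -pi, pi)
    expect_equal(ispc(phx, phy), oracle_ispc(phx, phy), tolerance = 1e-12)
    zx <- complex(real = rnorm(n), imaginary = rnorm(n))
    zy <- complex(real = rnorm(n), imaginary = rnorm(n))
    expect_equal(pli(zx, zy), oracle_pli(zx, zy), tolerance = 1e-12)
  }
})

test_that("ISPC converges to the Bessel ratio under von Mises phase noise", {
  set.seed(31)
  for (kappa in c(0, 1, 4)) {
    th <- rvonmises(1e5, kappa) + 0.7   # mean offset must not matter
    expected <- if (kappa == 0) 0 else besselI(kappa, 1) / besselI(kappa, 0)
    expect_equal(ispc(th, rep(0, length(th))), expected, tolerance = 0.01)
  }
})

test_that("estimator invariances hold", {
  set.seed(41)
  n <- 200
  zx <- complex(real = rnorm(n), imaginary = rnorm(n))
  zy <- complex(real = rnorm(n), imaginary = rnorm(n))
  rot <- exp(1i * 0.9)
  expect_equal(pli(zx * rot, zy * rot), pli(zx, zy), tolerance = 1e-12)
  expect_equal(pli(zx, zy), pli(zy, zx), tolerance = 1e-12)
  phx <- runif(n, -pi, pi); phy <- runif(n, -pi, pi)
  expect_equal(ispc(phx, phy), ispc(phy, phx), tolerance = 1e-12)
  px <- rnorm(n)^2; py <- rnorm(n)^2
  expect_equal(as.numeric(spearman_power(exp(px), py, n, 1)),
               as.numeric(spearman_power(px, py, n, 1)), tolerance = 1e-12)
})

test_that("connectivity matrices are symmetric, zero-diagonal and in range", {
  set.seed(51)
  n <- 4; T <- 400
  coef <- array(complex(real = rnorm(n * 2 * T), imaginary = rnorm(n * 2 * T)),
                c(n, 2, T))
  coef[4, , ] <- coef[3, , ]   # duplicate channel
  dec <- fake_decomposition(coef, fs = 100, freqs = c(9, 10))
  for (meas in c("spearman_power", "ispc", "pli")) {
    M <- connectivity_matrix(dec, meas, band = c(8, 12), window_s = 1)
    expect_equal(unclass(M), t(unclass(M)))
    expect_equal(diag(M), setNames(rep(0, n), dec$labels))
    if (meas != "spearman_power") {
      expect_true(all(M >= 0 & M <= 1))
    } else {
      expect_true(all(M >= -1 & M <= 1))
      expect_equal(unname(M[3, 4]), 1.0)  # identical power series
    }
  }
  one_ch <- fake_decomposition(coef[1, , , drop = FALSE], fs = 100,
                               freqs = c(9, 10))
  expect_error(connectivity_matrix(one_ch, "ispc"), "2 channels")
})

test_that("pairwise PLI kernel agrees with the scalar estimator", {
  set.seed(61)
  n <- 5; T <- 300
  z <- matrix(complex(real = rnorm(n * T), imaginary = rnorm(n * T)), n, T)
  M <- restwire:::pli_matrix_cpp(z)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    expect_equal(M[i, j], pli(z[i, ], z[j, ]), tolerance = 1e-12)
})

test_that("per-window matrices and channel strengths are consistent", {
  set.seed(71)
  n <- 3; T <- 600
  coef <- array(complex(real = rnorm(n * T), imaginary = rnorm(n * T)),
                c(n, 1, T))
  dec <- fake_decomposition(coef, fs = 100, freqs = 10)
  wins <- connectivity_windows(dec, "ispc", band = c(8, 12), window_s = 1)
  expect_length(wins, 6)
  st <- channel_strength_windows(dec, "ispc", band = c(8, 12), window_s = 1)
  expect_equal(dim(st), c(6, 3))
  expect_equal(unname(st[2, 1]), mean(wins[[2]][1, 2:3]))
})
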