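# Independent brute-force oracles used to validate the estimators and
# graph metrics. Deliberately written as plain loops, sharing no code
# with the package internals.

oracle_spearman <- function(x, y) {
  rx <- rank(x)  # average ranks for ties
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

oracle_ispc <- function(phix, phiy) {
  s <- 0 + 0i
  for (t in seq_along(phix)) s <- s + exp(1i * (phix[t] - phiy[t]))
  Mod(s / length(phix))
}

oracle_pli <- function(zx, zy) {
  s <- 0
  for (t in seq_along(zx)) {
    im <- Im(zx[t] * Conj(zy[t]))
    s <- s + sign(im)
  }
  abs(s / length(zx))
}

# von Mises sampler (Best & Fisher rejection scheme), mean direction 0
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1
      out[i] <- sign(u3 - 0.5) * acos(f)
    }
  }
  out
}

# brute-force binary-graph metrics: density, mean local clustering,
# transitivity, number of components, characteristic path length over
# reachable pairs
oracle_graph_metrics <- function(A) {
  n <- nrow(A)
  dens <- sum(A[upper.tri(A)]) / (n * (n - 1) / 2)
  cl <- mean(sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k) links <- links + A[nb[a], nb[b]]
    2 * links / (k * (k - 1))
  }))
  tri <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k && A[i, j] == 1 && A[j, k] == 1) {
      triples <- triples + 1
      if (A[i, k] == 1) tri <- tri + 1
    }
  }
  trans <- if (triples > 0) tri / triples else 0
  seen <- rep(FALSE, n); ncomp <- 0
  for (s in seq_len(n)) {
    if (!seen[s]) {
      ncomp <- ncomp + 1
      stack <- s
      while (length(stack)) {
        v <- stack[1]; stack <- stack[-1]
        if (!seen[v]) { seen[v] <- TRUE; stack <- c(stack, which(A[v, ] == 1)) }
      }
    }
  }
  dmat <- matrix(Inf, n, n); dmat[A == 1] <- 1; diag(dmat) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (dmat[i, k] + dmat[k, j] < dmat[i, j]) dmat[i, j] <- dmat[i, k] + dmat[k, j]
  reach <- is.finite(dmat) & row(dmat) != col(dmat)
  cpl <- if (any(reach)) mean(dmat[reach]) else 0
  c(density = dens, clustering = cl, transitivity = trans,
    n_components = ncomp, path_length = cpl)
}

# 5-node graph from a 10-bit code over the upper triangle
graph_from_code <- function(code, n = 5) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(intToBits(code))[seq_len(n * (n - 1) / 2)]
  A + t(A)
}

# small analytic decomposition built directly from given complex series
# (channels x freq x time), bypassing the wavelet transform
fake_decomposition <- function(coef, fs = 100, freqs = seq_len(dim(coef)[2])) {
  structure(list(coef = coef, frequencies = as.numeric(freqs), fs = fs,
                 valid = rep(TRUE, dim(coef)[3]),
                 labels = sprintf("CH%02d", seq_len(dim(coef)[1])),
                 subject = "S01", condition = "EC", n_cycles = 7),
            class = "analytic_decomposition")
}
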