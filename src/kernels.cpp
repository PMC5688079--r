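#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Phase-lag index for all channel pairs from complex analytic series.
// z: channels x time. PLI_ij = | mean_t sgn(Im(z_i(t) * conj(z_j(t)))) |.
// Accumulates column-by-column (one time point holds all channels
// contiguously) so the O(n^2 T) sweep stays cache-resident.
// [[Rcpp::export]]
NumericMatrix pli_matrix_cpp(ComplexMatrix z) {
  const int n = z.nrow(), T = z.ncol();
  const int npair = n * (n - 1) / 2;
  std::vector<double> acc(npair, 0.0);
  std::vector<double> xr(n), xi(n);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) {
      const Rcomplex v = z(i, t);
      xr[i] = v.r;
      xi[i] = v.i;
    }
    int idx = 0;
    for (int i = 0; i < n; ++i) {
      const double ri = xr[i], ii = xi[i];
      for (int j = i + 1; j < n; ++j) {
        // Im(z_i * conj(z_j)) = Im(z_i) Re(z_j) - Re(z_i) Im(z_j)
        const double im = ii * xr[j] - ri * xi[j];
        acc[idx++] += (im > 0.0) - (im < 0.0);
      }
    }
  }
  NumericMatrix out(n, n);
  int idx = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double v = std::fabs(acc[idx++] / (double)T);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}

// Metric curves along a threshold sweep of a symmetric weighted matrix.
// m:    matrix whose values are thresholded (connectivity or wiring cost)
// cost: matrix summed over surviving edges (wiring-cost weights)
// thr:  threshold vector (any order)
// sublevel: edge iff m_ij <= tau, else edge iff m_ij >= tau
// Returns K x 4: clustering, density, path_length, wiring_cost.
// Clustering is the mean local clustering coefficient (0 for degree < 2);
// path length is the mean geodesic over reachable pairs (0 if none).
// Adjacency is held as bitsets: neighbour intersections (triangles) and
// BFS level sets reduce to word AND/OR + popcount.
// [[Rcpp::export]]
NumericMatrix filtration_curves_cpp(NumericMatrix m, NumericMatrix cost,
                                    NumericVector thr, bool sublevel) {
  const int n = m.nrow(), K = thr.size();
  const int W = (n + 63) / 64;
  NumericMatrix out(K, 4);
  std::vector<uint64_t> adj((size_t)n * W);
  std::vector<uint64_t> visited(W), frontier(W), nxt(W);
  std::vector<int> deg(n);

  for (int k = 0; k < K; ++k) {
    const double tau = thr[k];
    std::fill(adj.begin(), adj.end(), 0ULL);
    std::fill(deg.begin(), deg.end(), 0);
    int m_edges = 0;
    double wcost = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double v = m(i, j);
        if (sublevel ? (v <= tau) : (v >= tau)) {
          adj[(size_t)i * W + j / 64] |= 1ULL << (j % 64);
          adj[(size_t)j * W + i / 64] |= 1ULL << (i % 64);
          ++deg[i];
          ++deg[j];
          ++m_edges;
          wcost += cost(i, j);
        }
      }
    }
    const double density =
        (n > 1) ? (2.0 * m_edges) / ((double)n * (n - 1)) : 0.0;

    // mean local clustering: links among N(i) via bitset intersections
    double csum = 0.0;
    for (int i = 0; i < n; ++i) {
      const int ki = deg[i];
      if (ki < 2) continue;
      const uint64_t* ai = &adj[(size_t)i * W];
      long links2 = 0;  // counts each neighbour-pair edge twice
      for (int w = 0; w < W; ++w) {
        uint64_t bits = ai[w];
        while (bits) {
          const int j = w * 64 + __builtin_ctzll(bits);
          bits &= bits - 1;
          const uint64_t* aj = &adj[(size_t)j * W];
          for (int w2 = 0; w2 < W; ++w2)
            links2 += __builtin_popcountll(ai[w2] & aj[w2]);
        }
      }
      csum += (double)links2 / ((double)ki * (ki - 1));
    }
    const double clustering = (n > 0) ? csum / n : 0.0;

    // characteristic path length over reachable pairs: level-set BFS
    double dsum = 0.0;
    long npairs = 0;
    for (int s = 0; s < n; ++s) {
      if (deg[s] == 0) continue;
      std::fill(visited.begin(), visited.end(), 0ULL);
      std::fill(frontier.begin(), frontier.end(), 0ULL);
      visited[s / 64] = frontier[s / 64] = 1ULL << (s % 64);
      int d = 0;
      while (true) {
        std::fill(nxt.begin(), nxt.end(), 0ULL);
        for (int w = 0; w < W; ++w) {
          uint64_t bits = frontier[w];
          while (bits) {
            const int j = w * 64 + __builtin_ctzll(bits);
            bits &= bits - 1;
            const uint64_t* aj = &adj[(size_t)j * W];
            for (int w2 = 0; w2 < W; ++w2) nxt[w2] |= aj[w2];
          }
        }
        ++d;
        long reached = 0;
        for (int w = 0; w < W; ++w) {
          nxt[w] &= ~visited[w];
          visited[w] |= nxt[w];
          reached += __builtin_popcountll(nxt[w]);
        }
        if (reached == 0) break;
        dsum += (double)d * reached;
        npairs += reached;
        frontier = nxt;
      }
    }
    const double cpl = (npairs > 0) ? dsum / (double)npairs : 0.0;

    out(k, 0) = clustering;
    out(k, 1) = density;
    out(k, 2) = cpl;
    out(k, 3) = wcost;
  }
  colnames(out) = CharacterVector::create("clustering", "density",
                                          "path_length", "wiring_cost");
  return out;
}
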