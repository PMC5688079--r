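---
title: "Methods: resting-state iEEG connectivity, wiring cost and threshold filtration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state iEEG connectivity, wiring cost and threshold filtration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the pipeline

Eyes-closed (EC) and eyes-open (EO) rest are the two standard baseline
conditions in electrophysiology. They are not interchangeable: opening the
eyes attenuates the posterior alpha rhythm (8--12 Hz) and reorganizes
alpha-band coupling -- the *alpha desynchronization* effect. `restwire`
implements an analysis chain for asking, channel by channel and network by
network, whether two 3-minute resting blocks recorded from intracranial
electrodes differ between the two conditions:

1. zero-phase band-pass (0.5--70 Hz) and 60 Hz notch filtering;
2. complex Morlet wavelet decomposition giving instantaneous power and
   phase per channel and frequency;
3. three functional-connectivity estimators -- windowed Spearman power
   correlation, intersite phase clustering (ISPC), phase-lag index (PLI);
4. a wiring-cost matrix `W = D * F` weighting connectivity `F` by the
   inter-electrode Euclidean distance `D` (elementwise);
5. binary networks at a fixed `mean + SD` threshold and a 14-metric
   battery;
6. a threshold *filtration*: the whole family of binary networks over
   every possible threshold, summarized by metric-versus-threshold
   curves, which removes the arbitrary-threshold problem;
7. window-level permutation tests contrasting the conditions per channel,
   per region, and per filtration curve.

Because clinical iEEG cannot be redistributed, the package ships a
synthetic generator that emulates the statistical structure this analysis
assumes; every stage is exercised end-to-end on generated cohorts.

# The synthetic generator

Each channel is a narrow-band alpha oscillator riding on `1/f^beta`
background noise:

* A complex *driver* oscillator at the alpha centre frequency (10 Hz)
  with a phase random walk (diffusion 1.5 rad/sqrt(s)) and a smooth
  (~1 s) amplitude modulation.
* Channel `i` mixes the driver with an independent oscillator of its own:
  `z_i = w_i * d(t) * exp(i theta_i) + sqrt(1 - w_i^2) * o_i(t)`, with
  `w_i = sqrt(max_j C_ij)` from the condition's coupling matrix `C`. The
  per-channel phase jitter relative to the driver therefore shrinks as
  coupling grows, and ISPC, PLI and power correlation all rise together
  with `C`.
* `theta_i`, a fixed per-channel lag drawn once per recording from
  U(0.2, 1.2) rad, keeps the coupling away from exact zero lag so that
  the lag-sensitive PLI can see it (a pure common driver would be
  invisible to PLI by construction).
* The background is Gaussian noise spectrally shaped to `1/f^beta`
  (default `beta = 1`), scaled to unit variance; the oscillator amplitude
  is `alpha_power_scale` (RMS units of the noise).

Default study conditions: 11 subjects, two 180 s blocks (EC then EO) at
500 Hz, heterogeneous implants drawn from the typical mesial-temporal
epilepsy categories (hippocampal and other depth electrodes, temporal /
frontal / interhemispheral / frontal-polar strips, and an 8 x 8 subdural
grid for two subjects; 10 mm contact spacing throughout). Condition
contrast: alpha coupling 0.8 (EC) vs 0.2 (EO) and alpha amplitude scale
2.0 vs 1.0, encoding stronger, more coherent alpha with eyes closed.
The phase-diffusion default comes from a stationarity argument, not
tuning: a diffusion of `sigma = 1.5` rad/sqrt(s) gives the phasor
autocorrelation `exp(-sigma^2 t / 2)`, i.e. a ~0.9 s coherence time, so a
3-minute block contains roughly 200 effectively independent phase
samples and the ISPC of *uncoupled* channels concentrates near
`sqrt(pi / (4 * 200)) ~ 0.06` -- clearly separated from even weak true
coupling, while keeping the alpha line width well under 1 Hz.

What the generator does *not* emulate: volume conduction and common
reference artifacts, non-stationarity across the 3-minute block beyond
the slow amplitude modulation, movement/electrode artifacts, epileptiform
transients, and any spatial falloff of coupling with distance. Passing
tests on synthetic cohorts therefore demonstrate that the estimators and
tests behave correctly under the assumed data model, not that the
physiological effect is reproduced in patients.

One master seed expands to per-subject, per-condition child seeds by
fixed integer arithmetic, so any single recording can be regenerated in
isolation and full pipeline reruns are byte-identical.

# Spectral estimation

Morlet wavelets use a constant 7 cycles (`sigma_t = n_cycles / (2 pi f)`,
about 111 ms at 10 Hz), sampled on -1..1 s so the kernel always has an
odd number of points, and unit-energy normalization. Constant cycles
favour frequency precision over temporal precision, which is the right
trade-off for long resting blocks. The frequency axis for band analyses
is 1 Hz steps across the band; alpha is 8--12 Hz inclusive (five
frequencies). Band-level connectivity is computed per frequency and then
averaged across the band's frequencies -- averaging the complex
coefficients first would mix phases across frequencies and bias the
phase statistics.

Edge handling: half a kernel length (1 s at the defaults) is masked at
each end of the record instead of padding; all downstream estimators use
only the valid samples. The offline filter chain is a 4th-order
Butterworth high-pass and low-pass plus a 2nd-order band-stop notch, each
applied forward-backward: the filters must be zero-phase because two of
the three connectivity measures are phase statistics.

# Connectivity estimators

* **Windowed Spearman power correlation.** Power series are segmented
  into non-overlapping 5 s windows; each window is rank-transformed
  (average ranks on ties) and Pearson-correlated, and the window
  correlations are averaged. A window in which either series is constant
  has no defined correlation and is skipped; a pair with fewer than half
  its windows usable is an error. A Fisher-Z transform (`atanh`) is
  available for averaging/testing, but thresholding and the wiring cost
  always operate on the raw correlation scale.
* **ISPC** `= |mean_t exp(i(phi_x - phi_y))|`: the resultant length of
  the phase-difference distribution. Sensitive to all phase-locked
  coupling, including zero-lag (volume-conducted) coupling.
* **PLI** `= |mean_t sgn(Im(z_x conj(z_y)))|`: counts which side of the
  real axis the phase difference falls on; exact zero-lag coupling
  contributes `sgn(0) = 0` and is ignored. The cross-spectrum here is the
  instantaneous wavelet cross-spectrum -- both series come from the same
  convolution, and no segment-averaged spectral estimator is involved.

The 5 s windowing is applied to the power measure (where it improves the
signal-to-noise ratio of the correlation); phase measures use the whole
valid series by default, with a windowed variant available. The window
length for phase measures is exposed (`phase_window_s`) but off by
default, and window-level matrices for the permutation tests always use
per-window versions of all three measures so that the resampling unit is
the same across measures.

# Wiring cost

`W_ij = D_ij * F_ij` with `D` in mm. The scalar "wiring cost of a
network" is the sum of `W_ij` over the unordered pairs that are edges of
the network under consideration (the mean per edge is available as an
option). Negative Spearman entries keep their sign in `W`: anticorrelated
pairs reduce the total, and the filtration orders values as-is. Both
choices are recorded in the outputs.

# Fixed thresholds, filtration, and the two rules

The fixed-threshold network uses `tau = mean + SD` of the off-diagonal
upper-triangle values -- population SD (divide by N), since the values
are the complete population of pairs, not a sample -- and the
**superlevel** rule: edge iff `F_ij >= tau` (connectivity *above*
threshold is a connection).

The filtration instead sweeps the sorted multiset of all off-diagonal
values and defaults to the **sublevel** rule (edge iff value `<= tau`),
which is what makes the family a genuine filtration: edge sets are nested
as the threshold grows, from the empty graph below the minimum value to
the complete graph at the maximum. The two conventions are deliberately
different -- a fixed "strong edges only" cut answers one question, a
nested sweep answers another -- and every result records which rule
produced it. The upper-triangle multiset (n(n-1)/2 values) is used as the
threshold vector; adding the symmetric duplicates or diagonal would
produce the identical network family.

Four curves are tracked along the sweep: mean local clustering, edge
density, characteristic path length, and total wiring cost of the
surviving edges. Disconnected-graph conventions, applied consistently
everywhere: path length averages over reachable pairs only (0 if there
are none); clustering of a node with degree < 2 is 0; transitivity,
assortativity and modularity of degenerate graphs are 0; eigenvector
centrality is computed on the largest component (leading eigenvector of
its adjacency submatrix, via LAPACK, which is deterministic), zeros
elsewhere, normalized to unit maximum. Community structure is the greedy
modularity-maximizing partition (deterministic agglomerative merges);
core/periphery quality is the Borgatti-Everett correlation between the
adjacency and an ideal core structure, scanning core sizes over the
degree ranking. Per-node metrics enter the battery as means over nodes.

Cross-condition difference curves are formed by re-evaluating both
filtrations exactly on the union of the two threshold grids (the curves
are right-continuous step functions, so exact re-evaluation is cheap and
interpolation-free) and subtracting EC - EO. At the final union
threshold both sublevel networks are complete, so the density and
clustering differences terminate at exactly zero.

# Permutation statistics

The test family for condition contrasts is not uniquely determined by the
problem, so the package commits to one construction and documents it:

* **Channel test.** Per channel, the summary value is its mean
  connectivity to all other channels within each 5 s window. The
  statistic is the difference of condition means; the null shuffles
  condition labels over the pooled windows (two-sided,
  `p = (1 + #{|null| >= |obs|}) / (1 + n_perm)`). Channels are also
  aggregated by implant region code and the same test applied per
  region. Stars follow the `p < 0.05` (*) / `p < 0.001` (**) coding.
* **Curve test.** Condition mean matrices are rebuilt from the window
  matrices; the observed statistic per metric is the area between the EC
  and EO curves over a fixed quantile grid of the pooled (label-invariant)
  matrix values; the null permutes window labels and recomputes
  everything. The quantile grid (default 100 points) rather than the full
  threshold multiset keeps the permutation loop affordable at grid sizes
  of thousands of pairs; the observed full-resolution curves are still
  written by the pipeline.

The assumed null is exchangeability of 5 s windows across conditions.
This ignores serial dependence within a block and the fixed EC-then-EO
ordering; both are acknowledged limitations of the design being emulated,
not of the test implementation. p-values have resolution
`1/(n_perm + 1)` and are valid (never anti-conservative beyond that
resolution) under exchangeability; the test suite verifies the type-I
error of both tests by simulation and the power of the curve test on the
default condition contrast.

No multiple-testing correction is applied by default (per-channel
uncorrected reporting mirrors the descriptive per-patient tables this
format follows); `p.adjust` can be applied to any result table by the
user.

# Problem sizes used by tests and the acceptance script

The test suite runs reduced problem sizes chosen to exercise every code
path while keeping the suite fast: 2--8 channel recordings of 10--90 s at
200--500 Hz for estimator and generator properties, 1000 simulated nulls
(5 channels each, 199 permutations) and 200 curve-test nulls (99
permutations) for calibration, 20 seeds for power checks, and a 3-subject
2-minute 250 Hz demo pipeline for the byte-identical rerun check. The
acceptance script runs the full study conditions (11 subjects, 3-minute
blocks, 500 Hz, 999/199 permutations). These sizes are package choices,
stated here so results are interpreted at the scale that produced them.

# Known limitations

* The generator's coupling is spatially unstructured (no
  distance-dependent falloff), so synthetic wiring-cost contrasts are
  driven by connectivity, not geometry.
* EDF support is deliberately minimal: plain EDF, one common integer
  sampling rate, 1 s records, 16-bit quantization (round-trip error
  bounded by physical range / 65534). EDF+ annotations are not parsed.
* The curve permutation test recomputes filtrations on a quantile grid;
  with very small channel counts the grid can contain ties, which is
  handled but reduces resolution.
* Characteristic path length under the reachable-pairs convention is not
  monotone under edge addition (connecting components adds long paths);
  comparisons of path-length curves across very different densities
  should keep this in mind.
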