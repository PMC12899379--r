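---
title: "Data-adaptive frequency bands for collections of stationary time series"
author: "fbam package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-adaptive frequency bands for collections of stationary time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbam)
```

## The problem

Biomedical signals — stride intervals, inter-beat intervals, pupil diameter,
EEG — are routinely summarized by splitting the frequency axis into a few
bands and averaging spectral power within each band. Fixed conventional
bands are not guaranteed to preserve the differences that actually exist
between subjects, and a heterogeneous study population may contain
subpopulations whose spectra call for different bands altogether. This
package estimates, from a collection of K equal-length stationary series,

* a partition of the replicates into J subpopulations,
* a set of L frequency bands per subpopulation, and
* the band-average summary measures ("collapsed measures") themselves,

all chosen so that the resulting piecewise-constant summaries lose as little
of the spectral variability as possible, together with criteria that select
J and L.

## Model and objective

Each replicate k in subpopulation j is modeled as a zero-mean second-order
stationary series whose replicate-specific power spectrum
$g_{jk}(\omega) = |A_{jk}(\omega)|^2$ arises from a random transfer function
$A_{jk}$, i.i.d. within a subpopulation. The subpopulation spectrum is the
expectation $\bar g_j(\omega) = E|A_{jk}(\omega)|^2$; the variance of
$|A_{jk}|^2$ is the *extra-spectral variability* that makes a single
replicate insufficient for estimating $\bar g_j$.

A band partition $W_j = \{W_{j1}, \dots, W_{jL}\}$ covers $(0, 0.5)$
(cycles/sample) with half-open intervals. The collapsed measure of
replicate k on band l is the band average
$\hat y_{jkl} = \#(W_{jl})^{-1} \sum_{\omega \in W_{jl}} \hat g_{jk}(\omega)$,
and $\hat y_{j\cdot l}$ is its cross-replicate mean. The fitted object
minimizes the least-squares objective

$$
\hat{\mathcal L}(C, W_1, \dots, W_J \mid J, L) \;=\;
\frac 1T \sum_{j=1}^{J} \sum_{k=1}^{K_j} \sum_{l=1}^{L}
\sum_{\omega \in W_{jl}} \left(\hat g_{jk}(\omega) - \hat y_{j\cdot l}\right)^2
$$

over clusterings C and band partitions, a K-means-type loss whose "centers"
are piecewise-constant mean collapsed spectra. All band arithmetic uses
integer cut positions on the Fourier grid $\omega_m = m/T$,
$m = 1, \dots, \lfloor T/2\rfloor - 1$ (the zero and Nyquist indices are
excluded); frequencies in Hz are derived views (`cycles/sample × sampling
rate`) and never stored.

## Spectral estimation

Replicate spectra are estimated with sine-taper multitaper estimators:
orthonormal tapers $h_{rt} = \sqrt{2/(T+1)}\,\sin(\pi r t/(T+1))$,
$R = \lfloor\sqrt T\rfloor$ tapers by default, and the estimate
$\hat g(\omega_m) = R^{-1}\sum_r |\sum_t h_{rt} x_t e^{-2\pi i \omega_m t}|^2$.
Under this normalization a unit-variance white noise series has unit
spectrum, which keeps objective values on an interpretable scale; the raw
periodogram is available through `direct_spectral_estimate()` with an
all-ones taper. `estimate_spectra(standardize = TRUE)` applies an ordinary
least-squares linear detrend followed by division by the sample standard
deviation (`ddof = 1`) — the preprocessing typically used for normalized
spectral analysis of biomedical signals. Simulated data are analyzed on the
raw scale by default: variance standardization removes overall-level
differences between subpopulations, which are a genuine clustering signal
(we verified on the piecewise-smooth simulation model that standardization
degrades subpopulation recovery).

Supplying more tapers than T is capped at T with a warning; only T sine
tapers exist.

## Selection criteria

Two similarity ratios drive model selection.

**Bands (S1).** For adjacent bands l, l+1 within a subpopulation, the ratio
$\hat R^{(1)}_{jl}$ compares the two within-band root-sums-of-squares around
their band means to the root-sum-of-squares around the pooled two-band
mean. Distinct neighboring bands give small ratios; near-identical
neighbors give ratios near or above one. `criterion_s1()` averages the
$J(L-1)$ ratios. We deliberately use the plain mean over the ratio terms:
in our simulation checks a $1/(JL)$ scaling (which implicitly multiplies
the mean ratio by $(L-1)/L$) biases selection toward too few bands —
with it, the selected L on the piecewise-smooth model stays at 2 even when
the spectra have three clearly distinct plateaus, while the plain mean
recovers L = 3.

**Subpopulations (S2).** For groups i, j, the ratio $\hat R^{(2)}_{ij}$
compares the size-weighted within-group spectral variabilities around each
group's mean collapsed spectrum to the distance between those two step
functions on the full Fourier grid. `criterion_s2()` averages, over groups,
the worst-case (largest) similarity to any other group. Both ratios are
invariant to a common rescaling of all spectra.

For joint selection over a grid of fitted (J, L) cells, the two criteria
are scaled by their respective maxima over the grid (`a1`, `a2`) so neither
dominates, and the cell minimizing $S^{(1)}/a_1 + S^{(2)}/a_2$ is chosen;
`bands_only` and `subpops_only` modes minimize a single criterion along one
axis. Degenerate ratios (zero denominators, possible in finite data when
two bands or two groups are numerically identical) raise errors in the
low-level functions but are mapped to $+\infty$ during selection, so such
cells are never chosen. Ties break toward smaller J, then smaller L
(parsimony).

A property of S1 worth knowing: it penalizes splitting a *flat* spectral
region (the two halves have similar means) but cannot penalize splitting a
smooth *slope*, where any split produces bands with clearly different
means. On spectra with a steep low-frequency roll-off shared by all
subpopulations, S1 and S2 may therefore prefer an extra band on the slope
when the L grid allows it — the extra band is a real reduction in
approximation error, just not one that separates subpopulations. The
two-component autoregressive simulation model (model "3") exhibits exactly
this behavior. When a parsimonious shared band count matters more than
approximation fidelity, restrict the L grid or use `bands_only` selection
per subpopulation and inspect `tidy()` output.

## Optimization

The objective is nonsmooth and multimodal in the clustering and the cut
positions, so it is minimized with an island-model genetic algorithm
(`run_ga()`), with a chromosome holding the K integer labels and the J
sorted cut vectors:

* **Mutation** (`mutate_solution()`): every label is resampled uniformly
  over 1..J with probability $p_m$; every cut is modified with probability
  $p_m$, half the time by a local jitter of at most
  $\lceil 0.05 M\rceil$ grid steps, half the time by a uniform resample
  over all positions. The resample component matters: the per-group cut
  landscape can have separated modes (e.g., which spectral peak a band
  brackets), and a bounded jitter alone cannot cross them. Offspring are
  repaired to validity (empty groups refilled from the largest group; cut
  vectors sorted, clamped, minimum band width enforced, irreparable ones
  redrawn).
* **Selection**: each parent produces two offspring; parents and offspring
  are ranked by loss and the best `population_size` survive, with runs of
  identical chromosomes collapsed so unmutated copies do not flood the
  population. An elitist step reinserts the previous generation's best
  chromosome if it was lost.
* **Islands**: `n_islands` populations (default 6) evolve independently
  and exchange `n_migrants` random chromosomes in a ring every
  `migration_interval` generations (defaults 5 and 50).
* **Memetic refinement**: at every migration epoch each island's elite is
  polished deterministically by alternating (a) *exact* optimal band
  segmentation given the labels, computed by segmented-least-squares
  dynamic programming in $O(M^2 L)$ per group, and (b) k-means-style
  reassignment of each replicate to the subpopulation whose mean collapsed
  spectrum fits it best; a pass is accepted only if the loss strictly
  decreases. The genetic search provides global exploration; the
  refinement removes its slow final convergence. On small instances where
  the optimum can be enumerated exhaustively the combination attains it
  essentially always (see the test suite).

The default per-entry mutation probability is the standard
one-over-chromosome-length rule $1/(K + J(L-1))$: a fixed rate such as
0.05 makes the probability that an offspring keeps its labels intact decay
like $0.95^K$, which starves cut refinement for realistic K. An explicit
numeric `mutation_prob` is honored as given.

Runs stop after `max_generations` (default 500) or when the global elite
has not improved by a relative $10^{-10}$ for `stall_generations` (default
100) generations. All randomness is driven by R's RNG; `run_ga(seed =)`
and `fit_grid(seed =)` give bitwise-reproducible results, with per-cell
seeds derived deterministically from the master seed so grid cells are
order-independent.

## Simulated populations

`simulate_fbam_model()` generates three-group populations with known
structure, used throughout the tests:

* **Model "1"** — piecewise-smooth spectra with three plateaus per group
  (group boundaries (0.1, 0.25), (0.2, 0.3), (0.25, 0.4); mean levels
  15/7.5/2, 25/12.5/4, 35/17.5/6), replicate levels jittered uniformly by
  ±2, and smoothstep (cubic, zero end-slope) transitions of half-width
  0.025 — so the value at a boundary is the mean of the adjacent plateaus.
  Series are produced by Gaussian spectral synthesis,
  $X_t = \sum_m \sqrt{2 g(\omega_m)/T}(A_m \cos 2\pi\omega_m t +
  B_m \sin 2\pi\omega_m t)$, whose expected periodogram is the target
  spectrum; the test suite verifies band-averaged multitaper estimates
  recover the plateau levels within 10%.
* **Models "2a"/"2b"/"2c"** — AR(2) processes parameterized by spectral
  peak location $\psi$ and bandwidth $\ell$ via
  $\phi_1 = 2\cos(2\pi\psi)e^{-\ell}$, $\phi_2 = -e^{-2\ell}$, innovation
  SD 2.25; group peak centers (0.23, 0.25, 0.27), (0.21, 0.25, 0.29),
  (0.19, 0.25, 0.31) with per-replicate jitter ±0.02 — three degrees of
  separability.
* **Model "3"** — sums of two independent AR(2) components: a broad
  low-frequency component ($\psi = 0$, $\ell \sim U[0.48, 0.52]$, SD 2.5)
  common to all groups, plus a group-specific mid-frequency peak (centers
  0.2/0.26/0.32 ± 0.015, bandwidths 0.05/0.065/0.095, SD 2).

AR(2) series use Gaussian innovations with a 500-sample burn-in (the
slowest transient in these settings decays well within it). What the
generators do *not* emulate: nonstationarity, trends, missing samples,
non-Gaussian innovations, long-range dependence, and unequal series
lengths — so passing tests demonstrate correct behavior under the stated
stationary Gaussian conditions, not robustness to real-data artifacts.

## Numerical choices

* Minimum band width `w_min = 5` Fourier frequencies (configurable):
  similarity ratios and collapsed means are degenerate on near-empty
  bands.
* The $1/T$ prefactor of the objective is kept exactly, so reported losses
  are comparable across series lengths.
* Cut positions are half-open, left-closed integer indices; the boundary
  frequency reported for cut c is the midpoint $(c - 0.5)/T$ between the
  last index of one band and the first of the next.
* Boundary evaluation against ground truth (`match_boundaries()`) matches
  estimated to true groups by exact assignment (permutation enumeration,
  J ≤ 6) minimizing total absolute boundary discrepancy.
* The exhaustive-search oracle, the dynamic-programming segmentation and
  the cumulative-sum loss identity used in the genetic algorithm are all
  checked in the test suite against naive elementwise loops at
  $10^{-10}$ tolerance.

## Problem sizes in the test suite

The packaged simulation experiments are scaled-down twins of a full study:
10 replications per setting, K_j ∈ {20, 30} replicates per group,
T ∈ {500, 1000}, grids {2..4} × {2..4} (extended to L = 5 for model "3"),
and a reduced search budget (2 islands, at most 200 generations per cell).
These sizes keep the default `R CMD check`-style run to a few minutes while
leaving the qualitative conclusions unchanged; the full-size design (100
replications, 6 islands, grids to 6) is available by changing the
corresponding arguments.

## Known limitations

* All subpopulations share one L (a deliberate modeling assumption);
  allowing unequal band counts would need a variable-length chromosome.
* The method summarizes spectra through their piecewise-constant
  approximations; subpopulations that differ only in features invisible to
  band averages (e.g., equal-power peaks at slightly different locations
  within one band) are hard to separate.
* The band-similarity criterion does not penalize subdividing smooth
  spectral slopes (see above), so the selected L can exceed the "visual"
  band count when the grid allows it.
* Series must be equal-length and complete; preprocessing (outlier
  handling, interpolation, filtering) is the caller's responsibility.
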