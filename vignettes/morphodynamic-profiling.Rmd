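---
title: "Spectral profiling of cellular morphodynamics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral profiling of cellular morphodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphospec)
```

`morphospec` turns a segmented time-lapse movie of a single cell into a
spatiotemporal description of its edge dynamics: a protrusion activity
map, instantaneous frequency/amplitude spectra of that map, a partition
of the map into motion regimens, and lagged correlations between motion
and a windowed biosensor signal. This vignette documents the models
behind each stage, the tunable parameters with their units and
defaults, the numerical conventions adopted where the mathematics
leaves freedom, and what the synthetic test bed does and does not
establish about real data.

## 1. Segmentation

A frame is prefiltered with a Gaussian approximation of the microscope
point spread function (`psf_sigma`, pixels, default 1.5 — roughly the
PSF of a 40x/1.25 NA objective at ~0.3 µm pixels). The threshold is the
first valley of a smoothing spline fitted to the intensity histogram
after the lowest-intensity (background) mode. Two numerical choices
matter here:

* the spline is fitted to *log* counts. A sharp background peak
  otherwise makes the spline ring through the empty inter-mode valley,
  creating spurious extrema;
* when the valley is an extended flat stretch (well-separated modes,
  the common case for cultured cells on dark background), "the first
  local minimum" is numerically ill-defined, so the centre of the
  minimal stretch between the background mode and the strongest
  remaining mode is used. For genuinely overlapping modes this reduces
  to the usual valley minimum.

If the smoothed histogram is unimodal the function refuses to guess and
asks for `threshold_override`. Post-processing fills intracellular
holes up to `max_hole_area` (default 100 px²; the cutoff for "small"
holes is not canonical and is exposed), closes gaps with a disc of
`closure_radius` (default 3 px), and keeps the largest 4-connected
component. Foreground components use 4-connectivity and background
holes 8-connectivity — the standard dual convention, stated because it
changes which diagonal-pixel configurations count as holes.

## 2. Contours and edge tracking

### Sub-pixel contours

The boundary pixels of the mask are traced in order (one contour node
per boundary pixel) and refined to sub-pixel positions by five
iterations of Taubin smoothing (lambda = 0.5, mu = −0.53). Taubin
smoothing is the shrinkage-free variant of Laplacian polygon smoothing:
it removes the ±0.5 px staircase of the pixel trace, which would
otherwise corrupt normals and strain terms, without the systematic
radius loss of a moving average. On phantoms this convention lands
within 2% of analytic arclengths both for a digital disk and for a
filled square; a plain moving average fails the square (corner
shrinkage) and the raw trace fails the disk (staircase inflation).
A periodic cubic spline through the smoothed nodes provides positions
at arbitrary arclength parameters.

### Marker mapping

Virtual markers x(t, p_i) on the earlier contour are mapped to
parameters o_i on the later contour by minimizing, per segment between
contour crossings,

    SUMA + omega * SUMB,
    SUMA = sum_i ||x(t+1, o_i) - x(t, p_i)||^2,
    SUMB = sum_i [(o_i - o_{i-1}) / (p_i - p_{i-1})]^2,

subject to e1 = o1 < o2 < ... < on = en, i.e. displacement vectors never
cross. Because each term couples only adjacent markers, the discretized
problem (a grid of `grid_density` candidate parameters per source node,
default 4) is a chain and is solved *exactly* by dynamic programming —
deterministic and verifiable against exhaustive enumeration, which the
test suite does on hundreds of random instances. Conventions:

* `omega = w * SUMA/SUMB` is evaluated once, at the closest-point
  correspondence of each source node onto the target (the natural
  "iteration 1"); one DP solve follows. The balance factor changes
  little under re-iteration, so a single solve is the default
  (`w` default 1; 0 = displacement only, large = spacing-preserving).
* Segments longer than `nmax` markers (default 50, valid range
  10–100) are down-sampled to `nmax`, solved, and up-sampled by
  monotone (Hyman) interpolation of o(p), which cannot violate the
  ordering constraint.
* Contour pairs without crossings (e.g. a cell that only grew), or with
  geometrically inconsistent crossing patterns, are treated as one
  periodic segment anchored at the target point closest to the first
  source marker. Identical contours reduce to this case and return the
  identity mapping.
* The outward normal is the rotated tangent, oriented by probing the
  mask on both sides of each node; velocities are displacement
  projections on it, scaled to µm/min (protrusion positive). Markers
  are reset at every frame pair; no multi-frame marker paths are
  constructed.

## 3. Sampling windows

Windows attach to the edge through the Euclidean distance transform D
of the mask. The discrete method bins every interior pixel by its
distance d_i to the nearest boundary pixel (bands `b_edges`, µm) and by
the arclength l_i from the window origin to that boundary pixel
(slices, default width ~3 µm to match the spatial autocorrelation of
edge motion; band depth default 3 µm). Windows of one band partition
the band's pixels exactly; the origin pixel (l = 0) is assigned to
slice 1 so nothing is dropped. The discrete method supports no master
contour other than the edge, because the nearest-boundary index field
inward from the edge does not cover all boundary pixels.

The sub-pixel method extracts isocontours of D at the band values
(marching squares with linear interpolation; the mask outline
corresponds to level 0.5 px, so physical band values are offset by half
a pixel), places slice start positions along a master contour, and
grows slice curves by gradient ascent of D with a fixed 0.5 px step
along the normalized bilinearly interpolated gradient (stall tolerance
1e-3). The raw-gradient step of the continuous formulation has unit
magnitude near the edge but degrades near ridges; the normalized fixed
step is unconditionally stable and terminates when the ascent crosses
the outermost band value. Windows are polygons bounded by two
isocontours and two slice curves; windows whose ascent stalls on a
distance-transform ridge or whose polygon approaches the image border
are excluded and flagged. On a disk phantom the polygon areas tile the
band area to well under 1%.

Propagation across frames always rebuilds the bands on the new mask
(bands keep their distance to the edge); the default
`constant_slice_count` method keeps the number of slices fixed and lets
their widths rescale with edge length, which is the configuration used
for regimen-level signaling analyses. Origin-anchored and
vector-following variants are provided.

Velocity maps have one column per frame *pair* (N_t − 1), biosensor
maps one per frame (N_t); regimen analyses align activity column t with
the velocity column for the displacement t → t+1. This convention is
stated because nothing in the mathematics forces it.

## 4. Hilbert–Huang spectra

Each map row (velocity time series of one sector) is decomposed by
empirical mode decomposition: cubic-spline envelopes through local
maxima/minima, envelope-mean subtraction, repeated until the candidate
satisfies the IMF conditions (extrema and zero-crossing counts differ
by at most one) *and* a Cauchy-type criterion
SD = Σ(h_{k−1} − h_k)² / Σh_{k−1}² < 0.2 (max 100 sifts). End effects
are controlled by mirroring the two nearest extrema about each series
end — the dominant convention, and the one a fully independent
reference implementation in the test suite uses. The number of IMFs is
fixed at six per axis so decompositions are comparable across cells and
conditions; series that exhaust earlier pad with zero components,
flagged. Completeness (Σ IMFs + residual = input to machine precision)
is enforced by construction and asserted to 1e-9 in the tests.

The Hilbert transform (FFT analytic signal) gives the instantaneous
frequency as the unwrapped-phase derivative over 2π (central
differences; the first and last samples are marked invalid) and the
instantaneous amplitude as the analytic-signal modulus. Negative
instantaneous frequencies can arise at weak-amplitude samples; they are
retained in the stored fields but excluded from distribution summaries
by default (`drop_negative`).

Columns (spatial axis) are decomposed the same way with two extra
conventions: the sector axis is circular, so each column is tiled three
times and the centre third kept (`spatial_boundary = "periodic"`,
with `"open"` available since the right choice depends on whether the
windows close around the cell), and spatial frequencies are reported in
cycles/sector (convertible via the sector width, whose physical value
is a windowing choice rather than a property of the decomposition).

## 5. Feature field and region merging

Each grid cell carries 12 amplitude-weighted instantaneous frequencies:
six temporal and six spatial, each weighted by A²/A²_max, the
instantaneous relative energy of that IMF order. Two normalizer
conventions deserve attention:

* *Scope.* The normalizer is written without an IMF index: it is the
  maximum over all six orders for the sector (temporal channels) or
  time point (spatial channels). This is also the scientifically
  sensible reading: per-order normalization re-inflates noise-dominated
  orders to weight ~1, destroying the energy bookkeeping the weights
  exist for. A per-order variant is kept (`amax_scope = "per_imf"`).
* *Robustness.* The literal maximum of an instantaneous amplitude
  series is an extreme-value statistic; across sectors its sampling
  jitter multiplies every weight of the sector and becomes the dominant
  feature noise. The default normalizer is therefore the 95th
  percentile of the amplitude, with weights clipped to [0, 1]
  (`amax_quantile = 1` restores the literal maximum).

Statistical region merging runs on the 4-connected sector-time grid
(circular along sectors, open along time). Edges are visited in
ascending order of the maximum per-channel absolute difference (ties
broken by grid position, so the partition is deterministic), and two
regions merge while every channel's mean difference is within
sqrt(T²(R1) + T²(R2)), with

    T(R)^2 = R_max^2 * 2^-(Q+1) / |R| * ln((|R|+1)^min(|R|, R_max) * 6 N_t N_s)

on features linearly rescaled per channel to [0, R_max = 256]. The
bound follows the standard concentration-inequality structure of SRM
thresholds; `R_max` plays the double role of feature range and region
size cap, which keeps the formula dimensionally coherent. The merging
delicacy Q (default 3) halves T² per unit; `q_scan()` reports region
counts and the explained-variance fraction over a Q range together with
a knee estimate (the smallest Q after the largest explained-variance
jump whose marginal gain falls below 5% of the curve's rise).

`srm_cluster()` accepts a `channels` subset. This mirrors the practice
of clustering on reduced feature vectors (frequency-only,
amplitude-only, single-IMF) and matters for validation: in the planted
two-block recovery fixture the blocks differ only in temporal
frequency, so the six spatial channels carry, by construction, no block
information — only per-column-normalized noise, which at columns where
both planted tones vanish simultaneously becomes column-wide outliers
that partition the time axis at any Q. Recovery is therefore assessed
on the temporal channels; the Q-monotonicity and variance diagnostics
run on the full 12-channel field. On real cells the spatial channels
carry genuine boundary-undulation structure and the full vector is the
default.

Missing feature entries (invalid boundary samples, degenerate
decompositions) are imputed by the per-sector median across time
(temporal channels) or per-time-point median across sectors (spatial
channels) and flagged.

## 6. Profiling, robustness, coupling

Distribution comparisons use the two-sample Kolmogorov–Smirnov
statistic (`stats::ks.test`, asymptotic p; the implementation is
checked exhaustively against a brute-force CDF sweep on small
multisets). Central frequencies are per-sector medians (robust to the
heavy spectral tails) summarized as mean ± SE across sectors.
Population heatmaps order cells either as given or by ascending mean
absolute velocity, the ordering that exposes amplitude-driven
structure. Analyses always use raw samples; histogram binning
(Freedman–Diaconis) is for display only.

The mapping-error simulation perturbs a map by uniform noise on
[−rate·Δ, +rate·Δ]. Δ defaults to the per-sector RMS inter-frame
velocity step — a proxy for the length difference of a displacement
vector that targets a neighboring virtual marker, which bounds the
worst-case mapping error under the non-crossing constraint — and is
pluggable (`scale_fun`) because the error-scale definition is a
modeling choice.

Cross-correlation is Pearson at integer-frame lags on mean-subtracted,
pairwise-complete series, with no prewhitening beyond mean subtraction
(per-sector standardization is implicit in per-sector Pearson; the
estimator is exposed rather than hidden). Two lag conventions coexist
deliberately: `xcorr()` is motion-centric (a peak at +k s means the
activity follows the motion by k s), while `regimen_xcorr()` reports on
the negated axis used in activity-vs-motion figures, where a positive
lobe at a *negative* lag means the activity is delayed relative to
protrusion. The ±1.96/√n bounds are per-lag white-noise heuristics
without autocorrelation correction and are labeled as such; FWHM of the
dominant significant lobe is measured on the sector-averaged curve by
linear interpolation. Regimen time windows are maximal runs of at least
20 frames carrying the label; shorter runs are skipped.

## 7. The synthetic test bed

`gen_blob_movie()` renders a star-convex cell whose boundary radius is
R₀ + Σ aₖ wₖ(θ) sin(2π fₖ t + φₖ) with raised-cosine angular tapers
(so analytic normal velocities exist and are continuous), constant
foreground/background intensities, and i.i.d. Gaussian pixel noise.
Star-convexity is what makes exact ground truth possible; it is also
the generator's main idealization. `gen_coupled_activity()` adds an
activity channel equal to baseline + gain · v(θ, t − lag) within a
band of fixed depth from the edge. `gen_planted_map()` builds
sector-time maps from sinusoidal blocks plus noise. All generators are
seed-reproducible bit for bit.

Default study conditions, chosen once: 10 s frame interval and ~0.3 µm
pixels (typical epifluorescence acquisition for edge dynamics; the
biosensor channel in such experiments is often sampled at 5 s), planted
frequencies in the 0.002–0.02 Hz band where protrusion-retraction
cycles live, mode amplitudes ~1–2 µm on a ~9–12 µm cell, and for the
region-merging fixture 64 sectors × 180 frames (a 30-min movie) with
amplitude 2 µm/min and noise SD 0.4 µm/min (SNR 5). The
robustness-simulation map uses noise SD 0.05 µm/min ≈ 4% of its
velocity step scale, matching the intrinsic mapping-error level
estimated for real movies, so that the smallest perturbation rates
(1%, 3%) act on a map whose own noise floor does not drown them.
Coupling fixtures use lags at a quarter of the dominant period or
broadband (filtered-noise) series: with a pure tone, a lag of half a
period is indistinguishable from a sign flip, so period-commensurate
lags are avoided in ground-truth constructions.

What passing these tests shows: the geometry, decomposition,
statistics, and clustering do what their definitions promise, at
realistic noise levels, with exact oracles wherever one exists
(enumeration for the DP, CDF sweep for K-S, analytic phantoms for
contours, windows and spectra, an independent reference sifting
implementation for EMD). What they do not show: performance on real
cells with textured interiors, uneven illumination, segmentation
ambiguity, non-star-convex shapes (retraction fibers, concave lobes),
or spatially correlated imaging noise — none of which the generator
models.

## 8. Known limitations

* Single cells only; masks must be one connected component.
* The DP mapper is exact for its discretization; very coarse
  `grid_density` with many markers can make strict monotonicity
  infeasible (it errors rather than degrades).
* EMD mode allocation near band boundaries is convention-sensitive;
  comparisons across datasets should use identical sift settings.
* The SRM threshold's early-stage bounds exceed the feature range for
  singleton regions, so very-low-Q partitions are order-driven; this is
  inherent to the threshold family, not to this implementation.
* Significance bounds on correlation curves ignore autocorrelation;
  treat them as visual guides, not tests.
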