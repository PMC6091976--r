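# morphospec

Spectral profiling of cellular morphodynamics in R.

Migrating cells protrude and retract their edges in nonstationary
cycles. `morphospec` quantifies this behavior from segmented
fluorescence time-lapse movies: it tracks the cell outline frame to
frame, compiles signed normal edge velocities into a **protrusion
activity map** (rows = ~3 µm boundary sectors, columns = time), and
decomposes that map into **instantaneous frequency and amplitude
spectra** with the Hilbert–Huang transform (HHT). The spectra profile
and compare cells, partition the map into **motion regimens** by
statistical region merging (SRM), and relate those regimens to windowed
biosensor activity via lagged cross-correlation. It is aimed at
quantitative cell biologists and image-analysis methodologists working
on cell migration and peripheral signaling.

## The method in brief

**Edge tracking.** Sub-pixel cell outlines are extracted per frame and
virtual markers `x(t, p_i)` are mapped onto the next outline by
minimizing, per boundary segment between contour crossings,

```
SUMA + ω·SUMB  =  Σ‖x(t+1, o_i) − x(t, p_i)‖²  +  ω·Σ[(o_i − o_{i−1})/(p_i − p_{i−1})]²
```

subject to `e₁ = o₁ < o₂ < … < o_n = e_n` (displacement vectors must not
cross). The unit-balancing factor `ω = w·SUMA/SUMB` is fixed at a
closest-point initialization; the discrete problem is solved exactly by
dynamic programming. Projections of the displacements on the outward
normal give signed velocities (protrusion positive, µm/min).

**Spectral decomposition.** Each map row (and, circularly, each column)
is sifted into six intrinsic mode functions `c_i` with residual `r`,
`X(t) = Σ c_i(t) + r(t)`; the Hilbert transform of each IMF yields the
instantaneous frequency `F(t) = (1/2π)·d/dt arctan(H[c]/c)` and
amplitude `A(t) = √(c² + H[c]²)`.

**Profiling and clustering.** Pooled per-IMF frequency/amplitude
distributions are compared with two-sample Kolmogorov–Smirnov
statistics. Per grid cell, a 12-dimensional feature vector of
amplitude-weighted instantaneous frequencies
`φ = [F_{i,t}·A_{i,t}²/A²_max,t, F_{i,s}·A_{i,s}²/A²_max,s]` feeds an SRM
clustering whose merging threshold shrinks with region size and the
delicacy parameter Q. Per-regimen biosensor activity and
motion–activity cross-correlation (with lag and FWHM of the dominant
lobe) complete the analysis.

A synthetic-data module generates deforming-blob movies, coupled
activity channels, and planted sector–time maps with analytic ground
truth, so the whole chain is testable without external data.

## Worked example

```r
library(morphospec)

# a deforming blob with two planted oscillation modes + analytic truth
spec <- blob_movie_spec(
  image_size = 96, n_frames = 90, dt = 10, pixel_size = 0.3,
  base_radius = 9, noise_sd = 0.02, seed = 3,
  modes = list(
    list(freq = 0.005, amp = 1.2, phase = 0, window = NULL),
    list(freq = 0.002, amp = 0.8, phase = 1, window = c(0, pi))
  )
)
movie <- gen_blob_movie(spec, n_sectors = 24)

masks <- segment_movie(movie$images)        # histogram-valley threshold
track <- track_movie(masks, dt = 10, pixel_size = 0.3)
vmap  <- sector_velocity_map(track, 24, dt = 10)
vmap
#> <activity_map> 24 sectors x 89 time points, dt = 10s, units = um/min
#>   value range: [-3.2, 3.09], 0 missing

cor(as.vector(vmap), as.vector(movie$velocity), use = "complete.obs")
#> [1] 0.9941252

field <- decompose_map(vmap)                # 6 temporal + 6 spatial IMFs
central_frequency_curve(field)
#> # A tibble: 6 x 4
#>     imf central_frequency        se n_sectors
#>   <int>             <dbl>     <dbl>     <int>
#> 1     1           0.0188   0.00258         24
#> 2     2           0.00479  0.0000271       24
#> 3     3           0.00186  0.000193         3
#> ...
```

The tracked velocities correlate with the analytic ground truth at
r = 0.994. IMF1 holds the frame-to-frame tracking jitter (~0.02 Hz,
near the Nyquist band); IMF2 recovers the planted global mode
(0.0048 vs 0.005 Hz) and IMF3 the slower windowed mode (0.0019 vs
0.002 Hz, present only in the sectors its angular window covers). From
the same field, `feature_field()` + `srm_cluster()` label motion
regimens, and `regimen_xcorr()` recovers a planted 50 s activity delay
as a cross-correlation extremum at −50 s.

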