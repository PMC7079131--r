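---
title: "Models and methods behind navclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind navclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navclust)
```

navclust quantifies the supramolecular organization of the cardiac
voltage-gated sodium channel (Nav1.5) and the gating consequences of its
auxiliary β3-subunit through three independent analysis chains:
whole-cell voltage-clamp kinetics, single-molecule localization
(STORM-type) cluster statistics, and 3D proximity-ligation-assay (PLA)
image quantification.  Because each chain normally consumes recordings
and images that cannot be redistributed, the package pairs every analysis
stage with a seeded synthetic-data generator carrying full ground truth,
and validates the stages as parameter-recovery experiments.

## 1. Electrophysiology

### Model

Sodium conductance is obtained from current by the chord relation
$G_\mathrm{Na} = I_\mathrm{Na} / (V - E_\mathrm{Na})$, and steady-state
gating follows the two-parameter Boltzmann curve

$$\frac{G}{G_\max} = \frac{1}{1 + \exp[(V - V_{1/2})/k]},$$

stored internally with $k > 0$ and an explicit activation/inactivation
*sense* flag.  Published tables are inconsistent about the sign of the
inactivation slope factor; the sense flag removes that ambiguity from all
downstream code, and `charge_from_slope()` converts $k$ into an effective
gating charge via $k = RT/zF$.

The conductance time course after a voltage step follows the
Hodgkin–Huxley $m^3h$ solution

$$G_\mathrm{Na}(t) = \bar G_\mathrm{Na}
  \left[m_\infty - (m_\infty - m_0)e^{-t/\tau_m}\right]^3
  \left[h_\infty - (h_\infty - h_0)e^{-t/\tau_h}\right] + \text{offset},$$

where the activation endpoints are cube roots of the activation
Boltzmann values at the voltages before and after the step, the
inactivation endpoints are the inactivation Boltzmann values at the same
voltages, and the offset absorbs the finite background membrane
conductance.  The offset is treated as a conductance summand, matching
the units of the equation it appears in.  Recovery from inactivation is
mono-exponential, $I_{P2}/I_{P1} = 1 - e^{-t/\tau}$, with
$t_{1/2} = \tau \ln 2$ exactly; current decay is modelled as a sum of a
fast and a slow exponential.

### Protocols and generator

The generators reproduce the standard clamp protocols: activation
(holding −120 mV, 50-ms test pulses −90…+35 mV in 5-mV steps, 26
sweeps), steady-state inactivation (100-ms conditioning pre-pulses
−140…−50 mV, 19 sweeps, test pulse −40 mV), and two-pulse recovery
(24 intervals, 3…72 ms in 3-ms steps).  Sampling defaults to 125 kHz
(`dt_ms = 0.008`), the acquisition rate of the protocols being emulated.

Two design choices deserve comment:

* **Time-constant curves.**  No parametric $\tau(V)$ form is tabulated
  for this channel, so the generator defaults are bell-shaped curves —
  $\tau_m$ peaking near the activation midpoint (0.15–0.5 ms) and
  $\tau_h$ peaking near the inactivation midpoint (0.5–5 ms) — the
  qualitative shape and magnitude typical of fast cardiac sodium
  current.
* **Amplitude conventions.**  A genuinely simultaneous $m^3h$ transient
  cannot make the *peak* conductance equal the steady-state activation
  curve: inactivation always erodes part of the rising phase.  The
  generator therefore offers two conventions.  The default,
  `amplitude = "steady_state"`, pins each sweep's peak conductance to
  $\bar G\,\mathrm{act}(V)\,h_0$ while keeping the $m^3h$ shape, so the
  steady-state analysis (peaks → reversal → Boltzmann) inverts the
  generator exactly in the noise-free limit.  `amplitude = "hh"` renders
  the raw $m^3h$ model and is the right input for exercising the
  time-constant fits, which hold the endpoints and $\bar G$ fixed and
  free only $\tau_m$, $\tau_h$ and the offset.  Validating each stage
  against the convention it analyzes keeps both recoveries exact without
  biasing either.

### Fitting choices

All nonlinear fits use `nls` with the bounded trust-region `"port"`
algorithm.  Initial midpoints come from the interpolated half-maximum
crossing, the slope starts at 8 mV with bounds (0.5, 30) mV, and time
constants are bounded to (0.05, 100) ms with tail log-linear regression
supplying the inactivation guess; the $m^3h$ fit retries from a short
ladder of initial values and keeps the lowest-residual solution.  The
peak search excludes the first 0.3 ms after a step (residual capacitive
transient) and, by default, applies a 0.12-ms running mean before taking
the extremum — the bandwidth of a 5-kHz acquisition filter — because the
extreme-value statistics of broadband sample noise would otherwise bias
peak currents (and hence $G_{\max}$) upward.  Setting `smooth_ms = 0`
recovers raw sample extrema.  Conductance is never evaluated within
2.5 mV of the fitted reversal potential (singular driving force).
Activation families are normalized per cell to their own maximum; pooled
normalization is not used.

Both correction magnitudes that appear in condition comparisons (the
5.5-mV inactivation shift used for time-constant overlays and the −5-mV
shift used for decay-constant overlays) are plain arguments to
`apply_voltage_shift()` rather than baked-in constants, since the two
published uses differ.

The Nernst slope is exposed as a parameter (default 58 mV/decade) rather
than computed from $RT/F$ at an assumed temperature: the conventional
room-temperature slope reproduces the printed prediction (17.46 mV for a
70/35 mM sodium gradient) exactly, while $RT/F$ at 22–23 °C does not.

## 2. Localization microscopy

### Generator

`simulate_localization_pattern()` draws cluster centers uniformly in the
field, places member molecules either as isotropic Gaussian scatter
(radius = per-axis SD) or on regular polygons with exact nearest-neighbor
spacing (`cluster_geometry = "spaced"`, used for dimer/tetramer
geometries), and adds uniform background monomers so a requested
clustered fraction holds.  Each molecule emits `1 + Geometric` blinks
(default mean 3 — single-fluorophore overcounting is real but
unparameterized in the source data, so a modest geometric default is
used) displaced by the localization error (default SD 10 nm).  Defaults
emulate a 5 × 5 µm membrane field with 40 % of molecules in ~8-nm
clusters.  `simulate_blinking_movie()` renders molecules as Poisson-noise
2D Gaussian spots on a 100-nm camera grid (the camera's pixel pitch is
not published; 100 nm is typical for EMCCD super-resolution hardware)
with optional cumulative linear drift.

### Analysis

`localize_frames()` estimates per-frame background by median/MAD (the
"peak intensity to noise" ratio is defined against this robust SD, since
the original processing chain does not define its noise estimator), takes
3 × 3 local maxima at ≥ 6 × noise as candidates, cuts 9-pixel windows,
discards every window containing more than one candidate (multi-emitter
rejection), and fits a 2D Gaussian for sub-pixel positions.
`drift_correct()` reconstructs temporal-bin histograms and aligns them to
the first bin by Fourier cross-correlation with sub-pixel quadratic peak
interpolation.

`detect_clusters()` substitutes a density-reachability (DBSCAN)
clusterer — defaults `eps = 20` nm, `min_pts = 3` — for the external
Bayesian cluster engine used in the original analysis, which is not
specified by the source and is treated as a pluggable interface; the
reported per-cluster outputs (radius and occupancy) are the same.  The
cluster radius is the RMS member-to-centroid distance, a stable statistic
on the 5–15 nm scale of dimer/oligomer geometries.  Nearest-neighbor
distances use an exact grid-indexed search (verified against the
brute-force pairwise scan) computed over the full field before any ROI
restriction, so a point near an ROI edge may legitimately find its
neighbor outside the ROI.  Histogram conventions: 2-nm bins for
nearest-neighbor distances, 5-nm bins for radii, densities normalized to
unit area; modal values are refined within the peak bin by parabolic
interpolation.

The two-sample Kolmogorov–Smirnov statistic is computed exactly from the
merged empirical CDFs, with the asymptotic p-value from the Kolmogorov
distribution at effective size $n_a n_b/(n_a + n_b)$ and an optional
permutation p-value.  Percent-clustered is computed over blinks (not
molecules), matching how the quantity is reported for blinking data.

## 3. PLA quantification

`segment_channel()` applies a separable 3D Gaussian blur (sigmas in
voxel units: 0.5 for DAPI, 0.25 for GFP) and the triangle threshold —
the bin of maximal perpendicular distance from the chord joining the
histogram peak to the far end of its longer tail.  For count-valued data
whose range is narrower than 256 the histogram uses unit-width integer
bins (the 8-bit convention); fractional bins would interleave empty bins
and corrupt the chord geometry.  Because thresholded Poisson noise still
leaves isolated speckle voxels, masks are cleaned by removing connected
components below 200 voxels before cell labelling — far below any
nucleus or cytoplasm volume at the default geometry.

`detect_pla_dots()` flags voxels equal to their 3 × 3 × 1 in-plane
maximum filter (the zero set of the original-minus-max-filter difference)
and keeps those whose prominence over the local surround — value minus
the median of a 9 × 9 × 3 neighborhood excluding the 3 × 3 in-plane
core — reaches the noise tolerance (default 15, interpreted on the
8-bit intensity scale; the tolerance is applied to the original image at
difference-flagged voxels).  Signed distances to the nuclear mask are
exact Euclidean distances to the nearest voxel across the mask boundary,
negative inside the nucleus, with voxel anisotropy respected; the
implementation searches only boundary voxels, which provably contain the
minimizer, and is tested for exact agreement with a whole-volume scan.
Cells are connected components of the GFP mask (touching cells are not
split — the counting is volume-based, so no watershed is attempted), and
dot intensity is the background-subtracted sum over a 3-voxel-radius
in-plane sphere.

The stack generator places non-overlapping ellipsoidal nuclei with
cytoplasmic shells (4-voxel placement margin so thresholded masks cannot
bridge adjacent cells), renders puncta as 3D Gaussians (amplitude 100
over a mean background of 2 counts), and places 70 % of puncta within
2 voxels of the cell boundary to emulate plasma-membrane-predominant
signal.  The near-dark background emulates offset-subtracted confocal
acquisition and keeps the Poisson noise floor below both the triangle
threshold and the maxima tolerance; at substantially higher background
the fixed tolerance of 15 would sit inside the Poisson tail and any
detector honouring it would report noise maxima as dots.

## 4. What the synthetic tests do and do not show

The generators reproduce the *geometry* of the study conditions — the
voltage protocols and published gating parameters, clustered point
patterns at the reported 40 % clustered fraction and 6/12-nm spacings,
and membrane-weighted puncta at the reported channel counts — with
idealized noise (Gaussian current noise, Poisson shot noise, isotropic
localization error).  They do not model series-resistance artefacts,
fluorophore photophysics beyond on/off blinking, optical aberrations,
chromatic misregistration, or realistic cardiomyocyte geometry.  Passing
recovery tests therefore demonstrates that the analysis stages are
correct and unbiased under the stated models, not that they are robust
to every artefact of real recordings.

Problem sizes were chosen so the whole validation suite runs on a
laptop-scale machine: 100 replicates for Boltzmann and time-constant
recovery, ~10⁴ localizations per condition for the nearest-neighbor and
KS analyses, five 128 × 128 × 10 stacks of five cells for PLA recovery,
and 50 replicates of ten cells for the end-to-end gating pipeline.

## 5. Numerical details and degenerate inputs

* Fits that cannot span their transition (flat gating data) raise
  degenerate-fit errors; per-voltage time-constant fits that fail are
  flagged and skipped without aborting the family.
* The double-exponential fit relabels components so $\tau_1 < \tau_2$
  and reports an F-test against the nested single exponential.
* Sweeps at the reversal potential are excluded from conductance
  conversion (undefined driving force).
* All generators restore the caller's RNG state; a fixed seed gives
  bit-identical output, and the pipeline manifest records the seed so
  any run is reproducible from its manifest alone.
* `run_pipeline()` derives per-stage seeds from the global seed by fixed
  offsets so stages can be rerun independently without re-simulating
  upstream stages.
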