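# navclust

Cardiac voltage-gated sodium channels (Nav1.5) do not sit on the plasma
membrane as isolated molecules: super-resolution imaging shows them
assembling into nanoscale clusters, and the auxiliary β3-subunit
reshapes both the cluster geometry and several gating properties without
changing the clustered fraction itself.  Quantifying that picture takes
three very different measurements — whole-cell voltage-clamp kinetics,
single-molecule localization (STORM) statistics, and proximity-ligation
assay (PLA) image analysis — and `navclust` implements all three as one
tested R package, for electrophysiologists and imaging labs who want the
complete analysis chain plus simulators to validate it against known
ground truth.

## What it computes

**Electrophysiology.**  Peak currents and I/V relations, reversal
potential by zero-crossing interpolation, chord conductance
G = I/(V − E_Na), Boltzmann fits of steady-state activation and
inactivation G/G_max = 1/(1 + exp[(V − V½)/k]), gating endpoints by the
cube-root construction, Hodgkin–Huxley m³h time-constant fits

G(t) = Ḡ·[m∞ − (m∞ − m0)e^(−t/τm)]³·[h∞ − (h∞ − h0)e^(−t/τh)] + offset,

double-exponential decay of the inactivating current, mono-exponential
recovery from inactivation with t½ = τ·ln 2, effective gating charge
z = RT/(Fk), and the Nernst prediction for the sodium gradient.

**Localization microscopy.**  Frame-by-frame 2D Gaussian localization
with multi-emitter rejection, cross-correlation drift correction,
density-reachability (DBSCAN) cluster detection reporting per-cluster
radius and occupancy plus percent-clustered and cluster density,
exact first-nearest-neighbor distance distributions, and the two-sample
Kolmogorov–Smirnov comparison between conditions.

**PLA stacks.**  3D Gaussian blur + triangle-threshold segmentation of
the DAPI and GFP channels, punctum detection by in-plane maximum filter
with a prominence (noise-tolerance) criterion, exact signed Euclidean
distances to the nuclear mask, and per-GFP-positive-cell dot counts and
intensities.

Every stage has a seeded generator (`simulate_activation_family()`,
`simulate_localization_pattern()`, `simulate_blinking_movie()`,
`simulate_pla_stack()`, …) that emits the corresponding input with full
ground truth, so the package validates itself by parameter recovery.

## Worked example

Simulate one cell's three clamp families at published gating parameters
(20 pA noise), a clustered localization field, and a PLA stack, then run
the corresponding analyses:

```r
library(navclust)

cfg <- ephys_sim_config(noise_sd = 20, seed = 42)
analyze_ephys_cell(simulate_activation_family(cfg),
                   simulate_inactivation_family(cfg),
                   simulate_recovery_family(cfg, tau_rec = 7.64))
#> Gating analysis
#>   activation:   vhalf -42.48 mV, k 7.43 mV (z 3.42)
#>   inactivation: vhalf -96.11 mV, k 7.24 mV (z 3.51)
#>   e_na 19.57 mV, gmax 72.81 nS, peak density 253.3 pA/pF
#>   recovery: tau 7.56 ms, t_half 5.24 ms

tab <- simulate_localization_pattern(loc_sim_config(
  n_clusters = 50, molecules_per_cluster = list(mean = 10, dispersion = 1),
  clustered_fraction = 0.4, loc_error_sd = 5,
  blinks_per_molecule = list(mean = 1), seed = 1))
detect_clusters(tab, eps = 20, min_pts = 3)
#> cluster_set: 48 clusters from 1215 localizations (38.8% clustered)

quantify_pla_stack(simulate_pla_stack(pla_sim_config(seed = 7)))
#> pla_result: 40 dots in 5 cells (8.00 +/- 0.55 dots/cell)
```

The gating fit recovers the planted midpoints (−42.62 / −96.14 mV) and
recovery time constant (7.64 ms → t½ 5.27 ms expected) to within the
noise; the cluster summary returns the planted 40 % clustered fraction;
the PLA result matches the five simulated cells with eight puncta each.

A pipeline driver with reproducible manifests is available as
`run_pipeline("simulate-ephys" | "fit-ephys" | "simulate-storm" |
"analyze-storm" | "simulate-pla" | "quantify-pla", …)`, and
`inst/scripts/navclust` wraps it for shell use.

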