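# synloc

Quantification of protease localization at the CAR T-cell immune synapse
from multi-channel confocal z-stacks, for imaging groups measuring lysosomal
cargo (e.g. CTSB-mCherry) recruitment to the antigen contact site, plus the
plate-reader kinetics summaries and sample-size arithmetic that accompany
such studies.

## What it computes

Given a two-channel z-stack (structural/actin channel + reporter channel)
of one cell spread on an antigen-coated coverslip, with plane 1 at the
coverslip and plane spacing $d_z$:

* **Synapse plane** — after background subtraction, axial intensity
  gradients are estimated for every voxel of sufficient intensity. Below
  the cell these gradients are positive (the axial PSF tail makes intensity
  rise as the focal plane approaches the cell); the synapse is the first
  plane, scanning upward, at which gradients are no longer consistently
  positive (fraction of positive-gradient voxels $< \theta$, default 0.75).
* **Centre of fluorescence (COF)** — the intensity-weighted centroid of the
  masked reporter voxels,
  $\mathrm{COF} = \sum_i w_i \mathbf{x}_i / \sum_i w_i$, and its axial
  distance $|z_{\mathrm{COF}} - z_{\mathrm{syn}}|$ to the synapse plane (µm).
* **Axial dispersion** — $\sum_i w_i\,|z_i - z_{\mathrm{COF}}| / \sum_i w_i$
  (µm); low values mean tight axial packing near one plane.
* **Clustering coefficient** — the pair autocorrelation $g(r)$ of the
  reporter intensity in the synapse plane (FFT autocorrelation normalised by
  the squared mean masked intensity and by the mask autocorrelation for edge
  correction, zero lag excluded), averaged over radial bins up to
  $r_{\max}$ (0.25 or 0.5 µm) to give $g_{\mathrm{ave}}$; $g \equiv 1$
  under complete spatial randomness.

Plate-reader time courses (minutes × wells) are summarised as peak,
time-to-peak, trapezoidal AUC and percent-of-control, and study design uses

$$ n = \left\lceil \frac{(\sigma_1^2 + \sigma_2^2)(z_{1-\alpha/2} + z_{1-\beta})^2}{\Delta^2} \right\rceil . $$

A seeded synthetic-microscopy generator (`simulate_cell()`) produces
two-channel stacks with exact source-level ground truth, so the whole chain
is testable without any imaging data.

## Worked example

```r
library(synloc)

cfg <- sim_config()                       # 9 x 9 um field, dz = 0.3 um, interface on plane 4
sim <- simulate_cell(cfg, "synapse_enriched", list(f_syn = 0.9),
                     n_points = 300, seed = 42)
report <- analyze_cell(sim$stack, analysis_config(),
                       cell_id = "cell42", condition = "enriched")
report[, c("synapse_plane", "cof_z_um", "cof_distance_um",
           "axial_dispersion_um", "g_ave")]
#> synapse_plane            4.000
#> cof_z_um                 1.248
#> cof_distance_um          0.348
#> axial_dispersion_um      0.499
#> g_ave                    1.207
```

The detected plane (4) matches the simulated interface exactly. The COF
sits 0.35 µm above the synapse plane (source-level truth: 0.39 µm for this
seed) and the signal is tightly packed axially (dispersion 0.50 µm versus
1.125 µm expected for a uniformly filled 4.5 µm cell, i.e. $H/4$).
`g_ave` ≈ 1.2 reflects only vesicle-scale graininess; laterally clustered
fields score 3–5.

```r
group_size(delta = 25, sigma1 = 10, alpha = 0.05, power = 0.80)
#> [1] 3
#> attr(,"n_raw")
#> [1] 2.511642
```

The numbered scripts under `analysis/` run the full simulation studies
(cohort simulation, synapse recovery, localization contrast, clustering
discrimination, kinetics, group sizes) and write their tables under
`results/`.

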