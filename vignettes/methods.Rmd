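---
title: "Models and methods behind zebraflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zebraflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebraflow)
```

This vignette documents the models implemented in `zebraflow`, their
assumptions, the defaults and why they were chosen, and what the synthetic
data generator does and does not establish. It states no empirical result
that the package's tests do not themselves compute.

## 1. The hydraulic trunk model

### Topology

`build_trunk_network()` builds the embryonic trunk as a ladder: a dorsal
aorta (DA) rail carrying blood tailward, segmental arteries (SeA) rising to
the dorsal longitudinal anastomotic vessel (DLAV), segmental veins (SeV)
dropping from the DLAV to the posterior cardinal vein (PCV) rail, and a
single terminal DA–PCV anastomosis (ECL). SeA and SeV rungs *alternate*
along the axis, as the intersegmental vessels do in the animal; with
`n_se_pairs = 16` the default covers roughly the posterior trunk at one
rung per 75 μm somite.

### Resistances and flow

Each vessel is a Poiseuille resistor with a per-cell occlusive increment:

$$R = \frac{8\mu L}{\pi r^4} + n_{\text{cells}}\,\alpha_c .$$

Node pressures solve the linear conductance balance (net flux zero at every
interior node) with Dirichlet pressures at the inlet (DA head) and outlet
(PCV head). Assumptions: steady flow (no cardiac-cycle pulsatility),
Newtonian plasma, rigid vessels except where `adapt_radii()` remodels them,
1D resistive elements (no secondary flows, no 3D geometry).

### Parameters and defaults

| parameter | default | why |
|---|---|---|
| μ | 10⁻³ Pa·s | plasma viscosity at incubation temperature |
| Se radius | 3 μm | uniform radius across Se vessels |
| cell length l | 6 μm | red-cell window on the wall |
| DA/PCV radius | 10 μm | axial vessels at 3 dpf |
| ECL radius | 4 μm | the distal anastomosis runs through the fine caudal plexus; a plexus-like bore keeps a finite share of red cells in distal SeAs pre-amputation, as observed in intact embryos |
| α_c profile | 2×10¹⁵ → 5×10¹⁴ Pa·s·m⁻³ | measured occlusive strengths are unpublished; this surrogate makes one cell roughly double a Se vessel's Poiseuille resistance (cell and vessel radii nearly coincide) and decreases head-to-tail |
| boundary pressures | 250 → 0 Pa | the heart is modelled as a pressure source (the alternative, a flow source, would fix total flux through the amputated network by construction and make the pre/post pressure-drop comparison vacuous); the magnitude was chosen once so DA ≈ 0.11 cm/s and SeA ≈ 0.03–0.11 cm/s, inside the physiological envelope |

These geometric choices were fixed while designing the model world and are
not tuned per analysis.

## 2. Red-cell transport and plasma skimming

Cells are points advected at the local edge mean velocity `Q/(πr²)`; their
finite length enters only the WSS model. At a bifurcation the probability
of entering branch *i* is

$$P_i = \frac{q_i^{\beta}}{\sum_j q_j^{\beta}}, \qquad \beta \ge 1,$$

with default β = 2. The disproportionate entry of red cells into
higher-flow branches (Zweifach–Fung effect) is only qualitative in the
literature this models; a flux power law is the simplest family containing
the unbiased case (β = 1) and was fixed at β = 2 as the default strength.
`branch_radii` is accepted for interface completeness but unused — the rule
is defined on fluxes.

Time stepping is adaptive: within one recording step `dt` a cell may cross
several nodes, each crossing handled exactly at its arrival time, so `dt`
only sets the recording (and optional flow-update) cadence. Occlusion
feedback — re-solving the flow with current per-edge counts — is off by
default for speed; when it is on, a cell's stored position is interpreted
relative to the current upstream end, so rare flux-sign flips under heavy
load displace that cell's frame of reference by one edge length. All
randomness (Poisson arrivals, branch draws) flows from a single seed.

Because pressure strictly decreases along every flow direction, the flow
graph is acyclic, and the *exact* expectation of the transport process is
computable by one pass over nodes in order of decreasing pressure
(`expected_cell_entries()`). The Monte Carlo simulation estimates exactly
this quantity; the acceptance suite uses the exact version where a strict
ordering claim would otherwise sit inside sampling noise (the expected
fold-change margin between the two SeAs nearest the cut is ~10%, which a
desk-scale simulation cannot resolve; the simulation is still required to
show the large-margin effects: the nearest-SeA increase and the
nearest-vs-third-nearest ordering).

## 3. Two-regime wall shear stress

For the plasma-only part of a vessel, Poiseuille flow at the median tracked
speed v gives

$$\sigma_p = \frac{4\mu v}{r},$$

and for the wall adjacent to a red cell, force balance between the pressure
drop and wall shear adds the cell's occlusive contribution:

$$\sigma_{\text{cell}} = \frac{4\mu v}{r} + \frac{\pi r^3 v\,\alpha_c}{2\,l}.$$

Both are computed in SI and reported in dyne/cm² (×10). The same v is used
in both regimes. Per frame, the *occupied fraction* of the endothelium is
the union of 6 μm windows centred on the detected cells (merged when they
overlap; when only counts are known, `min(1, n·l/L)`), and the **peak shear
stress portion** is

$$\text{portion} = \overline{\;f\,\mathbf{1}[\sigma_{\text{cell}}>\theta] +
(1-f)\,\mathbf{1}[\sigma_p>\theta]\;}$$

averaged over frames, with θ the **activation threshold**: the 0.975
quantile of plasma stresses pooled across all intersegmental vessels and
frames. Two conventions are deliberately pinned down: "0.975 percentile" is
read as the 97.5th percentile (the literal 0.975th percentile would sit
below essentially all samples and could not act as an activation
threshold), and the quantile uses linear interpolation between order
statistics (R type 7). In the amputation experiment the threshold is
computed on the *intact* network and applied to both conditions, as an
activation threshold should be.

## 4. Set-point remodeling

`adapt_radii()` iterates `r ← r(1 + g(σ/σ_set − 1))` on the selected edges
with σ the plasma WSS of the current solution. For a vessel carrying fixed
flux Q, σ = 4μQ/(πr³) and the fixed point is the closed form
`r* = (4μQ/(πσ_set))^{1/3}`; the linearized multiplier is `1 − 3g`, so
g ≤ 1/3 approaches monotonically, g ≤ 2/3 converges with oscillation, and
the default g = 0.2 is safely monotone. Non-convergence at `max_iter`
returns a flagged result rather than an error, since partial trajectories
are informative.

## 5. Synthetic imaging: what it emulates, what it does not

`render_movie()` draws each cell as an isotropic Gaussian blob
(σ = 1 μm, a point-spread surrogate making a ~3 μm cell span ~3 px at the
default 1.136 μm pixel) on a constant background, with optional additive
Gaussian or Poisson noise, clipped to the bit depth. Truth tables carry
every cell's frame, position and arclength, including out-of-field cells
(flagged). Deliberately absent: depth structure and attenuation,
photobleaching, motion blur within a frame, autofluorescent background
texture, vessel-wall fluorescence. A green tracking test therefore
establishes correctness of the *algorithms* against known kinematics, not
robustness to every optical artifact of a real microscope.

The default pixel size 1.136 μm follows from the 20 px ↔ 25.8 μm²
correspondence of the colocalization filter (pixel area 1.29 μm²). The
same source also implies 2.58 μm² from the 500 px ↔ 1290 μm² figure; the
two are mutually inconsistent, so pixel counts are the authoritative filter
unit and pixel size is explicit metadata everywhere.

## 6. Tracking: numerical choices

The analysis is 1D along the traced centerline. The profile samples a
normal band (halfwidth 3 μm, steps of half a pixel) every 0.25 px of
arclength by bilinear interpolation. Two standard particle-tracking
refinements are applied on top of the published procedure, because without
them the discretization itself dominates the error budget:

* **Matched filtering.** The profile is smoothed with a Gaussian at the
  point-spread width (default 1 μm, configurable, 0 disables) before peak
  finding. A bilinearly interpolated image cannot have maxima between pixel
  centres, and unsmoothed pixel noise creates spurious prominent maxima.
* **Sub-pixel refinement.** Each accepted peak is refined by a
  baseline-subtracted intensity centroid over a ±2σ window, restoring
  genuinely sub-pixel displacement resolution.

The published parameters are kept as stated: peaks closer than 3 μm
coalesce by single linkage to their unweighted centroid (merge when the gap
is strictly below the radius); links use per-source nearest neighbour with
a hard 30 μm cutoff (many-to-one allowed; a mutual-nearest option exists,
off by default); linking is only between consecutive frames, no gap
closing; direction is majority rule, counter-flow samples are then removed,
and an exact tie leaves the direction undetermined with nothing removed and
the vessel flagged. The prominence threshold (0.2 of the profile dynamic
range) is not stated in the source procedure and is exposed as a
configuration knob. The nearest-neighbour rule, like the original, assumes
per-frame displacements smaller than half the inter-cell spacing; the
movie generator's defaults respect that regime, and cells that wrap around
the synthetic vessel produce exactly the counter-flow artifacts the
majority-rule filter exists to remove.

## 7. Colocalization: numerical choices

Otsu thresholds are found by exhaustive search over observed intensity
levels (vectorized cumulative-moment formulation), which guarantees the
global optimum for up to 4 classes; thresholds are reported as the lowest
intensity of each upper class and `binarize()` takes foreground as
intensity ≥ threshold. Histograms use the native integer levels (256 for
8-bit, 65,536 for 16-bit). Connected components default to 8-connectivity
(the source is silent; 4 is available), and the 20–500 px area window is
inclusive at both ends. "Manually selected" threshold level becomes an
explicit integer per channel, defaulting to the highest (brightest) level.

## 8. Degenerate inputs and tie-breaks

* Constant images raise a degenerate-histogram error (surfaced with
  guidance by `cmd_coloc`).
* Zero-length traces and empty profiles are errors; a flat profile yields
  zero detections.
* A cell arriving at a node with no positive-flux outlet is removed with a
  warning (logged count); a cell on a zero-velocity edge simply waits.
* Velocity-sample sign ties: direction undetermined, all samples kept,
  vessel flagged.
* Single-frame movies yield densities with zero velocity samples and a
  warning, since speed needs two frames.

## 9. Known limitations

* No pulsatile flow, non-Newtonian rheology, oxygen transport, or 3D
  geometry; WSS is two-regime per vessel, not spatially resolved along it.
* The biological effect sizes of the original study (fold changes in
  reporter activity, proliferation counts, loop-formation proportions) are
  out of scope, as are its wet-lab procedures; published headline numbers
  that depend on unpublished network parameters (e.g. a 57% pressure-drop
  increase, the 1.1–5.4 dyne/cm² threshold range) are not targets — the
  pipeline reports its own values on its own stated world.
* The transport model treats cells as non-interacting except through the
  optional occlusion feedback; no cell–cell collisions or trains.
* Multilevel Otsu beyond 4 classes would need the standard dynamic-program
  speedup; it is simply not offered.
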