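---
title: "Modeling and measuring cell reorientation under cyclic stretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring cell reorientation under cyclic stretch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclostretch)
```

## The problem

Adherent cells on a uniaxially, cyclically stretched elastic substrate
reorient perpendicular ("transverse") to the direction of stretching. The
phenomenon is driven not by the stretch itself but by what happens during the
*relaxation* phase of each cycle: on release of strain the cell retracts
globally and immediately, and during the following relaxation window it
extends — persistently in the transverse direction, and with a
progressively weakening rate in the axial direction. Accumulated over
hundreds of cycles, these stepwise events reorient the cell.

`cyclostretch` packages the measurement toolchain used to study this process
(difference imaging with a diagonal quadrant partition, moment-ellipse
morphometrics, fiducial-grid strain measurement) together with a synthetic
generator of cell-mask time courses that implements the per-cycle
retraction/protrusion model. Because the raw time-lapse recordings behind
such experiments are rarely shared, the generator is a first-class module:
it defines reference inputs with exact ground truth against which every
measurement stage can be validated.

## Measurement conventions

All images are matrices indexed `[row, col]`; x runs along columns and is
the default stretch (axial) axis. Lengths are in micrometres via
`pixel_size`, areas in µm², strains are dimensionless engineering strains.

**Orientation index.** A cell mask is summarized by its moment-equivalent
ellipse (the ellipse with the mask's area-normalized second central
moments). The orientation index is $\cos 2\theta$ with $\theta$ the angle
between the major axis and a reference axis. Two conventions coexist in the
field: measured from the stretch axis (+1 = aligned with stretching, −1 =
transverse; the package default) and measured from the transverse axis
(sign flipped). `orientation_index(fit, reference=)` exposes both. For
nearly circular masks (eccentricity < 0.01) the angle is undefined; the
package reports 0 by a documented tie-break, so a perfect disc has index
+1. This is a labeling convention, not a claim about the cell.

**Rectangle lengths.** "Axial length" and "transverse length" are the
extents of the stretch-axis-aligned bounding rectangle — not a rotated
minimum-area rectangle — because the quantities of interest are lengths
*along* the two fixed laboratory directions.

**Quadrant partition.** The cell is split into two axial and two transverse
sectors by the ±45° diagonals through the foreground centroid. Pixels
exactly on a diagonal are assigned to the axial sectors (symmetrically by
the sign of the axial offset), and the centroid pixel to `axial_plus`, so
the partition is a total function. The partition is anchored in the
*earlier* frame of each difference pair: the reference state against which
change is measured.

**Difference maps.** For binary masks the protrusion/retraction map is the
exact set difference (+1 gained, −1 lost), so per-quadrant sums conserve
total area change exactly in pixels. Intensity input is supported on a
best-effort basis via a user-supplied threshold after median background
centring; binary-mask mode is the reference behavior.

**Normalization.** Net quadrant changes are normalized by the mean
spreading area of the two frames of the pair (default), with the initial
area selectable instead (`normalization = "initial_area"`); the two differ
only by the slow drift of cell area between frames.

## The per-cycle dynamics model

The generator formalizes the qualitative per-cycle phenomenology as the
simplest rate laws with named constants:

* **Retraction.** On each release, a fraction
  $r(n) = r_\infty + (r_0 - r_\infty)\,e^{-(n-1)/n_d}$
  of the current spreading area is removed uniformly around the perimeter
  (implemented as removal of exactly `round(r·A)` pixels in increasing
  distance-to-background order — a calibrated erosion). The transient
  $r_0 \to$ floor captures the strong first-cycle response that decays
  precipitously over a few cycles; the small persistent floor $r_\infty$
  is needed for a late-time balance in which transverse extension wins
  only modestly over retraction. With $r_\infty = 0$ the pure exponential
  law is recovered.
* **Protrusion.** During relaxation, area is added at rate $p_T$ (fraction
  of spreading area per second) split between the two transverse sectors,
  and $p_A(t) = p_{A0}\,e^{-t/\tau_A}$ ($t$ = cumulative stretching time,
  minutes) split between the axial sectors. Growth is realized as
  ring-by-ring boundary dilation restricted to the sector — which provably
  preserves 4-connectivity — with partial rings filled nearest the sector
  axis first, plus seeded angular noise of amplitude `noise_sigma` (µm)
  that roughens the boundary. Tip-weighted filling reflects that
  lamellipodial extension concentrates at the cell poles.
* **During stretching** the cell passively follows the substrate: frames
  acquired mid-stretch are the current mask under the affine substrate map
  (axial factor $1+\varepsilon$, transverse factor
  $1 - 0.15\,\varepsilon$ by default, the Poisson-like sign being
  configurable since only the magnitude ratio is constrained by the
  device). No active dynamics occur in the stretch window.

Because pixel counts are exact, every simulated cycle satisfies the mass
balance `area change = protrusion − retraction` identically — a property
the test suite asserts.

### Default parameters

The literature gives no numeric values for $r_0, p_T, p_{A0}$; they are
model constants calibrated once, by a length/area balance argument, to
reproduce the qualitative control phenotype at the default geometry (50 µm
cell radius, 0.5 µm/pixel, 512×512 frames, 15% strain at 0.5 Hz, square
wave):

| condition | $r_0$ | $n_d$ | $r_\infty$ | $p_T$ (/s) | $p_{A0}$ (/s) | $\tau_A$ (min) |
|---|---|---|---|---|---|---|
| control | 0.05 | 3 | 1.1e−4 | 2.4e−4 | 0.8e−4 | 10 |
| blebbistatin | 0.002 | 3 | 0 | 1e−5 | 1.0e−4 | 900 |
| nocodazole | 0.08 | 3 | 1.4e−4 | 3.2e−4 | 0.8e−4 | 6 |
| nocodazole + blebbistatin | 0.001 | 3 | 0 | 0 | 1.4e−4 | 900 |

The balance argument, in outline: uniform removal of a total area fraction
$\Sigma r$ from a disc of radius $R$ shortens both rectangle lengths by
$\approx \Sigma r \cdot R$, while adding an area fraction $P$ in a sector
pair lengthens that axis by $\approx P \cdot A / w$ ($w \approx \sqrt2 R$
the sector chord). The control values put the 90-min totals in the regime
axial-shortening > 0, transverse-elongation > 0, with the axial loss
concentrated in the first half (transient retraction plus decaying axial
protrusion) and a spreading-area minimum early in the run followed by
recovery — the two-phase structure seen in experiments. The drug presets
keep only the orderings that are experimentally established: myosin II
inhibition suppresses retraction and transverse protrusion while sustaining
axial protrusion (axial orientation results); microtubule disassembly
enhances retraction and transverse protrusion (amplified transverse
reorientation); the combination amplifies the blebbistatin pattern.

What the generator deliberately does **not** emulate: phase-contrast
texture (masks only), focal adhesions or cytoskeletal substructure,
cell–cell contacts (isolated cells only), migration, and biological
cell-to-cell rate variability beyond initial-shape randomness. Passing
tests therefore validate the *measurement* chain and the *logic* of the
per-cycle model, not any quantitative biological rate.

### Initial cells

`make_initial_cell()` perturbs a disc radius with low-order (modes 2–5)
random Fourier coefficients of relative amplitude `irregularity` (default
0.06 in the pipeline), giving gently anisotropic cells with random
initial long-axis directions — enough that a population's orientation
index starts away from saturation and moves over the run.

## Micropattern strain measurement

The fiducial module renders the standard 50 µm squares at 100 µm pitch as
bead fluorescence: ~1 bead/µm² with placement jitter, mapped by the affine
substrate strain, perturbed by Gaussian localization noise, splatted
bilinearly and blurred by a 0.4 µm PSF. `detect_grid()` re-measures the
pattern via Otsu thresholding and component labeling, rejecting
border-touching components and area outliers (>50% from the median).

Strain is computed from the change in lattice *pitch* (center-to-center
spacing), not square side lengths: centroid spacing is insensitive to the
threshold-dependent bias that affects extents, while the side lengths remain
available as a cross-check. Square matching across frames reduces to a
count check plus row-major ordering, which is sufficient below 20% strain
at 100 µm pitch (displacements stay well under half a pitch after removing
the mean). Residual strain after relaxation is the same computation on a
before/after pair and is reported as a magnitude percentage.

## Numerical choices and degenerate inputs

* Retraction tie-break: pixels of equal distance are removed in linear
  index order (deterministic). If a removal disconnects the mask, detached
  fragments are also removed and counted as retracted area, keeping both
  the single-component invariant and the exact mass balance.
* Protrusion quotas are split ceiling/floor between the paired sectors;
  if a sector's growth ring is exhausted against the frame border the step
  aborts with a dynamics error rather than silently clipping.
* The affine resampler is inverse-mapped bilinear interpolation about the
  image center; binary masks are re-binarized at 0.5. The map is invertible
  to within one boundary pixel (round-trip Jaccard > 0.98 at 15% strain).
* Angles are stored in degrees and wrapped into (−90°, 90°]; the
  90°-rotation equivariance of the ellipse fit is tested via exact
  transposition.
* Empty masks, border-touching foreground, multi-component masks, blank
  fiducial images, mismatched grids, and schedules referencing missing
  cycles all fail fast with classed, descriptive errors.

## Desk-scale pipeline runs

A faithful 90-minute run at 0.5 Hz is 2700 cycles; the pipeline instead
integrates the rate laws in closed form over each interval between
checkpoints (default {0, 5, 15, 30, 45, 60, 90} min) and applies one
effective dynamics step per interval. The geometric-series partial sum
gives the interval's retraction fraction exactly; protrusion integrals are
exact for the exponential law. Order within an interval (retract, then
protrude) differs from the interleaved truth by less than the per-interval
step size, which is small by construction. Per-cycle quadrant-profile
probes (the retraction and 10-s extension responses at cycles 1 and 2 and
at each checkpoint) are measured on a copy of the state, since one probe
cycle changes the area by < 0.1%. `simulate_timecourse()` provides the
uncompressed per-cycle mode used by the fidelity tests.

Problem sizes in the shipped tests and acceptance runs — 3-cell
populations, 512×512 frames, 6×6 grids at 0.5 µm/pixel — were chosen so a
full three-condition comparison completes in well under a minute while
every length scale (cell radius ≫ pixel, pitch ≫ localization noise)
stays in a realistic regime.

## Known limitations

* The 10-s extension probes report the measurement-window convention;
  actual per-cycle extension is the relax-duration/window fraction of the
  reported values (`relaxation_fraction_check()` documents exactly this).
* Compressed runs do not model within-interval fluctuations, so per-cycle
  statistics beyond the probed checkpoints require the uncompressed mode.
* The transverse rectangle length can dip during the first few cycles
  while the retraction transient still dominates the constant transverse
  protrusion; monotone transverse growth is a steady-cycling property.
* Intensity-mode difference imaging has no principled default threshold;
  it is parameterized but not validated against real phase-contrast data.
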