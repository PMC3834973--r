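---
title: "MR-guided metal artifact reduction: models, parameters and design choices"
author: "mrmar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR-guided metal artifact reduction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmar)
```

## The problem

High-density dental metal absorbs low-energy X-ray photons nearly
completely. Projection bins whose rays cross an implant measure a signal
dominated by beam hardening and photon starvation rather than by tissue
attenuation, and filtered back-projection (FBP) propagates that
inconsistency along every contributing ray: the reconstruction shows
bright and dark streaks fanning out from the metal. Sinogram-domain
repairs (interpolating over the "metal trace") must invent the missing
line integrals from their neighbors; image-domain repairs must invent
plausible tissue values. This package implements an image-domain method
whose source of missing information is a co-registered MR slice: dental
metal does not destroy the MR image, so MR similarity can say *which*
uncorrupted CT pixels are tissue-equivalent to each corrupted one.

## The correction model

Given CT slice $f$, co-registered MR slice $g$, and a corrupted-pixel mask
$M$, each corrupted pixel $p$ is repaired from the window $W(p)$ (default
$5\times5$) around it:

1. candidates $q \in W(p)\setminus\{p\}$ are ranked by $|g(q) - g(p)|$,
   ties broken by row-major scan order;
2. the first candidate with $M(q) = 0$ donates its CT value:
   $f'(p) \leftarrow f(q)$;
3. pixels with $M = 0$ are never altered (bit-exact contract).

Donor values are read from the pre-pass CT, so the result does not depend
on the scan order within a pass. A window can be entirely corrupted; such
pixels are retried in later passes (pixels corrected in pass $k$ are legal
donors in pass $k+1$, up to `maxPasses = 5`), and any survivors are filled
with their window mean (`fallback = "neighborhood_mean"`) or left, per
configuration. The literal one-pass loop "search until an uncorrupted
pixel is found" does not terminate when the whole window is corrupted;
bounded passes plus a fallback make the procedure total while agreeing
with the one-pass behavior wherever that behavior is defined. Border
pixels see the image with its outer two rows/columns replicated.

The similarity metric is the absolute MR intensity difference to the MR
value at the window center — the simplest reading of "most similar", and
deliberately MR-vs-MR (the CT center value is corrupted and carries no
usable information). The center position itself is never a candidate.

## Detection

Detection runs on the reconstructed gray values with no calibration
assumption. The slice is winsorized at `clipQuantiles` and normalized to
$[0,1]$; quantiles are affine-equivariant, so the resulting mask is
invariant to any affine rescaling of the input intensities. Winsorization
plays the role display windowing plays for clinical gray-scale CT: metal
and the most severe streaks saturate at the top of the scale, dark streak
troughs at the bottom. Without it, metal stretches the intensity range so
far that the top Otsu classes chase the extreme metal tail and the
streaks themselves land in the tissue classes; we measured the fraction
of truly corrupted pixels recoverable by any top/bottom class rule to
collapse to roughly a quarter in that regime.

The histogram (256 bins, half-open bins, last bin closed) is split into
`nClasses = 50` classes by multi-level Otsu thresholding, solved *exactly*
by dynamic programming over contiguous bin ranges with precomputed
cumulative sums — not by greedy or recursive splitting — so the
implementation can be tested for equality against exhaustive enumeration
on small instances. For two classes it reduces to classic Otsu. The mask
is then

* the `brightK` highest classes (metal plus bright streaks), plus
* the `darkK` lowest classes *inside the body support* (dark streaks).

The body support is the largest connected component of pixels at or above
`bodyThreshold` (0.1) with holes filled. Dark values outside the body are
air and are already correct; restoring them would be wasted work.

`brightK = 4`, `darkK = 3` and `clipQuantiles = c(0.01, 0.96)` were
calibrated once on the package's own simulator: a grid over class counts
and clip quantiles was scored by the corrected image's RMS error on the
ground-truth corrupted region (not by mask overlap alone — replacing a
healthy pixel with a tissue-matched donor is nearly free, while a
corrupted donor is costly, so recall matters more than precision), and
among near-optimal settings the most parsimonious mask was chosen. The
class count of 50 follows the same empirical route the method's authors
describe for their clinical images.

## The validation apparatus

No clinical data ships with the package; a simulator defines the study
conditions.

**Geometry and reconstruction.** 2D parallel beam: 180 views at 1° over
$[0, 180)$, detector pitch equal to the pixel spacing, bin count just
above the image diagonal. The forward projector integrates bilinearly at
half-pixel steps; FBP uses the discrete band-limited Ram-Lak impulse
response ($h[0] = 1/4$, $h[k] = -1/(\pi k)^2$ for odd $k$), with an
optional Hann apodization flag (default off — sharper streaks make
detection realistically hard). The parallel-beam downscoping keeps the
artifact phenomenology (streaks along rays through metal) while admitting
closed-form oracles: a uniform disk's projection is the chord length
$2\sqrt{r^2 - s^2}$, and the FBP∘FP round trip of a smooth 128×128
phantom stays below 5% relative RMSE inside the reconstruction circle
(measured ≈ 0.7%). Tangent bins are excluded from the chord comparison:
a rasterized disk differs from the analytic disk at first order in pixel
size exactly there, for any projector.

**Phantom.** A dental-level axial slice on the normalized scale (air ≈ 0,
soft tissue ≈ 0.3, bone ≈ 0.7): soft-tissue outline, thin cranial bone
ring, interior soft tissue at 0.35, dark oral airway, and a U-shaped arch
of eight tooth ellipses. The tooth row matters: the standard
linear-interpolation baseline only exhibits its characteristic failure —
secondary artifacts from bridging projections across *structured* anatomy
— when the metal trace crosses structure. Implants are metal disks
(intensity 3.0, radii 2–4 px at 128×128, scaling with the clinical matrix)
placed at seeded tooth positions: dental fillings sit in teeth.

**Corruption model.** On metal-trace bins the line integral $v$ becomes
$\min(c\,(v/c)^\gamma,\; c)$ with $\gamma = 2$ and cap $c$ defaulting to
0.95 of the maximum clean line integral through metal (power law = beam
hardening under-measurement; clip = photon starvation), followed by
Poisson counting noise at $I_0 = 10^5$ photons over the whole sinogram
with attenuation scale `muPerUnit = 0.04` per unit line integral. The
trace is defined by at least half a pixel of metal path
(`traceThreshold = 0.5`): with a zero threshold the projector's bilinear
footprint flags rays that barely graze the metal, and the power law would
then corrupt essentially clean bins. All randomness is seeded;
re-runs are bit-identical.

**Pseudo-MR.** Synthesized from the *clean* anatomy — the clinical premise
is that dental metal leaves the MR usable — by a tissue-level remap (bone
and teeth dark, soft tissue bright: ct levels (0, 0.05, 0.3, 0.35, 0.7) →
mr levels (0.02, 0.06, 0.85, 0.95, 0.15)), Gaussian smoothing (σ = 1 px),
additive Gaussian noise (σ = 0.02), an optional susceptibility signal-void
halo around metal (`voidRadius`, default off), and an optional rigid shift
to study misregistration (default off). What the pseudo-MR does *not*
emulate: genuine MR contrast mechanisms, coil inhomogeneity, anatomy
visible on MR but not CT, and non-rigid misregistration. Passing tests
therefore show the pipeline's mechanics are correct under ideal
registration and informative MR contrast — not that the method survives
every clinical MR.

## The simulation study

`runStudy()` crosses implant counts (default 1–3) with seeds (default
0–4). Per condition it scores three reconstructions — uncorrected, LI
(per-view linear interpolation over the metal trace of the *true* metal
mask, then FBP), and the proposed detect-plus-correct pipeline — against
the FBP round trip of the clean phantom, so reconstruction discretization
error is charged to no method. The artifact ROI is the detected mask minus
true metal, identical for all methods within a condition; metal pixels are
excluded because no method is asked to invent metal values. With zero
implants there is nothing to correct and all methods report the identical
image.

Two empirical regularities from this study are worth stating plainly.
First, the LI baseline's artifact-ROI error grows with the implant count
(the merged traces get wider and cross more of the tooth row). Second, in
this apparatus LI remains *stronger* than the image-domain method at 1–3
implants: the corruption model confines all damage to the trace of an
exactly known metal mask, which makes sinogram interpolation a near-oracle
repair, while the window-based correction is bounded below by the residual
corruption of its donors. A perfect-mask experiment isolates the
correction engine from detection: with the ground-truth corrupted mask and
noiseless pseudo-MR, correction removes ≈ 80% of the artifact-ROI RMS
error. The gap to the full pipeline is therefore a detection problem, and
the package reports both numbers rather than hiding the comparison.

## Numerical choices and degenerate inputs

* Histogram bins are half-open, last bin closed; class labels count
  thresholds strictly below the value; similarity ties in the donor search
  break by row-major order — all deterministic across platforms.
* A constant image has no histogram-based threshold; detection refuses it
  ("degenerate histogram").
* An all-corrupted mask has no donors anywhere and is refused.
* Views that are entirely metal trace cannot be interpolated and are
  refused.
* Problem sizes: tests and the acceptance script run the study at 128×128
  with 180 views and 5 seeds, the same grid the method's defaults were
  designed for; 512×512 mirrors the clinical matrix and is supported
  throughout.

## Known limitations

* Per-slice 2D only; the parallel-beam geometry is a deliberate
  downscoping of clinical cone-beam acquisitions.
* Detection is histogram-global: streak pixels whose intensity falls
  inside the tissue range are invisible to any class-selection rule, which
  bounds the full pipeline's recall.
* The evaluation compares against the clean FBP round trip of the same
  simulator that generated the corruption; conclusions about clinical
  cone-beam data, real MR contrast, or registration error are out of
  reach of this test bed.
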