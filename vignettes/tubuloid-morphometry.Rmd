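---
title: "Tubuloid morphometry: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tubuloid morphometry: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubulomorph)
```

## The measurement problem

3D tubuloid cultures contain three morphological classes: globular,
non-differentiated *prestructures*; *spheroids* with a circular clear lumen;
and *tubules* with a slit-like lumen roughly 50 µm across. After an induced
cystogenic insult, tracked tubules drift toward spherical, cyst-like shapes
over about a week. The quantities of interest are per-structure region
statistics (bounding-box width, height, area), a scalar "likeness to a
sphere" score, class compositions, per-structure identity over time, the
fraction of structures that switched a red→green membrane reporter, and
paired before/after statistics.

## Shape model: the capsule

Every structure is modelled in 2-D projection as a **capsule** (stadium): a
rectangle of width $w$ and length $L-w$ capped by two semicircles of
diameter $w$, with filled area

$$A_f = w\,(L-w) + \pi (w/2)^2 .$$

At $L = w$ this degrades continuously to a disk, so one parameterization
spans spheroids and tubules. The lumen is the *inward offset* of the outer
capsule at fraction $f$ of the width: a capsule of width $f w$ and length
$L-(1-f)w$ on the same centreline, area $f w (L-w) + \pi (f w/2)^2$. This
leaves a uniform wall and produces exactly the observed phenomenology —
circular lumens in round structures, slit-like lumens in elongated ones —
from a single parameter. Prestructures have $f = 0$.

## The spherical-agreement score

From axis-aligned bounding-box dimensions $w, h$ and measured area $A$:

$$r = \tfrac12\min(w,h),\quad A_s = \pi r^2,\quad
d = \frac{|A - A_s|}{A_s},\quad S = \max(0,\,1-d).$$

Design notes:

* **Convention.** The published description of this family of scores states
  a reference area of $2\pi r^2$ with $r$ equal to the full shortest
  dimension, on a scale from 1 (spheroid) to 0 (tubule). No literal reading
  of that formula can place a perfect circle at 1, so the package's default
  (`normalized`) uses the unique simple reading consistent with the stated
  endpoints — the inscribed disk of diameter $\min(w,h)$ — and retains the
  literal recipe as `convention = "as_printed"` for transparency.
* **Denominator.** The percent difference divides by the reference area
  $A_s$; dividing by the measured area instead is available via
  `denominator = "measured"`.
* **Clamping.** $S$ is clamped at 0 rather than renormalised, so
  arbitrarily long tubules saturate; for a lumen-free capsule the clamp is
  reached at $L/w = 1 + \pi/4 \approx 1.785$. Canonical tubules therefore
  sit exactly at the tubule endpoint of the scale.
* **Area choice.** Pipeline morphometry scores the *filled* region area
  (wall plus lumen), matching what a drawn-ROI region measurement reports;
  the wall-only mask area is also carried in every record.

Properties exercised by the tests: $S(\text{disk}) = 1$ exactly; $S$ is
monotone non-increasing in $L$ at fixed $w$ and strictly decreasing until
the clamp; $S$ is scale-invariant; analytic and rasterized scores agree
within 0.05.

## Measurement conventions

* Bounding boxes are **axis-aligned**, as drawn-ROI statistics would be.
  Rotated structures measure wider boxes; the generator reports axis-aligned
  truth for comparability and keeps default orientations within ±0.05 rad of
  the axes so bbox descriptors remain meaningful. Strongly rotated tubules
  fall to the `ambiguous` class rather than being miscalled — a documented
  limitation of bbox-based descriptors, not of the generator.
* Pixel indexing is 0-based half-open internally; reported dimensions are
  inclusive in µm (a single pixel measures one pixel-size across). Area is
  pixel count × pixel area.
* Calibrations default to 1.6 µm/px (population, "4×" regime) and
  0.32 µm/px (individual, "20×" regime); both are configurable, and every
  run records its calibration.

## Classification thresholds

All cutoffs are declared operationalizations of descriptive criteria, kept
in `classification_thresholds()` and echoed in output metadata: lumen area
fraction ≥ 0.05 for a lumen to count; lumen circularity ≥ 0.6 with aspect
ratio ≤ 1.5 for spheroids; aspect ratio ≥ 2.0 with minor dimension in
30–80 µm for tubules; first matching rule wins; everything else is
`ambiguous` — an explicit reject class added because a rule-based system
needs one (the original blinded manual scheme had none). Wall thickness
("1–2 cells") is not used: the generator has no nuclei channel.

## Tracking

Greedy nearest-centroid linking in ascending distance order with a 50 µm
gate (gel-embedded structures are nearly stationary; the generator's default
centroid drift is a 4 µm/timepoint random walk, far below the gate). Ties
break deterministically by smaller structure id. A track interrupted at one
timepoint may bridge the gap if the displacement over the doubled interval
is within 1.5× the gate. Greedy matching is a documented simplification:
under heavy crowding or crossings an optimal assignment would be needed.

## Reporter quantification

A pixel is positive in a channel when its intensity exceeds the
background-derived threshold (mean + 2 sd of intensity outside all masks;
the interactive plugin this emulates does not publish its rule, so ours is
declared and configurable). Double-positive pixels count in both channels
by default (membrane overlap realism); `winner_takes_all` assigns each
pixel to its brighter channel. A structure with fewer than 10% positive
pixels is flagged `no_signal` (reporter-negative, e.g. prestructures) and
never called converted; otherwise the structure is called converted when
the green fraction reaches 0.5 — an invented, reported convention.

## Statistical layer

Paired and pooled-variance two-sample Student *t*-tests are implemented from
their defining formulas with tail probabilities from R's *t* distribution,
and are cross-checked in the tests against `stats::t.test` to 1e-10. The
paper-style tracked analysis (`fig5_analysis`) scores each complete track at
the last pre-induction timepoint and at the evaluation timepoint (default
168 h; the source report is internally inconsistent between 72 h and a
168 h course, so the timepoint is an explicit parameter), then runs one
two-tailed paired test per arm. Zero-variance differences raise a
degenerate-input error rather than returning a p-value. No multiplicity
adjustment is applied at this layer.

## What the generator emulates — and what it does not

Emulated: field-of-view mixtures of the three classes with non-overlapping
placement; two-arm induction design with pre- and post-induction imaging at
0/48/96/168 h; mosaic conversion restricted to differentiated structures
with per-structure probability 0.8 and per-pixel mosaicism 0.85; exponential
relaxation of elongation $E(t) = 1 + (E_0-1)e^{-\lambda (t-t_0)}$ for
converted structures (default $\lambda = 0.00625\,\mathrm{h^{-1}}$, chosen
once so that ~65% of excess elongation is lost by 168 h — the published
assay reports no numeric effect size, so this magnitude is a simulation
choice, not an inference); multiplicative log-normal geometric jitter
(3%/timepoint); additive Gaussian camera noise on a 16-bit scale; per-pixel
ground-truth labels.

Not emulated: true transmitted-light bright-field texture (structures are
rendered bright-on-dark so thresholding is deterministic); 3-D volume and
optical PSF; cell walls as discrete cells; touching/merging structures;
division, fusion or death; gene expression. Passing tests therefore
demonstrate correctness of the measurement and statistical machinery under
a faithful geometric model — they do not certify segmentation performance
on real transmitted-light micrographs, where thresholding is the step that
would need adaptation.

The default tracked-arm composition is 10 spheroids + 10 tubules per arm
(20 differentiated structures, mirroring the assay's design). Tubules start
at the clamped score 0, so under the no-effect null their before/after
differences contribute exact zeros; the spheroid half keeps the paired
test's difference distribution continuous. The test suite verifies the
resulting operating characteristics empirically: type-I rate within
[0.025, 0.075] at nominal 0.05 over 1000 seeds, and power ≥ 80% at the
default effect with n = 20.

## Numerical choices and degenerate inputs

* Otsu threshold on the normalised bright-field channel; components below
  500 µm² are dropped as debris (configurable).
* Focus proxy: mean gradient magnitude on the mask rim normalised by
  object/background contrast; the default cutoff 0.2 was calibrated on the
  generator so Gaussian defocus of σ ≥ 3 px is excluded while sharp
  renders are kept (σ = 0 scores ≈ 0.42–0.46, σ = 3 ≈ 0.15–0.18).
* Lumen circularity is capped at 1.1 to absorb raster perimeter error.
* Blank fields segment to an empty record set (not an error); uncalibrated
  images, empty masks, non-positive dimensions, zero-variance samples and
  mixed score conventions raise errors.
* All randomness flows from user-supplied seeds; identical configuration
  and seed reproduce byte-identical output bundles.

## Problem sizes used in the checks

The packaged checks run at desk scale by design: 100 random shapes for the
raster/analytic oracle, 300 noise-free structures for classifier recovery,
50 structures × 4 timepoints × 10 seeds for tracking, 100-seed power and
1000-seed type-I sweeps at the ground-truth level (the imaging path is
exercised end-to-end separately), and full imaging runs of 2 arms × 20
structures × 4 timepoints for the determinism and headline analyses.
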