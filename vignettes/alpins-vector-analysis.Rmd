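---
title: "Alpins vector analysis of astigmatism outcomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpins vector analysis of astigmatism outcomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astigvec)
```

## The model

A cylinder reading is a magnitude $M$ (diopters) at an axis
$\theta \in (0, 180]$ degrees. Because the axis is 180°-periodic,
readings cannot be averaged or subtracted directly: two cylinders at 1°
and 179° are nearly identical, not 178° apart. The doubled-angle
decomposition

$$x = M\cos 2\theta, \qquad y = M\sin 2\theta$$

maps astigmatism onto an ordinary plane where vectors add component-wise;
the inverse is $M = \sqrt{x^2+y^2}$, $\theta = \tfrac12\,\mathrm{atan2}(y, x)$
wrapped into $(0,180]$. The zero vector is given axis 180 by convention —
the axis of a 0 D cylinder carries no information.

Before any vector arithmetic two normalizations are applied, in either
order (they commute, which the test suite verifies):

1. **Positive-cylinder conversion.** A negative-cylinder reading
   $(-M, \theta)$ denotes the same correction as $(+M, \theta + 90)$;
   axes are reported in $(0,180]$, so $-2.00 \times 90$ becomes
   $+2.00 \times 180$ and $-1.00 \times 180$ becomes $+1.00 \times 90$.
2. **Left-eye mirroring.** OS axes are reflected, $\theta \to 180-\theta$,
   so that cyclotorsion-like errors, which are mirror-symmetric between
   eyes, do not cancel when a cohort mixes OD and OS. Mirroring is applied
   once, before all computation *and* plotting, so every reported and drawn
   quantity lives in one consistent frame.

Per eye, with an emmetropic target (the input format carries no target
column, so emmetropia is the only supported target):

- $\mathrm{TIA} = $ preoperative vector (the intended change is the full
  preoperative astigmatism);
- $\mathrm{SIA} = \mathrm{preop} - \mathrm{postop}$ in doubled-angle
  rectangular coordinates, magnitude $\sqrt{SIA_x^2 + SIA_y^2}$;
- $\mathrm{DV} = \mathrm{TIA} - \mathrm{SIA}$, which under emmetropia
  collapses algebraically to the postoperative vector — an identity the
  tests exploit as an oracle;
- $\mathrm{CI} = |\mathrm{SIA}| / |\mathrm{TIA}|$, undefined (NA) when
  $|\mathrm{TIA}| = 0$.

The sign convention for SIA is the subtraction written above. Some of the
wider literature defines the achieved change with the opposite sign; the
convention used here is self-consistent with $\mathrm{DV} =
\mathrm{TIA} - \mathrm{SIA}$ and makes DV equal the residual
postoperative astigmatism, which is what the DV graph is meant to show.

Cohort summaries are computed on the doubled-angle plane: arithmetic means
and sample standard deviations ($n-1$ denominator; cohorts are samples,
matching common clinical reporting; SDs are defined as 0 when $n = 1$) of
$x$ and $y$, and the *vector mean* — the polar vector recovered from
$(\bar x, \bar y)$ — which the plots draw as a red diamond. The CI panel
reports a geometric mean instead, which is only defined over strictly
positive values: undefined CIs (zero-TIA eyes) and zero CIs (log
undefined) are excluded and the excluded count reported. Zero-TIA eyes
remain in the TIA/SIA/DV graphs with magnitude 0; nothing is ever
auto-discarded for having 0.00 D of astigmatism.

## Input handling

Files have five columns and no header: eye (`OD`/`OS`), preop magnitude,
preop axis, postop magnitude, postop axis. Two deliberate strictness
choices:

- The reader never silently skips a first row. A first row with no
  OD/OS label and no numeric cells is almost certainly a header, and
  silently dropping it would hide data loss, so it is an error with a
  "remove the header row" hint.
- Comma-decimal numbers (`1,50`) are a notation error, not missing data,
  and produce an explicit error (in CSV they additionally split the field,
  so the column-count error carries the same hint).

Any other row with a missing, blank or non-numeric cell, a bad eye label,
an axis outside $[0,180]$ or a magnitude at or beyond a configurable 30 D
sanity bound is discarded, counted, and logged with its 1-based row number
and reason. Axis 0 and axis 180 are both accepted on input and treated as
the same meridian. XLSX is the reference dialect (read via readxl); CSV is
supported for convenience. The XLSX writer produces a minimal
single-sheet workbook with fixed archive timestamps, so identical data
yield byte-identical files.

## The four graphs

Each graph is an upper semicircle — single-angle data occupy only 0–180°,
with 0° at the right and 180° at the left. Shaded sectors mark
orientation: blue against-the-rule bands at 0–30° and 150–180°, a red
with-the-rule band at 60–120°, unshaded oblique bands at 30–60° and
120–150°. The classifier that backs the shading treats the exact boundary
angles (30, 60, 120, 150) as oblique by default — the shaded bands are
described by their interiors and exact ties are measurement artifacts —
but exposes the policy as a parameter. Each eye is a black radial line
ending in a blue circle; the vector mean is a red diamond on the TIA, SIA
and DV graphs and intentionally absent from the CI graph, per reporting
standards. Styling (colors, fonts, 25% shade opacity) is fixed rather than
configurable so figures remain comparable across studies.

Two conventions the standards leave open, chosen here and isolated so they
could be changed:

- **CI point placement.** The CI graph needs an angle for each
  dimensionless CI value; each eye's CI is drawn at its TIA axis (the
  intended-treatment meridian), which groups eyes by the astigmatism type
  that was treated.
- **Radial limits.** The smallest limit covering all points, in 0.5 D
  steps for the vector graphs and on a 0.5, 1, 2, 4, … ladder for CI;
  four radial gridlines and a numeric scale beneath the graph, chosen for
  legibility. A spec whose points exceed its limit is refused before
  rendering, so markers are never clipped.

Figures export as TIFF at 300 dpi by default ("high-resolution" print
quality) into a folder named after the data file, one deterministic file
per graph (`TIA.tif`, …).

## The synthetic-cohort generator

`generate_cohort()` emulates demonstration cohorts of the three
astigmatism types (WTR, ATR, oblique; 25 eyes each by default) with a
known ground truth. Per eye: side drawn with OS fraction 0.5; preop
magnitude from a normal truncated at 0.25 D; preop axis from a wrapped
normal around the sector center (90/180/45°); the applied treatment has
magnitude `correction_ratio` × TIA at the intended axis perturbed by
normal axis noise, and the postoperative reading is the doubled-angle
remainder `preop − treatment`, emitted in negative-cylinder notation by
default. Defaults — magnitude mean 1.50 D, SD 0.50 D, axis spread SD 5°,
correction ratio 0.95, axis noise SD 5° — were chosen once as typical of
laser-refractive-surgery cohorts: cylinder mostly 0.75–2.5 D, axes tightly
grouped per type, a slight average undercorrection.

Because the treatment magnitude is constructed as an exact multiple of the
TIA magnitude, every defined CI equals the correction ratio exactly
(before rounding) *regardless of axis noise* — axis error moves the DV,
not the SIA magnitude. Clinical rounding (magnitudes to 0.25 D, axes to
whole degrees, applied after outcome construction) is what perturbs
recovered CIs in realistic output; the tests therefore check exact
recovery with rounding disabled and statistical recovery (geometric mean
within ±0.02 at n = 500 over 20 seeds) with rounding enabled. Problem
sizes in the suite (10⁴-vector property sweeps, 20 × 500-eye recovery
runs, three 25-eye end-to-end cohorts) keep the full suite under a
minute while exercising every invariant.

What the generator does **not** model: spheres and spherical equivalent,
vertex-distance (spectacle-to-corneal-plane) conversion, healing dynamics,
eye-to-eye correlation within patients, or surgeon- and platform-specific
bias. Passing tests on synthetic cohorts show the vector arithmetic,
summaries and plots are correct under the stated generative model; they do
not validate any clinical claim about real populations.

## Numerical notes

- Trigonometry uses `cospi`/`sinpi`, so cardinal meridians are exact:
  converting 1.00 D at 90° gives $(-1, 0)$ with no rounding residue.
- Polar ↔ rectangular round trips are identity to 1e−9 D and 1e−7 degrees
  (property-tested over 10⁴ random vectors); SIA magnitudes agree with the
  independent law-of-cosines form
  $\sqrt{M_1^2 + M_2^2 - 2M_1M_2\cos 2\Delta\theta}$ to 1e−9.
- Numbers are written to disk in the shortest decimal form that parses
  back to the identical double, so write → read round trips are exact.

## Limitations

The package computes exactly the four quantities above: no
flattening/torque/angle-of-error extensions of the full Alpins system, no
vector analysis tables, no double-angle plots, no corneal-plane
conversion, and no statistical hypothesis tests — the printed means and
SDs are inputs for whatever testing the analyst chooses downstream.
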